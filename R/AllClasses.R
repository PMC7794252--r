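#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowData colData assay
NULL

#' Single-chromosome genome with its sequence
#'
#' Holds one chromosome as an uppercase character string over the A/C/G/T/N
#' alphabet. All genomic coordinates in this package are 0-based, half-open;
#' a TA dinucleotide site is identified by the 0-based position of its T.
#'
#' @slot id Sequence identifier (FASTA header word).
#' @slot sequence Uppercase DNA string.
#' @export
setClass("TnGenome", representation(id = "character", sequence = "character"))

setValidity("TnGenome", function(object) {
  if (length(object@id) != 1L || length(object@sequence) != 1L)
    return("'id' and 'sequence' must each be a single string")
  if (grepl("[^ACGTN]", object@sequence))
    return("sequence contains characters outside A/C/G/T/N")
  TRUE
})

#' Tiling catalog of genes and intergenic regions
#'
#' A set of features (genes plus constructed intergenic regions) that
#' partitions the genome exactly: features are pairwise disjoint and their
#' lengths sum to the genome length. Coordinates are 0-based half-open.
#'
#' @slot features data.frame with columns feature_id, kind ("gene" or
#'   "intergenic"), start, end, strand, length.
#' @slot genomeId Identifier of the genome the catalog indexes.
#' @slot genomeLength Genome length in bp.
#' @export
setClass("FeatureCatalog", representation(
  features = "data.frame", genomeId = "character", genomeLength = "numeric"))

setValidity("FeatureCatalog", function(object) {
  f <- object@features
  need <- c("feature_id", "kind", "start", "end", "strand", "length")
  if (!all(need %in% names(f)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  if (nrow(f) == 0L) return("catalog is empty")
  if (anyDuplicated(f$feature_id)) return("duplicate feature_id")
  o <- order(f$start)
  fo <- f[o, ]
  if (any(fo$start >= fo$end)) return("feature with non-positive length")
  if (fo$start[1L] != 0 || fo$end[nrow(fo)] != object@genomeLength ||
      (nrow(fo) > 1L && any(fo$start[-1L] != fo$end[-nrow(fo)])))
    return("features do not tile [0, genome length) exactly")
  TRUE
})

#' Parameters of a simulated Tn-seq selection screen
#'
#' Bundles every knob of the simulation and analysis: library saturation,
#' per-arm survival, colony bottlenecks, replication, sequencing depth and
#' read structure, and the statistical thresholds.
#'
#' @slot saturation Fraction of TA sites carrying an insertion clone.
#' @slot growthFactorControl Fold CFU change in the control arm.
#' @slot survivalSub Surviving fraction, sub-bactericidal arm.
#' @slot survivalBact Surviving fraction, bactericidal arm.
#' @slot bottlenecks Named colony counts (control, sub, bactericidal).
#' @slot nReplicates Number of biological replicates.
#' @slot readsPerSample Sequencing reads emitted per sample.
#' @slot tagLength Genomic tag length in bp.
#' @slot barcodeLength Group barcode length in bp.
#' @slot readErrorRate Per-base substitution error rate.
#' @slot pseudocount Reads added to actual and predicted when forming Dval
#'   for testing.
#' @slot minSites Minimum distinct insertion sites for a feature to enter
#'   significance testing.
#' @slot alpha Significance threshold on the per-feature P value.
#' @export
setClass("ScreenConfig", representation(
  saturation = "numeric", growthFactorControl = "numeric",
  survivalSub = "numeric", survivalBact = "numeric",
  bottlenecks = "numeric", nReplicates = "integer",
  readsPerSample = "integer", tagLength = "integer",
  barcodeLength = "integer", readErrorRate = "numeric",
  pseudocount = "numeric", minSites = "integer", alpha = "numeric"))

setValidity("ScreenConfig", function(object) {
  frac <- c(saturation = object@saturation, survivalSub = object@survivalSub,
            survivalBact = object@survivalBact,
            readErrorRate = object@readErrorRate)
  bad <- names(frac)[frac < 0 | frac > 1]
  if (length(bad)) return(paste0("field '", bad[1L], "' must lie in [0, 1]"))
  if (object@growthFactorControl <= 0) return("'growthFactorControl' must be positive")
  if (!identical(sort(names(object@bottlenecks)),
                 sort(c("control", "sub", "bactericidal"))))
    return("'bottlenecks' must be named control, sub, bactericidal")
  if (any(object@bottlenecks < 1)) return("'bottlenecks' must be >= 1")
  if (object@nReplicates < 1L) return("'nReplicates' must be >= 1")
  if (object@readsPerSample < 1L) return("'readsPerSample' must be >= 1")
  if (object@tagLength < 12L) return("'tagLength' must be >= 12 (tag uniqueness)")
  if (object@barcodeLength < 4L) return("'barcodeLength' must be >= 4")
  if (object@pseudocount < 0) return("'pseudocount' must be >= 0")
  if (object@minSites < 1L) return("'minSites' must be >= 1")
  if (object@alpha <= 0 || object@alpha > 1) return("'alpha' must be in (0, 1]")
  TRUE
})

#' Table of transposon insertion clones
#'
#' One record per clone: the TA site (0-based position of the T), the
#' transposon orientation, the feature containing the site, and the clone's
#' abundance (cells or colonies, depending on the pipeline stage).
#'
#' @slot position Integer 0-based TA positions.
#' @slot orientation "+" or "-" per clone.
#' @slot featureId Containing feature per clone.
#' @slot abundance Non-negative abundance per clone.
#' @export
setClass("TnLibrary", representation(
  position = "integer", orientation = "character",
  featureId = "character", abundance = "numeric"))

setValidity("TnLibrary", function(object) {
  n <- length(object@position)
  if (length(object@orientation) != n || length(object@featureId) != n ||
      length(object@abundance) != n)
    return("all slots must have one entry per clone")
  if (n && !all(object@orientation %in% c("+", "-")))
    return("orientation must be '+' or '-'")
  if (n && any(object@abundance < 0)) return("negative abundance")
  if (anyDuplicated(paste(object@position, object@orientation)))
    return("more than one clone at the same (position, orientation)")
  TRUE
})

#' Per-insertion-site read counts across samples
#'
#' A SummarizedExperiment whose rows are insertion sites -- keyed by
#' `ta_position` (0-based) and `orientation` ("+", "-", or "*" once
#' orientations have been collapsed) in `rowData` -- and whose single
#' `counts` assay holds non-negative integer read counts, one column per
#' sample.
#'
#' @export
setClass("SiteCounts", contains = "SummarizedExperiment")

setValidity("SiteCounts", function(object) {
  rd <- rowData(object)
  if (!all(c("ta_position", "orientation") %in% names(rd)))
    return("rowData must contain 'ta_position' and 'orientation'")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  if (nrow(object) && any(assay(object, "counts") < 0))
    return("negative counts")
  TRUE
})
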