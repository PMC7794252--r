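#' Construct a TnGenome from a sequence string
#'
#' @param sequence DNA string (case-insensitive; A/C/G/T/N only).
#' @param id Sequence identifier.
#' @return A [TnGenome-class] object.
#' @examples
#' g <- TnGenome("GATTACA")
#' taSites(g)
#' @export
TnGenome <- function(sequence, id = "chr") {
  new("TnGenome", id = id, sequence = toupper(as.character(sequence)))
}

#' @describeIn TnGenome Genome length in bp.
#' @param x A TnGenome.
#' @export
setMethod("length", "TnGenome", function(x) nchar(x@sequence))

#' @describeIn TnGenome Genome sequence as a single string.
#' @param object A TnGenome.
#' @export
genomeSequence <- function(object) object@sequence

#' @describeIn TnGenome Genome identifier.
#' @export
genomeId <- function(object) object@id

setMethod("show", "TnGenome", function(object) {
  cat("TnGenome '", object@id, "': ", nchar(object@sequence), " bp, ",
      length(taSites(object)), " TA sites\n", sep = "")
})

#' Read a single-chromosome genome from FASTA
#'
#' Multi-record FASTA files are rejected: the coordinate frame is a single
#' chromosome.
#'
#' @param path Path to a FASTA file.
#' @return A [TnGenome-class].
#' @export
readGenomeFasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("FASTA file '", path, "' contains ", length(set),
         " records; a single chromosome is required")
  id <- sub("\\s.*$", "", names(set)[1L])
  TnGenome(as.character(set[[1L]]), id = id)
}

#' Write a TnGenome to FASTA
#' @param genome A [TnGenome-class].
#' @param path Output path.
#' @export
writeGenomeFasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome@sequence)
  names(set) <- genome@id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Enumerate candidate mariner insertion sites (TA dinucleotides)
#'
#' Returns every 0-based position p with sequence[p..p+1] == "TA", in
#' ascending order. TA is its own reverse complement, so the same physical
#' sites are found on either strand (after the reflection p -> L - 2 - p).
#'
#' @param genome A [TnGenome-class] or a DNA string.
#' @return Integer vector of 0-based positions of the T of each TA.
#' @examples
#' taSites(TnGenome("TATATA"))  # 0 2 4
#' @export
taSites <- function(genome) {
  s <- if (is(genome, "TnGenome")) genome@sequence else toupper(genome)
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-DNA characters")
  if (nchar(s) < 2L) return(integer(0))
  hits <- gregexpr("TA", s, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

## --- feature catalog -------------------------------------------------------

#' Read gene features from a GFF3 annotation
#'
#' Keeps records of type "gene"; converts the 1-based inclusive GFF
#' coordinates to the internal 0-based half-open frame. The feature id is
#' taken from the first available of locus_tag, ID, Name attributes.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with columns feature_id, kind ("gene"), start, end,
#'   strand.
#' @export
readGenesGFF3 <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) stop("no type=gene records in '", path, "'")
  md <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% names(md)) as.character(md[[col]]) else
    rep(NA_character_, length(gr))
  id <- pick("locus_tag")
  for (col in c("ID", "Name"))
    id <- ifelse(is.na(id) | id == "", pick(col), id)
  if (anyNA(id) || any(id == ""))
    id[is.na(id) | id == ""] <- paste0("gene", which(is.na(id) | id == ""))
  data.frame(
    feature_id = id, kind = "gene",
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Resolve overlapping gene annotations
#'
#' Genes fully contained within an earlier gene are dropped (with a
#' warning); a gene overlapping the tail of an earlier one is truncated to
#' begin at that gene's end. This keeps the catalog a strict partition, on
#' which the conservation of total predicted reads depends.
#'
#' @param genes data.frame as from [readGenesGFF3()].
#' @return Non-overlapping genes, sorted by start.
#' @export
resolveGeneOverlaps <- function(genes) {
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  keep <- logical(nrow(genes))
  hi <- -1L
  for (i in seq_len(nrow(genes))) {
    if (genes$end[i] <= hi) {
      warning("gene '", genes$feature_id[i],
              "' is contained in an earlier gene; dropped")
      next
    }
    if (genes$start[i] < hi) genes$start[i] <- hi
    keep[i] <- TRUE
    hi <- genes$end[i]
  }
  genes[keep, , drop = FALSE]
}

#' Construct intergenic regions between non-overlapping genes
#'
#' Returns the maximal gaps between consecutive genes (plus leading and
#' trailing gaps) as kind = "intergenic" features, so that genes plus
#' intergenic regions tile the genome exactly. Ids are deterministic:
#' `IG_<left-gene>_<right-gene>`, with START/END at the chromosome ends.
#'
#' @param genes Non-overlapping gene data.frame sorted by start.
#' @param genomeLength Genome length in bp.
#' @return data.frame of intergenic features (possibly 0 rows).
#' @export
buildIntergenicRegions <- function(genes, genomeLength) {
  if (nrow(genes)) {
    genes <- genes[order(genes$start), , drop = FALSE]
    if (any(genes$start[-1L] < genes$end[-nrow(genes)])) {
      i <- which(genes$start[-1L] < genes$end[-nrow(genes)])[1L]
      stop("overlapping genes: '", genes$feature_id[i], "' and '",
           genes$feature_id[i + 1L], "'")
    }
    if (genes$start[1L] < 0 || genes$end[nrow(genes)] > genomeLength)
      stop("gene outside [0, genome length)")
  }
  bounds_left <- c(0L, genes$end)
  bounds_right <- c(genes$start, genomeLength)
  left_name <- c("START", genes$feature_id)
  right_name <- c(genes$feature_id, "END")
  gap <- bounds_right > bounds_left
  n <- sum(gap)
  data.frame(
    feature_id = if (n) paste0("IG_", left_name[gap], "_", right_name[gap])
                 else character(0),
    kind = rep("intergenic", n),
    start = as.integer(bounds_left[gap]), end = as.integer(bounds_right[gap]),
    strand = rep(".", n), stringsAsFactors = FALSE)
}

#' Build the tiling feature catalog of genes plus intergenic regions
#'
#' @param genes Gene data.frame (overlaps resolved automatically).
#' @param genome A [TnGenome-class], or a genome length.
#' @return A [FeatureCatalog-class].
#' @export
featureCatalog <- function(genes, genome) {
  gl <- if (is(genome, "TnGenome")) length(genome) else as.numeric(genome)
  gid <- if (is(genome, "TnGenome")) genome@id else "chr"
  genes <- resolveGeneOverlaps(genes)
  ig <- buildIntergenicRegions(genes, gl)
  feats <- rbind(genes[, c("feature_id", "kind", "start", "end", "strand")],
                 ig[, c("feature_id", "kind", "start", "end", "strand")])
  feats <- feats[order(feats$start), , drop = FALSE]
  feats$length <- feats$end - feats$start
  rownames(feats) <- NULL
  new("FeatureCatalog", features = feats, genomeId = gid, genomeLength = gl)
}

#' @describeIn featureCatalog Features as a data.frame sorted by start.
#' @param catalog A [FeatureCatalog-class].
#' @export
features <- function(catalog) catalog@features

setMethod("show", "FeatureCatalog", function(object) {
  f <- object@features
  cat("FeatureCatalog on '", object@genomeId, "' (", object@genomeLength,
      " bp): ", sum(f$kind == "gene"), " genes, ",
      sum(f$kind == "intergenic"), " intergenic regions\n", sep = "")
})

#' Locate the feature containing a genomic position
#'
#' Each position belongs to exactly one feature of a tiling catalog; a TA
#' site is assigned by the position of its T (half-open intervals, so a
#' site at a feature's `end` belongs to the next feature).
#'
#' @param position Integer vector of 0-based positions.
#' @param catalog A [FeatureCatalog-class].
#' @return Character vector of feature ids, one per position.
#' @export
locateFeature <- function(position, catalog) {
  f <- catalog@features
  if (any(position < 0 | position >= catalog@genomeLength))
    stop("position outside [0, genome length)")
  f$feature_id[findInterval(position, f$start)]
}

#' Write a feature catalog as TSV
#' @param catalog A [FeatureCatalog-class].
#' @param path Output path.
#' @export
writeFeatureCatalog <- function(catalog, path) {
  utils::write.table(catalog@features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write gene features as GFF3
#' @param genes Gene data.frame (0-based half-open coordinates).
#' @param genome A [TnGenome-class].
#' @param path Output path.
#' @export
writeGenesGFF3 <- function(genes, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome@id, length(genome)), con)
  writeLines(sprintf("%s\ttnscreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
                     genome@id, genes$start + 1L, genes$end,
                     ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                     genes$feature_id, genes$feature_id), con)
  invisible(path)
}
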