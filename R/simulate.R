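#' Screen configuration constructor
#'
#' Defaults describe the selection screen the simulator emulates: a library
#' saturating 63% of TA sites; a 3-h treatment giving ~20-fold growth in
#' the control arm, ~83% kill (17% survival) in the sub-bactericidal arm
#' and ~99.5% kill (0.5% survival) in the bactericidal arm; colony
#' bottlenecks of 100,000 / 8,000 / 230; and 3 biological replicates.
#'
#' @param saturation Fraction of TA sites carrying an insertion.
#' @param growthFactorControl Fold CFU change for the control arm.
#' @param survivalSub Surviving fraction, sub-bactericidal arm.
#' @param survivalBact Surviving fraction, bactericidal arm.
#' @param bottlenecks Named colony counts (control, sub, bactericidal).
#' @param nReplicates Biological replicates.
#' @param readsPerSample Sequencing reads per sample.
#' @param tagLength Genomic tag length (bp) of each junction read.
#' @param barcodeLength Group barcode length (bp).
#' @param readErrorRate Per-base substitution error rate.
#' @param pseudocount Reads added to actual and predicted in the Dval used
#'   for significance testing.
#' @param minSites Minimum distinct insertion sites per analyzed feature.
#' @param alpha P-value threshold for the hit call.
#' @return A [ScreenConfig-class].
#' @export
screenConfig <- function(saturation = 0.63,
                         growthFactorControl = 20,
                         survivalSub = 0.17,
                         survivalBact = 0.005,
                         bottlenecks = c(control = 100000, sub = 8000,
                                         bactericidal = 230),
                         nReplicates = 3,
                         readsPerSample = 200000,
                         tagLength = 16,
                         barcodeLength = 6,
                         readErrorRate = 0,
                         pseudocount = 0.5,
                         minSites = 3,
                         alpha = 0.05) {
  new("ScreenConfig",
      saturation = saturation, growthFactorControl = growthFactorControl,
      survivalSub = survivalSub, survivalBact = survivalBact,
      bottlenecks = bottlenecks, nReplicates = as.integer(nReplicates),
      readsPerSample = as.integer(readsPerSample),
      tagLength = as.integer(tagLength),
      barcodeLength = as.integer(barcodeLength),
      readErrorRate = readErrorRate, pseudocount = pseudocount,
      minSites = as.integer(minSites), alpha = alpha)
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig: saturation ", object@saturation,
      ", control x", object@growthFactorControl,
      ", survival sub ", object@survivalSub, " / bact ", object@survivalBact,
      "\n  bottlenecks ", paste(names(object@bottlenecks),
                                object@bottlenecks, sep = "=", collapse = " "),
      ", ", object@nReplicates, " replicates, ",
      object@readsPerSample, " reads/sample, tag ", object@tagLength,
      " bp\n", sep = "")
})

#' Default per-group barcodes
#'
#' Three length-6 barcodes with pairwise Hamming distance 6, one per
#' experimental group.
#' @return Named character vector (control, sub, bactericidal).
#' @export
defaultBarcodes <- function() {
  c(control = "ACGTCA", sub = "TGCAGT", bactericidal = "CATGAC")
}

#' Per-feature survival multipliers under treatment
#'
#' A multiplier of 1 is neutral; m > 1 means insertions in the feature
#' confer resistance (their survival under treatment is m times the
#' baseline). Control survival is always the neutral baseline.
#'
#' @param catalog A [FeatureCatalog-class].
#' @param resistant Named numeric vector of multipliers for the non-neutral
#'   features (names are feature ids).
#' @return Named numeric vector over all catalog features.
#' @export
fitnessMap <- function(catalog, resistant = numeric(0)) {
  f <- features(catalog)
  m <- stats::setNames(rep(1, nrow(f)), f$feature_id)
  if (length(resistant)) {
    unknown <- setdiff(names(resistant), f$feature_id)
    if (length(unknown))
      stop("fitness map names not in catalog: ", paste(unknown, collapse = ", "))
    if (any(resistant <= 0)) stop("multipliers must be > 0")
    m[names(resistant)] <- resistant
  }
  m
}

## --- TnLibrary accessors ---------------------------------------------------

#' Clone records of a TnLibrary as a data.frame
#' @param lib A [TnLibrary-class].
#' @return data.frame with ta_position, orientation, feature_id, abundance.
#' @export
cloneTable <- function(lib) {
  data.frame(ta_position = lib@position, orientation = lib@orientation,
             feature_id = lib@featureId, abundance = lib@abundance,
             stringsAsFactors = FALSE)
}

setMethod("length", "TnLibrary", function(x) length(x@position))

setMethod("show", "TnLibrary", function(object) {
  cat("TnLibrary: ", length(object@position), " clones, total abundance ",
      format(sum(object@abundance), big.mark = ","), "\n", sep = "")
})

## --- simulation stages -----------------------------------------------------

#' Simulate a saturated transposon insertion library
#'
#' Each TA site independently carries a clone with probability
#' `saturation`; the transposon orientation is uniform over +/-. Initial
#' clone abundances are log-normal (sigma = 0.5 on the natural log) around
#' a common mean, mimicking a nearly random distribution of insertions.
#'
#' @param taIndex Integer vector of 0-based TA positions.
#' @param catalog A [FeatureCatalog-class] (assigns each clone a feature).
#' @param config A [ScreenConfig-class].
#' @param meanAbundance Mean initial cells per clone (sets the absolute
#'   scale of later Poisson selection noise).
#' @return A [TnLibrary-class].
#' @export
simulateLibrary <- function(taIndex, catalog, config = screenConfig(),
                            meanAbundance = 200) {
  if (length(taIndex) == 0L) stop("TA site index is empty")
  occupied <- stats::runif(length(taIndex)) < config@saturation
  pos <- as.integer(taIndex[occupied])
  n <- length(pos)
  orient <- if (n) sample(c("+", "-"), n, replace = TRUE) else character(0)
  ab <- if (n) stats::rlnorm(n, meanlog = log(meanAbundance) - 0.5^2 / 2,
                             sdlog = 0.5) else numeric(0)
  new("TnLibrary", position = pos, orientation = orient,
      featureId = if (n) locateFeature(pos, catalog) else character(0),
      abundance = ab)
}

#' Apply one round of selection to a clone library
#'
#' The expected post-selection abundance of clone i is its abundance times
#' the arm's growth/survival factor: the control growth factor for the
#' control arm, or baseline survival times the clone's feature multiplier
#' for the treated arms. Realized abundances are independent Poisson draws
#' about the expectation, so each call is one biological replicate.
#'
#' @param lib A [TnLibrary-class] with positive total abundance.
#' @param fitness Named multiplier vector from [fitnessMap()].
#' @param config A [ScreenConfig-class].
#' @param group One of "control", "sub", "bactericidal".
#' @return A [TnLibrary-class] with integer post-selection abundances
#'   (clones drawn 0 are retained with abundance 0 until the bottleneck).
#' @export
simulateSelection <- function(lib, fitness, config, group) {
  group <- match.arg(group, c("control", "sub", "bactericidal"))
  if (sum(lib@abundance) <= 0) stop("library has no abundance")
  if (group == "control") {
    factor <- rep(config@growthFactorControl, length(lib))
  } else {
    s <- if (group == "sub") config@survivalSub else config@survivalBact
    mult <- fitness[lib@featureId]
    mult[is.na(mult)] <- 1
    eff <- s * mult
    if (any(eff > 1)) {
      warning(sum(eff > 1), " clone(s) with survival multiplier exceeding ",
              "certainty; clipped to 1")
      eff <- pmin(eff, 1)
    }
    factor <- eff
  }
  out <- lib
  out@abundance <- as.numeric(stats::rpois(length(lib), lib@abundance * factor))
  out
}

#' Sample a colony bottleneck
#'
#' Draws `nColonies` colonies multinomially with probabilities proportional
#' to post-selection abundances; clones drawn zero times are removed.
#'
#' @param lib A [TnLibrary-class].
#' @param nColonies Number of colonies picked.
#' @return A [TnLibrary-class] of surviving clones with colony counts as
#'   abundance.
#' @export
simulateBottleneck <- function(lib, nColonies) {
  if (nColonies < 1) stop("'nColonies' must be >= 1")
  tot <- sum(lib@abundance)
  if (tot <= 0) stop("library extinct: no surviving abundance to plate")
  counts <- as.numeric(stats::rmultinom(1L, size = nColonies,
                                        prob = lib@abundance / tot))
  keep <- counts > 0
  new("TnLibrary", position = lib@position[keep],
      orientation = lib@orientation[keep],
      featureId = lib@featureId[keep], abundance = counts[keep])
}

#' Simulate a full selection screen
#'
#' One initial library; for each requested arm and replicate, an
#' independent Poisson selection draw followed by the arm's colony
#' bottleneck. Sample names are `<group>_rep<r>`.
#'
#' @param taIndex 0-based TA positions of the genome.
#' @param catalog A [FeatureCatalog-class].
#' @param config A [ScreenConfig-class].
#' @param fitness Named multipliers ([fitnessMap()]); default all neutral.
#' @param groups Arms to simulate.
#' @param seed Optional integer seed (fixes the whole screen).
#' @return List with elements `library` (the initial [TnLibrary-class]),
#'   `samples` (named list of post-bottleneck libraries) and `groups`
#'   (named vector mapping sample name to arm).
#' @export
simulateScreen <- function(taIndex, catalog, config = screenConfig(),
                           fitness = fitnessMap(catalog),
                           groups = c("control", "sub", "bactericidal"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lib <- simulateLibrary(taIndex, catalog, config)
  samples <- list()
  grp <- character(0)
  for (g in groups) {
    for (r in seq_len(config@nReplicates)) {
      sel <- simulateSelection(lib, fitness, config, g)
      nm <- sprintf("%s_rep%d", g, r)
      samples[[nm]] <- simulateBottleneck(sel, config@bottlenecks[[g]])
      grp[nm] <- g
    }
  }
  list(library = lib, samples = samples, groups = grp)
}

#' Site counts of a simulated screen without read generation
#'
#' Draws `readsPerSample` sequencing reads per sample multinomially over
#' that sample's clones and returns the per-site count table directly.
#' This is the count-level fast path: with error-free reads the full
#' FASTQ/demultiplex/map path reproduces these counts exactly (sequencing
#' of a clone's junction is a deterministic function of its site), so the
#' downstream statistics are identical.
#'
#' @param screen Result of [simulateScreen()].
#' @param config A [ScreenConfig-class].
#' @return A [SiteCounts-class] with one row per clone of the initial
#'   library and one column per sample.
#' @export
simulateScreenCounts <- function(screen, config = screenConfig()) {
  lib <- screen$library
  key <- paste0(lib@position, lib@orientation)
  counts <- matrix(0L, nrow = length(lib), ncol = length(screen$samples),
                   dimnames = list(key, names(screen$samples)))
  for (nm in names(screen$samples)) {
    s <- screen$samples[[nm]]
    draws <- stats::rmultinom(1L, size = config@readsPerSample,
                              prob = s@abundance / sum(s@abundance))
    counts[match(paste0(s@position, s@orientation), key), nm] <- draws
  }
  siteCounts(counts, position = lib@position, orientation = lib@orientation,
             group = screen$groups)
}

#' Construct a SiteCounts object
#'
#' @param counts Integer matrix, sites x samples.
#' @param position 0-based TA positions, one per row.
#' @param orientation "+", "-" (or "*" for orientation-collapsed rows).
#' @param group Optional named vector mapping sample name to arm.
#' @return A [SiteCounts-class].
#' @export
siteCounts <- function(counts, position, orientation, group = NULL) {
  counts <- as.matrix(counts)
  rd <- DataFrame(ta_position = as.integer(position),
                  orientation = orientation)
  cd <- if (is.null(group)) DataFrame(row.names = colnames(counts)) else
    DataFrame(group = unname(group[colnames(counts)]),
              row.names = colnames(counts))
  rownames(counts) <- paste0(position, orientation)
  new("SiteCounts",
      SummarizedExperiment(assays = list(counts = counts), rowData = rd,
                           colData = cd))
}
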