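#' Length-expected read count of a feature
#'
#' Under a uniform insertion/read model a feature is expected to receive
#' reads in proportion to its length: predicted = totalMappedReads *
#' featureLength / catalogLength. Over a tiling catalog the predictions
#' sum to the mapped total.
#'
#' @param featureLength Feature length(s) in bp.
#' @param totalMappedReads Total uniquely mapped reads in the sample.
#' @param catalogLength Summed feature length (= genome length for a
#'   tiling catalog).
#' @return Expected read count(s).
#' @export
predictedReads <- function(featureLength, totalMappedReads, catalogLength) {
  if (catalogLength <= 0) stop("'catalogLength' must be positive")
  if (any(featureLength <= 0) || totalMappedReads <= 0)
    stop("lengths and read totals must be positive")
  totalMappedReads * featureLength / catalogLength
}

#' Dval: normalized representation of a feature in a library
#'
#' Dval = (actual + pseudocount) / (predicted + pseudocount). Dval = 1
#' means the feature holds exactly its length-proportional share of reads.
#' A positive pseudocount keeps Dval (and hence SI) defined for features
#' emptied by bactericidal selection while leaving well-covered features
#' essentially unchanged.
#'
#' @param actual Actual read count(s).
#' @param predicted Predicted read count(s) ([predictedReads()]).
#' @param pseudocount Reads added to both terms (default 0).
#' @return Dval value(s).
#' @export
dval <- function(actual, predicted, pseudocount = 0) {
  if (any(actual < 0)) stop("negative read counts")
  if (any(predicted <= 0)) stop("'predicted' must be positive")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  (actual + pseudocount) / (predicted + pseudocount)
}

#' Survival index of a feature
#'
#' SI = Dval in the treated arm / Dval in the control arm. SI = 1: the
#' insertion has no effect on survival under treatment; SI > 1: the mutant
#' is enriched (resistant); SI < 1: depleted (sensitive).
#'
#' @param dvalTreated Dval(s) in the treated sample.
#' @param dvalControl Dval(s) in the control sample (must be > 0; use a
#'   positive pseudocount when actual counts can be 0).
#' @return SI value(s).
#' @export
survivalIndex <- function(dvalTreated, dvalControl) {
  if (any(dvalControl <= 0))
    stop("control Dval must be > 0 (use a positive pseudocount)")
  dvalTreated / dvalControl
}

#' Aggregate site counts by feature
#'
#' actual_reads(feature, sample) is the sum of collapsed per-position
#' counts at TA positions inside the feature's half-open interval;
#' n_sites is the number of distinct positions with a nonzero count in at
#' least one of the given samples.
#'
#' @param sc A [SiteCounts-class] (collapsed internally if needed).
#' @param catalog A [FeatureCatalog-class] tiling the genome.
#' @param samples Samples over which n_sites is taken (default all).
#' @return List: `actual` (features x samples matrix over all catalog
#'   features), `n_sites` (named vector), `features` (the catalog table).
#' @export
aggregateByFeature <- function(sc, catalog, samples = colnames(sc)) {
  cc <- if (all(rowData(sc)$orientation == "*")) sc else
    collapseOrientations(sc)
  f <- features(catalog)
  counts <- assay(cc, "counts")
  pos <- rowData(cc)$ta_position
  fid <- if (length(pos)) locateFeature(pos, catalog) else character(0)
  actual <- matrix(0, nrow(f), ncol(counts),
                   dimnames = list(f$feature_id, colnames(counts)))
  if (length(pos)) {
    agg <- rowsum(counts, group = fid)
    actual[rownames(agg), ] <- agg
    observed <- rowSums(counts[, samples, drop = FALSE] > 0) > 0
    ns <- table(factor(fid[observed], levels = f$feature_id))
  } else {
    ns <- table(factor(character(0), levels = f$feature_id))
  }
  list(actual = actual, n_sites = stats::setNames(as.integer(ns), f$feature_id),
       features = f)
}

#' Two-tailed one-sample t-test of replicate log survival indices
#'
#' Tests ln(SI) against 0 across biological replicates -- equivalent to a
#' paired t-test of ln Dval(treated) vs ln Dval(control) per replicate.
#' Zero variance is flagged degenerate: with a nonzero mean the P value is
#' reported below machine resolution; with zero mean it is exactly 1.
#'
#' @param logSI Numeric vector of per-replicate ln(SI) values (>= 2 finite
#'   values required).
#' @return List: `p` (two-tailed P), `t`, `df`, `degenerate` (logical).
#' @export
replicateSignificance <- function(logSI) {
  logSI <- logSI[is.finite(logSI)]
  n <- length(logSI)
  if (n < 2L) stop("at least 2 replicates with finite ln(SI) are required")
  m <- mean(logSI)
  s <- stats::sd(logSI)
  if (s == 0) {
    if (m == 0) return(list(p = 1, t = 0, df = n - 1L, degenerate = TRUE))
    return(list(p = .Machine$double.xmin, t = sign(m) * Inf, df = n - 1L,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(p = 2 * stats::pt(-abs(t), df = n - 1L), t = t, df = n - 1L,
       degenerate = FALSE)
}

#' Per-feature fitness table of a treated-vs-control comparison
#'
#' For each catalog feature and each replicate pair, computes actual and
#' predicted reads, Dval in both samples, and SI; then the geometric mean
#' SI across replicates, the one-sample t-test P value on ln(SI), BH
#' q-values (over features passing the minimum-site filter) and the hit
#' call. Raw Dvals (pseudocount 0) are reported per sample alongside the
#' pseudocounted values used for SI.
#'
#' @param sc A [SiteCounts-class] containing all samples of the comparison.
#' @param catalog A [FeatureCatalog-class].
#' @param treated Sample names of the treated arm, one per replicate.
#' @param control Sample names of the control arm, paired by position.
#' @param pseudocount Pseudocount for the tested Dval (default 0.5 reads).
#' @param minSites Minimum n_sites for significance testing (default 3).
#' @param alpha P threshold of the hit call (default 0.05).
#' @return data.frame with one row per feature: feature_id, kind, length,
#'   n_sites, actual_/predicted_/dval_ columns per sample, si_rep<r>,
#'   mean_si, p_value, q_value, passes_min_sites, hit_call.
#' @export
featureFitness <- function(sc, catalog, treated, control,
                           pseudocount = 0.5, minSites = 3L, alpha = 0.05) {
  if (length(treated) != length(control))
    stop("'treated' and 'control' must pair one sample per replicate")
  nrep <- length(treated)
  samples <- c(treated, control)
  if (!all(samples %in% colnames(sc)))
    stop("samples missing from the count table: ",
         paste(setdiff(samples, colnames(sc)), collapse = ", "))
  agg <- aggregateByFeature(sc, catalog, samples = samples)
  f <- agg$features
  L <- sum(f$length)
  actual <- agg$actual[, samples, drop = FALSE]
  totals <- colSums(actual)
  if (any(totals <= 0)) stop("sample with zero mapped reads")
  pred <- outer(f$length, totals) / L
  colnames(pred) <- samples
  dvRaw <- actual / pred
  dvTest <- (actual + pseudocount) / (pred + pseudocount)
  si <- dvTest[, treated, drop = FALSE] / dvTest[, control, drop = FALSE]
  colnames(si) <- sprintf("si_rep%d", seq_len(nrep))
  logsi <- log(si)
  meanSI <- exp(rowMeans(logsi))
  m <- rowMeans(logsi)
  s <- apply(logsi, 1L, stats::sd)
  p <- rep(NA_real_, nrow(f))
  if (nrep >= 2L) {
    tstat <- m / (s / sqrt(nrep))
    p <- 2 * stats::pt(-abs(tstat), df = nrep - 1L)
    p[s == 0 & m == 0] <- 1
    p[s == 0 & m != 0] <- .Machine$double.xmin
  }
  passes <- agg$n_sites >= minSites
  q <- rep(NA_real_, nrow(f))
  q[passes] <- stats::p.adjust(p[passes], method = "BH")
  hit <- ifelse(!passes | is.na(p) | p > alpha, "none",
                ifelse(meanSI > 1, "resistant",
                       ifelse(meanSI < 1, "sensitive", "none")))
  out <- data.frame(feature_id = f$feature_id, kind = f$kind,
                    length = f$length, n_sites = unname(agg$n_sites),
                    stringsAsFactors = FALSE)
  for (sm in samples) {
    out[[paste0("actual_", sm)]] <- actual[, sm]
    out[[paste0("predicted_", sm)]] <- pred[, sm]
    out[[paste0("dval_", sm)]] <- dvRaw[, sm]
  }
  out <- cbind(out, as.data.frame(si))
  out$mean_si <- meanSI
  out$p_value <- p
  out$q_value <- q
  out$passes_min_sites <- unname(passes)
  out$hit_call <- hit
  rownames(out) <- NULL
  out
}

#' Restrict a fitness table to reliably covered features
#'
#' Features need at least `minSites` distinct insertion sites for a
#' reliable frequency-change call; the number removed is recorded in the
#' "removed" attribute.
#'
#' @param table A [featureFitness()] result.
#' @param minSites Inclusive minimum (default 3: "3 or more").
#' @return Filtered data.frame.
#' @export
filterMinSites <- function(table, minSites = 3L) {
  if (minSites < 1L) stop("'minSites' must be >= 1")
  keep <- table$n_sites >= minSites
  out <- table[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Ranked hit list of a fitness table
#'
#' Features passing the minimum-site filter with P <= alpha and geometric
#' mean SI on the requested side of 1, sorted by mean SI (descending for
#' resistant hits, ascending for sensitive).
#'
#' @param table A [featureFitness()] result.
#' @param alpha P-value threshold (default 0.05; raw P, not q).
#' @param direction "resistant" (SI > 1) or "sensitive" (SI < 1).
#' @return data.frame of hits with a `rank` column.
#' @export
rankHits <- function(table, alpha = 0.05, direction = c("resistant",
                                                        "sensitive")) {
  direction <- match.arg(direction)
  keep <- table$passes_min_sites & !is.na(table$p_value) &
    table$p_value <= alpha &
    (if (direction == "resistant") table$mean_si > 1 else table$mean_si < 1)
  out <- table[keep, , drop = FALSE]
  out <- out[order(out$mean_si,
                   decreasing = (direction == "resistant")), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
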