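#' Exact TA-anchored tag index of a genome
#'
#' For every TA site the index stores the forward-convention tag
#' (`genome[p, p + tagLength)`) and the reverse-convention tag (reverse
#' complement of `genome[p + 2 - tagLength, p + 2)`). Tag strings occurring
#' more than once in the combined set are flagged ambiguous and retained;
#' they are never silently resolved. Windows running off a chromosome end
#' or containing N yield no entry.
#'
#' @slot tag Tag strings.
#' @slot position 0-based TA position per tag.
#' @slot orientation "+" or "-" per tag.
#' @slot ambiguous TRUE where the tag string is not unique in the genome.
#' @slot tagLength Tag length (bp).
#' @export
setClass("TagIndex", representation(
  tag = "character", position = "integer", orientation = "character",
  ambiguous = "logical", tagLength = "integer"))

setMethod("show", "TagIndex", function(object) {
  cat("TagIndex: ", length(object@tag), " tags of ", object@tagLength,
      " bp (", sum(object@ambiguous), " ambiguous)\n", sep = "")
})

#' Build the tag index for a genome
#'
#' @param genome A [TnGenome-class].
#' @param tagLength Tag length in bp.
#' @param taIndex Optional precomputed TA positions ([taSites()]).
#' @return A [TagIndex-class].
#' @export
buildTagIndex <- function(genome, tagLength, taIndex = taSites(genome)) {
  pos <- rep(as.integer(taIndex), 2L)
  orient <- rep(c("+", "-"), each = length(taIndex))
  tag <- junctionTag(genome, pos, orient, tagLength)
  ok <- !is.na(tag)
  tag <- tag[ok]; pos <- pos[ok]; orient <- orient[ok]
  dup <- tag %in% tag[duplicated(tag)]
  new("TagIndex", tag = tag, position = pos, orientation = orient,
      ambiguous = dup, tagLength = as.integer(tagLength))
}

#' Demultiplex reads by group barcode
#'
#' Assigns each read to the unique barcode within `maxMismatches` Hamming
#' distance of its leading bases; reads matching no barcode within
#' tolerance are rejected and counted. Barcodes must be of equal length
#' with pairwise Hamming distance greater than `2 * maxMismatches`, which
#' makes the assignment unambiguous.
#'
#' @param sequences Character vector of read sequences.
#' @param barcodes Named character vector (group -> barcode).
#' @param maxMismatches Mismatch tolerance (default 1).
#' @return List: `group` (factor of assignments, NA = rejected), `tags`
#'   (named list of per-group read remainders with the barcode stripped),
#'   `summary` (data.frame of per-group assigned counts plus rejected).
#' @export
demultiplex <- function(sequences, barcodes, maxMismatches = 1L) {
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1L) stop("barcodes must have equal length")
  dmin <- minBarcodeDistance(barcodes)
  if (length(barcodes) > 1L && dmin <= 2L * maxMismatches)
    stop("barcode collision: minimum pairwise Hamming distance ", dmin,
         " must exceed 2 * maxMismatches = ", 2L * maxMismatches)
  prefix <- substr(sequences, 1L, bl)
  pm <- matrix(unlist(strsplit(prefix, "", fixed = TRUE), use.names = FALSE),
               ncol = bl, byrow = TRUE)
  mm <- vapply(barcodes, function(b) {
    bc <- strsplit(b, "")[[1L]]
    rowSums(pm != matrix(bc, nrow(pm), bl, byrow = TRUE))
  }, numeric(nrow(pm)))
  mm <- matrix(mm, ncol = length(barcodes),
               dimnames = list(NULL, names(barcodes)))
  best <- max.col(-mm, ties.method = "first")
  ok <- mm[cbind(seq_len(nrow(mm)), best)] <= maxMismatches
  group <- factor(ifelse(ok, names(barcodes)[best], NA),
                  levels = names(barcodes))
  rest <- substr(sequences, bl + 1L, nchar(sequences))
  tags <- split(rest, group)
  list(group = group, tags = tags,
       summary = data.frame(
         group = c(names(barcodes), "rejected"),
         reads = c(as.integer(table(group)), sum(is.na(group))),
         stringsAsFactors = FALSE))
}

minBarcodeDistance <- function(barcodes) {
  if (length(barcodes) < 2L) return(Inf)
  chars <- strsplit(barcodes, "")
  min(utils::combn(length(barcodes), 2L, function(ij)
    sum(chars[[ij[1L]]] != chars[[ij[2L]]])))
}

#' Map junction tags to TA sites by exact search
#'
#' Exact lookup against the [TagIndex-class]: a unique hit returns the TA
#' site and orientation; a tag matching a flagged-ambiguous index entry is
#' classified "ambiguous"; a tag with no index entry (including tags with
#' non-ACGT characters) is "unmapped".
#'
#' @param tags Character vector of tags (length = index tag length).
#' @param index A [TagIndex-class].
#' @return data.frame with columns ta_position, orientation, status
#'   ("unique", "ambiguous", "unmapped").
#' @export
mapTags <- function(tags, index) {
  if (length(tags) && any(nchar(tags) != index@tagLength))
    stop("tag length does not match index tag length")
  hit <- match(tags, index@tag)
  status <- ifelse(is.na(hit), "unmapped",
                   ifelse(index@ambiguous[hit], "ambiguous", "unique"))
  data.frame(ta_position = ifelse(status == "unique", index@position[hit],
                                  NA_integer_),
             orientation = ifelse(status == "unique", index@orientation[hit],
                                  NA_character_),
             status = status, stringsAsFactors = FALSE)
}

#' Enumerate reads per insertion site
#'
#' Counts uniquely mapped reads per (TA position, orientation) per sample.
#'
#' @param mapped Named list (one element per sample) of [mapTags()]
#'   results; only rows with status "unique" are counted.
#' @param group Optional named vector mapping sample name to arm.
#' @return A [SiteCounts-class] (empty with 0 rows if no reads mapped).
#' @export
countSites <- function(mapped, group = NULL) {
  uniq <- lapply(mapped, function(m) m[m$status == "unique", , drop = FALSE])
  keys <- unique(do.call(rbind, lapply(uniq, function(m)
    m[c("ta_position", "orientation")])))
  if (is.null(keys) || nrow(keys) == 0L) {
    return(siteCounts(matrix(0L, 0L, length(mapped),
                             dimnames = list(NULL, names(mapped))),
                      position = integer(0), orientation = character(0),
                      group = group))
  }
  keys <- keys[order(keys$ta_position, keys$orientation), , drop = FALSE]
  kid <- paste0(keys$ta_position, keys$orientation)
  counts <- vapply(uniq, function(m) {
    tab <- table(factor(paste0(m$ta_position, m$orientation), levels = kid))
    as.integer(tab)
  }, integer(nrow(keys)))
  counts <- matrix(counts, ncol = length(mapped),
                   dimnames = list(kid, names(mapped)))
  siteCounts(counts, position = keys$ta_position,
             orientation = keys$orientation, group = group)
}

#' Collapse the two orientations of each TA site
#'
#' Sums "+" and "-" counts at the same TA position; the downstream Dval/SI
#' statistics are computed on this per-position table.
#'
#' @param sc A [SiteCounts-class].
#' @return A [SiteCounts-class] with orientation "*".
#' @export
collapseOrientations <- function(sc) {
  pos <- rowData(sc)$ta_position
  m <- rowsum(assay(sc, "counts"), group = pos, reorder = TRUE)
  upos <- sort(unique(pos))
  cd <- colData(sc)
  grp <- if ("group" %in% names(cd))
    stats::setNames(cd$group, rownames(cd)) else NULL
  siteCounts(m, position = upos, orientation = rep("*", length(upos)),
             group = grp)
}

#' Write a SiteCounts table as TSV
#' @param sc A [SiteCounts-class].
#' @param path Output path.
#' @export
writeSiteCounts <- function(sc, path) {
  df <- cbind(as.data.frame(rowData(sc)[c("ta_position", "orientation")]),
              as.data.frame(assay(sc, "counts")))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-position wiggle-style track of one sample
#'
#' Two columns (position, count) over positions with nonzero count, for
#' genome-browser inspection. Positions are written 1-based as in wiggle.
#'
#' @param sc A [SiteCounts-class].
#' @param sample Sample (column) name.
#' @param path Output path.
#' @export
writeSiteTrack <- function(sc, sample, path) {
  cc <- collapseOrientations(sc)
  v <- assay(cc, "counts")[, sample]
  keep <- v > 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("variableStep chrom=%s", "chr"), con)
  writeLines(paste(rowData(cc)$ta_position[keep] + 1L, v[keep]), con)
  invisible(path)
}
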