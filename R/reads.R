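#' Reverse complement of DNA strings
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Genomic junction tag of an insertion clone
#'
#' The tag is the genomic sequence adjacent to the transposon end, anchored
#' at the TA site: for a (+)-orientation clone at TA position p it is
#' `genome[p, p + tagLength)`; for (-) orientation it is the reverse
#' complement of `genome[p + 2 - tagLength, p + 2)`. Every valid tag
#' therefore begins with "TA".
#'
#' @param genome A [TnGenome-class].
#' @param position 0-based TA positions.
#' @param orientation "+" or "-" per position.
#' @param tagLength Tag length in bp.
#' @return Character vector of tags; NA where the tag window would run off
#'   the chromosome end (circular genomes are not modeled).
#' @export
junctionTag <- function(genome, position, orientation, tagLength) {
  s <- genome@sequence
  L <- nchar(s)
  tag <- rep(NA_character_, length(position))
  fwd <- orientation == "+" & position + tagLength <= L
  rev <- orientation == "-" & position + 2L - tagLength >= 0L
  if (any(fwd))
    tag[fwd] <- substring(s, position[fwd] + 1L, position[fwd] + tagLength)
  if (any(rev))
    tag[rev] <- revComp(substring(s, position[rev] + 3L - tagLength,
                                  position[rev] + 2L))
  tag[grepl("N", tag)] <- NA_character_
  tag
}

#' Generate barcoded junction reads for one sample
#'
#' Draws `nReads` reads multinomially over clones in proportion to
#' abundance; each read is the group barcode followed by the clone's
#' junction tag, with independent per-base substitution errors at
#' `config@readErrorRate`. The ground-truth site is recorded in the read
#' name (`r<i>|pos=<p>|strand=<+/->`).
#'
#' @param lib A [TnLibrary-class] (a post-bottleneck sample).
#' @param genome A [TnGenome-class].
#' @param config A [ScreenConfig-class].
#' @param barcode Barcode string of the sample's experimental group.
#' @param nReads Number of reads (default `config@readsPerSample`).
#' @return List: `sequences` (character), `names` (character), and `truth`
#'   (data.frame ta_position, orientation, reads: the exact multinomial
#'   draw per clone, including clones drawn zero times).
#' @export
generateReads <- function(lib, genome, config, barcode,
                          nReads = config@readsPerSample) {
  if (nReads < 1) stop("'nReads' must be >= 1")
  if (nchar(barcode) != config@barcodeLength)
    stop("barcode length does not match config")
  tags <- junctionTag(genome, lib@position, lib@orientation, config@tagLength)
  usable <- !is.na(tags) & lib@abundance > 0
  if (any(is.na(tags) & lib@abundance > 0))
    warning(sum(is.na(tags) & lib@abundance > 0),
            " clone(s) skipped: tag window off chromosome end")
  if (!any(usable)) stop("no clones with a valid tag window")
  draws <- integer(length(lib))
  draws[usable] <- as.integer(stats::rmultinom(
    1L, size = nReads, prob = lib@abundance[usable]))
  idx <- rep(seq_along(draws), draws)
  seqs <- paste0(barcode, tags[idx])
  if (config@readErrorRate > 0) seqs <- addReadErrors(seqs, config@readErrorRate)
  list(sequences = seqs,
       names = sprintf("r%d|pos=%d|strand=%s", seq_along(idx),
                       lib@position[idx], lib@orientation[idx]),
       truth = data.frame(ta_position = lib@position,
                          orientation = lib@orientation,
                          reads = draws, stringsAsFactors = FALSE))
}

# independent per-base substitutions; an erroneous base is replaced by one
# of the three other nucleotides uniformly
addReadErrors <- function(seqs, rate) {
  width <- nchar(seqs[1L])
  nmut <- stats::rbinom(length(seqs), width, rate)
  hit <- which(nmut > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(seqs[i], "")[[1L]]
    at <- sample.int(width, nmut[i])
    chars[at] <- vapply(chars[at],
                        function(b) sample(setdiff(bases, b), 1L), "")
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Write reads as FASTQ (Phred+33, constant quality)
#' @param sequences Character vector of read sequences.
#' @param names Read names.
#' @param path Output path.
#' @export
writeReadsFastq <- function(sequences, names, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names
  qual <- Biostrings::BStringSet(strrep("I", nchar(sequences)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into sequences and names
#' @param path FASTQ path.
#' @return List with `sequences` and `names` character vectors.
#' @export
readReadsFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(sequences = unname(as.character(x)), names = names(x))
}
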