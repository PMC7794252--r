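# fixtures are generated in code; seeds fixed per test for reproducibility

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# catalog with explicit gene intervals on a bare genome length
geneCatalog <- function(starts, ends, genomeLength,
                        ids = sprintf("g%d", seq_along(starts))) {
  genes <- data.frame(feature_id = ids, kind = "gene",
                      start = as.integer(starts), end = as.integer(ends),
                      strand = "+", stringsAsFactors = FALSE)
  featureCatalog(genes, genomeLength)
}

# minimal TnLibrary without going through simulateLibrary
tnLib <- function(position, orientation, featureId, abundance) {
  new("TnLibrary", position = as.integer(position),
      orientation = orientation, featureId = featureId,
      abundance = as.numeric(abundance))
}

md5 <- function(path) unname(tools::md5sum(path))
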