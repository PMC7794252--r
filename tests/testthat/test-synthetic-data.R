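test_that("library occupancy follows the configured saturation", {
  set.seed(21)
  g <- randomGenome(4000)
  cat1 <- featureCatalog(tileGenes(4000, 10), g)
  ta <- taSites(g)

  full <- simulateLibrary(ta, cat1, screenConfig(saturation = 1))
  expect_equal(sort(full@position), ta)  # every site occupied

  expect_equal(length(simulateLibrary(ta, cat1, screenConfig(saturation = 0))),
               0L)

  # occupancy over 10,000 sites within the exact binomial 99% interval
  ta10k <- seq(0L, by = 3L, length.out = 10000L)
  g10k <- TnGenome(strrep("TAG", 10000L))
  cat10k <- geneCatalog(0, 30000, 30000)
  lib <- simulateLibrary(taSites(g10k), cat10k, screenConfig(saturation = 0.63))
  band <- qbinom(c(0.005, 0.995), 10000, 0.63)
  expect_gte(length(lib), band[1])
  expect_lte(length(lib), band[2])

  expect_error(screenConfig(saturation = 1.5), "saturation")
})

test_that("selection scales abundances by the arm's expected factor", {
  set.seed(22)
  cfg <- screenConfig()
  cat1 <- geneCatalog(0, 1000, 1000)
  n <- 2000
  lib <- tnLib(seq_len(n) * 2 - 2, rep(c("+", "-"), n / 2),
               rep("g1", n), rep(500, n))
  fit <- fitnessMap(cat1)

  # control: x20 growth, frequencies preserved in expectation
  ctrl <- simulateSelection(lib, fit, cfg, "control")
  expect_equal(sum(ctrl@abundance), 20 * sum(lib@abundance),
               tolerance = 3 / sqrt(20 * sum(lib@abundance)))

  # bactericidal: total survival 0.5% within Poisson error
  bact <- simulateSelection(lib, fit, cfg, "bactericidal")
  expected <- 0.005 * sum(lib@abundance)
  expect_lt(abs(sum(bact@abundance) - expected), 4 * sqrt(expected))

  expect_error(simulateSelection(lib, fit, cfg, "mock"), "arg")
})

test_that("rare resistant clones enrich by the closed-form fold change", {
  # frequency fold-change of a resistant class at initial frequency f with
  # multiplier m: m / (1 + f * (m - 1)); Monte-Carlo mean over 10,000
  # independent selection draws must agree within 3 standard errors
  set.seed(23)
  f <- 0.001; m <- 30
  cfg <- screenConfig(survivalBact = 0.005)
  cat2 <- geneCatalog(c(0, 100), c(100, 1000), 1000, ids = c("res", "neu"))
  lib <- tnLib(c(10, 500), c("+", "+"), c("res", "neu"),
               c(f, 1 - f) * 1e6)
  fit <- fitnessMap(cat2, c(res = m))

  fold <- replicate(10000, {
    tr <- suppressWarnings(simulateSelection(lib, fit, cfg, "bactericidal"))
    co <- simulateSelection(lib, fit, cfg, "control")
    (tr@abundance[1] / sum(tr@abundance)) / (co@abundance[1] / sum(co@abundance))
  })
  closed <- m / (1 + f * (m - 1))
  se <- sd(fold) / sqrt(length(fold))
  expect_lt(abs(mean(fold) - closed), 3 * se)
})

test_that("bottleneck sampling is multinomial over surviving clones", {
  set.seed(24)
  # a single surviving clone receives every colony
  solo <- tnLib(0, "+", "g1", 5)
  out <- simulateBottleneck(solo, 230)
  expect_equal(out@abundance, 230)

  # pigeonhole: 230 colonies can keep at most 230 distinct clones
  n <- 12000
  big <- tnLib(seq_len(n) * 2 - 2, rep("+", n), rep("g1", n), rep(1, n))
  expect_lte(length(simulateBottleneck(big, 230)), 230L)

  # uniform library: marginal counts are binomial(100000, 1/1000); at the
  # 99% band about 1% of clones fall outside by construction
  u <- tnLib(seq_len(1000) * 2 - 2, rep("+", 1000), rep("g1", 1000),
             rep(1, 1000))
  bn <- simulateBottleneck(u, 100000)
  counts <- rep(0, 1000)
  counts[match(bn@position, u@position)] <- bn@abundance
  band <- qbinom(c(0.005, 0.995), 100000, 1 / 1000)
  inside <- mean(counts >= band[1] & counts <= band[2])
  expect_gte(inside, 0.97)

  dead <- tnLib(0, "+", "g1", 0)
  expect_error(simulateBottleneck(dead, 10), "extinct")
})

test_that("junction tags follow the TA-anchored read conventions", {
  g <- TnGenome("AACGTAGGCTACGT")
  expect_identical(junctionTag(g, 4L, "+", 6L), "TAGGCT")
  expect_identical(junctionTag(g, 4L, "-", 6L), "TACGTT")
  # off-end windows yield NA (circular genomes not modeled)
  expect_true(is.na(junctionTag(g, 9L, "+", 6L)))
  expect_true(is.na(junctionTag(g, 2L, "-", 6L)))
  # N inside the window suppresses the tag
  gn <- TnGenome("AACGNAGGTACGTACG")
  expect_true(is.na(junctionTag(gn, 8L, "-", 6L)))
})

test_that("generated reads carry the group barcode and TA-anchored tags", {
  set.seed(26)
  g <- randomGenome(3000)
  cat1 <- featureCatalog(tileGenes(3000, 6), g)
  cfg <- screenConfig(readsPerSample = 2000)
  lib <- simulateLibrary(taSites(g), cat1, cfg)
  rd <- generateReads(lib, g, cfg, barcode = "ACGTCA", nReads = 2000)

  expect_length(rd$sequences, 2000)
  expect_equal(sum(rd$truth$reads), 2000)
  expect_true(all(substr(rd$sequences, 1, 6) == "ACGTCA"))
  # the genomic tag always begins with the TA of its insertion site
  expect_true(all(substr(rd$sequences, 7, 8) == "TA"))
  # read names carry the ground-truth site
  pos <- as.integer(sub(".*\\|pos=(\\d+)\\|.*", "\\1", rd$names))
  expect_true(all(pos %in% lib@position))
})

test_that("read generation is byte-deterministic under a fixed seed", {
  g <- randomGenome(2000)
  cat1 <- featureCatalog(tileGenes(2000, 4), g)
  cfg <- screenConfig(readsPerSample = 1000)
  fq <- c(tempfile(fileext = ".fastq"), tempfile(fileext = ".fastq"))
  for (i in 1:2) {
    set.seed(99)
    lib <- simulateLibrary(taSites(g), cat1, cfg)
    rd <- generateReads(lib, g, cfg, barcode = "ACGTCA", nReads = 1000)
    writeReadsFastq(rd$sequences, rd$names, fq[i])
  }
  expect_identical(md5(fq[1]), md5(fq[2]))
})

test_that("fitness maps validate features and clip impossible survival", {
  cat1 <- geneCatalog(c(0, 500), c(500, 1000), 1000)
  expect_error(fitnessMap(cat1, c(nope = 2)), "not in catalog")
  expect_error(fitnessMap(cat1, c(g1 = -1)), "> 0")

  fit <- fitnessMap(cat1, c(g1 = 30))
  expect_equal(unname(fit["g2"]), 1)

  # survival x multiplier > 1 is clipped with a warning
  set.seed(27)
  lib <- tnLib(c(0, 600), c("+", "+"), c("g1", "g2"), c(1e5, 1e5))
  cfg <- screenConfig(survivalSub = 0.17)
  expect_warning(out <- simulateSelection(lib, fit, cfg, "sub"), "clipped")
  expect_lt(abs(out@abundance[1] - 1e5), 4 * sqrt(1e5))
})
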