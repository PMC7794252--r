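test_that("predicted reads are length-proportional and conserve totals", {
  expect_equal(predictedReads(1000, 10000, 100000), 100)
  expect_equal(predictedReads(100000, 10000, 100000), 10000)  # whole genome
  # linearity over a tiling catalog
  lens <- c(300, 200, 500)
  expect_equal(sum(predictedReads(lens, 7777, sum(lens))), 7777)
  expect_error(predictedReads(100, 10, 0), "positive")
})

test_that("Dval is the pseudocounted actual/predicted ratio", {
  expect_equal(dval(200, 100), 2)
  expect_equal(dval(150, 150), 1)
  expect_equal(dval(0, 100, pseudocount = 0.5), 0.5 / 100.5)
  expect_equal(dval(0, 100, pseudocount = 0.5), 0.004975124, tolerance = 1e-6)
  expect_error(dval(-1, 100), "negative")
  expect_error(dval(1, 0), "positive")
})

test_that("survival index is the Dval ratio with directional meaning", {
  expect_identical(survivalIndex(1.7, 1.7), 1)    # neutral mutation
  expect_equal(survivalIndex(2, 0.5), 4)          # resistant
  expect_lt(survivalIndex(dval(0, 100, 0.5), 1), 0.01)  # sensitive, near 0
  expect_error(survivalIndex(1, 0), "pseudocount")
})

test_that("feature aggregation respects half-open boundaries", {
  cat1 <- geneCatalog(0, 10, 20)  # gene [0,10) + IG_g1_END [10,20)
  counts <- matrix(c(5L, 2L), ncol = 1, dimnames = list(NULL, "s1"))
  sc <- siteCounts(counts, position = c(4L, 12L), orientation = c("*", "*"))
  agg <- aggregateByFeature(sc, cat1)
  expect_equal(agg$actual["g1", "s1"], 5)
  expect_equal(agg$actual["IG_g1_END", "s1"], 2)
  expect_equal(unname(agg$n_sites), c(1L, 1L))

  # a site exactly at a gene's end belongs to the next feature
  sc2 <- siteCounts(matrix(3L, dimnames = list(NULL, "s1")),
                    position = 10L, orientation = "*")
  agg2 <- aggregateByFeature(sc2, cat1)
  expect_equal(agg2$actual["g1", "s1"], 0)
  expect_equal(agg2$actual["IG_g1_END", "s1"], 3)

  # empty table: all features zero
  sc0 <- siteCounts(matrix(0L, 0, 1, dimnames = list(NULL, "s1")),
                    position = integer(0), orientation = character(0))
  agg0 <- aggregateByFeature(sc0, cat1)
  expect_true(all(agg0$actual == 0))
  expect_true(all(agg0$n_sites == 0))
})

test_that("replicate log-SI t-test matches independent oracles", {
  # closed-form CDF for df = 2: F(t) = (1 + t / sqrt(2 + t^2)) / 2
  res <- replicateSignificance(c(0.5, 0.7, 0.6))
  expect_equal(res$t, 10.3923, tolerance = 1e-4)
  t <- res$t
  expect_equal(res$p, 1 - t / sqrt(2 + t^2), tolerance = 1e-12)
  expect_equal(res$p, 0.0091326, tolerance = 1e-4)
  # cross-check against stats::t.test on random replicate sets
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1), sd = 0.5)
    expect_equal(replicateSignificance(x)$p, t.test(x, mu = 0)$p.value)
  }
  # degenerate cases
  expect_equal(replicateSignificance(c(0, 0, 0))$p, 1)
  deg <- replicateSignificance(c(0.4, 0.4, 0.4))
  expect_true(deg$degenerate)
  expect_lt(deg$p, 1e-300)
  expect_error(replicateSignificance(0.5), "2 replicates")
})

test_that("length-weighted mean Dval equals 1 on every sample", {
  set.seed(42)
  g <- randomGenome(20000)
  cat1 <- featureCatalog(tileGenes(20000, 25), g)
  cfg <- screenConfig(readsPerSample = 20000)
  scr <- simulateScreen(taSites(g), cat1, cfg, seed = 42)
  sc <- simulateScreenCounts(scr, cfg)
  agg <- aggregateByFeature(sc, cat1)
  lens <- agg$features$length
  for (sm in colnames(agg$actual)) {
    pred <- predictedReads(lens, sum(agg$actual[, sm]), sum(lens))
    dv <- dval(agg$actual[, sm], pred)
    expect_lt(abs(weighted.mean(dv, lens) - 1), 1e-9)
  }
})

test_that("Dval and SI are invariant to sequencing depth scaling", {
  cat1 <- geneCatalog(c(0, 400), c(400, 1000), 1000)
  counts <- matrix(c(30L, 50L, 20L, 10L, 40L, 25L), ncol = 2,
                   dimnames = list(NULL, c("t", "c")))
  pos <- c(10L, 450L, 700L)
  sc <- siteCounts(counts, pos, rep("*", 3))
  scaled <- siteCounts(cbind(t = counts[, "t"] * 7L, c = counts[, "c"]),
                       pos, rep("*", 3))
  ft <- featureFitness(sc, cat1, treated = "t", control = "c",
                       pseudocount = 0)
  ft7 <- featureFitness(scaled, cat1, treated = "t", control = "c",
                        pseudocount = 0)
  expect_equal(ft7$dval_t, ft$dval_t)
  expect_equal(ft7$si_rep1, ft$si_rep1)
})

test_that("the minimum-site filter keeps features with 3 or more sites", {
  tab <- data.frame(feature_id = letters[1:4], n_sites = c(1L, 2L, 3L, 5L))
  kept <- filterMinSites(tab, 3L)
  expect_equal(kept$feature_id, c("c", "d"))  # exactly 3 retained: inclusive
  expect_equal(attr(kept, "removed"), 2L)
  expect_equal(nrow(filterMinSites(tab, 1L)), 4L)
  expect_error(filterMinSites(tab, 0L), ">= 1")
})

test_that("hit ranking applies the alpha cut and direction", {
  tab <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    mean_si = c(4, 4, 0.3, 9),
    p_value = c(0.01, 0.2, 0.01, 0.04),
    passes_min_sites = c(TRUE, TRUE, TRUE, TRUE))
  hits <- rankHits(tab, alpha = 0.05, direction = "resistant")
  expect_equal(hits$feature_id, c("d", "a"))  # sorted by SI, b and c excluded
  expect_equal(hits$rank, 1:2)
  sens <- rankHits(tab, alpha = 0.05, direction = "sensitive")
  expect_equal(sens$feature_id, "c")
})

test_that("the feature fitness table conserves reads and flags hits", {
  set.seed(43)
  g <- randomGenome(30000)
  cat1 <- featureCatalog(tileGenes(30000, 40), g)
  planted <- c("gene010", "gene025")
  fit <- fitnessMap(cat1, setNames(c(30, 30), planted))
  cfg <- screenConfig(readsPerSample = 40000,
                      bottlenecks = c(control = 20000, sub = 4000,
                                      bactericidal = 500))
  scr <- simulateScreen(taSites(g), cat1, cfg, fitness = fit,
                        groups = c("control", "bactericidal"), seed = 43)
  sc <- simulateScreenCounts(scr, cfg)
  ft <- featureFitness(sc, cat1,
                       treated = sprintf("bactericidal_rep%d", 1:3),
                       control = sprintf("control_rep%d", 1:3))
  # actual and predicted reads both sum to the per-sample mapped total
  for (sm in c("bactericidal_rep1", "control_rep2")) {
    expect_equal(sum(ft[[paste0("actual_", sm)]]), 40000)
    expect_equal(sum(ft[[paste0("predicted_", sm)]]), 40000)
  }
  expect_true(all(ft$mean_si > 0))
  expect_equal(ft$mean_si, exp(rowMeans(log(
    as.matrix(ft[, sprintf("si_rep%d", 1:3)])))))
  expect_true(all(ft$q_value[ft$passes_min_sites] >=
                  ft$p_value[ft$passes_min_sites] - 1e-12))
  hits <- rankHits(ft)
  expect_true(all(planted %in% hits$feature_id))
})
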