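test_that("Cf is the mean long/short ratio of the PA-NL wells", {
  expect_equal(computeCf(lwl = c(200, 220), swl = c(1000, 1100)), 0.2)
  expect_equal(computeCf(0, 1000), 0)
  expect_error(computeCf(numeric(0), numeric(0)), "no PA-NL")
  expect_error(computeCf(10, 0), "zero or missing")
})

test_that("BRET ratios subtract bleed-through and keep negative values", {
  expect_equal(bretRatio(300, 1000, cf = 0.2), 0.1)
  expect_equal(bretRatio(100, 1000, cf = 0.2), -0.1)
  expect_error(bretRatio(10, 0, 0.2), "positive")
  # self-correction identity: a PA-NL well scored with its own Cf is 0
  lwl <- c(210, 195); swl <- c(1000, 980)
  cf <- computeCf(lwl, swl)
  expect_equal(mean(bretRatio(lwl, swl, cf)), 0, tolerance = 1e-15)
})

test_that("PIR and LuC ratios normalize capture to the PA-NL reference", {
  expect_equal(computePirPanl(nlOut = 600, nlIn = 1000), 0.2)
  expect_equal(computePirPanl(0, 1000), 0)
  expect_equal(computePirPanl(500, 1000, volumeFactor = 1), 0.5)
  expect_error(computePirPanl(5, 0), "zero or missing")
  expect_equal(lucRatio(150, 500, pirPanl = 0.2), 0.5)
  expect_equal(lucRatio(0, 500, pirPanl = 0.2), 0)
  expect_error(lucRatio(10, 10, pirPanl = 0), "positive")
  # self-normalization identity: PA-NL against its own PIR is exactly 1
  nlo <- c(450, 480); nli <- c(1000, 1100)
  pir <- computePirPanl(nlo, nli)
  expect_equal(mean(lucRatio(nlo, nli, pir)), 1, tolerance = 1e-15)
})

test_that("control correction subtracts the larger control and is equivariant", {
  expect_equal(correctRatio(0.10, 0.02, 0.04), 0.06)
  expect_equal(correctRatio(0.10, 0, 0), 0.10)
  expect_equal(correctRatio(0.02, 0.05, 0.01), -0.03)
  expect_error(correctRatio(0.1, NA, 0.01), "control1")
  expect_error(correctRatio(0.1, 0.01, NA), "control2")
  set.seed(5)
  for (i in 1:25) {
    v <- rnorm(3); k <- rnorm(1)
    expect_equal(correctRatio(v[1] + k, v[2] + k, v[3] + k),
                 correctRatio(v[1], v[2], v[3]), tolerance = 1e-12)
  }
})

test_that("BRET and LuC ratios are invariant to common channel scaling", {
  set.seed(9)
  for (i in 1:20) {
    swl <- runif(1, 500, 5000); lwl <- swl * runif(1, 0.1, 0.9)
    nli <- runif(1, 100, 1000); nlo <- nli * runif(1, 0.01, 2)
    k <- runif(1, 0.1, 10)
    expect_equal(bretRatio(lwl * k, swl * k, 0.2), bretRatio(lwl, swl, 0.2),
                 tolerance = 1e-12)
    expect_equal(lucRatio(nlo * k, nli * k, 0.2), lucRatio(nlo, nli, 0.2),
                 tolerance = 1e-12)
  }
})

test_that("sensitized-emission FRET efficiency removes both bleed-throughs", {
  expect_equal(fretEfficiency(da = 50, dd = 100, aa = 200, cD = 0.3, cA = 0.05), 5)
  expect_equal(fretEfficiency(da = 0.3 * 100 + 0.05 * 200, dd = 100, aa = 200,
                              cD = 0.3, cA = 0.05), 0)
  expect_equal(fretEfficiency(da = 10, dd = 50, aa = 100, cD = 0, cA = 0), 10)
  expect_error(fretEfficiency(10, 10, 0, 0.1, 0.1), "positive")
})

test_that("screen scoring reproduces the generative model at zero noise", {
  sim <- simulateScreen(simulationParams(nPairs = 12, noiseCv = 0, seed = 3))
  sc <- scoreScreen(sim$screen)
  rep_rows <- sc[sc$level == "replicate", ]
  tr <- sim$truth
  key <- paste(rep_rows$pair_id, rep_rows$experiment_id)
  tkey <- paste(tr$pair_id, tr$experiment_id)
  tr <- tr[match(key, tkey), ]
  expect_lt(max(abs(rep_rows$c_bret - tr$expected_cbret)), 1e-9)
  expect_lt(max(abs(rep_rows$c_luc - tr$expected_cluc)), 1e-9)
  # non-interacting pairs are exactly zero
  neg <- !tr$label
  expect_equal(rep_rows$c_bret[neg], rep(0, sum(neg)), tolerance = 1e-12)
  expect_equal(rep_rows$c_luc[neg], rep(0, sum(neg)), tolerance = 1e-12)
})

test_that("aggregate scores are the mean of per-replicate corrected values", {
  sim <- simulateScreen(simulationParams(nPairs = 8, noiseCv = 0.05, seed = 21))
  sc <- scoreScreen(sim$screen)
  for (p in unique(sc$pair_id)) {
    reps <- sc[sc$pair_id == p & sc$level == "replicate", ]
    agg <- sc[sc$pair_id == p & sc$level == "aggregate", ]
    expect_equal(agg$c_bret, mean(reps$c_bret), tolerance = 1e-12)
    expect_equal(agg$c_luc, mean(reps$c_luc), tolerance = 1e-12)
  }
})

test_that("independent noisy replicates agree tightly on cBRET", {
  sim <- simulateScreen(simulationParams(nPairs = 80, noiseCv = 0.05, seed = 2))
  sc <- scoreScreen(sim$screen)
  r1 <- sc[sc$level == "replicate" & sc$experiment_id == "1", ]
  r2 <- sc[sc$level == "replicate" & sc$experiment_id == "2", ]
  r2 <- r2[match(r1$pair_id, r2$pair_id), ]
  res <- replicateCorrelation(r1$c_bret, r2$c_bret, method = "pearson")
  expect_gt(res$estimate, 0.9)
})

test_that("correction factors honour the requested scope", {
  sim <- simulateScreen(simulationParams(nPairs = 4, noiseCv = 0.05, seed = 13))
  sc_plate <- scoreScreen(sim$screen, cfScope = "plate")
  sc_exp <- scoreScreen(sim$screen, cfScope = "experiment")
  expect_true(all(sc_plate$cf_scope[sc_plate$level == "replicate"] == "plate"))
  expect_true(all(sc_exp$cf_scope[sc_exp$level == "replicate"] == "experiment"))
  # single-plate screen: pooling across the experiment is the same thing
  expect_equal(sc_plate$c_bret, sc_exp$c_bret, tolerance = 1e-12)
})
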