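test_that("equilibrium occupancy solves the binding quadratic exactly", {
  for (k in c(1e-9, 1e-7, 1e-5))
    expect_equal(equilibriumOccupancy(k, k, k), (3 - sqrt(5)) / 2,
                 tolerance = 1e-12)
  expect_equal(equilibriumOccupancy(1e-7, 0, 1e-8), 0)
  expect_equal(equilibriumOccupancy(0, 1e-7, 1e-8), 0)
  # stoichiometric limit: kd << concentrations, acceptor >= donor
  expect_equal(equilibriumOccupancy(1e-7, 1e-7, 1e-13), 1, tolerance = 1e-3)
  expect_error(equilibriumOccupancy(1, 1, 0), "positive")
})

test_that("occupancy is monotone in kd and in acceptor abundance", {
  set.seed(30)
  for (i in 1:50) {
    D <- 10^runif(1, -9, -6)
    A <- 10^runif(1, -9, -5)
    kds <- sort(10^runif(4, -10, -4))
    occ <- equilibriumOccupancy(D, A, kds)
    expect_true(all(diff(occ) <= 1e-12))
    As <- sort(10^runif(4, -9, -4))
    occA <- equilibriumOccupancy(D, As, kds[1])
    expect_true(all(diff(occA) >= -1e-12))
  }
})

test_that("simulation is byte-identical for the same seed and params", {
  p <- simulationParams(nPairs = 10, noiseCv = 0.1, seed = 99)
  s1 <- simulateScreen(p)
  s2 <- simulateScreen(p)
  expect_identical(s1$truth, s2$truth)
  expect_identical(wells(s1$screen), wells(s2$screen))
  s3 <- simulateScreen(simulationParams(nPairs = 10, noiseCv = 0.1, seed = 100))
  expect_false(identical(wells(s1$screen), wells(s3$screen)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulateScreen(simulationParams(nPairs = 4, seed = 1)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("the simulator validates parameter ranges and requires a seed", {
  expect_error(simulationParams(nPairs = 10), "seed")
  expect_error(simulationParams(nPairs = 0, seed = 1))
  expect_error(simulationParams(fractionPositive = 1.5, seed = 1))
  expect_error(simulationParams(noiseCv = -0.1, seed = 1))
})

test_that("noiseless saturation series are fit back to the true half-max", {
  sim <- simulateSaturationSeries(kd = 1e-7, donorTotal = 1e-10,
                                  acceptorTotals = 10^seq(-9, -5.5,
                                                          length.out = 10),
                                  bretMax = 0.5, noiseCv = 0, seed = 1)
  fit <- fitSaturation(sim$series$ratio, sim$series$bret)
  expect_true(fit@converged)
  expect_equal(fit@bret50, sim$truth$halfmaxRatio, tolerance = 1e-3)
  expect_equal(fit@bretMax, 0.5, tolerance = 1e-3)
})

test_that("fitted bret50 preserves the ordering of dissociation constants", {
  grids <- 10^seq(-8.5, -5, length.out = 10)
  weak <- simulateSaturationSeries(kd = 1e-6, donorTotal = 1e-9,
                                   acceptorTotals = grids, seed = 2)
  strong <- simulateSaturationSeries(kd = 1e-8, donorTotal = 1e-9,
                                     acceptorTotals = grids, seed = 3)
  fw <- fitSaturation(weak$series$ratio, weak$series$bret)
  fs <- fitSaturation(strong$series$ratio, strong$series$bret)
  expect_true(fw@converged && fs@converged)
  expect_gt(fw@bret50, fs@bret50)
})

test_that("narrow acceptor grids are flagged as degenerate designs", {
  sim <- simulateSaturationSeries(kd = 1e-7, donorTotal = 1e-9,
                                  acceptorTotals = seq(1e-7, 1.8e-7,
                                                       length.out = 6),
                                  seed = 4)
  fit <- fitSaturation(sim$series$ratio, sim$series$bret)
  expect_false(fit@converged)
})

test_that("bret50 rank-correlates with kd across a 20-pair affinity panel", {
  set.seed(44)
  kds <- 10^runif(20, -9, -6)
  b50 <- vapply(seq_along(kds), function(i) {
    sim <- simulateSaturationSeries(kd = kds[i], donorTotal = 1e-9,
                                    acceptorTotals = 10^seq(-8.5, -5,
                                                            length.out = 9),
                                    bretMax = runif(1, 0.2, 0.6),
                                    noiseCv = 0.10, seed = 100 + i)
    fitSaturation(sim$series$ratio, sim$series$bret)@bret50
  }, 0)
  ok <- is.finite(b50)
  expect_gte(sum(ok), 15)
  res <- replicateCorrelation(b50[ok], kds[ok], method = "spearman")
  expect_gt(res$estimate, 0)
  expect_lt(res$p.value, 1e-3)
})

test_that("the default benchmark screen is recovered at the fixed cutoffs", {
  sim <- simulateScreen(simulationParams(nPairs = 160, noiseCv = 0.05,
                                         seed = 42))
  sc <- scoreScreen(sim$screen)
  calls <- callInteractions(sc)
  tru <- unique(sim$truth[, c("pair_id", "label", "kd")])
  m <- merge(calls, tru, by = "pair_id")
  strongPos <- m$label & m$kd <= 1e-6
  expect_gte(mean(m$any_positive[strongPos]), 0.9)
  expect_gte(mean(!m$any_positive[!m$label]), 0.95)
})

test_that("synthetic image pairs encode the requested shift and ratios", {
  sim <- simulateImagePair(shape = c(48, 48), ratioMap = 0.3,
                           shift = c(2, -1), noiseCv = 0, seed = 5)
  expect_identical(dim(sim$chShort), c(48L, 48L))
  reg <- registerTranslation(sim$chShort, sim$chLong, maxShift = 4)
  expect_identical(as.vector(reg), c(2L, -1L))
})
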