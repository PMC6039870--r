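# build a scores data.frame (replicate + aggregate rows) for a panel of
# partners from per-partner true values with multiplicative noise
makeProfile <- function(values, nrep = 2, cv = 0, seed = 1,
                        luc = NULL) {
  set.seed(seed)
  partners <- names(values)
  rows <- list()
  for (r in seq_len(nrep)) {
    noise <- exp(rnorm(length(values), 0, sqrt(log(1 + cv^2))))
    lnoise <- exp(rnorm(length(values), 0, sqrt(log(1 + cv^2))))
    rows[[r]] <- data.frame(
      pair_id = partners, experiment_id = as.character(r),
      level = "replicate",
      c_bret = unname(values) * noise,
      c_luc = if (is.null(luc)) unname(values) * 2 * lnoise
              else unname(luc) * lnoise,
      stringsAsFactors = FALSE)
  }
  rep_df <- do.call(rbind, rows)
  agg <- aggregate(cbind(c_bret, c_luc) ~ pair_id, rep_df, mean)
  agg$experiment_id <- NA_character_; agg$level <- "aggregate"
  rbind(rep_df, agg[, names(rep_df)])
}

test_that("call flips classify as lost and gained", {
  wt <- makeProfile(c(p1 = 0.10, p2 = 0.005))
  va <- makeProfile(c(p1 = 0.005, p2 = 0.10))
  cmp <- compareVariantProfiles(wt, va, nPerm = 500, seed = 2)
  bret <- cmp[cmp$readout == "bret", ]
  expect_identical(bret$effect_class[bret$pair_id == "p1"], "lost")
  expect_identical(bret$effect_class[bret$pair_id == "p2"], "gained")
})

test_that("identical profiles are unchanged with zero deltas", {
  wt <- makeProfile(c(a = 0.2, b = 0.05, c = 0.002), cv = 0.05, seed = 3)
  cmp <- compareVariantProfiles(wt, wt, nPerm = 500, seed = 4)
  expect_true(all(cmp$effect_class == "unchanged"))
  expect_true(all(cmp$delta == 0))
})

test_that("zero-noise classification matches ground truth exactly", {
  truth <- c(a = 0.20, b = 0.10, c = 0.05, d = 0.002)
  altered <- truth; altered[c("a", "b")] <- altered[c("a", "b")] / 2
  wt <- makeProfile(truth, cv = 0)
  va <- makeProfile(altered, cv = 0)
  cmp <- compareVariantProfiles(wt, va, nPerm = 500, seed = 5)
  bret <- cmp[cmp$readout == "bret", ]
  cls <- setNames(bret$effect_class, bret$pair_id)
  expect_identical(unname(cls[c("a", "b")]), c("decreased", "decreased"))
  expect_identical(unname(cls[c("c", "d")]), c("unchanged", "unchanged"))
})

test_that("classification is antisymmetric under profile swap", {
  set.seed(6)
  vals <- setNames(round(runif(12, 0, 0.3), 3), sprintf("p%02d", 1:12))
  alt <- vals * sample(c(0.4, 1, 2.5), 12, replace = TRUE)
  wt <- makeProfile(vals, cv = 0.05, seed = 7)
  va <- makeProfile(alt, cv = 0.05, seed = 8)
  fwd <- compareVariantProfiles(wt, va, nPerm = 2000, seed = 9)
  rev <- compareVariantProfiles(va, wt, nPerm = 2000, seed = 9)
  swap <- c(lost = "gained", gained = "lost", decreased = "increased",
            increased = "decreased", unchanged = "unchanged",
            incomparable = "incomparable")
  expect_identical(unname(swap[fwd$effect_class]), rev$effect_class)
  expect_equal(fwd$delta, -rev$delta, tolerance = 1e-12)
})

test_that("halved-occupancy partners are detected with few false positives", {
  set.seed(10)
  vals <- setNames(runif(20, 0.05, 0.3), sprintf("p%02d", 1:20))
  altered_idx <- sprintf("p%02d", 1:10)
  alt <- vals; alt[altered_idx] <- alt[altered_idx] / 2
  wt <- makeProfile(vals, cv = 0.05, seed = 11)
  va <- makeProfile(alt, cv = 0.05, seed = 12)
  cmp <- compareVariantProfiles(wt, va, nPerm = 4000, seed = 13)
  bret <- cmp[cmp$readout == "bret", ]
  hit <- bret$effect_class %in% c("decreased", "lost")
  expect_gte(sum(hit[bret$pair_id %in% altered_idx]), 8)
  expect_lte(sum(hit[!bret$pair_id %in% altered_idx]), 1)
})

test_that("partners present in only one profile are incomparable", {
  wt <- makeProfile(c(a = 0.1, b = 0.2))
  va <- makeProfile(c(a = 0.1))
  cmp <- compareVariantProfiles(wt, va, nPerm = 200, seed = 14)
  expect_true(all(cmp$effect_class[cmp$pair_id == "b"] == "incomparable"))
})

test_that("single-group resampling agrees with exact permutation enumeration", {
  set.seed(15)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(4, mean = sample(c(0, 1.5), 1))
    exact <- oracleTwoSamplePermutation(a, b)
    res <- resamplingManyToOne(a, list(g = b), nPerm = 20000, seed = 16 + i)
    expect_lt(abs(res$p_raw - exact), 0.02)
    expect_equal(res$p_adjusted, res$p_raw)  # single group: no adjustment
  }
})

test_that("a strongly shifted group is called at adjusted p < 0.01", {
  set.seed(20)
  ctrl <- rnorm(6, 0, 1)
  groups <- list(null1 = rnorm(4), null2 = rnorm(4),
                 shifted = rnorm(4, mean = 5))
  res <- resamplingManyToOne(ctrl, groups, nPerm = 2000, seed = 21)
  expect_lt(res$p_adjusted[res$group == "shifted"], 0.01)
  expect_gt(min(res$p_adjusted[res$group != "shifted"]), 0.05)
})

test_that("family-wise error of the max-T test stays near nominal", {
  set.seed(22)
  hits <- replicate(200, {
    ctrl <- rnorm(6)
    groups <- list(a = rnorm(4), b = rnorm(4), c = rnorm(4))
    res <- resamplingManyToOne(ctrl, groups, nPerm = 299,
                               seed = sample.int(1e6, 1))
    any(res$p_adjusted < 0.05)
  })
  expect_lte(mean(hits), 0.07)
})

test_that("insufficient replication is an error", {
  expect_error(resamplingManyToOne(1, list(g = c(1, 2))), "2 replicates")
  expect_error(resamplingManyToOne(c(1, 2), list(g = 3)), "2 replicates")
})
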