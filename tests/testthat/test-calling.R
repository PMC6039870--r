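test_that("cutoff class is membrane only when both proteins are membrane", {
  ann <- c(STX1A = "membrane", VAMP2 = "membrane", BAD = "non_membrane")
  expect_identical(cutoffClass("STX1A", "VAMP2", ann), "membrane_pair")
  expect_identical(cutoffClass("STX1A", "BAD", ann), "default")
  expect_identical(cutoffClass("XX", "YY", ann), "default")
  expect_identical(cutoffClass("XX", "YY", NULL), "default")
})

test_that("calls use inclusive class-specific cutoffs", {
  s <- data.frame(pair_id = "p", c_bret = 0.02, c_luc = 0.01)
  def <- callInteractions(s, classes = "default")
  expect_true(def$bret_positive); expect_false(def$luc_positive)
  expect_false(def$double_positive); expect_true(def$any_positive)
  mem <- callInteractions(s, classes = "membrane_pair")
  expect_false(mem$bret_positive); expect_false(mem$any_positive)
  # inclusive boundary
  b <- callInteractions(data.frame(pair_id = "p", c_bret = 0.01,
                                   c_luc = -1), classes = "default")
  expect_true(b$bret_positive)
})

test_that("uncorrected scores are refused from calling", {
  s <- data.frame(pair_id = c("a", "b"), c_bret = c(0.1, 0.2),
                  c_luc = c(0.1, 0.2), uncorrected = c(FALSE, TRUE))
  calls <- callInteractions(s)
  expect_equal(nrow(calls), 1L)
  expect_identical(attr(calls, "excluded"), "b")
})

test_that("membrane reclassification never flips a negative call positive", {
  set.seed(31)
  s <- data.frame(pair_id = sprintf("p%02d", 1:40),
                  c_bret = rnorm(40, 0.02, 0.03),
                  c_luc = rnorm(40, 0.03, 0.04))
  def <- callInteractions(s, classes = "default")
  mem <- callInteractions(s, classes = "membrane_pair")
  expect_true(all(!def$any_positive | def$any_positive >= mem$any_positive))
  expect_true(all(mem$bret_positive <= def$bret_positive))
  expect_true(all(mem$luc_positive <= def$luc_positive))
})

test_that("raising cutoffs never increases any positive count", {
  set.seed(17)
  s <- data.frame(pair_id = sprintf("p%03d", 1:100),
                  c_bret = rnorm(100, 0.02, 0.05),
                  c_luc = rnorm(100, 0.02, 0.05))
  base <- summarizeScreen(callInteractions(s, scheme = cutoffScheme()))
  for (i in 1:10) {
    db <- runif(1, 0, 0.05); dl <- runif(1, 0, 0.05)
    up <- cutoffScheme(0.01 + db, 0.03 + dl, 0.03 + db, 0.05 + dl)
    high <- summarizeScreen(callInteractions(s, scheme = up))
    for (col in c("bret_positive", "luc_positive", "double_positive",
                  "any_positive"))
      expect_lte(high[[col]], base[[col]])
  }
})

test_that("screen summaries report recovery by reference label", {
  s <- data.frame(pair_id = c("a", "b", "c", "d"),
                  c_bret = c(0.10, 0.002, 0.05, -0.01),
                  c_luc = c(0.10, 0.01, 0.01, 0.001))
  calls <- callInteractions(s)
  labels <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  sm <- summarizeScreen(calls, labels)
  expect_equal(sm$n, c(4, 2, 2))
  pos <- sm[sm$group == "positive", ]
  expect_equal(pos$any_positive, 1)
  expect_equal(pos$pct_any, 50)
  neg <- sm[sm$group == "negative", ]
  expect_equal(neg$any_positive, 1)  # pair c is a false positive by BRET
  # all-negative screen: zero everywhere
  none <- callInteractions(data.frame(pair_id = c("x", "y"),
                                      c_bret = c(-0.1, 0), c_luc = c(0, 0.01)))
  sm0 <- summarizeScreen(none)
  expect_equal(sm0$any_positive, 0)
  expect_equal(sm0$pct_any, 0)
})

test_that("ROC analysis matches hand-computable cases", {
  perfect <- rocAnalysis(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect@auc, 1)
  # concordant pairs: (0.8 vs 0.6) + (0.8 vs 0.1) + (0.2 vs 0.1) = 3 of 4
  mixed <- rocAnalysis(c(0.8, 0.2, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(mixed@auc, 0.75)
  expect_error(rocAnalysis(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("trapezoidal AUC equals the concordant-pair statistic", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    roc <- rocAnalysis(scores, labels)
    expect_equal(roc@auc, oracleAucConcordance(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- rnorm(60); labels <- runif(60) > 0.4
  roc <- rocAnalysis(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<")))
  expect_equal(roc@auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(77)
  scores <- rnorm(200)
  labels <- rep(c(TRUE, FALSE), each = 100)
  aucs <- replicate(100, rocAnalysis(scores, sample(labels))@auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("Fisher's exact test matches full hypergeometric enumeration", {
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10),
               tolerance = 1e-12)
  set.seed(19)
  for (i in 1:40) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisherExact2x2(tab), oracleFisher2x2(tab),
                 tolerance = 1e-9)
    # invariances: transposition and swapping both rows and both columns
    expect_equal(fisherExact2x2(t(tab)), fisherExact2x2(tab),
                 tolerance = 1e-12)
    expect_equal(fisherExact2x2(tab[2:1, 2:1]), fisherExact2x2(tab),
                 tolerance = 1e-12)
  }
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisherExact2x2(matrix(c(0.5, 1, 1, 1), 2)), "integer")
})

test_that("replicate correlation handles linear and monotone relations", {
  x <- c(0.01, 0.05, 0.1, 0.2, 0.35, 0.5, 0.02, 0.08, 0.15, 0.4)
  expect_equal(replicateCorrelation(x, 2 * x + 1)$estimate, 1)
  sp <- replicateCorrelation(x, exp(x), method = "spearman")
  expect_equal(sp$estimate, 1)
  expect_lt(replicateCorrelation(x, exp(3 * x))$estimate, 1)
  y <- c(0.3, 0.2, 0.9, 0.1, 0.5, 0.55, 0.25, 0.15, 0.6, 0.05)
  expect_equal(replicateCorrelation(x, y, method = "spearman")$estimate,
               oracleSpearman(x, y), tolerance = 1e-12)
  expect_error(replicateCorrelation(rep(1, 5), 1:5), "constant")
  expect_error(replicateCorrelation(1:2, 2:3), "3 complete")
})
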