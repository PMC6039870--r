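## Turning corrected scores into interaction calls, and the reference-set
## statistics used to calibrate and benchmark the assay.

#' Cutoff class of a protein pair
#'
#' A pair is held to the stricter membrane cutoffs only when BOTH proteins
#' are membrane-associated; pairs with at least one cytoplasmic, nuclear or
#' unannotated protein use the default cutoffs.
#'
#' @param proteinA,proteinB character vectors of protein symbols
#'   (vectorized).
#' @param annotation named localization vector from [readLocalization()],
#'   or NULL (all proteins default to non_membrane).
#' @return character vector, "membrane_pair" or "default".
#' @export
cutoffClass <- function(proteinA, proteinB, annotation = NULL) {
  a <- localizationOf(annotation, proteinA)
  b <- localizationOf(annotation, proteinB)
  ifelse(a == "membrane" & b == "membrane", "membrane_pair", "default")
}

#' Call interactions from corrected scores
#'
#' Applies the inclusive (>=) cutoff scheme to aggregate cBRET and cLuC
#' ratios. Scores flagged `uncorrected` are refused from calling and
#' reported via the `"excluded"` attribute of the result.
#'
#' @param scores data.frame from [scoreScreen()], or any data.frame with
#'   columns `pair_id`, `c_bret` and (optionally) `c_luc`. When a `level`
#'   column is present only `"aggregate"` rows are used.
#' @param scheme A [CutoffScheme-class] (defaults to the published cutoffs).
#' @param classes optional character vector of cutoff classes per row of
#'   `scores` ("default"/"membrane_pair"); computed from `screen` +
#'   `annotation` when omitted.
#' @param screen optional [LuthyScreen-class] used to resolve pair proteins.
#' @param annotation optional localization annotation.
#' @return data.frame with columns `pair_id`, `cutoff_class`, `c_bret`,
#'   `c_luc`, `bret_positive`, `luc_positive`, `double_positive`,
#'   `any_positive`. For BRET-only data `luc_positive` is NA and
#'   `any_positive`/`double_positive` reduce to the BRET flag.
#' @export
callInteractions <- function(scores, scheme = cutoffScheme(), classes = NULL,
                             screen = NULL, annotation = NULL) {
  stopifnot(is(scheme, "CutoffScheme"))
  s <- as.data.frame(scores)
  if ("level" %in% names(s)) s <- s[s$level == "aggregate", , drop = FALSE]
  if (!all(c("pair_id", "c_bret") %in% names(s)))
    stop("scores must contain pair_id and c_bret")
  if (!"c_luc" %in% names(s)) s$c_luc <- NA_real_
  excluded <- character(0)
  if ("uncorrected" %in% names(s)) {
    excluded <- s$pair_id[s$uncorrected]
    if (length(excluded))
      s <- s[!s$uncorrected, , drop = FALSE]
  }
  if (any(is.na(s$c_bret)))
    stop("aggregate c_bret missing for pair(s): ",
         paste(s$pair_id[is.na(s$c_bret)], collapse = ", "))
  if (is.null(classes)) {
    if (!is.null(screen)) {
      pp <- pairProteins(screen)
      idx <- match(s$pair_id, pp$pair_id)
      classes <- cutoffClass(pp$donor_protein[idx], pp$acceptor_protein[idx],
                             annotation)
    } else classes <- rep("default", nrow(s))
  } else {
    if (length(classes) == 1L) classes <- rep(classes, nrow(s))
    stopifnot(length(classes) == nrow(s),
              all(classes %in% c("default", "membrane_pair")))
  }
  mem <- classes == "membrane_pair"
  cb <- ifelse(mem, scheme@cbretMembrane, scheme@cbretDefault)
  cl <- ifelse(mem, scheme@clucMembrane, scheme@clucDefault)
  bret_pos <- s$c_bret >= cb
  luc_pos <- ifelse(is.na(s$c_luc), NA, s$c_luc >= cl)
  double_pos <- bret_pos & ifelse(is.na(luc_pos), FALSE, luc_pos)
  any_pos <- bret_pos | ifelse(is.na(luc_pos), FALSE, luc_pos)
  out <- data.frame(pair_id = s$pair_id, cutoff_class = classes,
                    c_bret = s$c_bret, c_luc = s$c_luc,
                    bret_positive = bret_pos, luc_positive = luc_pos,
                    double_positive = double_pos, any_positive = any_pos,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Proteins tested in each pair of a screen
#'
#' @param screen A [LuthyScreen-class].
#' @return data.frame `pair_id`, `donor_protein`, `acceptor_protein`.
#' @export
pairProteins <- function(screen) {
  p <- screenPairs(screen)
  cs <- constructs(screen)
  data.frame(pair_id = p$pair_id,
             donor_protein = cs$protein[match(p$donor_id, cs$construct_id)],
             acceptor_protein = cs$protein[match(p$acceptor_id, cs$construct_id)],
             stringsAsFactors = FALSE)
}

#' Summarize a called screen
#'
#' Counts and percentages of BRET-positive, LuC-positive, double-positive
#' and any-positive pairs, overall and (when reference labels are supplied)
#' within the true-positive and true-negative subsets, giving the assay's
#' recovery rates on a reference panel.
#'
#' @param calls data.frame from [callInteractions()].
#' @param labels optional logical vector (aligned with `calls`, or named by
#'   pair id) marking reference positives.
#' @return data.frame with one row per group ("all", and "positive" /
#'   "negative" when labels are given): `n`, counts and `pct_*` percentages.
#' @export
summarizeScreen <- function(calls, labels = NULL) {
  cnt <- function(d) {
    n <- nrow(d)
    k <- function(v) sum(v, na.rm = TRUE)
    data.frame(n = n,
               bret_positive = k(d$bret_positive),
               luc_positive = k(d$luc_positive),
               double_positive = k(d$double_positive),
               any_positive = k(d$any_positive),
               pct_bret = 100 * k(d$bret_positive) / max(n, 1L),
               pct_luc = 100 * k(d$luc_positive) / max(n, 1L),
               pct_double = 100 * k(d$double_positive) / max(n, 1L),
               pct_any = 100 * k(d$any_positive) / max(n, 1L))
  }
  out <- cbind(group = "all", cnt(calls), stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    if (!is.null(names(labels)))
      labels <- unname(labels[calls$pair_id])
    stopifnot(length(labels) == nrow(calls))
    out <- rbind(out,
                 cbind(group = "positive", cnt(calls[labels %in% TRUE, ])),
                 cbind(group = "negative", cnt(calls[labels %in% FALSE, ])))
  }
  rownames(out) <- NULL
  out
}

#' Empirical ROC analysis of a labeled score set
#'
#' Computes the full empirical ROC over all distinct score thresholds
#' (prediction positive when score >= threshold, matching the inclusive
#' cutoff convention), the trapezoidal AUC, its Hanley-McNeil standard
#' error, and the Youden-optimal threshold as a suggestion for cutoff
#' calibration.
#'
#' @param scores numeric vector of (corrected) ratios.
#' @param labels logical (or 0/1) vector; both classes must be represented.
#' @return A [RocResult-class].
#' @export
rocAnalysis <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("both positive and negative labels are required for ROC analysis")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t), 0) / nPos
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t), 0) / nNeg
  xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  # Hanley & McNeil (1982) analytic standard error of the empirical AUC
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  aucSe <- sqrt((auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
                 (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg))
  youden <- thr[which.max(tpr - fpr)]
  new("RocResult", thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
      aucSe = aucSe, youden = youden, nPos = as.integer(nPos),
      nNeg = as.integer(nNeg))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by summing, over all tables with the observed
#' margins, the hypergeometric probabilities no larger than that of the
#' observed table (the conventional minimum-likelihood definition). Used
#' for comparing recovery rates between affinity sub-groups.
#'
#' @param x 2x2 matrix (or coercible) of non-negative integer counts.
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(5, 5, 5, 5), 2))    # 1
#' @export
fisherExact2x2 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L)))
    stop("x must be a 2x2 table")
  if (any(is.na(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8))
    stop("x must contain non-negative integer counts")
  stats::fisher.test(matrix(as.integer(round(x)), 2L))$p.value
}

#' Between-replicate correlation of interaction scores
#'
#' Pearson or Spearman correlation with a two-tailed p-value from the
#' t-approximation (the asymptotic test of `stats::cor.test`; for Spearman
#' the AS89/t approximation is used rather than the exact permutation
#' distribution).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param method "pearson" or "spearman".
#' @return list with `estimate` (coefficient) and `p.value`.
#' @export
replicateCorrelation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for constant input")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE,
                        alternative = "two.sided")
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}
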