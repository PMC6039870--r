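## Differential interaction profiling: the effect of bait variants (for
## example disease missense mutations) on an interaction panel relative to
## wild type. Two inference tools are provided: a shared-control
## many-to-one max-T permutation test for group-level comparisons, and a
## per-partner max-T resampling test with panel-pooled noise variance used
## by the profile classifier (replicate numbers per partner are far too
## small for within-partner permutation alone).

#' Many-to-one resampling comparison against a shared control
#'
#' Permutation analog of a one-way ANOVA followed by many-to-one post hoc
#' comparisons: each treatment group is compared against the shared control
#' with the absolute difference of means, and family-wise adjusted p-values
#' are obtained from the permutation distribution of the maximum statistic
#' (max-T adjustment), making the procedure assumption-light and exact in
#' distribution under exchangeability. Deterministic for a given seed and
#' permutation count.
#'
#' @param control numeric vector of control replicates (n >= 2).
#' @param groups named list of numeric treatment-group vectors (each
#'   n >= 2).
#' @param nPerm number of random permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame with one row per group: `group`, `delta` (group mean
#'   minus control mean), `statistic`, `p_raw`, `p_adjusted`.
#' @export
resamplingManyToOne <- function(control, groups, nPerm = 10000, seed = 1) {
  if (!is.list(groups)) groups <- list(group1 = groups)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (length(control) < 2 || any(vapply(groups, length, 0L) < 2))
    stop("at least 2 replicates are required in the control and every group")
  pool <- c(control, unlist(groups, use.names = FALSE))
  nTot <- length(pool)
  nC <- length(control)
  sizes <- vapply(groups, length, 0L)
  ends <- nC + cumsum(sizes)
  starts <- ends - sizes + 1L
  obsDelta <- vapply(groups, mean, 0) - mean(control)
  obsT <- abs(obsDelta)

  .withSeed(seed, {
    permT <- matrix(0, nPerm, length(groups))
    for (b in seq_len(nPerm)) {
      perm <- pool[sample.int(nTot)]
      mC <- mean(perm[seq_len(nC)])
      for (g in seq_along(groups))
        permT[b, g] <- abs(mean(perm[starts[g]:ends[g]]) - mC)
    }
    maxT <- apply(permT, 1L, max)
    p_raw <- vapply(seq_along(groups), function(g)
      (1 + sum(permT[, g] >= obsT[g] - 1e-12)) / (nPerm + 1), 0)
    p_adj <- vapply(seq_along(groups), function(g)
      (1 + sum(maxT >= obsT[g] - 1e-12)) / (nPerm + 1), 0)
    data.frame(group = names(groups), delta = unname(obsDelta),
               statistic = unname(obsT), p_raw = p_raw, p_adjusted = p_adj,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

# Per-partner max-T resampling with noise SD pooled across the panel.
# Returns adjusted p-values for |t| = |delta| / (s * sqrt(1/nw + 1/nv)).
.panelMaxT <- function(wtMat, varMat, nPerm, seed) {
  # wtMat/varMat: lists (per partner) of replicate vectors
  resid2 <- 0; df <- 0L
  for (v in c(wtMat, varMat)) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) {
      resid2 <- resid2 + sum((v - mean(v))^2)
      df <- df + length(v) - 1L
    }
  }
  s <- if (df > 0) sqrt(resid2 / df) else 0
  n <- length(wtMat)
  tObs <- numeric(n)
  for (i in seq_len(n)) {
    wv <- wtMat[[i]][!is.na(wtMat[[i]])]; vv <- varMat[[i]][!is.na(varMat[[i]])]
    if (!length(wv) || !length(vv)) { tObs[i] <- NA_real_; next }
    delta <- mean(vv) - mean(wv)
    se <- s * sqrt(1 / length(wv) + 1 / length(vv))
    tObs[i] <- if (se == 0) { if (delta == 0) 0 else Inf } else abs(delta) / se
  }
  ok <- !is.na(tObs)
  m <- sum(ok)
  p_adj <- rep(NA_real_, n)
  if (m > 0) {
    maxZ <- .withSeed(seed, {
      z <- matrix(stats::rnorm(nPerm * m), nPerm, m)
      apply(abs(z), 1L, max)
    })
    p_adj[ok] <- vapply(tObs[ok], function(t)
      (1 + sum(maxZ >= t - 1e-12)) / (nPerm + 1), 0)
  }
  p_raw <- 2 * stats::pnorm(-tObs)
  list(t = tObs, p_raw = p_raw, p_adjusted = p_adj, s = s, df = df)
}

#' Compare a variant's interaction profile against wild type
#'
#' For every partner protein measured with both the wild-type and the
#' variant bait, computes the change in aggregate cBRET and cLuC, a
#' resampling-based family-wise adjusted p-value (max-T over the panel,
#' with the replicate noise SD pooled across partners), and an effect class
#' per readout:
#' \describe{
#'   \item{lost}{wild type called positive, variant negative.}
#'   \item{gained}{wild type negative, variant positive.}
#'   \item{decreased/increased}{call retained positive in both, adjusted
#'     p below `alpha` and |delta| at or above the readout's effect floor.}
#'   \item{unchanged}{otherwise.}
#' }
#' Partners present in only one profile are reported as `incomparable`,
#' never dropped silently. The classification is antisymmetric: swapping
#' the two profiles swaps lost with gained and decreased with increased.
#'
#' @param wt,variant score data.frames from [scoreScreen()] (replicate and
#'   aggregate rows) for the same partner panel, keyed by `pair_id`.
#' @param scheme A [CutoffScheme-class].
#' @param classes cutoff classes per partner ("default"/"membrane_pair"),
#'   a single value, or a named vector by pair id; default all "default".
#' @param deltaFloorBret,deltaFloorLuc minimum |delta| for a
#'   decreased/increased class (defaults mirror the calling cutoffs, 0.01
#'   and 0.03).
#' @param alpha significance level for the adjusted p-value (default 0.05).
#' @param nPerm resampling draws for the max-T adjustment (default 10000).
#' @param seed integer seed.
#' @return data.frame with one row per partner and readout: `pair_id`,
#'   `readout` ("bret"/"luc"), `wt_value`, `variant_value`, `delta`,
#'   `statistic`, `p_raw`, `p_adjusted`, `wt_positive`, `variant_positive`,
#'   `effect_class`.
#' @export
compareVariantProfiles <- function(wt, variant, scheme = cutoffScheme(),
                                   classes = "default",
                                   deltaFloorBret = 0.01,
                                   deltaFloorLuc = 0.03,
                                   alpha = 0.05, nPerm = 10000, seed = 1) {
  stopifnot(is(scheme, "CutoffScheme"))
  getRep <- function(s) s[s$level == "replicate", , drop = FALSE]
  getAgg <- function(s) s[s$level == "aggregate", , drop = FALSE]
  wtR <- getRep(wt); vaR <- getRep(variant)
  wtA <- getAgg(wt); vaA <- getAgg(variant)
  partners <- sort(union(wtA$pair_id, vaA$pair_id))
  shared <- intersect(wtA$pair_id, vaA$pair_id)
  if (!all(table(wtR$pair_id[wtR$pair_id %in% shared]) >= 2) ||
      !all(table(vaR$pair_id[vaR$pair_id %in% shared]) >= 2))
    stop("at least 2 replicate experiments per profile are required")

  if (length(classes) == 1L && is.null(names(classes)))
    classes <- stats::setNames(rep(classes, length(partners)), partners)
  cls <- rep("default", length(partners))
  names(cls) <- partners
  hit <- intersect(names(classes), partners)
  cls[hit] <- classes[hit]

  repvals <- function(repdf, col)
    lapply(shared, function(p) repdf[[col]][repdf$pair_id == p])
  out <- list()
  for (readout in c("bret", "luc")) {
    col <- if (readout == "bret") "c_bret" else "c_luc"
    floorv <- if (readout == "bret") deltaFloorBret else deltaFloorLuc
    cut_def <- if (readout == "bret") scheme@cbretDefault else scheme@clucDefault
    cut_mem <- if (readout == "bret") scheme@cbretMembrane else scheme@clucMembrane
    wtVal <- wtA[[col]][match(partners, wtA$pair_id)]
    vaVal <- vaA[[col]][match(partners, vaA$pair_id)]
    if (all(is.na(wtVal)) && all(is.na(vaVal))) next  # readout not measured
    mt <- .panelMaxT(repvals(wtR, col), repvals(vaR, col), nPerm,
                     seed + (readout == "luc"))
    ix <- match(partners, shared)
    t_all <- mt$t[ix]; praw <- mt$p_raw[ix]; padj <- mt$p_adjusted[ix]
    cutoff <- ifelse(cls == "membrane_pair", cut_mem, cut_def)
    wtPos <- wtVal >= cutoff
    vaPos <- vaVal >= cutoff
    delta <- vaVal - wtVal
    eff <- character(length(partners))
    for (i in seq_along(partners)) {
      if (is.na(wtVal[i]) || is.na(vaVal[i])) { eff[i] <- "incomparable"; next }
      sig <- !is.na(padj[i]) && padj[i] < alpha && abs(delta[i]) >= floorv
      eff[i] <-
        if (wtPos[i] && !vaPos[i]) "lost"
        else if (!wtPos[i] && vaPos[i]) "gained"
        else if (wtPos[i] && vaPos[i] && sig && delta[i] < 0) "decreased"
        else if (wtPos[i] && vaPos[i] && sig && delta[i] > 0) "increased"
        else "unchanged"
    }
    out[[readout]] <- data.frame(
      pair_id = partners, readout = readout,
      wt_value = wtVal, variant_value = vaVal, delta = delta,
      statistic = t_all, p_raw = praw, p_adjusted = padj,
      wt_positive = wtPos, variant_positive = vaPos, effect_class = eff,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
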