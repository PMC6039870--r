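## Donor-saturation and dose-response fitting, plus the simple perturbation
## normalizations used in time-course and tagging-orientation experiments.

#' Acceptor/donor expression ratio from fluorescence and luminescence
#'
#' The fluorescence/luminescence ratio of a well estimates the acceptor to
#' donor molar ratio once normalized to the same ratio measured for the
#' tandem PA-mCit-NL fusion, in which acceptor and donor are present at
#' exactly 1:1 stoichiometry.
#'
#' @param fluor acceptor (mCitrine) fluorescence.
#' @param lum donor (NanoLuc) luminescence (> 0).
#' @param tandemRefRatio fluorescence/luminescence ratio of the tandem
#'   construct (> 0).
#' @return estimated acceptor:donor molar ratio (vectorized).
#' @examples
#' normalizeAcceptorDonor(2000, 500, tandemRefRatio = 2)  # 2
#' @export
normalizeAcceptorDonor <- function(fluor, lum, tandemRefRatio) {
  if (any(!is.na(lum) & lum <= 0))
    stop("luminescence must be positive")
  if (any(is.na(tandemRefRatio)) || any(tandemRefRatio <= 0))
    stop("tandemRefRatio must be positive")
  (fluor / lum) / tandemRefRatio
}

.saturationModel <- function(r, bretMax, bret50) bretMax * r / (bret50 + r)

#' Fit a donor-saturation curve (BRETmax / BRET50)
#'
#' Least-squares fit of the one-site rectangular hyperbola
#' `BRET(r) = bretMax * r / (bret50 + r)` to a titration of acceptor/donor
#' expression ratios r. `bret50` is the ratio at half-maximal BRET and
#' rank-correlates with the dissociation constant of the pair. Raw BRET or
#' corrected cBRET values are both accepted as the response.
#'
#' Initialization uses `bretMax = max(response)` and `bret50 =` the ratio
#' nearest half-max; on failure two further starts (lower/upper quartile
#' ratios) are tried. Degenerate series (flat response, all-equal ratios,
#' or a half-saturation point pinned to the search bounds) are reported
#' with `converged = FALSE` rather than a silent value.
#'
#' @param ratio acceptor/donor ratios (>= 4 distinct values; a span of at
#'   least 4-fold is required for a trustworthy fit and narrower designs
#'   are flagged).
#' @param bret observed BRET or cBRET values.
#' @return A [SaturationFit-class].
#' @export
fitSaturation <- function(ratio, bret) {
  stopifnot(length(ratio) == length(bret))
  keep <- !is.na(ratio) & !is.na(bret)
  ratio <- ratio[keep]; bret <- bret[keep]
  if (length(unique(ratio)) < 4L)
    stop("at least 4 distinct acceptor/donor ratios are required")
  if (any(ratio < 0))
    stop("ratios must be non-negative")
  fail <- function(msg)
    new("SaturationFit", bretMax = NA_real_, bret50 = NA_real_,
        rss = NA_real_, converged = FALSE, diagnostics = msg)
  if (stats::sd(bret) == 0)
    return(fail("flat response: bret50 unidentifiable"))
  narrow <- max(ratio) / max(min(ratio[ratio > 0]), .Machine$double.xmin) < 4
  lo <- c(bretMax = -Inf, bret50 = max(ratio) * 1e-9)
  hi <- c(bretMax = Inf, bret50 = max(ratio) * 1e6)
  halfmax <- ratio[which.min(abs(bret - max(bret) / 2))]
  starts <- list(
    c(bretMax = max(bret), bret50 = max(halfmax, lo[["bret50"]])),
    c(bretMax = max(bret), bret50 = unname(stats::quantile(ratio, 0.25))),
    c(bretMax = max(bret), bret50 = unname(stats::quantile(ratio, 0.75))))
  best <- NULL
  for (st in starts) {
    st["bret50"] <- min(max(st[["bret50"]], lo[["bret50"]]), hi[["bret50"]])
    fit <- tryCatch(
      minpack.lm::nlsLM(bret ~ bretMax * ratio / (bret50 + ratio),
                        start = as.list(st), lower = lo, upper = hi,
                        control = minpack.lm::nls.lm.control(
                          ptol = 1e-10, ftol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(fail("least-squares fit did not converge"))
  cf <- stats::coef(best$fit)
  b50 <- unname(cf["bret50"])
  if (b50 <= lo[["bret50"]] * 1.01 || b50 >= hi[["bret50"]] * 0.99)
    return(fail("bret50 pinned to search bounds: saturation not identifiable"))
  if (narrow)
    return(fail("ratio span below 4-fold: bret50 not identifiable"))
  new("SaturationFit", bretMax = unname(cf["bretMax"]), bret50 = b50,
      rss = best$rss, converged = TRUE, diagnostics = "")
}

.fourPL <- function(x, bottom, top, hill, x50)
  bottom + (top - bottom) / (1 + 10^((x50 - x) * hill))

#' Fit a four-parameter logistic dose-response curve (EC50/IC50)
#'
#' Fits `y = bottom + (top - bottom) / (1 + 10^((log10(ec50) - log10(d)) *
#' hill))` on log10 dose, with the Hill slope constrained positive so that
#' `bottom` and `top` are the low- and high-dose asymptotes. The direction
#' is inferred from their order: `top > bottom` is stimulation (EC50),
#' `top < bottom` inhibition (IC50); either way `ec50` is the inflection
#' concentration. Zero/vehicle doses are mapped to a floor two decades
#' below the lowest non-zero dose (configurable), a plotting/fitting
#' convention for the log axis.
#'
#' @param dose concentrations in M (>= 5 distinct levels).
#' @param response observed responses.
#' @param zeroFloor dose substituted for zero entries; default
#'   `min(dose[dose > 0]) / 100`.
#' @return A [DoseResponseFit-class].
#' @export
fitDoseResponse <- function(dose, response, zeroFloor = NULL) {
  stopifnot(length(dose) == length(response))
  keep <- !is.na(dose) & !is.na(response)
  dose <- dose[keep]; response <- response[keep]
  if (any(dose < 0)) stop("doses must be non-negative")
  if (length(unique(dose)) < 5L)
    stop("at least 5 distinct dose levels are required")
  if (is.null(zeroFloor)) zeroFloor <- min(dose[dose > 0]) / 100
  x <- log10(ifelse(dose == 0, zeroFloor, dose))
  fail <- function(msg)
    new("DoseResponseFit", bottom = NA_real_, top = NA_real_,
        hill = NA_real_, ec50 = NA_real_, direction = NA_character_,
        rss = NA_real_, converged = FALSE, diagnostics = msg)
  if (stats::sd(response) == 0)
    return(fail("flat response: slope unidentifiable"))
  lowResp <- mean(response[x <= stats::quantile(x, 0.2)])
  highResp <- mean(response[x >= stats::quantile(x, 0.8)])
  mid <- (max(response) + min(response)) / 2
  x50_0 <- x[which.min(abs(response - mid))]
  lo <- c(bottom = -Inf, top = -Inf, hill = 0.05, x50 = min(x) - 2)
  hi <- c(bottom = Inf, top = Inf, hill = 10, x50 = max(x) + 2)
  best <- NULL
  for (h0 in c(1, 0.5, 2)) {
    st <- list(bottom = lowResp, top = highResp, hill = h0, x50 = x50_0)
    fit <- tryCatch(
      minpack.lm::nlsLM(response ~ .fourPL(x, bottom, top, hill, x50),
                        start = st, lower = lo, upper = hi,
                        control = minpack.lm::nls.lm.control(
                          ptol = 1e-10, ftol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(fail("least-squares fit did not converge"))
  cf <- stats::coef(best$fit)
  if (cf[["hill"]] <= lo[["hill"]] * 1.01 ||
      abs(cf[["top"]] - cf[["bottom"]]) < 1e-12 * max(abs(response), 1))
    return(fail("slope unidentifiable (response effectively flat)"))
  if (cf[["x50"]] <= lo[["x50"]] + 1e-6 || cf[["x50"]] >= hi[["x50"]] - 1e-6)
    return(fail("inflection outside the sampled dose range"))
  new("DoseResponseFit",
      bottom = cf[["bottom"]], top = cf[["top"]], hill = cf[["hill"]],
      ec50 = 10^cf[["x50"]],
      direction = if (cf[["top"]] >= cf[["bottom"]]) "stimulation" else "inhibition",
      rss = best$rss, converged = TRUE, diagnostics = "")
}

#' Normalize a perturbation time course to its untreated control
#'
#' Pointwise ratio of treated over reference measurements at exactly
#' matching time points; no interpolation is performed, since the assay
#' normalizes like-to-like wells (e.g. compound-treated vs untreated, or
#' heat-shocked vs 37 degC control plates).
#'
#' @param treated,reference data.frames with columns `time` and `ratio`.
#' @return data.frame `time`, `ratio` with the normalized values at the
#'   treated time points.
#' @export
normalizeTimecourse <- function(treated, reference) {
  stopifnot(all(c("time", "ratio") %in% names(treated)),
            all(c("time", "ratio") %in% names(reference)))
  idx <- match(treated$time, reference$time)
  if (anyNA(idx))
    stop("no matching reference time point for t = ",
         paste(treated$time[is.na(idx)], collapse = ", "))
  ref <- reference$ratio[idx]
  if (any(is.na(ref) | ref == 0))
    stop("reference value missing or zero at t = ",
         paste(treated$time[is.na(ref) | ref == 0], collapse = ", "))
  data.frame(time = treated$time, ratio = treated$ratio / ref)
}

#' Normalize a tagging-orientation matrix to its maximum
#'
#' For the eight possible donor/acceptor tag orientations of a pair, each
#' corrected ratio is divided by the highest of the obtained values, so the
#' best orientation reads 1 and negative entries keep their sign.
#'
#' @param values numeric vector (typically length 8, named by orientation).
#' @return values divided by the maximum finite entry.
#' @examples
#' normalizeOrientationMatrix(c(a = 0.02, b = 0.04))  # 0.5, 1
#' @export
normalizeOrientationMatrix <- function(values) {
  fin <- is.finite(values)
  if (!any(fin))
    stop("all orientation values are non-finite")
  m <- max(values[fin])
  if (m <= 0)
    stop("maximum orientation value must be positive for normalization")
  out <- values / m
  out[!fin] <- NA_real_
  out
}
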