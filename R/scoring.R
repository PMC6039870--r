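## Core ratio statistics of the double readout.
##
## BRET ratio = LWL/SWL - Cf, with Cf the donor-only bleed-through ratio of
## the PA-NL reference. LuC ratio = (NL_OUT / (volumeFactor x NL_IN)) / PIR,
## with PIR the precipitation ratio of the PA-NL reference. Corrected ratios
## subtract the larger of the two single-tag control ratios and may be
## negative; no truncation is applied anywhere.

#' Donor bleed-through correction factor Cf
#'
#' Mean over PA-NL reference wells of the long/short wavelength luminescence
#' ratio. Mean-of-ratios (not ratio-of-means) is used so that wells with
#' different expression levels contribute equally.
#'
#' @param lwl,swl long- and short-wavelength luminescence of the PA-NL
#'   wells (equal length, `swl` strictly positive).
#' @param scope identifier used in error messages (plate or experiment).
#' @return The dimensionless Cf scalar.
#' @examples
#' computeCf(lwl = c(200, 220), swl = c(1000, 1100))  # 0.2
#' @export
computeCf <- function(lwl, swl, scope = "experiment") {
  if (length(swl) == 0L)
    stop("no PA-NL reference wells available in scope '", scope, "'")
  if (length(lwl) != length(swl))
    stop("lwl and swl must have equal length")
  if (anyNA(swl) || any(swl <= 0))
    stop("PA-NL wells with zero or missing short-wavelength luminescence in scope '",
         scope, "'")
  mean(lwl / swl)
}

#' Raw BRET ratio of a well
#'
#' @param lwl,swl long- and short-wavelength luminescence (vectorized).
#' @param cf donor bleed-through correction factor ([computeCf()]).
#' @return `lwl/swl - cf`; negative values are retained.
#' @examples
#' bretRatio(300, 1000, cf = 0.2)  #  0.1
#' bretRatio(100, 1000, cf = 0.2)  # -0.1 (not clipped)
#' @export
bretRatio <- function(lwl, swl, cf) {
  if (any(!is.na(swl) & swl <= 0))
    stop("short-wavelength luminescence must be positive")
  lwl / swl - cf
}

#' Precipitation ratio of the PA-NL reference (PIR)
#'
#' Mean over PA-NL wells of `nlOut / (volumeFactor * nlIn)`. The volume
#' factor (default 3) accounts for the precipitated-to-input lysate volume
#' ratio (15 ul captured vs 5 ul measured input) and can be overridden for
#' other liquid-handling schemes.
#'
#' @param nlOut,nlIn post-precipitation and input luminescence of the PA-NL
#'   wells (`nlIn` strictly positive).
#' @param volumeFactor positive scalar, default 3.
#' @param scope identifier used in error messages.
#' @return The dimensionless PIR scalar.
#' @examples
#' computePirPanl(nlOut = 600, nlIn = 1000)  # 0.2
#' @export
computePirPanl <- function(nlOut, nlIn, volumeFactor = 3, scope = "experiment") {
  if (length(nlIn) == 0L)
    stop("no PA-NL reference wells available in scope '", scope, "'")
  if (anyNA(nlIn) || any(nlIn <= 0))
    stop("PA-NL wells with zero or missing input luminescence in scope '",
         scope, "'")
  stopifnot(volumeFactor > 0)
  mean(nlOut / (volumeFactor * nlIn))
}

#' LuC co-precipitation ratio of a well
#'
#' @param nlOut,nlIn post-precipitation and input luminescence (vectorized).
#' @param pirPanl PIR of the PA-NL reference ([computePirPanl()]).
#' @param volumeFactor positive scalar, default 3 (must match the value used
#'   for `pirPanl`).
#' @return `(nlOut / (volumeFactor * nlIn)) / pirPanl`.
#' @examples
#' lucRatio(150, 500, pirPanl = 0.2)  # 0.5
#' @export
lucRatio <- function(nlOut, nlIn, pirPanl, volumeFactor = 3) {
  if (any(!is.na(nlIn) & nlIn <= 0))
    stop("input luminescence must be positive")
  if (is.na(pirPanl) || pirPanl <= 0)
    stop("pirPanl must be positive")
  stopifnot(volumeFactor > 0)
  (nlOut / (volumeFactor * nlIn)) / pirPanl
}

#' Control correction of an interaction ratio
#'
#' The two single-tag control ratios (free donor with the pair's acceptor;
#' the pair's donor with free acceptor) are compared and the higher one is
#' subtracted from the interaction ratio. The same rule yields cBRET from
#' BRET ratios and cLuC from LuC ratios. The operation is
#' translation-equivariant: adding a constant to all three inputs leaves the
#' result unchanged.
#'
#' @param interaction,control1,control2 numeric vectors (recycled).
#' @return `interaction - pmax(control1, control2)`; may be negative.
#' @examples
#' correctRatio(0.10, 0.02, 0.04)  #  0.06
#' correctRatio(0.02, 0.05, 0.01)  # -0.03 (retained)
#' @export
correctRatio <- function(interaction, control1, control2) {
  if (any(is.na(control1)))
    stop("control1 ratio is missing")
  if (any(is.na(control2)))
    stop("control2 ratio is missing")
  interaction - pmax(control1, control2)
}

#' Sensitized-emission FRET efficiency
#'
#' Apparent acceptor FRET efficiency, in percent, from three-channel
#' fluorescence readings after removing donor bleed-through and acceptor
#' cross-excitation:
#' `E = 100 * (DA - cD*DD - cA*AA) / AA`.
#'
#' @param da FRET-channel signal (donor excitation, acceptor emission).
#' @param dd donor-channel signal.
#' @param aa acceptor-channel signal (strictly positive).
#' @param cD donor bleed-through fraction (donor-only sample).
#' @param cA acceptor cross-excitation fraction (acceptor-only sample).
#' @return FRET efficiency in percent.
#' @examples
#' fretEfficiency(da = 50, dd = 100, aa = 200, cD = 0.3, cA = 0.05)  # 5
#' @export
fretEfficiency <- function(da, dd, aa, cD, cA) {
  if (any(!is.na(aa) & aa <= 0))
    stop("acceptor-channel signal must be positive")
  stopifnot(all(cD >= 0), all(cA >= 0))
  100 * (da - cD * dd - cA * aa) / aa
}

## Screen-level scoring -------------------------------------------------------

#' Score a complete screen: BRET, LuC, cBRET, cLuC per pair and replicate
#'
#' For each replicate experiment, correction factors (Cf and, when the LuC
#' channels are present, PIR) are computed from the PA-NL reference wells --
#' per plate when that plate carries PA-NL wells, otherwise pooled across
#' the experiment. Raw ratios are computed per well, averaged per pair, and
#' corrected within the replicate by subtracting the larger of the two
#' single-tag control ratios; corrected values are then averaged across
#' replicates ("aggregate" rows). Raw channels are never averaged across
#' replicates. Pairs lacking either control are flagged `uncorrected` and
#' excluded from calling.
#'
#' @param screen A [LuthyScreen-class].
#' @param cfScope "plate" (default; falls back to the experiment pool for
#'   plates without PA-NL wells) or "experiment" (always pooled).
#' @param volumeFactor LuC volume factor, default 3.
#' @return data.frame with columns `pair_id`, `experiment_id`, `level`
#'   ("replicate"/"aggregate"), `bret`, `control1_bret`, `control2_bret`,
#'   `c_bret`, `luc`, `control1_luc`, `control2_luc`, `c_luc`, `cf`,
#'   `pir_panl`, `cf_scope`, `uncorrected`. The per-experiment correction
#'   factors are attached as `attr(, "factors")`.
#' @export
scoreScreen <- function(screen, cfScope = c("plate", "experiment"),
                        volumeFactor = 3) {
  cfScope <- match.arg(cfScope)
  stopifnot(is(screen, "LuthyScreen"))
  if (!hasBret(screen))
    stop("screen lacks the BRET channels (swl_lum, lwl_lum)")
  withLuc <- hasLuc(screen)
  w <- wells(screen)
  w <- w[w$role != "blank", , drop = FALSE]
  p <- screenPairs(screen)
  w <- merge(w, p, by = "pair_id", all.x = TRUE, sort = FALSE)

  interaction_pairs <- unique(w$pair_id[w$role == "interaction"])
  res <- list()
  factors <- list()
  for (ex in experimentIds(screen)) {
    we <- w[w$experiment_id == ex, , drop = FALSE]
    panl <- we[we$role == "panl", , drop = FALSE]
    # experiment-wide pool, used directly or as fallback
    cf_exp <- computeCf(panl$lwl_lum, panl$swl_lum, scope = paste0("experiment ", ex))
    pir_exp <- if (withLuc)
      computePirPanl(panl$nl_out, panl$nl_in, volumeFactor,
                     scope = paste0("experiment ", ex)) else NA_real_
    cfOf <- function(plate) {
      pw <- panl[panl$plate_id == plate, , drop = FALSE]
      if (cfScope == "plate" && nrow(pw))
        c(cf = computeCf(pw$lwl_lum, pw$swl_lum, scope = plate),
          pir = if (withLuc) computePirPanl(pw$nl_out, pw$nl_in, volumeFactor,
                                            scope = plate) else NA_real_,
          scope = 1)
      else c(cf = cf_exp, pir = pir_exp, scope = 0)
    }
    plates <- unique(we$plate_id)
    pf <- do.call(rbind, lapply(plates, cfOf))
    rownames(pf) <- plates
    we$cf <- pf[we$plate_id, "cf"]
    we$pir <- pf[we$plate_id, "pir"]
    we$bret <- bretRatio(we$lwl_lum, we$swl_lum, we$cf)
    we$luc <- if (withLuc)
      lucRatio(we$nl_out, we$nl_in, 1, volumeFactor) / we$pir else NA_real_

    meanBy <- function(rows, value) {
      if (!nrow(rows)) return(stats::setNames(numeric(0), character(0)))
      tapply(rows[[value]], rows$key, mean)
    }
    ints <- we[we$role == "interaction", ]
    ints$key <- ints$pair_id
    c1 <- we[we$role == "control1", ]; c1$key <- c1$acceptor_id
    c2 <- we[we$role == "control2", ]; c2$key <- c2$donor_id

    bret_i <- meanBy(ints, "bret")
    luc_i <- meanBy(ints, "luc")
    bret_c1 <- meanBy(c1, "bret"); bret_c2 <- meanBy(c2, "bret")
    luc_c1 <- meanBy(c1, "luc"); luc_c2 <- meanBy(c2, "luc")

    pe <- p[match(names(bret_i), p$pair_id), , drop = FALSE]
    cb1 <- unname(bret_c1[pe$acceptor_id]); cb2 <- unname(bret_c2[pe$donor_id])
    cl1 <- unname(luc_c1[pe$acceptor_id]); cl2 <- unname(luc_c2[pe$donor_id])
    uncorr <- is.na(cb1) | is.na(cb2)
    cbret <- ifelse(uncorr, NA_real_, unname(bret_i) - pmax(cb1, cb2))
    cluc <- if (withLuc)
      ifelse(uncorr, NA_real_, unname(luc_i) - pmax(cl1, cl2)) else NA_real_

    cfs <- pf[ints$plate_id[match(names(bret_i), ints$pair_id)], , drop = FALSE]
    res[[ex]] <- data.frame(
      pair_id = names(bret_i), experiment_id = ex, level = "replicate",
      bret = unname(bret_i), control1_bret = cb1, control2_bret = cb2,
      c_bret = cbret,
      luc = unname(luc_i), control1_luc = cl1, control2_luc = cl2,
      c_luc = cluc,
      cf = unname(cfs[, "cf"]), pir_panl = unname(cfs[, "pir"]),
      cf_scope = ifelse(cfs[, "scope"] == 1, "plate", "experiment"),
      uncorrected = uncorr,
      stringsAsFactors = FALSE, row.names = NULL)
    factors[[ex]] <- data.frame(experiment_id = ex, plate_id = plates,
                                cf = unname(pf[, "cf"]),
                                pir_panl = unname(pf[, "pir"]),
                                scope = ifelse(pf[, "scope"] == 1,
                                               "plate", "experiment"),
                                stringsAsFactors = FALSE, row.names = NULL)
  }
  rep_df <- do.call(rbind, res)

  aggOne <- function(v) if (all(is.na(v))) NA_real_ else mean(v)
  agg <- do.call(rbind, lapply(split(rep_df, rep_df$pair_id), function(d) {
    data.frame(pair_id = d$pair_id[1], experiment_id = NA_character_,
               level = "aggregate",
               bret = aggOne(d$bret),
               control1_bret = aggOne(d$control1_bret),
               control2_bret = aggOne(d$control2_bret),
               c_bret = aggOne(d$c_bret),
               luc = aggOne(d$luc),
               control1_luc = aggOne(d$control1_luc),
               control2_luc = aggOne(d$control2_luc),
               c_luc = aggOne(d$c_luc),
               cf = NA_real_, pir_panl = NA_real_, cf_scope = NA_character_,
               uncorrected = any(d$uncorrected),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(rep_df, agg)
  out <- out[order(out$pair_id, out$level != "replicate", out$experiment_id), ]
  rownames(out) <- NULL
  attr(out, "factors") <- do.call(rbind, factors)
  out
}
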