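## Generative simulator of double-readout screens, saturation series,
## dose-response series and dual-channel bioluminescence images, with ground
## truth for every pipeline stage.
##
## Concentrations are abstract molar-scale scalars: every score in the
## pipeline is a ratio, so the expression-to-signal mapping is an arbitrary
## constant. Channel noise is multiplicative lognormal (luminescence noise
## scales with signal); expression variability is lognormal and redrawn per
## replicate experiment (independent transfections).

# run code under a seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# multiplicative lognormal noise with unit mean and given CV
.mnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# lognormal expression draws parameterized by median and CV
.rexpr <- function(n, median, cv) {
  if (cv == 0) return(rep(median, n))
  stats::rlnorm(n, meanlog = log(median), sdlog = sqrt(log(1 + cv^2)))
}

#' Fraction of donor molecules in complex at equilibrium
#'
#' Exact solution of the two-species binding equilibrium: the complex
#' concentration c solves `c^2 - c (D + A + KD) + D A = 0`, taking the root
#' with `c <= min(D, A)`; the returned occupancy is `c / D`. Computed with
#' the numerically stable form `c = 2 D A / (b + sqrt(b^2 - 4 D A))`,
#' `b = D + A + KD`, which avoids catastrophic cancellation for very small
#' KD.
#'
#' @param donorTotal,acceptorTotal total concentrations (M, >= 0;
#'   vectorized).
#' @param kd dissociation constant (M, > 0).
#' @return occupancy in `[0, 1]`; 0 when either species is absent.
#' @examples
#' equilibriumOccupancy(1e-7, 1e-7, 1e-7)  # (3 - sqrt(5)) / 2
#' @export
equilibriumOccupancy <- function(donorTotal, acceptorTotal, kd) {
  if (any(is.na(kd)) || any(kd <= 0)) stop("kd must be positive")
  if (any(donorTotal < 0) || any(acceptorTotal < 0))
    stop("concentrations must be non-negative")
  b <- donorTotal + acceptorTotal + kd
  disc <- b^2 - 4 * donorTotal * acceptorTotal
  cmpl <- 2 * donorTotal * acceptorTotal / (b + sqrt(pmax(disc, 0)))
  occ <- cmpl / donorTotal
  occ[is.nan(occ)] <- 0  # donorTotal == 0: no donor to occupy
  occ
}

#' Parameters of the screen simulator
#'
#' Defaults emulate the assay's design conditions: an acceptor:donor
#' transfection excess of ~10x, dissociation constants spanning nanomolar
#' to 10 micromolar, per-pair maximal BRET between 0.1 and 0.6 (transfer
#' efficiency depends on tag geometry), a donor bleed-through ratio of 0.2,
#' occupancy-proportional co-precipitation capture with a small nonspecific
#' background, and 5 percent multiplicative channel noise.
#'
#' @param nPairs number of tested pairs.
#' @param fractionPositive fraction of pairs that truly interact.
#' @param kdLog10Range log10 range (M) from which positive-pair KDs are
#'   drawn uniformly.
#' @param donorExpression,acceptorExpression `c(median, cv)` of the
#'   lognormal expression distributions (median in M).
#' @param cfTrue generative donor bleed-through ratio.
#' @param bretMaxRange per-pair uniform range of the maximal BRET ratio.
#' @param captureEfficiency LuC capture coupling: the captured prey signal
#'   is `lucBackground + captureEfficiency * occupancy`.
#' @param lucBackground nonspecific precipitation level.
#' @param noiseCv multiplicative lognormal channel noise CV.
#' @param volumeFactor LuC volume factor (see [computePirPanl()]).
#' @param pirTrue generative precipitation ratio of the PA-NL reference.
#' @param tandemBret BRET ratio (above bleed-through) of the tandem fusion.
#' @param nReplicates independent replicate experiments.
#' @param mode "full" (both readouts) or "bret_only" (no co-precipitation
#'   channels; downstream LuC operations refuse such data).
#' @param seed integer seed; mandatory, for reproducibility.
#' @return validated parameter list of class `"luthySimParams"`.
#' @export
simulationParams <- function(nPairs = 160,
                             fractionPositive = 0.5,
                             kdLog10Range = c(-9, -5),
                             donorExpression = c(median = 1e-7, cv = 0.25),
                             acceptorExpression = c(median = 1e-6, cv = 0.25),
                             cfTrue = 0.2,
                             bretMaxRange = c(0.1, 0.6),
                             captureEfficiency = 0.6,
                             lucBackground = 0.01,
                             noiseCv = 0.05,
                             volumeFactor = 3,
                             pirTrue = 0.15,
                             tandemBret = 0.5,
                             nReplicates = 2,
                             mode = c("full", "bret_only"),
                             seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducible simulation")
  mode <- match.arg(mode)
  stopifnot(nPairs >= 1, fractionPositive >= 0, fractionPositive <= 1,
            length(kdLog10Range) == 2, diff(kdLog10Range) >= 0,
            donorExpression[1] > 0, acceptorExpression[1] > 0,
            donorExpression[2] >= 0, acceptorExpression[2] >= 0,
            cfTrue > 0, length(bretMaxRange) == 2, all(bretMaxRange > 0),
            captureEfficiency >= 0, captureEfficiency <= 1,
            lucBackground >= 0, noiseCv >= 0, volumeFactor > 0, pirTrue > 0,
            tandemBret > 0, nReplicates >= 1)
  structure(list(
    nPairs = as.integer(nPairs), fractionPositive = fractionPositive,
    kdLog10Range = kdLog10Range,
    donorExpression = unname(donorExpression),
    acceptorExpression = unname(acceptorExpression),
    cfTrue = cfTrue, bretMaxRange = bretMaxRange,
    captureEfficiency = captureEfficiency, lucBackground = lucBackground,
    noiseCv = noiseCv, volumeFactor = volumeFactor, pirTrue = pirTrue,
    tandemBret = tandemBret, nReplicates = as.integer(nReplicates),
    mode = mode, seed = as.integer(seed)),
    class = "luthySimParams")
}

# signal scale constants (arbitrary counts per molar); only ratios matter
.SCALE <- c(lum = 1e10, fluor = 5e9, in_lum = 1e9, in_fluor = 2e9)

# sequential well ids on 384-well plates; the last 6 wells of each plate
# are reserved for the PA-NL and tandem reference wells
.wellAllocator <- function() {
  grid <- .validWellIds("384")
  cap <- length(grid) - 6L
  plate <- 0L; used <- cap
  function(n = 1L) {
    out <- character(n); pl <- character(n)
    for (i in seq_len(n)) {
      if (used >= cap) { plate <<- plate + 1L; used <<- 0L }
      used <<- used + 1L
      out[i] <- grid[used]; pl[i] <- sprintf("plate%02d", plate)
    }
    data.frame(plate_id = pl, well_id = out, stringsAsFactors = FALSE)
  }
}

#' Simulate a complete double-readout screen with ground truth
#'
#' Generates per pair and replicate an interaction well, the two single-tag
#' control wells (free donor + acceptor, donor + free acceptor; occupancy
#' zero by construction), and per plate a set of PA-NL reference and tandem
#' wells. Channel construction follows the assay's physics: short-wavelength
#' luminescence tracks donor expression; long-wavelength luminescence is
#' `SWL * (cfTrue + bretMax * occupancy)`; input luminescence tracks donor
#' expression in lysate; captured luminescence is
#' `volumeFactor * NL_IN * pirTrue * (lucBackground + captureEfficiency *
#' occupancy)`. At zero noise the scoring pipeline therefore recovers
#' `cBRET = bretMax * occupancy` and `cLuC = captureEfficiency * occupancy`
#' exactly.
#'
#' @param params from [simulationParams()].
#' @return list with elements `screen` (a [LuthyScreen-class]) and `truth`
#'   (data.frame, one row per pair per replicate: `pair_id`,
#'   `experiment_id`, `label`, `kd`, `bret_max`, `donor_conc`,
#'   `acceptor_conc`, `occupancy`, `expected_cbret`, `expected_cluc`).
#' @export
simulateScreen <- function(params) {
  stopifnot(inherits(params, "luthySimParams"))
  .withSeed(params$seed, {
    n <- params$nPairs
    nPos <- round(params$fractionPositive * n)
    label <- rep(FALSE, n)
    label[sample.int(n, nPos)] <- TRUE
    kd <- rep(NA_real_, n)
    kd[label] <- 10^stats::runif(nPos, params$kdLog10Range[1],
                                 params$kdLog10Range[2])
    bmax <- stats::runif(n, params$bretMaxRange[1], params$bretMaxRange[2])
    pid <- sprintf("pair%03d", seq_len(n))

    donor_id <- paste0("NL-X", seq_len(n))
    acceptor_id <- paste0("PA-mCit-Y", seq_len(n))
    constructs <- rbind(
      data.frame(construct_id = donor_id, protein = paste0("X", seq_len(n)),
                 tag_kind = "donor", orientation = "N",
                 stringsAsFactors = FALSE),
      data.frame(construct_id = acceptor_id,
                 protein = paste0("Y", seq_len(n)),
                 tag_kind = "acceptor", orientation = "N",
                 stringsAsFactors = FALSE),
      data.frame(construct_id = c("NL", "PA-mCit", "PA-NL", "PA-mCit-NL"),
                 protein = "none",
                 tag_kind = c("donor_control", "acceptor_control",
                              "panl_reference", "tandem_reference"),
                 orientation = "not_applicable", stringsAsFactors = FALSE))
    pairs <- rbind(
      data.frame(pair_id = pid, donor_id = donor_id,
                 acceptor_id = acceptor_id, stringsAsFactors = FALSE),
      data.frame(pair_id = paste0("c1_", pid), donor_id = "NL",
                 acceptor_id = acceptor_id, stringsAsFactors = FALSE),
      data.frame(pair_id = paste0("c2_", pid), donor_id = donor_id,
                 acceptor_id = "PA-mCit", stringsAsFactors = FALSE),
      data.frame(pair_id = c("panl", "tandem"),
                 donor_id = c("PA-NL", "PA-mCit-NL"),
                 acceptor_id = NA_character_, stringsAsFactors = FALSE))

    de <- params$donorExpression; ae <- params$acceptorExpression
    cv <- params$noiseCv
    nzn <- function(k) .mnoise(k, cv)

    wellRows <- list()
    truth <- list()
    for (r in seq_len(params$nReplicates)) {
      ex <- as.character(r)
      alloc <- .wellAllocator()
      D <- .rexpr(n, de[1], de[2])
      A <- .rexpr(n, ae[1], ae[2])
      occ <- ifelse(label, equilibriumOccupancy(D, A, ifelse(label, kd, 1)), 0)

      mkwell <- function(pair_id, role, Dw, Aw, occw, bmaxw, selfCapture = FALSE,
                         hasAcceptor = TRUE) {
        k <- length(Dw)
        pos <- alloc(k)
        swl <- .SCALE["lum"] * Dw * nzn(k)
        lwl <- swl * (params$cfTrue + bmaxw * occw) * nzn(k)
        fl <- if (hasAcceptor) .SCALE["fluor"] * Aw * nzn(k) else rep(0, k)
        d <- data.frame(plate_id = pos$plate_id, well_id = pos$well_id,
                        pair_id = pair_id, role = role, experiment_id = ex,
                        swl_lum = unname(swl), lwl_lum = unname(lwl),
                        cell_fluor = unname(fl), stringsAsFactors = FALSE)
        if (params$mode == "full") {
          nlin <- .SCALE["in_lum"] * Dw * nzn(k)
          capture <- if (selfCapture) rep(1, k)
                     else params$lucBackground + params$captureEfficiency * occw
          d$nl_in <- unname(nlin)
          d$mcit_in <- unname(if (hasAcceptor) .SCALE["in_fluor"] * Aw * nzn(k)
                              else rep(0, k))
          d$nl_out <- unname(params$volumeFactor * nlin * params$pirTrue *
                             capture * nzn(k))
          d$mcit_out <- unname(d$mcit_in * 0.1 * nzn(k))
        }
        d
      }

      # interaction wells
      wellRows[[paste0("int", r)]] <- mkwell(pid, "interaction", D, A, occ, bmax)
      # control wells: free donor with the pair's acceptor, and vice versa
      D_c1 <- .rexpr(n, de[1], de[2]); A_c2 <- .rexpr(n, ae[1], ae[2])
      wellRows[[paste0("c1", r)]] <-
        mkwell(paste0("c1_", pid), "control1", D_c1, A, 0, bmax)
      wellRows[[paste0("c2", r)]] <-
        mkwell(paste0("c2_", pid), "control2", D, A_c2, 0, bmax)
      # PA-NL reference wells (4 per plate used so far) + tandem wells
      plates <- unique(wellRows[[paste0("int", r)]]$plate_id)
      plates <- unique(c(plates, wellRows[[paste0("c1", r)]]$plate_id,
                         wellRows[[paste0("c2", r)]]$plate_id))
      for (pl in plates) {
        nref <- 4L
        Dp <- .rexpr(nref, de[1], de[2])
        panl <- mkwell(rep("panl", nref), "panl", Dp, Dp, 0, 0,
                       selfCapture = TRUE, hasAcceptor = FALSE)
        Dt <- .rexpr(2L, de[1], de[2])
        tand <- mkwell(rep("tandem", 2L), "tandem", Dt, Dt,
                       rep(1, 2L), params$tandemBret, selfCapture = TRUE,
                       hasAcceptor = TRUE)
        panl$plate_id <- pl; tand$plate_id <- pl
        # place references in the plate's remaining wells
        taken <- do.call(rbind, wellRows)
        taken <- taken$well_id[taken$plate_id == pl & taken$experiment_id == ex]
        free <- setdiff(.validWellIds("384"), taken)
        ids <- free[seq_len(nref + 2L)]
        panl$well_id <- ids[seq_len(nref)]
        tand$well_id <- ids[nref + (1:2)]
        wellRows[[paste0("ref", r, pl)]] <- rbind(panl, tand)
      }
      truth[[r]] <- data.frame(
        pair_id = pid, experiment_id = ex, label = label, kd = kd,
        bret_max = bmax, donor_conc = D, acceptor_conc = A, occupancy = occ,
        expected_cbret = bmax * occ,
        expected_cluc = params$captureEfficiency * occ,
        stringsAsFactors = FALSE)
    }
    wellsAll <- do.call(rbind, unname(wellRows))
    rownames(wellsAll) <- NULL
    md <- list(plate_format = "384",
               channel_mode = params$mode,
               cf_true = params$cfTrue, pir_true = params$pirTrue,
               params = params)
    screen <- LuthyScreen(wellsAll, pairs, constructs = constructs,
                          metadata = md)
    list(screen = screen, truth = do.call(rbind, truth))
  })
}

#' Simulate a donor-saturation titration
#'
#' BRET responses `bretMax * occupancy` at a fixed donor concentration and
#' increasing acceptor amounts, with multiplicative noise. The recorded
#' truth includes the acceptor/donor ratio at half-maximal occupancy, which
#' for the two-species equilibrium has the closed form
#' `(kd + donor/2) / donor`.
#'
#' @param kd dissociation constant (M).
#' @param donorTotal fixed donor concentration (M).
#' @param acceptorTotals strictly increasing acceptor concentrations (M).
#' @param bretMax maximal BRET at full occupancy.
#' @param noiseCv multiplicative noise CV.
#' @param seed integer seed.
#' @return list with `series` (data.frame `ratio`, `bret`) and `truth`
#'   (list with `kd`, `bretMax`, `halfmaxRatio`, `occupancy`).
#' @export
simulateSaturationSeries <- function(kd, donorTotal = 1e-9,
                                     acceptorTotals = donorTotal *
                                       2^(seq(0, 10, length.out = 12)),
                                     bretMax = 0.5, noiseCv = 0, seed = 1) {
  stopifnot(kd > 0, donorTotal > 0, all(diff(acceptorTotals) > 0))
  .withSeed(seed, {
    occ <- equilibriumOccupancy(donorTotal, acceptorTotals, kd)
    bret <- bretMax * occ * .mnoise(length(occ), noiseCv)
    list(series = data.frame(ratio = acceptorTotals / donorTotal,
                             bret = bret),
         truth = list(kd = kd, bretMax = bretMax,
                      halfmaxRatio = (kd + donorTotal / 2) / donorTotal,
                      occupancy = occ))
  })
}

#' Simulate a dose-response series from known 4PL parameters
#'
#' @param bottom,top,hill,ec50 generative 4PL parameters (see
#'   [fitDoseResponse()]).
#' @param doses concentrations (M), at least 5 levels.
#' @param noiseCv multiplicative noise CV.
#' @param seed integer seed.
#' @return list with `series` (data.frame `dose`, `response`) and `truth`.
#' @export
simulateDoseResponse <- function(bottom, top, hill, ec50,
                                 doses = 10^seq(-11, -5, length.out = 8),
                                 noiseCv = 0, seed = 1) {
  stopifnot(ec50 > 0, hill > 0, length(doses) >= 5)
  .withSeed(seed, {
    x <- log10(ifelse(doses == 0, min(doses[doses > 0]) / 100, doses))
    y <- .fourPL(x, bottom, top, hill, log10(ec50))
    y <- y * .mnoise(length(y), noiseCv)
    list(series = data.frame(dose = doses, response = y),
         truth = list(bottom = bottom, top = top, hill = hill, ec50 = ec50))
  })
}

#' Simulate a dual-channel bioluminescence image pair
#'
#' The short-wavelength channel is an intensity field plus background; the
#' long-wavelength channel is the intensity multiplied by a pixel-wise BRET
#' ratio map, translated by an integer shift (emulating the dual-view
#' optical offset), plus background. Noise is multiplicative on the signal.
#'
#' @param shape `c(rows, cols)` of the images.
#' @param ratioMap scalar or matrix of generative long/short ratios.
#' @param shift integer `c(dy, dx)` applied to the long channel.
#' @param background additive background level in both channels.
#' @param noiseCv multiplicative noise CV.
#' @param seed integer seed.
#' @param intensity optional intensity field matrix; default a centered
#'   bright rectangle (value 1000) on a dark field.
#' @return list with `chShort`, `chLong` (matrices) and `truth` (list with
#'   `ratioMap`, `shift`, `foreground` mask).
#' @export
simulateImagePair <- function(shape = c(64, 64), ratioMap = 0.3,
                              shift = c(0, 0), background = 0,
                              noiseCv = 0, seed = 1, intensity = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 8),
            all(abs(shift) < min(shape) / 4))
  shift <- as.integer(shift)
  .withSeed(seed, {
    if (is.null(intensity)) {
      intensity <- matrix(0, shape[1], shape[2])
      ri <- seq(floor(shape[1] / 4), ceiling(3 * shape[1] / 4))
      ci <- seq(floor(shape[2] / 4), ceiling(3 * shape[2] / 4))
      intensity[ri, ci] <- 1000
    }
    if (length(ratioMap) == 1L)
      ratioMap <- matrix(ratioMap, nrow(intensity), ncol(intensity))
    stopifnot(all(dim(ratioMap) == dim(intensity)))
    noise <- function(m) m * matrix(.mnoise(length(m), noiseCv),
                                    nrow(m), ncol(m))
    chShort <- noise(intensity) + background
    chLong <- noise(translateImage(intensity * ratioMap, shift[1], shift[2],
                                   fill = 0)) + background
    list(chShort = chShort, chLong = chLong,
         truth = list(ratioMap = ratioMap, shift = shift,
                      foreground = intensity > 0))
  })
}
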