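#' @import methods
NULL

## Central data container ----------------------------------------------------

#' LuthyScreen: a validated container for plate-based double-readout screens
#'
#' Holds per-well plate-reader measurements together with the construct and
#' pair annotation needed to score a LuTHy screen. Wells are stored in long
#' ("tidy") format, one row per well per replicate experiment; channels that
#' were not measured are simply absent as columns (absence is distinct from a
#' zero reading). Construct identity drives control resolution: the
#' single-tag control for the acceptor side (free NanoLuc donor, "control1")
#' depends only on the acceptor construct, and the donor-side control
#' (free PA-mCit acceptor, "control2") only on the donor construct, so
#' control wells may be shared between pairs.
#'
#' @slot wells data.frame with columns `plate_id`, `well_id`, `pair_id`,
#'   `role`, `experiment_id` plus any of the measurement channels
#'   `swl_lum`, `lwl_lum`, `cell_fluor`, `nl_in`, `mcit_in`, `nl_out`,
#'   `mcit_out` (all finite, non-negative where present).
#' @slot constructs data.frame with columns `construct_id`, `protein`,
#'   `tag_kind` (one of donor, acceptor, donor_control, acceptor_control,
#'   panl_reference, tandem_reference) and `orientation` (N, C,
#'   not_applicable).
#' @slot pairs data.frame mapping `pair_id` to `donor_id` and `acceptor_id`.
#' @slot metadata list of free-form metadata (extra input columns, channel
#'   mode, plate format).
#'
#' @seealso [readMeasurements()], [scoreScreen()], [simulateScreen()]
#' @export
setClass("LuthyScreen",
  representation(
    wells      = "data.frame",
    constructs = "data.frame",
    pairs      = "data.frame",
    metadata   = "list"
  )
)

.WELL_ROLES <- c("interaction", "control1", "control2", "panl", "tandem", "blank")
.TAG_KINDS  <- c("donor", "acceptor", "donor_control", "acceptor_control",
                 "panl_reference", "tandem_reference")
.CHANNELS   <- c("swl_lum", "lwl_lum", "cell_fluor", "nl_in", "mcit_in",
                 "nl_out", "mcit_out")

.validWellIds <- function(format = c("384", "96")) {
  format <- match.arg(format)
  if (format == "96") {
    as.vector(outer(LETTERS[1:8], 1:12, paste0))
  } else {
    as.vector(outer(LETTERS[1:16], 1:24, paste0))
  }
}

.validityLuthyScreen <- function(object) {
  msg <- character()
  w <- object@wells
  req <- c("plate_id", "well_id", "pair_id", "role", "experiment_id")
  missing_cols <- setdiff(req, names(w))
  if (length(missing_cols))
    return(paste("wells lacks column(s):", paste(missing_cols, collapse = ", ")))
  bad_role <- !w$role %in% .WELL_ROLES
  if (any(bad_role))
    msg <- c(msg, paste0("invalid role(s) in wells rows ",
                         paste(which(bad_role), collapse = ", ")))
  fmt <- object@metadata$plate_format
  if (is.null(fmt)) fmt <- "384"
  bad_well <- !w$well_id %in% .validWellIds(fmt)
  if (any(bad_well))
    msg <- c(msg, paste0("well id(s) out of range for a ", fmt, "-well plate in rows ",
                         paste(which(bad_well), collapse = ", "), ": ",
                         paste(unique(w$well_id[bad_well]), collapse = ", ")))
  for (ch in intersect(.CHANNELS, names(w))) {
    v <- w[[ch]]
    bad <- !is.na(v) & (!is.finite(v) | v < 0)
    if (any(bad))
      msg <- c(msg, paste0("channel ", ch, " has negative or non-finite values in rows ",
                           paste(which(bad), collapse = ", ")))
  }
  key <- paste(w$experiment_id, w$plate_id, w$well_id, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, paste0("duplicate (plate, well) keys within an experiment in rows ",
                         paste(which(duplicated(key)), collapse = ", ")))
  cs <- object@constructs
  if (nrow(cs)) {
    bad_kind <- !cs$tag_kind %in% .TAG_KINDS
    if (any(bad_kind))
      msg <- c(msg, "invalid tag_kind in constructs")
    ref <- cs$tag_kind %in% c("panl_reference", "tandem_reference")
    if (any(ref & !(is.na(cs$protein) | cs$protein == "none")))
      msg <- c(msg, "reference constructs (PA-NL, PA-mCit-NL) must carry protein 'none'")
    fus <- cs$tag_kind %in% c("donor", "acceptor")
    if (any(fus & (is.na(cs$protein) | cs$protein %in% c("", "none"))))
      msg <- c(msg, "donor/acceptor fusion constructs must carry a protein symbol")
  }
  p <- object@pairs
  used <- unique(w$pair_id[w$role == "interaction"])
  if (length(setdiff(used, p$pair_id)))
    msg <- c(msg, paste0("interaction wells reference unknown pair id(s): ",
                         paste(setdiff(used, p$pair_id), collapse = ", ")))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

setValidity("LuthyScreen", .validityLuthyScreen)

#' @describeIn LuthyScreen-accessors Number of wells across all experiments
#' @export
setMethod("length", "LuthyScreen", function(x) nrow(x@wells))

setMethod("show", "LuthyScreen", function(object) {
  ch <- intersect(.CHANNELS, names(object@wells))
  cat("LuthyScreen with", nrow(object@wells), "wells,",
      nrow(object@pairs), "pairs,",
      length(unique(object@wells$experiment_id)), "experiment(s)\n")
  cat("  channels:", if (length(ch)) paste(ch, collapse = ", ") else "none", "\n")
  cat("  mode:", if (hasLuc(object)) "BRET + LuC" else "BRET-only", "\n")
})

## Accessors ------------------------------------------------------------------

#' Accessors for LuthyScreen objects
#'
#' @param x,object A [LuthyScreen-class] object.
#' @return `wells`, `constructs`, `pairs` return the respective data.frames;
#'   `channelNames` the measurement channels present; `experimentIds` the
#'   replicate experiment labels; `hasBret`/`hasLuc` logicals indicating
#'   whether the in-cell BRET channels (short/long wavelength luminescence)
#'   or the co-precipitation channels (input/output luminescence) were
#'   measured.
#' @name LuthyScreen-accessors
NULL

#' @rdname LuthyScreen-accessors
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))
#' @rdname LuthyScreen-accessors
#' @export
setMethod("wells", "LuthyScreen", function(x) x@wells)

#' @rdname LuthyScreen-accessors
#' @export
setGeneric("constructs", function(x) standardGeneric("constructs"))
#' @rdname LuthyScreen-accessors
#' @export
setMethod("constructs", "LuthyScreen", function(x) x@constructs)

#' @rdname LuthyScreen-accessors
#' @export
setGeneric("screenPairs", function(x) standardGeneric("screenPairs"))
#' @rdname LuthyScreen-accessors
#' @export
setMethod("screenPairs", "LuthyScreen", function(x) x@pairs)

#' @rdname LuthyScreen-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname LuthyScreen-accessors
#' @export
setMethod("channelNames", "LuthyScreen",
          function(x) intersect(.CHANNELS, names(x@wells)))

#' @rdname LuthyScreen-accessors
#' @export
setGeneric("experimentIds", function(x) standardGeneric("experimentIds"))
#' @rdname LuthyScreen-accessors
#' @export
setMethod("experimentIds", "LuthyScreen",
          function(x) unique(x@wells$experiment_id))

#' @rdname LuthyScreen-accessors
#' @export
setGeneric("hasBret", function(x) standardGeneric("hasBret"))
#' @rdname LuthyScreen-accessors
#' @export
setMethod("hasBret", "LuthyScreen",
          function(x) all(c("swl_lum", "lwl_lum") %in% names(x@wells)))

#' @rdname LuthyScreen-accessors
#' @export
setGeneric("hasLuc", function(x) standardGeneric("hasLuc"))
#' @rdname LuthyScreen-accessors
#' @export
setMethod("hasLuc", "LuthyScreen",
          function(x) all(c("nl_in", "nl_out") %in% names(x@wells)))

#' Construct a LuthyScreen from its component tables
#'
#' Low-level constructor; most users will obtain screens from
#' [readMeasurements()] or [simulateScreen()].
#'
#' @param wells data.frame of per-well readings (see [LuthyScreen-class]).
#' @param pairs data.frame mapping `pair_id` to `donor_id`/`acceptor_id`.
#' @param constructs data.frame of construct annotation; inferred from roles
#'   when omitted.
#' @param metadata list of metadata; `metadata$plate_format` ("96" or "384",
#'   default "384") controls well-id validation.
#' @return A validated [LuthyScreen-class].
#' @export
LuthyScreen <- function(wells, pairs, constructs = NULL, metadata = list()) {
  wells <- as.data.frame(wells)
  if (!"experiment_id" %in% names(wells)) wells$experiment_id <- "1"
  wells$plate_id <- as.character(wells$plate_id)
  wells$well_id <- as.character(wells$well_id)
  wells$pair_id <- as.character(wells$pair_id)
  wells$role <- as.character(wells$role)
  wells$experiment_id <- as.character(wells$experiment_id)
  pairs <- as.data.frame(pairs)
  if (is.null(constructs))
    constructs <- .inferConstructs(wells, pairs)
  new("LuthyScreen", wells = wells, pairs = pairs,
      constructs = as.data.frame(constructs), metadata = metadata)
}

# Derive construct annotation from well roles when no construct table is
# supplied: free-tag controls are identified by the roles of the wells their
# pairs appear in, fusions default to N-terminal tagging.
.inferConstructs <- function(wells, pairs) {
  m <- merge(wells[, c("pair_id", "role")], pairs, by = "pair_id", all.x = TRUE)
  rec <- list()
  add <- function(id, protein, kind, ori = "not_applicable") {
    if (is.na(id) || !nzchar(id)) return()
    rec[[id]] <<- data.frame(construct_id = id, protein = protein,
                             tag_kind = kind, orientation = ori,
                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(m))) {
    role <- m$role[i]; d <- m$donor_id[i]; a <- m$acceptor_id[i]
    switch(role,
      panl     = add(d, "none", "panl_reference"),
      tandem   = add(d, "none", "tandem_reference"),
      control1 = { add(d, "none", "donor_control")
                   if (is.null(rec[[a]])) add(a, a, "acceptor", "N") },
      control2 = { add(a, "none", "acceptor_control")
                   if (is.null(rec[[d]])) add(d, d, "donor", "N") },
      interaction = { add(d, if (is.null(rec[[d]])) d else rec[[d]]$protein, "donor", "N")
                      add(a, if (is.null(rec[[a]])) a else rec[[a]]$protein, "acceptor", "N") },
      blank = NULL)
  }
  if (!length(rec))
    return(data.frame(construct_id = character(), protein = character(),
                      tag_kind = character(), orientation = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, unname(rec))
}

## Cutoff scheme --------------------------------------------------------------

#' Localization-stratified cutoff scheme for interaction calling
#'
#' Corrected ratios are compared inclusively (>=) against class-specific
#' cutoffs. Pairs in which both proteins are integral-membrane or
#' membrane-associated are prone to proximity artefacts at membrane surfaces
#' and are therefore held to more stringent cutoffs.
#'
#' @slot cbretDefault,clucDefault cutoffs applied to pairs with at least one
#'   cytoplasmic/nuclear/unannotated protein (defaults 0.01 and 0.03).
#' @slot cbretMembrane,clucMembrane cutoffs for membrane/membrane pairs
#'   (defaults 0.03 and 0.05).
#' @export
setClass("CutoffScheme",
  representation(cbretDefault = "numeric", clucDefault = "numeric",
                 cbretMembrane = "numeric", clucMembrane = "numeric"))

setValidity("CutoffScheme", function(object) {
  if (object@cbretMembrane < object@cbretDefault ||
      object@clucMembrane < object@clucDefault)
    "membrane cutoffs must be >= default cutoffs"
  else TRUE
})

#' @param cbretDefault,clucDefault,cbretMembrane,clucMembrane cutoff values;
#'   see [CutoffScheme-class].
#' @return A `CutoffScheme` object.
#' @rdname CutoffScheme-class
#' @export
cutoffScheme <- function(cbretDefault = 0.01, clucDefault = 0.03,
                         cbretMembrane = 0.03, clucMembrane = 0.05) {
  new("CutoffScheme", cbretDefault = cbretDefault, clucDefault = clucDefault,
      cbretMembrane = cbretMembrane, clucMembrane = clucMembrane)
}

setMethod("show", "CutoffScheme", function(object) {
  cat("CutoffScheme (inclusive >=)\n")
  cat(sprintf("  default:       cBRET >= %g, cLuC >= %g\n",
              object@cbretDefault, object@clucDefault))
  cat(sprintf("  membrane pair: cBRET >= %g, cLuC >= %g\n",
              object@cbretMembrane, object@clucMembrane))
})

## Fit result classes ---------------------------------------------------------

#' Donor-saturation fit result
#'
#' One-site hyperbolic fit BRET(r) = bretMax * r / (bret50 + r) of a donor
#' saturation series, where r is the acceptor/donor expression ratio. The
#' half-saturation point bret50 rank-correlates with the dissociation
#' constant of the interaction.
#'
#' @slot bretMax fitted asymptotic (corrected) BRET ratio.
#' @slot bret50 acceptor/donor ratio at half-maximal BRET.
#' @slot rss residual sum of squares.
#' @slot converged logical; FALSE for degenerate or non-identifiable series.
#' @slot diagnostics character; reason when not converged.
#' @export
setClass("SaturationFit",
  representation(bretMax = "numeric", bret50 = "numeric", rss = "numeric",
                 converged = "logical", diagnostics = "character"))

setMethod("show", "SaturationFit", function(object) {
  if (object@converged)
    cat(sprintf("SaturationFit: bretMax = %.4g, bret50 = %.4g (rss = %.3g)\n",
                object@bretMax, object@bret50, object@rss))
  else
    cat("SaturationFit: not converged -", object@diagnostics, "\n")
})

#' Four-parameter logistic dose-response fit result
#'
#' @slot bottom,top response asymptotes at low/high dose.
#' @slot hill Hill slope (positive; direction is carried separately).
#' @slot ec50 inflection concentration (M); reported as EC50 for
#'   stimulation and IC50 for inhibition.
#' @slot direction "stimulation" or "inhibition".
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @slot diagnostics character.
#' @export
setClass("DoseResponseFit",
  representation(bottom = "numeric", top = "numeric", hill = "numeric",
                 ec50 = "numeric", direction = "character", rss = "numeric",
                 converged = "logical", diagnostics = "character"))

setMethod("show", "DoseResponseFit", function(object) {
  if (object@converged)
    cat(sprintf("DoseResponseFit (%s): %s50 = %.4g M, hill = %.3g, bottom = %.4g, top = %.4g\n",
                object@direction,
                if (object@direction == "inhibition") "IC" else "EC",
                object@ec50, object@hill, object@bottom, object@top))
  else
    cat("DoseResponseFit: not converged -", object@diagnostics, "\n")
})

#' Empirical ROC analysis result
#'
#' @slot thresholds distinct score values, descending; scores >= threshold
#'   are predicted positive.
#' @slot tpr,fpr true/false positive rates along `thresholds`.
#' @slot auc trapezoidal area under the curve.
#' @slot aucSe Hanley-McNeil standard error of the AUC.
#' @slot youden threshold maximizing tpr - fpr (a suggestion, not an
#'   automatic cutoff).
#' @slot nPos,nNeg class sizes.
#' @export
setClass("RocResult",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric", aucSe = "numeric", youden = "numeric",
                 nPos = "integer", nNeg = "integer"))

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.3f +/- %.3f (%d pos, %d neg); Youden threshold = %.4g\n",
              object@auc, object@aucSe, object@nPos, object@nNeg, object@youden))
})

#' Pixel-wise ratiometric BRET map
#'
#' @slot ratio matrix of long/short channel ratios, NA outside the mask.
#' @slot mask logical matrix of foreground pixels (short channel above
#'   threshold after filtering and background subtraction).
#' @slot params list of the parameters used (median kernel, background
#'   percentile, threshold).
#' @export
setClass("BretMap",
  representation(ratio = "matrix", mask = "matrix", params = "list"))

setMethod("show", "BretMap", function(object) {
  n <- sum(object@mask)
  cat(sprintf("BretMap %d x %d: %d foreground pixels", nrow(object@ratio),
              ncol(object@ratio), n))
  if (n) cat(sprintf(", mean ratio %.4g", mean(object@ratio[object@mask])))
  cat("\n")
})
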