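## Pixel-wise ratiometric BRET maps from dual-channel bioluminescence
## images: rigid integer-pixel registration of the two spectral views,
## median smoothing, percentile background subtraction, intensity
## thresholding and per-pixel long/short division.

#' Translate an image by an integer pixel offset
#'
#' @param x numeric matrix.
#' @param dy,dx integer shifts (positive = down / right).
#' @param fill value for pixels shifted in from outside (default 0).
#' @return translated matrix of the same dimensions, with
#'   `out[i + dy, j + dx] == x[i, j]` where defined.
#' @export
translateImage <- function(x, dy, dx, fill = 0) {
  stopifnot(is.matrix(x))
  dy <- as.integer(dy); dx <- as.integer(dx)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr; ok_c <- src_c >= 1L & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- x[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Edge-replicated k x k median filter
#'
#' Square median filter with edge replication (border pixels are padded by
#' repeating the nearest image row/column), the smoothing step of the BRET
#' map procedure.
#'
#' @param x numeric matrix.
#' @param k odd kernel size >= 1.
#' @return filtered matrix of the same dimensions.
#' @export
medianFilter2d <- function(x, k) {
  stopifnot(is.matrix(x))
  if (k %% 2 != 1 || k < 1)
    stop("kernel size k must be an odd integer >= 1")
  if (k == 1) return(x)
  h <- (k - 1L) / 2L
  nr <- nrow(x); nc <- ncol(x)
  pad_r <- c(rep(1L, h), seq_len(nr), rep(nr, h))
  pad_c <- c(rep(1L, h), seq_len(nc), rep(nc, h))
  xp <- x[pad_r, pad_c, drop = FALSE]
  # stack the k^2 window-shifted copies and take the row-wise median
  stack <- matrix(0, nr * nc, k * k)
  m <- 1L
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    stack[, m] <- as.vector(xp[di + seq_len(nr), dj + seq_len(nc)])
    m <- m + 1L
  }
  matrix(apply(stack, 1L, stats::median), nr, nc)
}

#' Register two channels by integer-pixel translation
#'
#' Exhaustive search over integer shifts within `maxShift`, maximizing the
#' normalized cross-correlation (Pearson correlation of the overlapping
#' pixels). Ties are broken toward the smaller shift magnitude, then in
#' row-major order. The dual-view optical offset is a rigid translation, so
#' no rotation or subpixel refinement is attempted.
#'
#' @param ref,moving numeric matrices of identical shape (short- and
#'   long-wavelength channels).
#' @param maxShift maximum absolute shift searched in each axis (>= 0).
#' @return integer `c(dy, dx)` such that translating `moving` back by the
#'   negated shift aligns it with `ref` (i.e. `ref[i, j]` corresponds to
#'   `moving[i + dy, j + dx]`). Attributes: `ncc` (the correlation at the
#'   optimum) and `lowConfidence` (TRUE when the optimum lies on the search
#'   window boundary, suggesting the true shift exceeds `maxShift`).
#' @export
registerTranslation <- function(ref, moving, maxShift = 5L) {
  stopifnot(is.matrix(ref), is.matrix(moving), all(dim(ref) == dim(moving)),
            maxShift >= 0)
  if (stats::sd(ref) == 0 || stats::sd(moving) == 0)
    stop("correlation undefined: constant image")
  m <- as.integer(maxShift)
  best <- NULL
  for (dy in -m:m) for (dx in -m:m) {
    r_idx <- seq_len(nrow(ref)); c_idx <- seq_len(ncol(ref))
    rr <- r_idx[(r_idx + dy) >= 1 & (r_idx + dy) <= nrow(ref)]
    cc <- c_idx[(c_idx + dx) >= 1 & (c_idx + dx) <= ncol(ref)]
    if (length(rr) < 2 || length(cc) < 2) next
    a <- ref[rr, cc]
    b <- moving[rr + dy, cc + dx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    ncc <- stats::cor(as.vector(a), as.vector(b))
    cand <- list(dy = dy, dx = dx, ncc = ncc, norm = dy^2 + dx^2)
    if (is.null(best) ||
        ncc > best$ncc + 1e-12 ||
        (abs(ncc - best$ncc) <= 1e-12 &&
         (cand$norm < best$norm ||
          (cand$norm == best$norm &&
           (dy < best$dy || (dy == best$dy && dx < best$dx))))))
      best <- cand
  }
  if (is.null(best))
    stop("no valid shift found within the search window")
  out <- c(dy = best$dy, dx = best$dx)
  attr(out, "ncc") <- best$ncc
  attr(out, "lowConfidence") <- m > 0 && (abs(best$dy) == m || abs(best$dx) == m)
  out
}

#' Compute a pixel-wise BRET map from an aligned image pair
#'
#' Each channel is median-filtered (edge-replicated k x k kernel), then the
#' channel's b-th intensity percentile is subtracted (negative results
#' clamped to zero). Foreground is the set of pixels whose processed
#' short-wavelength intensity exceeds the threshold `t`; the ratio map is
#' long/short on the foreground and undefined (NA) elsewhere, so division
#' by zero cannot occur for any `t > 0`. The map is invariant under a
#' common scaling of both channels when `t` is scaled along.
#'
#' @param chShort,chLong numeric matrices of identical shape (already
#'   registered; see [registerTranslation()]).
#' @param k odd median kernel size (default 3).
#' @param backgroundPercentile percentile (0 <= b < 100) subtracted per
#'   channel (default 5).
#' @param threshold foreground threshold on the processed short channel.
#' @return A [BretMap-class].
#' @export
computeBretMap <- function(chShort, chLong, k = 3,
                           backgroundPercentile = 5, threshold = 1) {
  stopifnot(is.matrix(chShort), is.matrix(chLong),
            all(dim(chShort) == dim(chLong)))
  if (k %% 2 != 1) stop("kernel size k must be odd")
  if (backgroundPercentile < 0 || backgroundPercentile >= 100)
    stop("backgroundPercentile must be in [0, 100)")
  if (threshold < 0) stop("threshold must be >= 0")
  proc <- function(x) {
    f <- medianFilter2d(x, k)
    # b = 0 disables subtraction (the 0th percentile is the image minimum,
    # which would null a uniform field rather than estimate its background)
    bg <- if (backgroundPercentile == 0) 0 else
      stats::quantile(f, backgroundPercentile / 100, names = FALSE)
    pmax(f - bg, 0)
  }
  s <- proc(chShort); l <- proc(chLong)
  mask <- s > threshold
  ratio <- matrix(NA_real_, nrow(s), ncol(s))
  ratio[mask] <- l[mask] / s[mask]
  new("BretMap", ratio = ratio, mask = mask,
      params = list(k = k, backgroundPercentile = backgroundPercentile,
                    threshold = threshold))
}
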