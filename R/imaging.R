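# Autofocus scoring/selection and the voltage -> focus / scale
# calibration machinery for the liquid-lens objectives.

#' Autofocus score of one frame
#'
#' Score = (high-quantile intensity - background) / background, with the
#' background estimated as the median pixel value. A sparse bright bead
#' in focus concentrates flux in few pixels, so the upper quantile peaks
#' at the focal plane. A constant image scores 0.
#'
#' @param image numeric matrix (one frame)
#' @param signalQuantile quantile used as the signal estimate
#' @return dimensionless score >= 0 for in-focus spots on background
#' @export
autofocusScore <- function(image, signalQuantile = 0.995) {
  bg <- stats::median(image)
  sig <- stats::quantile(image, signalQuantile, names = FALSE)
  if (sig == bg) return(0)
  if (bg == 0) bg <- 1           # counts floor; keeps score finite on dark frames
  (sig - bg) / bg
}

#' Select the focal slice of a stack
#'
#' Returns the index of the slice with the maximal autofocus score.
#' Because the electrowetting lens is hysteretic, callers must approach
#' focus from the low-voltage regime: the stack is expected ordered by
#' increasing drive voltage, and the simulated acquisition loop always
#' re-approaches focus by ascending-voltage traversal.
#'
#' @param stack a \linkS4class{VideoStack} (or 3-D array) ordered by
#'   increasing voltage; at least 3 slices
#' @param signalQuantile passed to \code{\link{autofocusScore}}
#' @return integer slice index (1-based)
#' @export
selectFocus <- function(stack, signalQuantile = 0.995) {
  arr <- if (is(stack, "VideoStack")) stack@data else stack
  if (dim(arr)[3] < 3) stop("focus stack must contain at least 3 slices")
  scores <- vapply(seq_len(dim(arr)[3]),
                   function(i) autofocusScore(arr[, , i], signalQuantile),
                   numeric(1))
  if (diff(range(scores)) <= .Machine$double.eps * max(1, max(abs(scores))))
    stop("no focal plane found: all slices score equally")
  # a real focal peak scores several-fold above the typical slice; an
  # all-noise stack shows only percent-level sampling scatter in its
  # scores. Requires the z grid to span the defocus range, so the
  # median slice is well out of focus.
  m <- stats::median(scores)
  if (max(scores) < 1.5 * m)
    stop("no focal plane found: no slice scores significantly above the rest")
  which.max(scores)
}

.calibLookup <- function(curve, v, what) {
  if (any(v < min(curve@vRms) | v > max(curve@vRms)))
    stop("voltage outside calibration grid; no extrapolation")
  tab <- slot(curve, what)
  out <- stats::approx(curve@vRms, tab, xout = v)$y
  # focal plane (and scale) do not move below 30 V: return the
  # zero-voltage value exactly rather than an interpolated float
  flat <- v <= 30
  if (any(flat)) out[flat] <- tab[1]
  out
}

#' Convert drive voltage to focal-plane displacement
#'
#' Linear interpolation on the calibration table. For v <= 30 V the
#' focal plane has not yet moved and the zero-voltage value is returned
#' exactly. Voltages outside the tabulated grid are an error.
#'
#' @param curve a \linkS4class{CalibrationCurve}
#' @param v RMS voltage(s) (V)
#' @return focal-plane displacement (um)
#' @export
voltageToZ <- function(curve, v) .calibLookup(curve, v, "zDisp")

#' Convert drive voltage to pixel scale
#'
#' @inheritParams voltageToZ
#' @return pixel scale (um/px)
#' @export
voltageToScale <- function(curve, v) .calibLookup(curve, v, "scale")

#' Estimate the pixel scale from known stage steps
#'
#' First-order factor from a sequence of known-length XY stage steps in
#' random directions: scale = knownStepUm / mean(|pixel displacement|).
#' Optionally refined by the total corner-to-corner pixel span of a
#' target bead displaced across the whole field.
#'
#' @param stepDisplacementsPx n x 2 matrix of measured per-step pixel
#'   displacements; zero-length steps are excluded with a warning
#' @param knownStepUm commanded step length (um); default 3
#' @param refineSpanPx optional corner-to-corner pixel span
#' @param refineSpanUm optional corner-to-corner commanded distance (um)
#' @return list with \code{scale} (um/px), \code{se} (standard error),
#'   \code{n} steps used, and \code{refined} (um/px, or NA)
#' @export
estimateScale <- function(stepDisplacementsPx, knownStepUm = 3,
                          refineSpanPx = NULL, refineSpanUm = NULL) {
  steps <- matrix(stepDisplacementsPx, ncol = 2)
  if (nrow(steps) < 2) stop("at least 2 steps required")
  mags <- sqrt(rowSums(steps^2))
  if (any(mags == 0)) {
    warning("excluding ", sum(mags == 0), " zero-length displacement(s)")
    mags <- mags[mags > 0]
  }
  if (length(mags) < 2) stop("fewer than 2 usable steps")
  mbar <- mean(mags)
  sc <- knownStepUm / mbar
  # delta method for the SE of knownStepUm / mean(mags)
  se <- knownStepUm * stats::sd(mags) / (mbar^2 * sqrt(length(mags)))
  refined <- NA_real_
  if (!is.null(refineSpanPx) && !is.null(refineSpanUm))
    refined <- refineSpanUm / refineSpanPx
  list(scale = sc, se = se, n = length(mags), refined = refined)
}

#' Merge per-channel calibration curves
#'
#' If the per-channel scale curves agree to within \code{maxError}
#' fractional spread at every voltage node (default 5%), the channel
#' mean curve is substituted for all channels; otherwise the individual
#' curves are kept.
#'
#' @param curves list of \linkS4class{CalibrationCurve} on a common grid
#' @param maxError maximum tolerated fractional spread
#' @return list with \code{merged} (logical), \code{maxChannelError},
#'   and \code{curves} (a single mean curve if merged, else the input)
#' @export
mergeChannelCurves <- function(curves, maxError = 0.05) {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1]]@vRms
  for (cu in curves)
    if (!isTRUE(all.equal(cu@vRms, grid)))
      stop("curves must share a common voltage grid")
  S <- sapply(curves, function(cu) cu@scale)
  S <- matrix(S, nrow = length(grid))
  spread <- apply(S, 1, function(r) (max(r) - min(r)) / mean(r))
  err <- max(spread)
  if (err < maxError) {
    Z <- matrix(sapply(curves, function(cu) cu@zDisp), nrow = length(grid))
    mcurve <- calibrationCurve(grid, rowMeans(Z), rowMeans(S),
                               maxChannelError = err)
    list(merged = TRUE, maxChannelError = err, curves = list(mcurve))
  } else {
    list(merged = FALSE, maxChannelError = err, curves = curves)
  }
}
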