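# AFM force-curve analysis: Hooke's-law force, indentation from piezo
# minus deflection, automatic contact-point detection by minimum
# combined RMS error of a piecewise linear + Hertz fit, Young's modulus
# and compliance extraction, and batch medians.

#' Force and indentation from an approach curve
#'
#' Force from Hooke's law, F = k * deflection; indentation from the
#' difference between piezo motion and cantilever deflection, both
#' relative to the contact point. The deflection baseline (pre-contact
#' drift) is removed by the supplied line, or by the median of the
#' pre-contact samples when no line is given.
#'
#' @param curve a \linkS4class{ForceCurve}
#' @param contactIndex sample index (1-based) of the contact point
#' @param baseline optional c(intercept, slope) of the pre-contact
#'   deflection drift line (nm vs um); default: median pre-contact
#'   deflection, zero slope
#' @return data.frame with columns indentation_um and force_nN for the
#'   post-contact samples
#' @export
toForceIndentation <- function(curve, contactIndex, baseline = NULL) {
  z <- curve@zPiezo; d <- curve@deflection
  maxDefl <- 2^15   # nm; a saturated channel pins at full scale
  if (any(abs(d) >= maxDefl)) stop("saturated deflection channel")
  if (is.null(baseline))
    baseline <- c(stats::median(d[seq_len(max(contactIndex - 1, 1))]), 0)
  dc <- d - (baseline[1] + baseline[2] * z)       # nm
  post <- contactIndex:length(z)
  force <- curve@k * dc[post]                      # N/m * nm = nN
  indent <- (z[post] - z[contactIndex]) - dc[post] / 1000
  data.frame(indentation_um = indent, force_nN = force)
}

#' Fit the Hertz model to force-indentation data
#'
#' Least squares of F = (4/3) (E/(1-nu^2)) sqrt(R) delta^(3/2), which is
#' linear in E given the indentation. The fit is restricted to forces at
#' or below the trigger. Negative indentation samples are dropped.
#'
#' @param indentation indentation (um)
#' @param force force (nN)
#' @param R probe radius (um)
#' @param nu Poisson ratio, default 0.5
#' @param trigger only samples with force <= trigger are fitted
#' @return list: E (Pa), compliance (kPa^-1), rss (nN^2), n
#' @export
fitHertz <- function(indentation, force, R, nu = 0.5, trigger = Inf) {
  keep <- indentation >= 0 & force <= trigger
  delta <- indentation[keep]; f <- force[keep]
  if (length(delta) < 2 || max(delta) <= 0)
    stop("degenerate indentation range")
  x <- (4 / 3) * sqrt(R) * delta^1.5 * 1e-3 / (1 - nu^2)  # nN per Pa
  E <- sum(f * x) / sum(x * x)
  if (!is.finite(E) || E <= 0) stop("degenerate indentation range")
  r <- f - E * x
  list(E = E, compliance = 1000 / E, rss = sum(r * r), n = length(f))
}

#' Detect the contact point of an approach curve
#'
#' For every candidate contact index j the pre-contact deflection is fit
#' by a free line (slope captures drift) and the post-contact data by
#' the spherical Hertz model; the combined RMS force residual (line
#' residuals converted to force through the spring constant, both
#' segments weighted equally per sample) is recorded, and the j with the
#' minimum total RMS wins. Every sample is a candidate (exhaustive
#' scan). A minimum at either end of the scan range means the curve
#' never shows a contact and is an error.
#'
#' @param curve a \linkS4class{ForceCurve}
#' @param R probe radius (um), default 2.5
#' @param nu Poisson ratio, default 0.5
#' @param minSamples minimum pre- and post-contact samples, default 20
#' @return a \linkS4class{HertzFit}
#' @export
findContactPoint <- function(curve, R = 2.5, nu = 0.5, minSamples = 20) {
  z <- curve@zPiezo; d <- curve@deflection
  n <- length(z)
  if (n < 2 * minSamples)
    stop("curve too short: need >= ", 2 * minSamples, " samples")
  cand <- (minSamples + 1):(n - minSamples + 1)
  rmsTot <- rep(NA_real_, length(cand))
  fits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    j <- cand[i]
    pre <- seq_len(j - 1)
    lf <- stats::lm.fit(cbind(1, z[pre]), d[pre])
    ssPre <- sum(lf$residuals^2) * curve@k^2      # nm^2 -> nN^2
    base <- lf$coefficients
    dc <- d - (base[1] + base[2] * z)
    post <- j:n
    force <- curve@k * dc[post]
    indent <- (z[post] - z[j]) - dc[post] / 1000
    hf <- tryCatch(fitHertz(indent, force, R, nu), error = function(e) NULL)
    if (is.null(hf)) next
    rmsTot[i] <- sqrt((ssPre + hf$rss) / n)
    fits[[i]] <- list(base = base, hf = hf)
  }
  if (all(is.na(rmsTot))) stop("no contact detected")
  best <- which.min(rmsTot)
  if (best == 1 || best == length(cand)) stop("no contact detected")
  # a curve that never touches the cell is fit as well by a single line
  lf <- stats::lm.fit(cbind(1, z), d)
  rmsLine <- sqrt(sum(lf$residuals^2) * curve@k^2 / n)
  if (rmsTot[best] > rmsLine * 0.95) stop("no contact detected")
  j <- cand[best]
  hf <- fits[[best]]$hf
  new("HertzFit", contactIndex = j, contactZ = z[j], E = hf$E,
      compliance = hf$compliance, rmsError = rmsTot[best], R = R, nu = nu,
      meta = list(baseline = unname(fits[[best]]$base), k = curve@k,
                  location = curve@location))
}

#' Per-cell and per-group median compliances
#'
#' Each cell's repeat curves are reduced to a median compliance first,
#' then each group's cells to a group median, so cells (not curves) are
#' the experimental unit. The per-cell table feeds the rank statistics.
#'
#' @param fits data.frame with columns compliance_kPa (kPa^-1), cell and
#'   group (one row per fitted curve)
#' @return list: perCell (cell, group, n_curves, compliance_kPa),
#'   perGroup (group, n_cells, median_compliance_kPa)
#' @export
batchCompliance <- function(fits) {
  stopifnot(all(c("compliance_kPa", "cell", "group") %in% names(fits)))
  perCell <- do.call(rbind, lapply(split(fits, fits[c("group", "cell")],
                                         drop = TRUE), function(s)
    data.frame(cell = s$cell[1], group = s$group[1], n_curves = nrow(s),
               compliance_kPa = stats::median(s$compliance_kPa))))
  rownames(perCell) <- NULL
  perGroup <- do.call(rbind, lapply(split(perCell, perCell$group), function(s)
    data.frame(group = s$group[1], n_cells = nrow(s),
               median_compliance_kPa = stats::median(s$compliance_kPa))))
  rownames(perGroup) <- NULL
  list(perCell = perCell, perGroup = perGroup)
}
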