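# Mean-squared-displacement estimation, Bayesian classification of
# trajectories into the four motion models, the anomalous-diffusion
# filter, tau-reference summaries and the Stokes-Einstein viscosity
# benchmark.

.kBoltzmann <- 1.380649e-23  # J/K

#' Time-averaged MSD of one trajectory
#'
#' Overlapping-window estimator: msd(k dt) is the mean of
#' |r(i+k) - r(i)|^2 over all i, giving n - k displacement pairs at the
#' k-th lag. Lags run up to maxLagFraction of the track length; the
#' default 0.25 limits the strong correlation between long-lag
#' estimates. Sampling must be uniform (consecutive frame indices).
#'
#' @param traj data.frame with columns frame, t_s, x_um, y_um (one bead)
#' @param maxLagFraction largest lag as a fraction of track length
#' @return data.frame with columns tau_s, msd_um2, n_pairs
#' @examples
#' tr <- data.frame(frame = 0:2, t_s = 0:2, x_um = c(0, 1, 2), y_um = 0)
#' computeMsd(tr, maxLagFraction = 1)  # msd(1) = 1, msd(2) = 4
#' @export
computeMsd <- function(traj, maxLagFraction = 0.25) {
  n <- nrow(traj)
  if (n < 2) stop("trajectory must have at least 2 frames")
  df <- diff(traj$frame)
  if (any(df != df[1])) stop("non-uniform sampling: frame gaps differ")
  dt <- traj$t_s[2] - traj$t_s[1]
  maxLag <- max(1L, floor(maxLagFraction * (n - 1)))
  x <- traj$x_um; y <- traj$y_um
  msd <- numeric(maxLag); np <- integer(maxLag)
  for (k in seq_len(maxLag)) {
    dx <- x[(k + 1):n] - x[1:(n - k)]
    dy <- y[(k + 1):n] - y[1:(n - k)]
    msd[k] <- mean(dx * dx + dy * dy)
    np[k] <- n - k
  }
  data.frame(tau_s = seq_len(maxLag) * dt, msd_um2 = msd, n_pairs = np)
}

#' MSD curves for every bead of a trajectory table
#'
#' @param trajectories tidy trajectory data.frame (bead_id, frame, t_s,
#'   x_um, y_um, plus any provenance columns, which are carried through)
#' @param maxLagFraction passed to \code{\link{computeMsd}}
#' @return tidy data.frame: bead_id, tau_s, msd_um2, n_pairs and the
#'   per-bead provenance columns present in the input
#' @export
computeMsdAll <- function(trajectories, maxLagFraction = 0.25) {
  prov <- intersect(c("well", "fov", "condition", "stratum"),
                    names(trajectories))
  out <- lapply(split(trajectories, trajectories$bead_id), function(tr) {
    m <- computeMsd(tr, maxLagFraction)
    m$bead_id <- tr$bead_id[1]
    for (p in prov) m[[p]] <- tr[[p]][1]
    m
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("bead_id", "tau_s", "msd_um2", "n_pairs", prov)]
}

# weighted least squares of msd on columns X with non-negativity
# constraint enforced by trying boundary fits
.wlsNonneg <- function(X, y, w) {
  fit <- function(cols) {
    Xc <- X[, cols, drop = FALSE]
    beta <- tryCatch(
      solve(crossprod(Xc, Xc * w), crossprod(Xc, y * w)),
      error = function(e) NULL)
    if (is.null(beta) || any(beta < -1e-12)) return(NULL)
    b <- numeric(ncol(X)); b[cols] <- pmax(beta, 0)
    r <- y - X %*% b
    list(beta = b, rss = sum(w * r * r))
  }
  best <- fit(seq_len(ncol(X)))
  if (!is.null(best)) return(best)
  cand <- list()
  for (j in seq_len(ncol(X))) cand[[j]] <- fit(j)
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand)) {
    r <- y
    return(list(beta = numeric(ncol(X)), rss = sum(w * r * r)))
  }
  cand[[which.min(vapply(cand, function(f) f$rss, 0))]]
}

#' Fit one motion model to an MSD curve
#'
#' Weighted least squares (weights = number of displacement pairs per
#' lag) of the model's MSD form:
#' \itemize{
#'   \item N:  msd = c
#'   \item D:  msd = 4 D tau + c
#'   \item DR: msd = L^2 (1 - exp(-4 D tau / L^2)) + c
#'   \item DA: msd = 4 Dalpha tau^alpha + c
#' }
#' All four forms include the noise offset c, so localization error
#' cannot masquerade as confinement. The nonlinear parameter of DR and
#' DA is profiled: for a fixed confinement time (or exponent) the
#' remaining parameters are linear, and the 1-D profile is minimized by
#' golden-section search over a wide bounded range.
#'
#' @param curve data.frame from \code{\link{computeMsd}} with >= 5 lags
#' @param model "N", "D", "DR" or "DA"
#' @param alphaMax upper bound of the DA exponent search
#' @param weights optional explicit weights overriding the pair counts
#'   (used by the classifier's variance-calibrated likelihood)
#' @return list: model, params (named list), rss (weighted, with weights
#'   normalized to mean 1), n (lags), kPar (parameter count), fitted
#' @export
fitMotionModel <- function(curve, model = c("N", "D", "DR", "DA"),
                           alphaMax = 1.4, weights = NULL) {
  model <- match.arg(model)
  tau <- curve$tau_s; y <- curve$msd_um2
  n <- length(tau)
  if (n < 5) stop("at least 5 usable lags required")
  if (is.null(weights)) weights <- curve$n_pairs
  w <- weights / mean(weights)
  if (model == "N") {
    cH <- sum(w * y) / sum(w)
    r <- y - cH
    return(list(model = model, params = list(c = cH), rss = sum(w * r * r),
                n = n, kPar = 1, fitted = rep(cH, n)))
  }
  if (model == "D") {
    f <- .wlsNonneg(cbind(tau4 = 4 * tau, c = 1), y, w)
    return(list(model = model,
                params = list(D = f$beta[1], c = f$beta[2]), rss = f$rss,
                n = n, kPar = 2,
                fitted = 4 * f$beta[1] * tau + f$beta[2]))
  }
  if (model == "DR") {
    prof <- function(lt0) {
      g <- 1 - exp(-tau / exp(lt0))
      .wlsNonneg(cbind(g = g, c = 1), y, w)$rss
    }
    lo <- log(tau[1] / 10); hi <- log(tau[n] * 100)
    opt <- stats::optimize(prof, c(lo, hi))
    t0 <- exp(opt$minimum)
    f <- .wlsNonneg(cbind(g = 1 - exp(-tau / t0), c = 1), y, w)
    L2 <- f$beta[1]
    return(list(model = model,
                params = list(L = sqrt(L2), D = L2 / (4 * t0), c = f$beta[2]),
                rss = f$rss, n = n, kPar = 3,
                fitted = L2 * (1 - exp(-tau / t0)) + f$beta[2]))
  }
  # DA
  prof <- function(a) .wlsNonneg(cbind(p = 4 * tau^a, c = 1), y, w)$rss
  opt <- stats::optimize(prof, c(0.01, alphaMax), tol = 1e-8)
  a <- opt$minimum
  f <- .wlsNonneg(cbind(p = 4 * tau^a, c = 1), y, w)
  list(model = model,
       params = list(Dalpha = f$beta[1], alpha = a, c = f$beta[2]),
       rss = f$rss, n = n, kPar = 3,
       fitted = 4 * f$beta[1] * tau^a + f$beta[2])
}

#' Classify one trajectory by Bayesian model selection
#'
#' Fits all four motion models to the MSD curve and approximates each
#' model's evidence by BIC from a variance-calibrated Gaussian
#' likelihood. Two properties of time-averaged MSD curves are accounted
#' for explicitly: (i) adjacent lags are strongly correlated, so the
#' fit is evaluated on an octave-spaced (factor-2) lag subset, which
#' approximately decorrelates the residuals; (ii) the sampling variance
#' of the estimator grows with lag, Var(msd_k) ~ msd_k^2 * 4k / (3 n),
#' so the likelihood uses these variances rather than the pair-count
#' weights (which would grossly overweight long lags). The evidence is
#' then BIC = chi^2 + kPar * log(n) with n the number of frames, and
#' posteriors are the normalized exp(-BIC/2) under equal priors. Ties
#' are broken toward the simpler model (N < D < DR < DA by parameter
#' count). A model whose fit fails is marked infeasible (posterior 0);
#' all four failing is an error.
#'
#' @param curve data.frame from \code{\link{computeMsd}}
#' @return list: posteriors (named p_N, p_D, p_DR, p_DA, summing to 1),
#'   selected, fits (the four variance-calibrated fit objects; their
#'   parameter estimates, in particular the DA exponent, inherit the
#'   calibrated weighting and are the package's reference estimates)
#' @export
classifyTrajectory <- function(curve) {
  models <- c("N", "D", "DR", "DA")
  nAll <- nrow(curve)
  nFrames <- curve$n_pairs[1] + 1          # n_pairs at lag 1 is n - 1
  lags <- if (nAll < 16) seq_len(nAll) else
    unique(c(2^(0:floor(log2(nAll))), nAll))
  cv <- curve[lags, , drop = FALSE]
  sig <- cv$msd_um2 * sqrt(4 * lags / (3 * nFrames))
  sig <- pmax(sig, max(cv$msd_um2, .Machine$double.eps) * 1e-9)
  w <- 1 / sig^2
  fits <- lapply(models, function(m)
    tryCatch(fitMotionModel(cv, m, weights = w), error = function(e) NULL))
  names(fits) <- models
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("all motion-model fits infeasible")
  bic <- rep(Inf, 4)
  for (i in which(ok)) {
    chi2 <- fits[[i]]$rss * mean(w)        # rss uses weights normalized to mean 1
    bic[i] <- chi2 + fits[[i]]$kPar * log(nFrames)
  }
  post <- exp(-(bic - min(bic)) / 2)
  post[!is.finite(post)] <- 0
  post <- post / sum(post)
  # argmax with ties toward the simpler model: models are already ordered
  sel <- models[which(post >= max(post) - 1e-12)[1]]
  list(posteriors = stats::setNames(post, paste0("p_", models)),
       selected = sel, fits = fits)
}

#' Classify every bead of an MSD table
#'
#' @param msd tidy MSD data.frame from \code{\link{computeMsdAll}}
#' @return data.frame: one row per bead with posteriors p_N..p_DA,
#'   selected model, fitted DA parameters (Dalpha, alpha), noise offset
#'   of the selected model, and provenance columns
#' @export
classifyTrajectories <- function(msd) {
  prov <- intersect(c("well", "fov", "condition", "stratum"), names(msd))
  out <- lapply(split(msd, msd$bead_id), function(cv) {
    cl <- classifyTrajectory(cv)
    da <- cl$fits$DA
    row <- data.frame(bead_id = cv$bead_id[1], t(cl$posteriors),
                      selected = cl$selected,
                      Dalpha = if (!is.null(da)) da$params$Dalpha else NA,
                      alpha = if (!is.null(da)) da$params$alpha else NA)
    for (p in prov) row[[p]] <- cv[[p]][1]
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Retain anomalous-diffusion trajectories
#'
#' Keeps beads the classifier labels DA with posterior above the
#' threshold (default 0.5): beads stuck to the substrate (N) or freely
#' diffusing in the medium (D) are excluded from the compliance
#' analysis. Also tabulates the per-model selection frequencies.
#'
#' @param posteriors data.frame from \code{\link{classifyTrajectories}}
#' @param threshold DA posterior threshold, in (0, 1)
#' @return list: retained (subset of the input rows), modelFrequency
#'   (data.frame of per-model selection fractions)
#' @export
filterDa <- function(posteriors, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (!nrow(posteriors))
    return(list(retained = posteriors,
                modelFrequency = data.frame(model = character(),
                                            n = integer(),
                                            fraction = numeric())))
  keep <- posteriors$selected == "DA" & posteriors$p_DA > threshold
  tab <- table(factor(posteriors$selected, levels = c("N", "D", "DR", "DA")))
  freq <- data.frame(model = names(tab), n = as.integer(tab),
                     fraction = as.numeric(tab) / nrow(posteriors))
  list(retained = posteriors[keep, , drop = FALSE], modelFrequency = freq)
}

#' Median MSD and RMS displacement at a reference lag
#'
#' For each group (or the pooled set), takes each bead's MSD at the lag
#' nearest tauRef (within dt/2), and reports the median MSD (um^2), the
#' median RMS displacement sqrt(median MSD) in nm, and the bead count.
#'
#' @param msd tidy MSD data.frame from \code{\link{computeMsdAll}}
#' @param tauRef reference lag (s), default 1
#' @param by optional grouping column name (e.g. "condition")
#' @return data.frame: group, n_beads, median_msd_um2, median_rms_nm
#' @export
summarizeAtTau <- function(msd, tauRef = 1, by = NULL) {
  dt <- min(msd$tau_s)
  vals <- msdAtTau(msd, tauRef)
  grp <- if (is.null(by)) rep("all", nrow(vals)) else vals[[by]]
  out <- lapply(split(vals$msd_um2, grp), function(v)
    data.frame(n_beads = length(v), median_msd_um2 = stats::median(v),
               median_rms_nm = sqrt(stats::median(v)) * 1000))
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = names(out)), res)
  rownames(res) <- NULL
  res
}

#' Per-bead MSD values at a reference lag
#'
#' @inheritParams summarizeAtTau
#' @return data.frame: bead_id, msd_um2 at the nearest lag, plus
#'   provenance columns
#' @export
msdAtTau <- function(msd, tauRef = 1) {
  prov <- intersect(c("well", "fov", "condition", "stratum"), names(msd))
  dt <- min(msd$tau_s)
  out <- lapply(split(msd, msd$bead_id), function(cv) {
    i <- which.min(abs(cv$tau_s - tauRef))
    if (abs(cv$tau_s[i] - tauRef) > dt / 2)
      stop("tauRef beyond the curve's maximum lag")
    cv[i, c("bead_id", "msd_um2", prov)]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Viscosity of the medium from freely diffusing beads
#'
#' Fits the ensemble MSD of Brownian beads (weighted by pair counts,
#' pooled across beads) with the linear form 4 D tau + c and converts
#' the diffusion coefficient to a viscosity with the Stokes-Einstein
#' relation eta = kB T / (6 pi D r).
#'
#' @param msd tidy MSD data.frame of beads classified as model D
#' @param radius bead radius (um)
#' @param temperature absolute temperature (K), default 296
#' @param residTol warn if the relative weighted rms residual of the
#'   linear fit exceeds this (non-linear ensemble MSD)
#' @return list: viscosity_mPas, D_um2_s, c_um2
#' @examples
#' # D = 2.33 um^2/s, r = 0.1 um, T = 296 K -> ~0.93 mPa s
#' @export
viscosityFromEnsemble <- function(msd, radius, temperature = 296,
                                  residTol = 0.1) {
  agg <- stats::aggregate(cbind(w = n_pairs, wy = msd_um2 * n_pairs) ~ tau_s,
                          data = msd, FUN = sum)
  tau <- agg$tau_s; y <- agg$wy / agg$w; w <- agg$w / mean(agg$w)
  f <- .wlsNonneg(cbind(tau4 = 4 * tau, c = 1), y, w)
  D <- f$beta[1]
  if (D <= 0) stop("non-positive ensemble diffusion coefficient")
  ybar <- sum(w * y) / sum(w)
  relResid <- sqrt(f$rss / sum(w * (y - ybar)^2))
  if (relResid > residTol)
    warning(sprintf("ensemble MSD deviates from linearity (rel. resid %.2g)",
                    relResid))
  eta <- .kBoltzmann * temperature / (6 * pi * (D * 1e-12) * (radius * 1e-6))
  list(viscosity_mPas = eta * 1e3, D_um2_s = D, c_um2 = f$beta[2])
}
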