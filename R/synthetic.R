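# Seeded generators for every input the pipeline consumes: trajectories
# under the four motion models, rendered bead videos, through-focus
# stacks, AFM force curves, and whole multiwell plates.

.fgn_cache <- new.env(parent = emptyenv())

# Cholesky factor (upper) of the fractional-Gaussian-noise covariance for
# n increments at step dt, Hurst H; per-axis fBm variance 2*Dalpha*t^alpha
# is obtained by scaling unit-Dalpha noise. Cached per (n, dt, alpha).
.fgnChol <- function(nInc, dt, alpha) {
  key <- sprintf("n%d_dt%.12g_a%.12g", nInc, dt, alpha)
  if (!is.null(.fgn_cache[[key]])) return(.fgn_cache[[key]])
  H2 <- alpha                        # 2H = alpha
  k <- 0:(nInc - 1)
  # autocovariance of unit-variance-scale fGn: gamma(k) = dt^2H/2 *
  # (|k+1|^2H - 2|k|^2H + |k-1|^2H)
  gam <- dt^H2 / 2 * (abs(k + 1)^H2 - 2 * abs(k)^H2 + abs(k - 1)^H2)
  C <- stats::toeplitz(gam)
  U <- chol(C)
  .fgn_cache[[key]] <- U
  U
}

# n x m matrix of fBm increment columns with per-axis Var(x(t)) = 2*Dalpha*t^alpha
.fbmIncrements <- function(nInc, m, dt, alpha, Dalpha) {
  U <- .fgnChol(nInc, dt, alpha)
  z <- matrix(stats::rnorm(nInc * m), nInc, m)
  sqrt(2 * Dalpha) * crossprod(U, z)
}

# Reflect positions into [lo, hi] (billiard reflection, handles multiple bounces)
.reflect <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

.simPositions <- function(params, nFrames, dt, origin) {
  m <- params@model
  if (m == "N") {
    jsd <- sqrt(params@c / 4)       # per-axis jitter so that MSD plateau = c
    x <- origin[1] + stats::rnorm(nFrames, sd = jsd)
    y <- origin[2] + stats::rnorm(nFrames, sd = jsd)
  } else if (m == "D") {
    ssd <- sqrt(2 * params@D * dt)
    x <- origin[1] + cumsum(c(0, stats::rnorm(nFrames - 1, sd = ssd)))
    y <- origin[2] + cumsum(c(0, stats::rnorm(nFrames - 1, sd = ssd)))
  } else if (m == "DR") {
    ssd <- sqrt(2 * params@D * dt)
    half <- params@L / 2
    x <- .reflect(origin[1] + cumsum(c(0, stats::rnorm(nFrames - 1, sd = ssd))),
                  origin[1] - half, origin[1] + half)
    y <- .reflect(origin[2] + cumsum(c(0, stats::rnorm(nFrames - 1, sd = ssd))),
                  origin[2] - half, origin[2] + half)
  } else {                           # DA: exact fBm via Cholesky of fGn covariance
    inc <- .fbmIncrements(nFrames - 1, 2, dt, params@alpha, params@Dalpha)
    x <- origin[1] + cumsum(c(0, inc[, 1]))
    y <- origin[2] + cumsum(c(0, inc[, 2]))
  }
  if (params@locNoiseSd > 0) {
    x <- x + stats::rnorm(nFrames, sd = params@locNoiseSd)
    y <- y + stats::rnorm(nFrames, sd = params@locNoiseSd)
  }
  cbind(x, y)
}

#' Simulate one bead trajectory
#'
#' Generates a time-ordered 2-D position series under one of the four
#' motion models: N (fixed point plus static jitter), D (Brownian), DR
#' (Brownian motion reflected inside a square corral of side L), DA
#' (fractional Brownian motion with Hurst exponent alpha/2, generated
#' exactly by Cholesky factorization of the increment covariance).
#' Localization noise is added independently per frame and coordinate.
#'
#' @param params a \linkS4class{MotionModelParams}
#' @param spec a \linkS4class{FrameSpec} (supplies dt and nFrames)
#' @param seed integer seed; NULL leaves the RNG state alone
#' @param origin start position in um; default is the field center
#' @param beadId id stored in the bead_id column
#' @return data.frame with columns bead_id, frame (0-based), t_s, x_um, y_um
#' @examples
#' tr <- simulateTrajectory(motionParams("D", D = 0.1), frameSpec(nFrames = 50), seed = 1)
#' head(tr)
#' @export
simulateTrajectory <- function(params, spec, seed = NULL, origin = NULL,
                               beadId = 1L) {
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(origin))
    origin <- c(spec@width, spec@height) / 2 * spec@scale
  n <- spec@nFrames
  pos <- .simPositions(params, n, spec@dt, origin)
  data.frame(bead_id = beadId, frame = 0:(n - 1), t_s = (0:(n - 1)) * spec@dt,
             x_um = pos[, 1], y_um = pos[, 2])
}

#' Simulate an ensemble of trajectories
#'
#' Vectorized convenience around \code{\link{simulateTrajectory}}; for the
#' DA model all tracks share one cached Cholesky factor, making large
#' ensembles cheap.
#'
#' @inheritParams simulateTrajectory
#' @param n number of trajectories
#' @param origins n x 2 matrix of start positions (um); default field center
#' @return tidy data.frame (bead_id, frame, t_s, x_um, y_um)
#' @export
simulateTrajectories <- function(params, spec, n, seed = NULL, origins = NULL) {
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(origins)) {
    ctr <- c(spec@width, spec@height) / 2 * spec@scale
    origins <- matrix(ctr, n, 2, byrow = TRUE)
  }
  nf <- spec@nFrames
  if (params@model == "DA") {
    inc <- .fbmIncrements(nf - 1, 2 * n, spec@dt, params@alpha, params@Dalpha)
    xs <- apply(rbind(0, inc[, seq_len(n), drop = FALSE]), 2, cumsum) +
      rep(origins[, 1], each = nf)
    ys <- apply(rbind(0, inc[, n + seq_len(n), drop = FALSE]), 2, cumsum) +
      rep(origins[, 2], each = nf)
    if (params@locNoiseSd > 0) {
      xs <- xs + stats::rnorm(length(xs), sd = params@locNoiseSd)
      ys <- ys + stats::rnorm(length(ys), sd = params@locNoiseSd)
    }
    return(data.frame(
      bead_id = rep(seq_len(n), each = nf), frame = rep(0:(nf - 1), n),
      t_s = rep((0:(nf - 1)) * spec@dt, n), x_um = as.vector(xs),
      y_um = as.vector(ys)))
  }
  out <- vector("list", n)
  for (i in seq_len(n))
    out[[i]] <- simulateTrajectory(params, spec, seed = NULL,
                                   origin = origins[i, ], beadId = i)
  do.call(rbind, out)
}

# Add one Gaussian spot (possibly clipped at the frame edge) to a frame.
# cx, cy are 0-based pixel-center coordinates.
.addSpot <- function(frame, cx, cy, sigma, amplitude) {
  h <- nrow(frame); w <- ncol(frame)
  r <- ceiling(4 * sigma)
  x0 <- max(0, floor(cx) - r); x1 <- min(w - 1, ceiling(cx) + r)
  y0 <- max(0, floor(cy) - r); y1 <- min(h - 1, ceiling(cy) + r)
  if (x0 > x1 || y0 > y1) return(frame)
  xs <- x0:x1; ys <- y0:y1
  gx <- exp(-(xs - cx)^2 / (2 * sigma^2))
  gy <- exp(-(ys - cy)^2 / (2 * sigma^2))
  frame[ys + 1, xs + 1] <- frame[ys + 1, xs + 1] + amplitude * outer(gy, gx)
  frame
}

#' Render trajectories into a fluorescence video
#'
#' Each bead is drawn as a 2-D Gaussian of sigma \code{psfSigma} px with a
#' frame-independent amplitude (no photobleaching in the model), on a
#' constant background with i.i.d. Gaussian read noise; values are
#' rounded and clipped to the bit depth. Positions are converted from um
#' to px with the spec's scale; beads falling outside the field are
#' rendered clipped, with a warning.
#'
#' @param trajectories tidy trajectory data.frame (bead_id, frame, x_um, y_um)
#' @param spec a \linkS4class{FrameSpec}
#' @param seed integer seed for the read noise
#' @param amplitude peak spot amplitude above background (counts)
#' @return a \linkS4class{VideoStack}
#' @export
renderVideo <- function(trajectories, spec, seed = NULL, amplitude = 500) {
  if (!is.null(seed)) set.seed(seed)
  h <- spec@height; w <- spec@width; nf <- spec@nFrames
  maxval <- 2^spec@bitDepth - 1
  arr <- array(0L, c(h, w, nf))
  byFrame <- if (nrow(trajectories))
    split(trajectories[c("x_um", "y_um")], trajectories$frame) else list()
  if (nrow(trajectories)) {
    px <- trajectories$x_um / spec@scale
    py <- trajectories$y_um / spec@scale
    if (any(px < 0 | px > w - 1 | py < 0 | py > h - 1))
      warning("bead position(s) outside the field; rendering clipped")
  }
  frameKeys <- names(byFrame)
  for (f in seq_len(nf)) {
    img <- matrix(spec@backgroundLevel, h, w)
    sp <- byFrame[[as.character(f - 1)]]
    if (!is.null(sp) && nrow(sp)) {
      for (b in seq_len(nrow(sp)))
        img <- .addSpot(img, sp$x_um[b] / spec@scale, sp$y_um[b] / spec@scale,
                        spec@psfSigma, amplitude)
    }
    if (spec@readNoiseSd > 0)
      img <- img + stats::rnorm(h * w, sd = spec@readNoiseSd)
    arr[, , f] <- as.integer(pmin(pmax(round(img), 0), maxval))
  }
  new("VideoStack", data = arr, spec = spec)
}

#' Render a through-focus stack
#'
#' Models defocus as a Gaussian spot whose sigma grows with distance from
#' the focal plane, sigma(z) = psfSigma * sqrt(1 + ((z - zFocus)/zR)^2),
#' with flux conserved so the peak amplitude falls as 1/sigma(z)^2. The
#' returned stack has one slice per z-grid value; peak intensity is
#' maximal at the slice nearest zFocus.
#'
#' @param beadPositions n x 2 matrix of bead positions (px, 0-based)
#' @param zGrid z positions of the slices (um); must be non-empty
#' @param spec a \linkS4class{FrameSpec}; its nFrames is ignored
#' @param zFocus true focal plane (um)
#' @param zR defocus depth scale (um)
#' @param amplitude in-focus peak amplitude above background (counts)
#' @param seed integer seed for the read noise
#' @return a \linkS4class{VideoStack} with one slice per z value
#' @export
renderFocusStack <- function(beadPositions, zGrid, spec, zFocus = 0, zR = 2,
                             amplitude = 500, seed = NULL) {
  if (length(zGrid) == 0) stop("zGrid must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  beadPositions <- matrix(beadPositions, ncol = 2)
  h <- spec@height; w <- spec@width
  maxval <- 2^spec@bitDepth - 1
  arr <- array(0L, c(h, w, length(zGrid)))
  for (s in seq_along(zGrid)) {
    sig <- spec@psfSigma * sqrt(1 + ((zGrid[s] - zFocus) / zR)^2)
    amp <- amplitude * (spec@psfSigma / sig)^2
    img <- matrix(spec@backgroundLevel, h, w)
    for (b in seq_len(nrow(beadPositions)))
      img <- .addSpot(img, beadPositions[b, 1], beadPositions[b, 2], sig, amp)
    if (spec@readNoiseSd > 0)
      img <- img + stats::rnorm(h * w, sd = spec@readNoiseSd)
    arr[, , s] <- as.integer(pmin(pmax(round(img), 0), maxval))
  }
  sp <- spec
  sp@nFrames <- length(zGrid)
  new("VideoStack", data = arr, spec = sp)
}

#' Hertzian contact force of a spherical indenter
#'
#' F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2), evaluated in the
#' package's working units (E in Pa, R and delta in um, F in nN).
#'
#' @param delta indentation (um)
#' @param E Young's modulus (Pa)
#' @param R probe radius (um)
#' @param nu Poisson ratio
#' @return force (nN)
#' @examples
#' hertzForce(1, 500, 2.5, 0.5)  # ~1.405 nN
#' @export
hertzForce <- function(delta, E, R, nu = 0.5) {
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * delta^1.5 * 1e-3
}

#' Simulate an AFM approach curve
#'
#' Samples the piezo on an ascending grid. Before contact the force is
#' baseline noise; after contact the force follows the spherical Hertz
#' model, with the cantilever deflection solved self-consistently
#' (F = k * deflection, indentation = piezo displacement - deflection).
#' The approach terminates at the first sample reaching the trigger
#' force.
#'
#' @param E Young's modulus (Pa)
#' @param R probe radius (um); default 2.5 (5 um bead)
#' @param nu Poisson ratio; default 0.5 (incompressible)
#' @param k cantilever spring constant (N/m); default nominal 0.02
#' @param contactZ piezo position at contact (um)
#' @param noiseSd force noise sd (nN)
#' @param trigger trigger force (nN); 1 on-nucleus, 0.5 off-nucleus
#' @param seed integer seed
#' @param dz piezo sampling step (um)
#' @param zMax piezo range limit (um); error if the trigger is unreachable
#' @param location "on_nucleus" or "off_nucleus"
#' @return a \linkS4class{ForceCurve}; ground truth (E, contactZ) kept in meta
#' @export
simulateForceCurve <- function(E, R = 2.5, nu = 0.5, k = 0.02, contactZ = 1,
                               noiseSd = 0.02, trigger = 1, seed = NULL,
                               dz = 0.002, zMax = contactZ + 2.5,
                               location = "on_nucleus") {
  stopifnot(E > 0, R > 0, nu >= 0, nu <= 0.5, k > 0)
  if (!is.null(seed)) set.seed(seed)
  A <- (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * 1e-3   # nN / um^1.5
  z <- seq(0, zMax, by = dz)
  F <- numeric(length(z))
  nTrig <- NA_integer_
  for (i in seq_along(z)) {
    if (z[i] > contactZ) {
      zi <- z[i] - contactZ
      # solve F = A * (zi - F/(1000 k))^1.5
      F[i] <- stats::uniroot(function(f) A * pmax(zi - f / (1000 * k), 0)^1.5 - f,
                             c(0, A * zi^1.5 + 1e-9), tol = 1e-12)$root
      if (F[i] >= trigger) { nTrig <- i; break }
    }
  }
  if (is.na(nTrig)) stop("trigger force unreachable within piezo range")
  z <- z[seq_len(nTrig)]
  F <- F[seq_len(nTrig)]
  defl <- F / k                                       # nm
  if (noiseSd > 0) defl <- defl + stats::rnorm(length(defl), sd = noiseSd / k)
  new("ForceCurve", zPiezo = z, deflection = defl, k = k,
      location = location, trigger = trigger,
      meta = list(E = E, contactZ = contactZ, R = R, nu = nu,
                  noiseSd = noiseSd, synthetic = TRUE))
}

#' Simulate a whole multiwell plate of bead trajectories
#'
#' Draws a Poisson number of beads per field of view (mean
#' \code{beadsPerFov}, default 3), places them uniformly inside the field
#' with an edge margin, and simulates each under its well's condition
#' parameters. Output rows are tagged with well, fov, condition and
#' stratum, ready for the MSD / classification / statistics stages.
#'
#' @param layout a \linkS4class{PlateLayout}
#' @param conditionParams named list: condition label ->
#'   \linkS4class{MotionModelParams}
#' @param spec a \linkS4class{FrameSpec}
#' @param beadsPerFov mean bead count per FOV
#' @param seed integer seed
#' @param edgeMarginUm beads are placed at least this far from the field
#'   edge (um)
#' @return tidy trajectory data.frame with provenance columns
#'   (bead_id, frame, t_s, x_um, y_um, well, fov, condition, stratum)
#' @export
simulatePlate <- function(layout, conditionParams, spec, beadsPerFov = 3,
                          seed = NULL, edgeMarginUm = 10) {
  validObject(layout)
  missing <- setdiff(unique(layout@wells), names(conditionParams))
  if (length(missing))
    stop("no parameters for condition(s): ", paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  fw <- spec@width * spec@scale; fh <- spec@height * spec@scale
  # clamp so small test fields keep a usable interior
  edgeMarginUm <- min(edgeMarginUm, 0.2 * min(fw, fh))
  out <- vector("list", 0)
  beadCounter <- 0L
  for (well in names(layout@wells)) {
    cond <- layout@wells[[well]]
    strat <- layout@strata[[well]]
    par <- conditionParams[[cond]]
    for (fov in seq_len(layout@fovsPerWell)) {
      nb <- stats::rpois(1, beadsPerFov)
      if (nb == 0) next
      origins <- cbind(stats::runif(nb, edgeMarginUm, fw - edgeMarginUm),
                       stats::runif(nb, edgeMarginUm, fh - edgeMarginUm))
      tr <- simulateTrajectories(par, spec, nb, seed = NULL, origins = origins)
      tr$bead_id <- tr$bead_id + beadCounter
      beadCounter <- beadCounter + nb
      tr$well <- well; tr$fov <- fov; tr$condition <- cond; tr$stratum <- strat
      out[[length(out) + 1L]] <- tr
    }
  }
  if (!length(out))
    return(data.frame(bead_id = integer(), frame = integer(), t_s = numeric(),
                      x_um = numeric(), y_um = numeric(), well = character(),
                      fov = integer(), condition = character(),
                      stratum = character()))
  do.call(rbind, out)
}

#' Balanced plate layout
#'
#' Builds a layout in which every condition appears in every stratum
#' (the anti-bias arrangement in which each objective views the same
#' pattern of cell populations).
#'
#' @param conditions character vector of condition labels
#' @param nStrata number of strata (objective/plate pairings)
#' @param wellsPerCell wells per (condition, stratum) cell
#' @param fovsPerWell fields of view per well
#' @return a \linkS4class{PlateLayout}
#' @export
balancedPlateLayout <- function(conditions, nStrata = 8, wellsPerCell = 1,
                                fovsPerWell = 2) {
  grid <- expand.grid(rep_cell = seq_len(wellsPerCell),
                      condition = conditions,
                      stratum = paste0("S", seq_len(nStrata)),
                      stringsAsFactors = FALSE)
  ids <- sprintf("W%03d", seq_len(nrow(grid)))
  wells <- stats::setNames(grid$condition, ids)
  strata <- stats::setNames(grid$stratum, ids)
  new("PlateLayout", wells = wells, strata = strata, fovsPerWell = fovsPerWell)
}
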