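#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Frame and image-model specification
#'
#' Describes the geometry, timing and image model of an acquisition:
#' frame size, frame interval, number of frames, bit depth, pixel scale,
#' and the additive-Gaussian image model (constant background, read
#' noise, Gaussian point-spread sigma).
#'
#' Defaults mirror a 33 fps, 60 s acquisition of 2 um beads through a
#' reduced-NA (0.45) 40x objective at 0.25 um/px: 512 x 512 px, 1980
#' frames, 16-bit, psf sigma 2 px, background 100 counts, read noise
#' 2 counts.
#'
#' @slot width,height frame size in pixels
#' @slot dt frame interval (s)
#' @slot nFrames number of frames
#' @slot bitDepth 8 or 16
#' @slot scale pixel scale (um per px)
#' @slot backgroundLevel constant background (counts)
#' @slot readNoiseSd Gaussian read noise per pixel (counts)
#' @slot psfSigma in-focus Gaussian spot sigma (px)
#' @export
setClass("FrameSpec", representation(
  width = "numeric", height = "numeric", dt = "numeric",
  nFrames = "numeric", bitDepth = "numeric", scale = "numeric",
  backgroundLevel = "numeric", readNoiseSd = "numeric", psfSigma = "numeric"
))

setValidity("FrameSpec", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@nFrames < 2) msg <- c(msg, "nFrames must be >= 2")
  if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
  if (!object@bitDepth %in% c(8, 16)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (object@width < 1 || object@height < 1) msg <- c(msg, "frame must be >= 1 px")
  if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
  if (object@psfSigma <= 0) msg <- c(msg, "psfSigma must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a FrameSpec
#'
#' @param width,height frame size in pixels
#' @param dt frame interval in seconds (default 1/33 s)
#' @param nFrames number of frames (default 1980, i.e. 60 s at 33 fps)
#' @param bitDepth sample bit depth, 8 or 16
#' @param scale pixel scale in um per px
#' @param backgroundLevel constant background level in counts
#' @param readNoiseSd per-pixel Gaussian read noise sd in counts
#' @param psfSigma in-focus Gaussian spot sigma in px
#' @return a \linkS4class{FrameSpec}
#' @examples
#' frameSpec(nFrames = 100)
#' @export
frameSpec <- function(width = 512, height = 512, dt = 1/33, nFrames = 1980,
                      bitDepth = 16, scale = 0.25, backgroundLevel = 100,
                      readNoiseSd = 2, psfSigma = 2) {
  new("FrameSpec", width = width, height = height, dt = dt,
      nFrames = nFrames, bitDepth = bitDepth, scale = scale,
      backgroundLevel = backgroundLevel, readNoiseSd = readNoiseSd,
      psfSigma = psfSigma)
}

setMethod("show", "FrameSpec", function(object) {
  cat(sprintf("FrameSpec: %d x %d px, %d frames @ %.4g s, %d-bit, %.3g um/px\n",
              object@width, object@height, object@nFrames, object@dt,
              object@bitDepth, object@scale))
  cat(sprintf("  image model: background %.3g, read noise %.3g, psf sigma %.3g px\n",
              object@backgroundLevel, object@readNoiseSd, object@psfSigma))
})

#' Motion-model parameters for a single bead
#'
#' One of four motion models: \code{"N"} (elastic / stuck bead: static
#' jitter around a fixed point), \code{"D"} (Newtonian / free Brownian
#' diffusion), \code{"DR"} (confined diffusion in a corral), \code{"DA"}
#' (anomalous subdiffusion, generated as fractional Brownian motion with
#' Hurst exponent alpha/2).
#'
#' @slot model one of "N", "D", "DR", "DA"
#' @slot c static-noise MSD plateau for model N (um^2)
#' @slot D diffusion coefficient (um^2/s; models D, DR)
#' @slot L corral side length (um; model DR)
#' @slot Dalpha generalized diffusion coefficient (um^2/s^alpha; model DA)
#' @slot alpha anomalous exponent in (0, 1] (model DA)
#' @slot locNoiseSd localization noise per coordinate (um)
#' @export
setClass("MotionModelParams", representation(
  model = "character", c = "numeric", D = "numericOrNULL",
  L = "numericOrNULL", Dalpha = "numericOrNULL", alpha = "numericOrNULL",
  locNoiseSd = "numeric"
))

setValidity("MotionModelParams", function(object) {
  msg <- character()
  if (!object@model %in% c("N", "D", "DR", "DA"))
    msg <- c(msg, "model must be one of N, D, DR, DA")
  if (object@c < 0) msg <- c(msg, "c must be >= 0")
  if (object@locNoiseSd < 0) msg <- c(msg, "locNoiseSd must be >= 0")
  if (object@model %in% c("D", "DR")) {
    if (is.null(object@D) || object@D < 0) msg <- c(msg, "D must be >= 0")
  }
  if (object@model == "DR") {
    if (is.null(object@L) || object@L <= 0) msg <- c(msg, "L must be > 0 for model DR")
  }
  if (object@model == "DA") {
    if (is.null(object@alpha) || object@alpha <= 0 || object@alpha > 1)
      msg <- c(msg, "alpha must satisfy 0 < alpha <= 1 for model DA")
    if (is.null(object@Dalpha) || object@Dalpha < 0)
      msg <- c(msg, "Dalpha must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct motion-model parameters
#'
#' @param model "N", "D", "DR" or "DA"
#' @param c static-noise MSD plateau (um^2, model N)
#' @param D diffusion coefficient (um^2/s, models D and DR)
#' @param L corral side (um, model DR)
#' @param Dalpha generalized diffusion coefficient (um^2/s^alpha, model DA)
#' @param alpha anomalous exponent, 0 < alpha <= 1 (model DA)
#' @param locNoiseSd localization noise sd per coordinate (um); the
#'   default 0.02 um matches the centroid precision of a bright 2 um bead
#' @return a \linkS4class{MotionModelParams}
#' @examples
#' motionParams("DA", Dalpha = 0.01, alpha = 0.5)
#' @export
motionParams <- function(model, c = 0, D = NULL, L = NULL, Dalpha = NULL,
                         alpha = NULL, locNoiseSd = 0.02) {
  new("MotionModelParams", model = model, c = c, D = D, L = L,
      Dalpha = Dalpha, alpha = alpha, locNoiseSd = locNoiseSd)
}

setMethod("show", "MotionModelParams", function(object) {
  extra <- switch(object@model,
    N = sprintf("c = %.3g um^2", object@c),
    D = sprintf("D = %.3g um^2/s", object@D),
    DR = sprintf("D = %.3g um^2/s, L = %.3g um", object@D, object@L),
    DA = sprintf("Dalpha = %.3g um^2/s^a, alpha = %.3g", object@Dalpha, object@alpha))
  cat(sprintf("MotionModelParams [%s]: %s, locNoiseSd = %.3g um\n",
              object@model, extra, object@locNoiseSd))
})

#' A multi-frame video (or z-stack) with its acquisition spec
#'
#' Pixel data are stored as an integer array indexed \code{[y, x, frame]}
#' with 0-based pixel-center coordinates in all position conventions:
#' integer coordinate k is the center of the (k+1)-th pixel.
#'
#' @slot data integer array, dim = c(height, width, nFrames)
#' @slot spec the \linkS4class{FrameSpec}
#' @export
setClass("VideoStack", representation(data = "array", spec = "FrameSpec"))

setValidity("VideoStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be a 3-D array [y, x, frame]")
  if (d[1] != object@spec@height || d[2] != object@spec@width ||
      d[3] != object@spec@nFrames)
    return("array dimensions must match spec (height, width, nFrames)")
  TRUE
})

#' @describeIn VideoStack-class number of frames
#' @param x a VideoStack
#' @export
setMethod("length", "VideoStack", function(x) dim(x@data)[3])

#' Extract frames from a VideoStack
#' @param x a VideoStack
#' @param i frame index or indices
#' @return a matrix (single frame) or integer array
#' @export
setMethod("[", "VideoStack", function(x, i) {
  if (length(i) == 1) x@data[, , i] else x@data[, , i, drop = FALSE]
})

#' @rdname VideoStack-class
#' @param object a VideoStack
#' @export
setMethod("show", "VideoStack", function(object) {
  cat(sprintf("VideoStack: %d frames of %d x %d px (%d-bit), range [%d, %d]\n",
              dim(object@data)[3], dim(object@data)[2], dim(object@data)[1],
              object@spec@bitDepth, min(object@data), max(object@data)))
})

#' @rdname VideoStack-class
#' @export
videoData <- function(x) x@data

#' @rdname VideoStack-class
#' @export
videoSpec <- function(x) x@spec

#' Multiwell plate layout
#'
#' Maps well ids to condition labels and to strata (plate/objective
#' pairings used as blocking factors by the stratified statistics).
#'
#' @slot wells named character vector: well id -> condition label
#' @slot strata named character vector: well id -> stratum id
#' @slot fovsPerWell fields of view imaged per well
#' @export
setClass("PlateLayout", representation(
  wells = "character", strata = "character", fovsPerWell = "numeric"
))

setValidity("PlateLayout", function(object) {
  msg <- character()
  if (is.null(names(object@wells)) || any(names(object@wells) == ""))
    msg <- c(msg, "wells must be a named vector (well id -> condition)")
  if (!setequal(names(object@wells), names(object@strata)))
    msg <- c(msg, "every well must have both a condition and a stratum")
  if (object@fovsPerWell < 1) msg <- c(msg, "fovsPerWell must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlateLayout", function(object) {
  cat(sprintf("PlateLayout: %d wells, %d conditions, %d strata, %d FOV/well\n",
              length(object@wells), length(unique(object@wells)),
              length(unique(object@strata)), object@fovsPerWell))
})

#' @rdname PlateLayout-class
#' @param x a PlateLayout
#' @export
wellConditions <- function(x) x@wells

#' @rdname PlateLayout-class
#' @export
wellStrata <- function(x) x@strata

#' Liquid-lens calibration curve
#'
#' Tabulates, on an RMS-voltage grid, the focal-plane displacement and
#' the pixel scale of a voltage-controlled liquid-lens objective. The
#' plane of focus does not move until the voltage exceeds 30 V; above
#' that it moves monotonically toward the objective as voltage increases,
#' and the magnification changes with it.
#'
#' @slot vRms voltage grid (V)
#' @slot zDisp focal-plane displacement at each voltage (um)
#' @slot scale pixel scale at each voltage (um/px)
#' @slot maxChannelError max fractional spread across channels merged
#'   into this curve (0 for a single-channel curve)
#' @export
setClass("CalibrationCurve", representation(
  vRms = "numeric", zDisp = "numeric", scale = "numeric",
  maxChannelError = "numeric"
))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  n <- length(object@vRms)
  if (length(object@zDisp) != n || length(object@scale) != n)
    msg <- c(msg, "vRms, zDisp, scale must have equal length")
  if (is.unsorted(object@vRms, strictly = TRUE))
    msg <- c(msg, "vRms grid must be strictly increasing")
  if (any(object@scale <= 0)) msg <- c(msg, "scale must be > 0 everywhere")
  flat <- object@vRms <= 30
  if (sum(flat) >= 2 && diff(range(object@zDisp[flat])) > 1e-9)
    msg <- c(msg, "zDisp must be constant for vRms <= 30")
  hi <- object@zDisp[object@vRms >= 30]
  if (length(hi) >= 2 && any(diff(hi) >= 0))
    msg <- c(msg, "zDisp must be strictly decreasing (toward objective) above 30 V")
  if (length(msg)) msg else TRUE
})

#' Construct a calibration curve
#'
#' @param vRms strictly increasing voltage grid (V)
#' @param zDisp focal-plane displacement per voltage (um); constant up to
#'   30 V, strictly decreasing (plane moves toward the objective) above
#' @param scale um-per-px factor per voltage
#' @param maxChannelError fractional spread across channels (default 0)
#' @return a \linkS4class{CalibrationCurve}
#' @export
calibrationCurve <- function(vRms, zDisp, scale, maxChannelError = 0) {
  new("CalibrationCurve", vRms = vRms, zDisp = zDisp, scale = scale,
      maxChannelError = maxChannelError)
}

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: %d nodes, %.3g-%.3g V, z span %.3g um, channel spread %.2g%%\n",
              length(object@vRms), min(object@vRms), max(object@vRms),
              diff(range(object@zDisp)), 100 * object@maxChannelError))
})

#' AFM approach curve
#'
#' Piezo displacement and cantilever deflection channels of one approach,
#' ordered toward the surface, with the cantilever spring constant and
#' the force trigger that terminated the approach.
#'
#' @slot zPiezo piezo displacement samples (um, ascending)
#' @slot deflection cantilever deflection (nm)
#' @slot k spring constant (N/m)
#' @slot location "on_nucleus" or "off_nucleus"
#' @slot trigger trigger force (nN)
#' @slot meta list of provenance / ground-truth fields
#' @export
setClass("ForceCurve", representation(
  zPiezo = "numeric", deflection = "numeric", k = "numeric",
  location = "character", trigger = "numeric", meta = "list"
))

setValidity("ForceCurve", function(object) {
  msg <- character()
  if (length(object@zPiezo) != length(object@deflection))
    msg <- c(msg, "zPiezo and deflection must have equal length")
  if (object@k <= 0) msg <- c(msg, "spring constant k must be > 0")
  if (!object@location %in% c("on_nucleus", "off_nucleus"))
    msg <- c(msg, "location must be on_nucleus or off_nucleus")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf("ForceCurve [%s]: %d samples, z %.3g-%.3g um, k = %.3g N/m, trigger %.3g nN\n",
              object@location, length(object@zPiezo), min(object@zPiezo),
              max(object@zPiezo), object@k, object@trigger))
})

#' Hertzian contact fit of one force curve
#'
#' @slot contactIndex sample index (1-based) of the detected contact point
#' @slot contactZ piezo position of the contact point (um)
#' @slot E Young's modulus (Pa)
#' @slot compliance 1000 / E (kPa^-1)
#' @slot rmsError combined pre+post RMS force residual (nN)
#' @slot R probe radius (um)
#' @slot nu Poisson ratio
#' @slot meta list (baseline coefficients, fit diagnostics)
#' @export
setClass("HertzFit", representation(
  contactIndex = "numeric", contactZ = "numeric", E = "numeric",
  compliance = "numeric", rmsError = "numeric", R = "numeric",
  nu = "numeric", meta = "list"
))

setValidity("HertzFit", function(object) {
  msg <- character()
  if (object@E <= 0) msg <- c(msg, "E must be > 0")
  if (abs(object@compliance - 1000 / object@E) > 1e-6 * object@compliance)
    msg <- c(msg, "compliance must equal 1000/E")
  if (object@rmsError < 0) msg <- c(msg, "rmsError must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HertzFit", function(object) {
  cat(sprintf("HertzFit: contact at sample %d (z = %.4g um), E = %.4g Pa (%.3g kPa^-1), RMS %.3g nN\n",
              object@contactIndex, object@contactZ, object@E,
              object@compliance, object@rmsError))
})

#' Motion-region compressed video archive
#'
#' Stores the per-pixel temporal mean as a background image plus, for
#' each motion region of interest (ROI), a losslessly compressed pixel
#' stream. Reconstruction returns the background outside the ROIs and
#' bit-identical source pixels inside them, so beads can be retracked
#' from the archive.
#'
#' @slot background integer matrix, temporal mean rounded to bit depth
#' @slot rois data.frame of half-open 0-based pixel boxes (x0, y0, x1, y1)
#' @slot roiStreams list of raw vectors: gzip-compressed byte-plane pixel
#'   streams, one per ROI
#' @slot meta list: spec fields, codec id, per-ROI md5 checksums of the
#'   uncompressed streams, noise-floor estimate, byte counts
#' @export
setClass("CompressedArchive", representation(
  background = "matrix", rois = "data.frame", roiStreams = "list",
  meta = "list"
))

setValidity("CompressedArchive", function(object) {
  msg <- character()
  if (nrow(object@rois) != length(object@roiStreams))
    msg <- c(msg, "one stream per ROI required")
  if (nrow(object@rois)) {
    if (any(object@rois$x0 < 0) || any(object@rois$y0 < 0) ||
        any(object@rois$x1 > ncol(object@background)) ||
        any(object@rois$y1 > nrow(object@background)))
      msg <- c(msg, "ROIs must lie within frame bounds")
    if (any(object@rois$x1 <= object@rois$x0) ||
        any(object@rois$y1 <= object@rois$y0))
      msg <- c(msg, "ROIs must be non-empty half-open boxes")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CompressedArchive", function(object) {
  cat(sprintf("CompressedArchive: %d ROI(s), %d x %d background, codec %s\n",
              nrow(object@rois), ncol(object@background),
              nrow(object@background), object@meta$codec))
  if (!is.null(object@meta$rawBytes))
    cat(sprintf("  raw %.4g MB -> archive %.4g MB (%.2f%% reduction)\n",
                object@meta$rawBytes / 2^20, object@meta$archiveBytes / 2^20,
                100 * (1 - object@meta$archiveBytes / object@meta$rawBytes)))
})
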