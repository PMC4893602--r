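# Readers/writers for the package's plain-text interchange formats:
# trajectory CSV, MSD CSV, force-curve CSV, calibration CSV, plate
# layout JSON, and multi-page TIFF videos.

#' Write / read a tidy trajectory table
#'
#' Columns: bead_id, frame, t_s, x_um, y_um and, when present, well,
#' fov, condition, stratum.
#'
#' @param trajectories trajectory data.frame
#' @param path CSV file path
#' @return (read) the trajectory data.frame
#' @export
writeTrajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectories
#' @export
readTrajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an AFM force curve as CSV
#'
#' Columns z_piezo_um and deflection_nm; spring constant, location and
#' trigger are carried in a JSON sidecar (same path with extension
#' \code{.json}).
#'
#' @param curve a \linkS4class{ForceCurve}
#' @param path CSV file path
#' @return (read) a \linkS4class{ForceCurve}
#' @export
writeForceCurve <- function(curve, path) {
  utils::write.csv(data.frame(z_piezo_um = curve@zPiezo,
                              deflection_nm = curve@deflection),
                   path, row.names = FALSE)
  jsonlite::write_json(list(k = curve@k, location = curve@location,
                            trigger = curve@trigger),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeForceCurve
#' @export
readForceCurve <- function(path) {
  d <- utils::read.csv(path)
  m <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("ForceCurve", zPiezo = d$z_piezo_um, deflection = d$deflection_nm,
      k = m$k, location = m$location, trigger = m$trigger, meta = list())
}

#' Write / read a calibration curve as CSV
#'
#' Columns: v_rms, z_um, scale_um_per_px.
#'
#' @param curve a \linkS4class{CalibrationCurve}
#' @param path CSV file path
#' @return (read) a \linkS4class{CalibrationCurve}
#' @export
writeCalibration <- function(curve, path) {
  utils::write.csv(data.frame(v_rms = curve@vRms, z_um = curve@zDisp,
                              scale_um_per_px = curve@scale),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  d <- utils::read.csv(path)
  calibrationCurve(d$v_rms, d$z_um, d$scale_um_per_px)
}

#' Write / read a plate layout as JSON
#'
#' @param layout a \linkS4class{PlateLayout}
#' @param path JSON file path
#' @return (read) a \linkS4class{PlateLayout}
#' @export
writePlateLayout <- function(layout, path) {
  jsonlite::write_json(list(wells = as.list(layout@wells),
                            strata = as.list(layout@strata),
                            fovs_per_well = layout@fovsPerWell),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePlateLayout
#' @export
readPlateLayout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PlateLayout", wells = unlist(j$wells), strata = unlist(j$strata),
      fovsPerWell = j$fovs_per_well)
}

#' Write / read a video as multi-page TIFF
#'
#' Pixel values are stored at the spec's bit depth; reading requires a
#' \linkS4class{FrameSpec} describing the acquisition (TIFF carries no
#' timing or scale metadata).
#'
#' @param video a \linkS4class{VideoStack}
#' @param path TIFF file path
#' @param spec the \linkS4class{FrameSpec} of the stored video
#' @param compression TIFF compression, default "deflate"
#' @return (read) a \linkS4class{VideoStack}
#' @export
writeVideoStack <- function(video, path, compression = "deflate") {
  maxval <- 2^video@spec@bitDepth - 1
  pages <- lapply(seq_len(dim(video@data)[3]),
                  function(f) video@data[, , f] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = video@spec@bitDepth,
                  compression = compression)
  invisible(path)
}

#' @rdname writeVideoStack
#' @export
readVideoStack <- function(path, spec) {
  pages <- tiff::readTIFF(path, all = TRUE)
  maxval <- 2^spec@bitDepth - 1
  arr <- array(0L, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages))
    arr[, , f] <- as.integer(round(pages[[f]] * maxval))
  sp <- spec
  sp@nFrames <- length(pages)
  sp@height <- nrow(pages[[1]]); sp@width <- ncol(pages[[1]])
  new("VideoStack", data = arr, spec = sp)
}
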