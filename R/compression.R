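# Audit-preserving video compression: find motion regions with enough
# surrounding margin to allow retracking, store the cropped ROI pixel
# streams losslessly, and keep only the temporal-average image for the
# static background.

# integer pixel vector -> raw stream, 16-bit little-endian split into a
# low-byte plane followed by a high-byte plane (8-bit: single plane).
# Plane separation lets the entropy coder see the nearly-constant high
# bytes as one long run.
.pixelsToRaw <- function(x, bitDepth) {
  if (bitDepth == 8) return(as.raw(x))
  c(as.raw(x %% 256L), as.raw(x %/% 256L))
}

.rawToPixels <- function(r, bitDepth) {
  if (bitDepth == 8) return(as.integer(r))
  n <- length(r) / 2L
  as.integer(r[seq_len(n)]) + 256L * as.integer(r[n + seq_len(n)])
}

.md5raw <- function(r) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(r, f)
  unname(tools::md5sum(f))
}

#' Detect motion regions in a video
#'
#' Thresholds the per-pixel temporal standard deviation at
#' \code{activitySigma} times the noise floor (the median of the sd map),
#' labels connected components, dilates each component's bounding box by
#' \code{marginPx} so that beads can be retracked with full centroid
#' windows, and merges overlapping boxes. A video whose motion covers the
#' whole frame degenerates to a single full-frame ROI (with a message).
#'
#' @param video a \linkS4class{VideoStack} with >= 2 frames
#' @param activitySigma threshold in units of the noise floor
#' @param marginPx margin added on every side of each motion component;
#'   default 24 px = 3 bead diameters for a 2 um bead at 0.25 um/px
#' @return data.frame of half-open 0-based boxes (x0, y0, x1, y1);
#'   zero rows for a static video
#' @export
detectMotionRegions <- function(video, activitySigma = 5, marginPx = 24) {
  arr <- video@data
  d <- dim(arr)
  if (d[3] < 2) stop("motion detection requires at least 2 frames")
  # streaming mean / sd to avoid a double copy of the stack
  s1 <- matrix(0, d[1], d[2]); s2 <- matrix(0, d[1], d[2])
  for (f in seq_len(d[3])) {
    fr <- arr[, , f]
    s1 <- s1 + fr; s2 <- s2 + fr * fr
  }
  mu <- s1 / d[3]
  sdMap <- sqrt(pmax(s2 / d[3] - mu * mu, 0) * d[3] / (d[3] - 1))
  floorSd <- stats::median(sdMap)
  mask <- sdMap > activitySigma * floorSd
  if (!any(mask))
    return(data.frame(x0 = integer(), y0 = integer(), x1 = integer(),
                      y1 = integer()))
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  boxes <- do.call(rbind, lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    # matrix indices are 1-based [y, x]; convert to 0-based half-open
    c(x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
      x1 = max(idx[, 2]), y1 = max(idx[, 1]))
  }))
  boxes[, "x0"] <- pmax(0L, boxes[, "x0"] - marginPx)
  boxes[, "y0"] <- pmax(0L, boxes[, "y0"] - marginPx)
  boxes[, "x1"] <- pmin(d[2], boxes[, "x1"] + marginPx)
  boxes[, "y1"] <- pmin(d[1], boxes[, "y1"] + marginPx)
  boxes <- .mergeBoxes(boxes)
  if (nrow(boxes) == 1 && boxes[1, "x0"] == 0 && boxes[1, "y0"] == 0 &&
      boxes[1, "x1"] == d[2] && boxes[1, "y1"] == d[1])
    message("motion covers the whole frame: single full-frame ROI")
  as.data.frame(boxes)
}

# merge overlapping boxes until a fixed point
.mergeBoxes <- function(boxes) {
  repeat {
    n <- nrow(boxes)
    if (n <= 1) return(boxes)
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (boxes[i, "x0"] < boxes[j, "x1"] && boxes[j, "x0"] < boxes[i, "x1"] &&
            boxes[i, "y0"] < boxes[j, "y1"] && boxes[j, "y0"] < boxes[i, "y1"]) {
          boxes[i, ] <- c(min(boxes[i, "x0"], boxes[j, "x0"]),
                          min(boxes[i, "y0"], boxes[j, "y0"]),
                          max(boxes[i, "x1"], boxes[j, "x1"]),
                          max(boxes[i, "y1"], boxes[j, "y1"]))
          boxes <- boxes[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(boxes)
  }
}

#' Compress a video into a motion-region archive
#'
#' Stores the per-pixel temporal mean (rounded to the source bit depth)
#' as the background and, for each motion ROI, the cropped pixel stream
#' compressed losslessly (gzip over a byte-plane-separated stream). An
#' md5 checksum of each uncompressed ROI stream is kept so
#' reconstruction can be verified bit-exactly. The noise floor estimated
#' during motion detection is recorded in the metadata so tracking can
#' be re-run on the reconstruction with the same absolute threshold.
#'
#' @param video a \linkS4class{VideoStack}
#' @param activitySigma,marginPx passed to \code{\link{detectMotionRegions}}
#' @param rois optional precomputed ROI data.frame
#' @return a \linkS4class{CompressedArchive}
#' @export
compressVideo <- function(video, activitySigma = 5, marginPx = 24,
                          rois = NULL) {
  arr <- video@data
  d <- dim(arr)
  spec <- video@spec
  if (is.null(rois)) rois <- detectMotionRegions(video, activitySigma, marginPx)
  s1 <- matrix(0, d[1], d[2])
  for (f in seq_len(d[3])) s1 <- s1 + arr[, , f]
  background <- matrix(as.integer(round(s1 / d[3])), d[1], d[2])
  streams <- vector("list", nrow(rois))
  checksums <- character(nrow(rois))
  for (k in seq_len(nrow(rois))) {
    crop <- arr[(rois$y0[k] + 1):rois$y1[k], (rois$x0[k] + 1):rois$x1[k], ,
                drop = FALSE]
    r <- .pixelsToRaw(as.integer(crop), spec@bitDepth)
    checksums[k] <- .md5raw(r)
    streams[[k]] <- memCompress(r, type = "gzip")
  }
  bytesPerSample <- spec@bitDepth / 8
  rawBytes <- prod(d) * bytesPerSample
  # in-memory estimate; writeArchive() reports actual on-disk sizes
  archiveBytes <- sum(vapply(streams, length, 0L)) +
    length(memCompress(.pixelsToRaw(as.integer(background), spec@bitDepth),
                       type = "gzip"))
  noiseSd <- estimateNoiseSd(arr[, , 1])
  meta <- list(codec = "gzip-planar", bitDepth = spec@bitDepth,
               width = d[2], height = d[1], nFrames = d[3], dt = spec@dt,
               scale = spec@scale, psfSigma = spec@psfSigma,
               backgroundLevel = spec@backgroundLevel,
               readNoiseSd = spec@readNoiseSd,
               checksums = checksums, noiseSd = noiseSd,
               rawBytes = rawBytes, archiveBytes = archiveBytes)
  new("CompressedArchive", background = background, rois = rois,
      roiStreams = streams, meta = meta)
}

#' Reconstruct a video from an archive
#'
#' Returns the background image in static regions and bit-identical
#' source pixels inside every ROI; each decoded ROI stream is verified
#' against its stored checksum.
#'
#' @param archive a \linkS4class{CompressedArchive}
#' @param verify check md5 checksums of the decoded streams
#' @return a \linkS4class{VideoStack}
#' @export
decompressVideo <- function(archive, verify = TRUE) {
  m <- archive@meta
  arr <- array(rep(as.integer(archive@background), m$nFrames),
               c(m$height, m$width, m$nFrames))
  for (k in seq_len(nrow(archive@rois))) {
    r <- memDecompress(archive@roiStreams[[k]], type = "gzip")
    if (verify && .md5raw(r) != m$checksums[k])
      stop("checksum mismatch in ROI ", k)
    px <- .rawToPixels(r, m$bitDepth)
    b <- archive@rois[k, ]
    arr[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1, ] <-
      array(px, c(b$y1 - b$y0, b$x1 - b$x0, m$nFrames))
  }
  spec <- frameSpec(width = m$width, height = m$height, dt = m$dt,
                    nFrames = m$nFrames, bitDepth = m$bitDepth,
                    scale = m$scale, backgroundLevel = m$backgroundLevel,
                    readNoiseSd = m$readNoiseSd, psfSigma = m$psfSigma)
  new("VideoStack", data = arr, spec = spec)
}

#' Write a compressed archive to a directory
#'
#' Layout: \code{background.tif} (deflate-compressed TIFF),
#' \code{roi_<k>.bin} (gzip ROI streams), \code{rois.json},
#' \code{meta.json}.
#'
#' @param archive a \linkS4class{CompressedArchive}
#' @param dir output directory (created if needed)
#' @return invisibly, the total archive size in bytes on disk
#' @export
writeArchive <- function(archive, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- archive@meta
  maxval <- 2^m$bitDepth - 1
  tiff::writeTIFF(archive@background / maxval, file.path(dir, "background.tif"),
                  bits.per.sample = m$bitDepth, compression = "deflate")
  for (k in seq_along(archive@roiStreams))
    writeBin(archive@roiStreams[[k]], file.path(dir, sprintf("roi_%d.bin", k)))
  jsonlite::write_json(archive@rois, file.path(dir, "rois.json"))
  jsonlite::write_json(m, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- list.files(dir, full.names = TRUE)
  invisible(sum(file.size(files)))
}

#' Read a compressed archive from a directory
#'
#' @param dir directory written by \code{\link{writeArchive}}
#' @return a \linkS4class{CompressedArchive}
#' @export
readArchive <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rois <- jsonlite::read_json(file.path(dir, "rois.json"),
                              simplifyVector = TRUE)
  rois <- as.data.frame(rois)
  maxval <- 2^m$bitDepth - 1
  bg <- tiff::readTIFF(file.path(dir, "background.tif"))
  bg <- matrix(as.integer(round(bg * maxval)), nrow(bg), ncol(bg))
  streams <- lapply(seq_len(nrow(rois)), function(k) {
    f <- file.path(dir, sprintf("roi_%d.bin", k))
    readBin(f, "raw", file.size(f))
  })
  new("CompressedArchive", background = bg, rois = rois, roiStreams = streams,
      meta = as.list(m))
}

#' Compression ratio of an archive
#'
#' @param archive a \linkS4class{CompressedArchive}, or a directory
#'   written by \code{\link{writeArchive}}
#' @return list with rawBytes, archiveBytes, and reductionPercent =
#'   100 * (1 - archiveBytes / rawBytes)
#' @export
compressionRatio <- function(archive) {
  if (is.character(archive)) {
    m <- jsonlite::read_json(file.path(archive, "meta.json"),
                             simplifyVector = TRUE)
    rawBytes <- m$rawBytes
    archiveBytes <- sum(file.size(list.files(archive, full.names = TRUE)))
  } else {
    rawBytes <- archive@meta$rawBytes
    archiveBytes <- archive@meta$archiveBytes
  }
  list(rawBytes = rawBytes, archiveBytes = archiveBytes,
       reductionPercent = 100 * (1 - archiveBytes / rawBytes))
}
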