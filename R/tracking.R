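# Spot detection and greedy nearest-neighbour trajectory linking,
# replacing an external video spot tracker. Coordinates are 0-based with
# integer values at pixel centers.

# Background noise scale of a sparse-spot frame: sd of the pixels below
# the 99.5th percentile. Robust to the few bright bead pixels, and
# unlike the MAD it is not biased low by integer quantization of the
# counts (the MAD of integer-rounded Gaussian noise collapses to 1.48).
estimateNoiseSd <- function(frame, trim = 0.995) {
  cut <- stats::quantile(frame, trim, names = FALSE)
  stats::sd(frame[frame <= cut])
}

#' Detect bead spots in one frame
#'
#' Candidate spots are strict local maxima (8-neighbourhood) above
#' background + minIntensitySigma * noise; each is refined to a sub-pixel
#' position by an intensity-weighted centroid of the background-subtracted
#' (negative-clipped) pixels in a square window of radius
#' 3 * psfSigmaPx. Background defaults to the frame median and the noise
#' scale to a trimmed-sd estimate; both can be supplied explicitly so
#' that the same absolute threshold can be applied across related videos.
#'
#' @param frame numeric matrix [y, x]
#' @param minIntensitySigma detection threshold in noise sigmas
#' @param psfSigmaPx expected spot sigma (px); sets the centroid window
#' @param background background level; default median(frame)
#' @param noiseSd noise scale; default the trimmed-sd estimate
#'   (sd of the pixels below the 99.5th percentile)
#' @return data.frame with columns x, y (0-based sub-pixel px) and
#'   intensity (background-subtracted integrated counts); empty for a
#'   blank frame
#' @export
detectSpots <- function(frame, minIntensitySigma = 5, psfSigmaPx = 2,
                        background = NULL, noiseSd = NULL) {
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(background)) background <- stats::median(frame)
  if (is.null(noiseSd)) noiseSd <- estimateNoiseSd(frame)
  thr <- background + minIntensitySigma * noiseSd
  if (h < 3 || w < 3) return(data.frame(x = numeric(), y = numeric(),
                                        intensity = numeric()))
  # plateau-tolerant maxima (quantized counts often tie at the peak);
  # duplicate candidates on a plateau are merged below
  ctr <- frame[2:(h - 1), 2:(w - 1)]
  isMax <- ctr > thr &
    ctr >= frame[1:(h - 2), 2:(w - 1)] & ctr >= frame[3:h, 2:(w - 1)] &
    ctr >= frame[2:(h - 1), 1:(w - 2)] & ctr >= frame[2:(h - 1), 3:w] &
    ctr >= frame[1:(h - 2), 1:(w - 2)] & ctr >= frame[1:(h - 2), 3:w] &
    ctr >= frame[3:h, 1:(w - 2)] & ctr >= frame[3:h, 3:w]
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(x = numeric(), y = numeric(),
                                    intensity = numeric()))
  # keep the brightest candidate within one psf sigma
  if (nrow(idx) > 1) {
    vals <- frame[idx]
    ord <- order(vals, decreasing = TRUE)
    idx <- idx[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(idx))
    for (s in 2:nrow(idx)) {
      d2 <- (idx[seq_len(s - 1), 1] - idx[s, 1])^2 +
            (idx[seq_len(s - 1), 2] - idx[s, 2])^2
      if (any(keep[seq_len(s - 1)] & d2 <= psfSigmaPx^2)) keep[s] <- FALSE
    }
    idx <- idx[keep, , drop = FALSE]
  }
  rad <- ceiling(3 * psfSigmaPx)
  res <- matrix(NA_real_, nrow(idx), 3)
  for (s in seq_len(nrow(idx))) {
    py <- idx[s, 1] + 1L; px <- idx[s, 2] + 1L      # 1-based matrix indices
    y0 <- max(1L, py - rad); y1 <- min(h, py + rad)
    x0 <- max(1L, px - rad); x1 <- min(w, px + rad)
    win <- frame[y0:y1, x0:x1] - background
    win[win < 0] <- 0
    tot <- sum(win)
    if (tot <= 0) next
    xs <- (x0:x1) - 1L; ys <- (y0:y1) - 1L          # 0-based coordinates
    res[s, ] <- c(sum(colSums(win) * xs) / tot,
                  sum(rowSums(win) * ys) / tot, tot)
  }
  res <- res[!is.na(res[, 3]), , drop = FALSE]
  data.frame(x = res[, 1], y = res[, 2], intensity = res[, 3])
}

#' Link per-frame spots into trajectories
#'
#' Greedy nearest-neighbour linking: in each frame, candidate
#' (track, spot) pairs are assigned in order of increasing distance,
#' subject to a per-frame displacement cap; equidistant candidates are
#' broken toward the lower spot index. There is no gap closing: a track
#' whose spot disappears terminates, and a reappearing spot starts a new
#' track. Tracks shorter than minLengthFrames are discarded.
#'
#' @param spotsByFrame list (one element per frame, in frame order) of
#'   data.frames as returned by \code{\link{detectSpots}}
#' @param maxDispPx maximum allowed per-frame displacement (px)
#' @param minLengthFrames minimum retained track length (frames)
#' @return data.frame with columns bead_id, frame (0-based), x, y,
#'   intensity
#' @export
linkTrajectories <- function(spotsByFrame, maxDispPx = 5, minLengthFrames = 2) {
  tracks <- list()        # finished + active track data
  activeIdx <- integer()  # indices into tracks of active tracks
  nextId <- 1L
  for (f in seq_along(spotsByFrame)) {
    spots <- spotsByFrame[[f]]
    ns <- if (is.null(spots)) 0L else nrow(spots)
    assignedTrack <- rep(FALSE, length(activeIdx))
    assignedSpot <- rep(FALSE, ns)
    if (length(activeIdx) && ns) {
      lastx <- vapply(tracks[activeIdx], function(t) t$x[length(t$x)], 0)
      lasty <- vapply(tracks[activeIdx], function(t) t$y[length(t$y)], 0)
      dmat <- outer(lastx, spots$x, "-")^2 + outer(lasty, spots$y, "-")^2
      dmat <- sqrt(dmat)
      repeat {
        dmin <- min(dmat[!assignedTrack, !assignedSpot, drop = FALSE])
        if (!is.finite(dmin) || dmin > maxDispPx) break
        # ties broken toward the lower spot (column) index, then lower track
        hit <- which(dmat == dmin, arr.ind = TRUE)
        hit <- hit[!assignedTrack[hit[, 1]] & !assignedSpot[hit[, 2]], ,
                   drop = FALSE]
        if (!nrow(hit)) break
        hit <- hit[order(hit[, 2], hit[, 1])[1], ]
        ti <- hit[1]; si <- hit[2]
        tr <- tracks[[activeIdx[ti]]]
        tr$frame <- c(tr$frame, f - 1L)
        tr$x <- c(tr$x, spots$x[si]); tr$y <- c(tr$y, spots$y[si])
        tr$intensity <- c(tr$intensity, spots$intensity[si])
        tracks[[activeIdx[ti]]] <- tr
        assignedTrack[ti] <- TRUE; assignedSpot[si] <- TRUE
        dmat[ti, ] <- Inf; dmat[, si] <- Inf
        if (all(assignedTrack) || all(assignedSpot)) break
      }
    }
    # unmatched active tracks terminate (no gap closing)
    activeIdx <- activeIdx[assignedTrack]
    if (ns && any(!assignedSpot)) {
      for (si in which(!assignedSpot)) {
        tracks[[length(tracks) + 1L]] <- list(
          id = nextId, frame = f - 1L, x = spots$x[si], y = spots$y[si],
          intensity = spots$intensity[si])
        nextId <- nextId + 1L
        activeIdx <- c(activeIdx, length(tracks))
      }
    }
  }
  keep <- Filter(function(t) length(t$frame) >= minLengthFrames, tracks)
  if (!length(keep))
    return(data.frame(bead_id = integer(), frame = integer(), x = numeric(),
                      y = numeric(), intensity = numeric()))
  do.call(rbind, lapply(keep, function(t)
    data.frame(bead_id = t$id, frame = t$frame, x = t$x, y = t$y,
               intensity = t$intensity)))
}

#' Track beads through a video
#'
#' Runs \code{\link{detectSpots}} on every frame and
#' \code{\link{linkTrajectories}} across frames, then converts pixel
#' positions to um with the spec's scale and frame indices to seconds.
#' The detection threshold (background, noise) is estimated once from
#' the first frame unless supplied, so the same absolute threshold is
#' used on every frame.
#'
#' @param video a \linkS4class{VideoStack}
#' @param minIntensitySigma,psfSigmaPx passed to \code{\link{detectSpots}}
#' @param maxDispPx per-frame displacement cap (px)
#' @param minLengthFrames minimum track length; default half the video
#' @param background,noiseSd optional explicit detection threshold inputs
#' @return tidy trajectory data.frame (bead_id, frame, t_s, x_um, y_um,
#'   intensity)
#' @export
trackVideo <- function(video, minIntensitySigma = 5,
                       psfSigmaPx = video@spec@psfSigma, maxDispPx = 5,
                       minLengthFrames = NULL, background = NULL,
                       noiseSd = NULL) {
  spec <- video@spec
  nf <- dim(video@data)[3]
  if (is.null(minLengthFrames)) minLengthFrames <- ceiling(nf / 2)
  if (is.null(background)) background <- stats::median(video@data[, , 1])
  if (is.null(noiseSd)) noiseSd <- estimateNoiseSd(video@data[, , 1])
  spots <- lapply(seq_len(nf), function(f)
    detectSpots(video@data[, , f], minIntensitySigma, psfSigmaPx,
                background = background, noiseSd = noiseSd))
  tr <- linkTrajectories(spots, maxDispPx, minLengthFrames)
  data.frame(bead_id = tr$bead_id, frame = tr$frame, t_s = tr$frame * spec@dt,
             x_um = tr$x * spec@scale, y_um = tr$y * spec@scale,
             intensity = tr$intensity)
}
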