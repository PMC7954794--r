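# Endocytic foci trajectory post-processing: spurious-track filtering,
# outward-excursion trimming, effective distance toward the cell centroid,
# completion statistics and path straightness.
#
# Tracks are long-form data frames with columns track_id, cell_id, frame,
# x, y (pixels; frames strictly increasing within a track). Cells are
# data frames with cell_id, centroid_x, centroid_y.

check_tracks <- function(tracks) {
  need <- c("track_id", "cell_id", "frame", "x", "y")
  missing <- setdiff(need, names(tracks))
  if (length(missing) > 0L) {
    stop("track table lacks column(s): ", paste(missing, collapse = ", "))
  }
  invisible(tracks)
}

centroid_of <- function(cells, cell_id) {
  i <- match(cell_id, cells$cell_id)
  if (is.na(i)) stop("no centroid for cell '", cell_id, "'")
  c(cells$centroid_x[i], cells$centroid_y[i])
}

split_tracks <- function(tracks) {
  lapply(split(tracks, tracks$track_id), function(tr) {
    tr[order(tr$frame), , drop = FALSE]
  })
}

#' Remove spurious short tracks
#'
#' Tracks detected in fewer than \code{min_frames} frames are considered
#' spurious detections and removed.
#'
#' @param tracks Track table.
#' @param min_frames Minimum track length in frames (default 10).
#' @return Filtered track table.
#' @export
filter_tracks <- function(tracks, min_frames = 10L) {
  check_tracks(tracks)
  if (nrow(tracks) == 0L) return(tracks)
  n <- table(tracks$track_id)
  keep <- names(n)[n >= min_frames]
  tracks[tracks$track_id %in% keep, , drop = FALSE]
}

#' Trim spurious outward tail of one track
#'
#' Locates the frame at which the particle is closest to the cell centroid;
#' frames after that point are removed from the first frame whose distance
#' to the centroid exceeds the minimum by more than \code{tolerance_px}
#' (segments spuriously indicating movement back toward the membrane).
#' Frames before the minimum are always retained.
#'
#' @param track One track (rows of a track table, single track_id).
#' @param centroid Numeric (x, y) of the host cell centroid.
#' @param tolerance_px Allowed re-excursion beyond the minimum distance
#'   before trimming starts (default 2 px).
#' @return The trimmed track.
#' @export
trim_track <- function(track, centroid, tolerance_px = 2.0) {
  check_tracks(track)
  track <- track[order(track$frame), , drop = FALSE]
  d <- sqrt((track$x - centroid[1L])^2 + (track$y - centroid[2L])^2)
  i_min <- which.min(d)
  if (i_min < nrow(track)) {
    after <- (i_min + 1L):nrow(track)
    bad <- after[d[after] > d[i_min] + tolerance_px]
    if (length(bad) > 0L) {
      track <- track[seq_len(bad[1L] - 1L), , drop = FALSE]
    }
  }
  track
}

#' Trim all tracks against their host-cell centroids
#'
#' @param tracks Track table.
#' @param cells Cell table with centroids.
#' @param tolerance_px See [trim_track()].
#' @return Trimmed track table.
#' @export
trim_tracks <- function(tracks, cells, tolerance_px = 2.0) {
  check_tracks(tracks)
  if (nrow(tracks) == 0L) return(tracks)
  parts <- lapply(split_tracks(tracks), function(tr) {
    trim_track(tr, centroid_of(cells, tr$cell_id[1L]), tolerance_px)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Effective distance traveled toward the cell centroid
#'
#' For each track, e(t) = d(start, centroid) - d(position(t), centroid):
#' the net inward progress since the track's first frame. Returns the
#' per-frame mean over tracks still present at each frame offset (frames
#' counted from each track's start) and each track's final value.
#'
#' @param tracks Track table (filtered/trimmed).
#' @param cells Cell table with centroids.
#' @return List with \code{per_frame} (\code{frame_offset}, \code{mean_e},
#'   \code{n_tracks}) and \code{per_track} (\code{track_id},
#'   \code{final_e}, \code{n_frames}).
#' @export
effective_distance_series <- function(tracks, cells) {
  check_tracks(tracks)
  series <- lapply(split_tracks(tracks), function(tr) {
    cen <- centroid_of(cells, tr$cell_id[1L])
    d <- sqrt((tr$x - cen[1L])^2 + (tr$y - cen[2L])^2)
    d[1L] - d
  })
  per_track <- data.frame(track_id = names(series),
                          final_e = vapply(series, function(e) e[length(e)],
                                           numeric(1L)),
                          n_frames = lengths(series),
                          stringsAsFactors = FALSE, row.names = NULL)
  max_len <- max(lengths(series))
  per_frame <- data.frame(
    frame_offset = seq_len(max_len) - 1L,
    mean_e = vapply(seq_len(max_len), function(i) {
      v <- unlist(lapply(series, function(e) if (length(e) >= i) e[i]))
      mean(v)
    }, numeric(1L)),
    n_tracks = vapply(seq_len(max_len), function(i) {
      sum(lengths(series) >= i)
    }, integer(1L)))
  list(per_frame = per_frame, per_track = per_track)
}

#' Completion statistics and 95\% disassembly time
#'
#' A track is complete when it terminates strictly before the end of the
#' acquisition; tracks still present at the final frame are incomplete
#' (their disassembly was not observed). The 95\% disassembly time t95 is
#' the earliest frame by which at least 95\% of all tracks have ended;
#' \code{NA} when never reached during the acquisition.
#'
#' @param tracks Track table.
#' @param acquisition_end Final acquired frame number.
#' @param quantile Disassembled fraction defining the landmark time
#'   (default 0.95).
#' @return List with \code{n_complete}, \code{n_incomplete},
#'   \code{end_frames} (per track) and \code{t95}.
#' @export
completion_stats <- function(tracks, acquisition_end, quantile = 0.95) {
  check_tracks(tracks)
  end_frames <- vapply(split_tracks(tracks), function(tr) {
    max(tr$frame)
  }, numeric(1L))
  complete <- end_frames < acquisition_end
  n <- length(end_frames)
  t95 <- NA_real_
  if (any(complete)) {
    cand <- sort(unique(end_frames[complete]))
    frac <- vapply(cand, function(f) sum(end_frames <= f) / n, numeric(1L))
    hit <- which(frac >= quantile)
    if (length(hit) > 0L) t95 <- cand[hit[1L]]
  }
  list(n_complete = sum(complete), n_incomplete = sum(!complete),
       end_frames = end_frames, t95 = t95)
}

#' Straightness (linearity) of a track
#'
#' Net displacement divided by total path length: 1 for a straight-line
#' path, 0 for a path returning to its start.
#'
#' @param track One track (single track_id), at least 2 frames.
#' @return Straightness in \[0, 1\]; \code{NA} for zero path length.
#' @export
straightness <- function(track) {
  check_tracks(track)
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 2L) stop("need at least 2 frames")
  dx <- diff(track$x)
  dy <- diff(track$y)
  path <- sum(sqrt(dx^2 + dy^2))
  if (path == 0) return(NA_real_)
  net <- sqrt((track$x[nrow(track)] - track$x[1L])^2 +
              (track$y[nrow(track)] - track$y[1L])^2)
  net / path
}
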