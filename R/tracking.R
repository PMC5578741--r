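#' Tracking and filtering configuration
#'
#' Thresholds and scales of the microfluidic tracking pipeline. Defaults
#' follow the assay: particles below 5 px area or above 0.95 eccentricity are
#' discarded; tracks with position-spread ratio `sd(Y)/sd(X) >= 18` are
#' non-motile; tracks travelling less than 10 px are dropped; imaging at 12
#' frames/s with 0.3 um per pixel. The nearest-neighbour linking radius
#' defaults to 15 px, about three times the per-frame flow displacement
#' (30 um/s / 12 fps / 0.3 um/px = 8.33 px).
#'
#' @param area_min Minimum particle area (px).
#' @param ecc_max Maximum particle eccentricity.
#' @param motility_ratio_max Motility threshold on `sd(Y)/sd(X)`.
#' @param min_path_px Minimum cumulative path length (px).
#' @param link_max_px Maximum linking distance between frames (px).
#' @param fps Frame rate (frames/s).
#' @param px_um Pixel size (um/px).
#' @return An object of class `track_config`.
#' @export
track_config <- function(area_min = 5, ecc_max = 0.95,
                         motility_ratio_max = 18, min_path_px = 10,
                         link_max_px = 15, fps = 12, px_um = 0.3) {
  vals <- c(area_min = area_min, ecc_max = ecc_max,
            motility_ratio_max = motility_ratio_max,
            min_path_px = min_path_px, link_max_px = link_max_px,
            fps = fps, px_um = px_um)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all tracking configuration values must be positive", call. = FALSE)
  }
  structure(as.list(vals), class = "track_config")
}

check_detections <- function(detections, need_shape = TRUE) {
  cols <- c("frame", "x", "y", if (need_shape) c("area", "eccentricity"))
  miss <- setdiff(cols, names(detections))
  if (length(miss)) {
    stop("detections are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(detections)
}

#' Filter particle detections by size and shape
#'
#' Keeps detections with `area >= area_min` and `eccentricity <= ecc_max`;
#' both thresholds are inclusive (the stated cuts, "less than five pixels"
#' and "greater than 0.95", are strict). Row order is preserved.
#'
#' @param detections Data frame with columns `frame`, `x`, `y`, `area`,
#'   `eccentricity`.
#' @param cfg A [track_config()] object.
#' @return The surviving rows of `detections`.
#' @export
filter_particles <- function(detections, cfg = track_config()) {
  check_detections(detections)
  keep <- detections$area >= cfg$area_min &
    detections$eccentricity <= cfg$ecc_max
  detections[keep, , drop = FALSE]
}

#' Link detections into trajectories by nearest neighbour
#'
#' Greedy frame-to-frame assignment: for each frame, all (open track,
#' detection) pairs within `link_max_px` are considered in ascending distance
#' order; each track claims at most one detection and vice versa. Unmatched
#' detections open new tracks; a track that finds no match is terminated.
#' Deterministic given the input order.
#'
#' @param detections Data frame with columns `frame`, `x`, `y`; frames are
#'   processed in ascending order.
#' @param cfg A [track_config()] object.
#' @return A data frame with columns `track_id`, `frame`, `x`, `y`, ordered
#'   by `track_id` then `frame`.
#' @export
link_nearest_neighbor <- function(detections, cfg = track_config()) {
  check_detections(detections, need_shape = FALSE)
  if (nrow(detections) == 0L) {
    return(data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric()))
  }
  frames <- sort(unique(detections$frame))
  n <- nrow(detections)
  track_of <- integer(n)                 # track id per detection row
  idx_by_frame <- split(seq_len(n), factor(detections$frame, levels = frames))

  next_id <- 1L
  open_idx <- integer(0)                 # detection rows of currently open tracks
  for (f in seq_along(frames)) {
    rows <- idx_by_frame[[f]]
    matched_det <- rep(FALSE, length(rows))
    matched_trk <- rep(FALSE, length(open_idx))
    if (length(open_idx) && length(rows)) {
      dx <- outer(detections$x[open_idx], detections$x[rows], "-")
      dy <- outer(detections$y[open_idx], detections$y[rows], "-")
      d <- sqrt(dx^2 + dy^2)
      cand <- which(d <= cfg$link_max_px)
      for (k in cand[order(d[cand])]) {
        ti <- (k - 1L) %% length(open_idx) + 1L
        di <- (k - 1L) %/% length(open_idx) + 1L
        if (matched_trk[ti] || matched_det[di]) next
        matched_trk[ti] <- TRUE
        matched_det[di] <- TRUE
        track_of[rows[di]] <- track_of[open_idx[ti]]
      }
    }
    for (di in which(!matched_det)) {    # new tracks for unmatched detections
      track_of[rows[di]] <- next_id
      next_id <- next_id + 1L
    }
    open_idx <- rows                     # unmatched old tracks terminate
  }
  out <- data.frame(track_id = track_of,
                    frame = detections$frame,
                    x = detections$x, y = detections$y)
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Classify a trajectory as motile
#'
#' A track is motile when its cross-channel spread is comparable to its
#' along-flow spread: `sd(Y)/sd(X) < motility_ratio_max` (population standard
#' deviations). Flow-advected non-motile cells barely move in X, so their
#' ratio is large; `sd(X) = 0` is treated as an infinite ratio (non-motile).
#'
#' @param traj Data frame with columns `x`, `y` (one track).
#' @param cfg A [track_config()] object.
#' @return `TRUE` if motile.
#' @export
classify_motile <- function(traj, cfg = track_config()) {
  if (nrow(traj) < 2L) {
    stop("cannot classify a trajectory with fewer than 2 points",
         call. = FALSE)
  }
  sx <- pop_sd(traj$x)
  sy <- pop_sd(traj$y)
  if (sx == 0) return(FALSE)
  (sy / sx) < cfg$motility_ratio_max
}

pop_sd <- function(v) {
  sqrt(mean((v - mean(v))^2))
}

#' Cumulative path length of a trajectory
#'
#' Sum of step displacements between consecutive points, in pixels.
#'
#' @param traj Data frame with columns `x`, `y`, ordered by frame.
#' @return Path length (px); 0 for a single point.
#' @export
path_length <- function(traj) {
  if (nrow(traj) < 2L) return(0)
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Viability filter on path length
#'
#' A trajectory is viable when its cumulative path length reaches
#' `min_path_px` (tracks travelling less than that are dropped from the
#' position statistics).
#'
#' @inheritParams path_length
#' @param cfg A [track_config()] object.
#' @return `TRUE` if viable.
#' @export
filter_path_length <- function(traj, cfg = track_config()) {
  path_length(traj) >= cfg$min_path_px
}

#' Run the full tracking pipeline on raw detections
#'
#' Applies the stages in assay order: particle size/shape filters, nearest
#' neighbour linking, motility classification, path-length viability. Stages
#' only remove or group records; coordinates are never altered. Tracks with a
#' single point cannot be classified and are flagged non-motile and
#' non-viable.
#'
#' @param detections Data frame with columns `frame`, `x`, `y`, `area`,
#'   `eccentricity`.
#' @param cfg A [track_config()] object.
#' @return A data frame `track_id`, `frame`, `x`, `y`, `motile`, `viable`;
#'   `viable` requires motility and sufficient path length.
#' @examples
#' sim <- sim_trajectories(n_motile = 5, n_nonmotile = 3, seed = 1)
#' tracks <- analyze_tracks(sim$detections)
#' table(unique(tracks[c("track_id", "motile")])$motile)
#' @export
analyze_tracks <- function(detections, cfg = track_config()) {
  kept <- filter_particles(detections, cfg)
  tracks <- link_nearest_neighbor(kept, cfg)
  if (nrow(tracks) == 0L) {
    tracks$motile <- logical(0)
    tracks$viable <- logical(0)
    return(tracks)
  }
  per_track <- split(seq_len(nrow(tracks)), tracks$track_id)
  motile <- vapply(per_track, function(ix) {
    tr <- tracks[ix, , drop = FALSE]
    if (nrow(tr) < 2L) return(FALSE)
    classify_motile(tr, cfg)
  }, logical(1))
  viable <- vapply(per_track, function(ix) {
    tr <- tracks[ix, , drop = FALSE]
    nrow(tr) >= 2L && filter_path_length(tr, cfg)
  }, logical(1))
  id_chr <- as.character(tracks$track_id)
  tracks$motile <- unname(motile[id_chr])
  tracks$viable <- tracks$motile & unname(viable[id_chr])
  tracks
}

#' Normalized cross-channel position histogram
#'
#' Bins the X positions of every point of every viable trajectory and
#' normalizes by the number of measurements, giving the relative frequency of
#' occurrence of cross-channel positions.
#'
#' @param x Numeric vector of pooled X positions (px).
#' @param bin_edges Ascending bin edges (px); values outside are dropped.
#' @return A data frame `bin_left`, `bin_right`, `freq` with `sum(freq) = 1`.
#' @export
position_histogram <- function(x, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE) || length(bin_edges) < 2L) {
    stop("`bin_edges` must be strictly ascending with at least 2 values",
         call. = FALSE)
  }
  x <- x[x >= bin_edges[1L] & x <= bin_edges[length(bin_edges)]]
  if (length(x) == 0L) stop("no positions fall inside the bins", call. = FALSE)
  counts <- tabulate(findInterval(x, bin_edges, rightmost.closed = TRUE),
                     nbins = length(bin_edges) - 1L)
  data.frame(bin_left = bin_edges[-length(bin_edges)],
             bin_right = bin_edges[-1L],
             freq = counts / sum(counts))
}

#' Thermal migration coefficient
#'
#' Drift statistic of the pooled cross-channel positions of viable tracks:
#' `TMC = -2 * [(mean(X) - Xmin) / (Xmax - Xmin) - 0.5]`,
#' where `Xmin`/`Xmax` are the left/right channel cutoffs in pixels. As
#' printed, the statistic is +1 when all cells pool at the left cutoff and -1
#' at the right cutoff. With the cold wall on the left, accumulation at the
#' warm wall then reports a negative value; set `warm_positive = TRUE` to
#' negate the statistic so warm-side accumulation reports +1.
#'
#' @param x Numeric vector of pooled X positions (px) of viable paths.
#' @param x_min,x_max Left and right cutoffs (px), `x_min < x_max`. Default
#'   to the observed range of `x`; supplying the channel cutoffs explicitly
#'   is recommended for cross-run comparability. Positions are clipped into
#'   the interval.
#' @param warm_positive Negate the printed formula (see above).
#' @return An object of class `tmc_result`: list with `tmc` (in `[-1, 1]`),
#'   `n_points`, `x_min`, `x_max`, `mean_x`, `warm_positive`.
#' @examples
#' compute_tmc(rep(0, 100), x_min = 0, x_max = 1667)$tmc   # +1
#' @export
compute_tmc <- function(x, x_min = min(x), x_max = max(x),
                        warm_positive = FALSE) {
  if (length(x) == 0L || all(!is.finite(x))) {
    stop("no viable positions supplied", call. = FALSE)
  }
  if (!(is.numeric(x_min) && is.numeric(x_max) && x_min < x_max)) {
    stop("`x_min` must be smaller than `x_max`", call. = FALSE)
  }
  x <- pmin(pmax(x[is.finite(x)], x_min), x_max)
  tmc <- -2 * ((mean(x) - x_min) / (x_max - x_min) - 0.5)
  if (warm_positive) tmc <- -tmc
  structure(list(tmc = tmc, n_points = length(x), x_min = x_min,
                 x_max = x_max, mean_x = mean(x),
                 warm_positive = warm_positive),
            class = "tmc_result")
}

#' @export
print.tmc_result <- function(x, ...) {
  cat(sprintf("TMC = %.4f (n = %d positions, cutoffs [%g, %g]%s)\n",
              x$tmc, x$n_points, x$x_min, x$x_max,
              if (x$warm_positive) ", warm-positive" else ""))
  invisible(x)
}

#' Linear wall-to-wall temperature gradient
#'
#' Maps cross-channel position to temperature assuming the near-linear
#' gradient established between the cold (left) and warm (right) circulation
#' channels.
#'
#' @param T_left,T_right Wall temperatures (degC).
#' @param x_left,x_right Wall positions (px or um), `x_left < x_right`.
#' @return An object of class `gradient_map`.
#' @seealso [position_to_temperature()]
#' @export
gradient_map <- function(T_left, T_right, x_left = 0, x_right = 1667) {
  if (!(is.numeric(x_left) && is.numeric(x_right) && x_left < x_right)) {
    stop("`x_left` must be smaller than `x_right`", call. = FALSE)
  }
  stopifnot(is.finite(T_left), is.finite(T_right))
  structure(list(T_left = T_left, T_right = T_right,
                 x_left = x_left, x_right = x_right),
            class = "gradient_map")
}

#' Temperature at a cross-channel position
#'
#' Linear interpolation between the wall temperatures of a [gradient_map()].
#'
#' @param x Position(s) within `[x_left, x_right]`.
#' @param g A [gradient_map()] object.
#' @return Temperature(s) in degC.
#' @examples
#' g <- gradient_map(23.5, 41.5, 0, 1667)
#' position_to_temperature(0, g)          # 23.5
#' @export
position_to_temperature <- function(x, g) {
  if (!inherits(g, "gradient_map")) {
    stop("`g` must be a `gradient_map` object", call. = FALSE)
  }
  if (any(x < g$x_left | x > g$x_right)) {
    stop("position outside the channel walls", call. = FALSE)
  }
  g$T_left + (x - g$x_left) / (g$x_right - g$x_left) * (g$T_right - g$T_left)
}
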