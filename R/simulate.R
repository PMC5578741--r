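#' Simulate cell trajectories and particle detections in the assay channel
#'
#' Emulates the statistical structure of the microfluidic assay: cells are
#' advected down-channel (Y) by the flow while motile cells additionally
#' explore the cross-channel direction (X). Motile X motion is run-and-tumble
#' (a persistent velocity of `run_px` px/frame that reverses with probability
#' `tumble_prob` per frame) plus a per-step drift bias `drift_px` and Gaussian
#' noise `sigma_px`; purely diffusive X steps either fragment under any
#' sensible linking radius or fail the motility classifier, and swimming
#' cells are ballistic on the frame timescale anyway. Non-motile cells only
#' jitter in X (SD 0.1 px). X reflects at the channel walls `[0, channel_px]`
#' so cells stay observable. Detection areas and eccentricities are drawn
#' inside the valid ranges, so all records pass the particle filters.
#'
#' Defaults follow the imaging geometry: flow displacement
#' 30 um/s / 12 fps / 0.3 um/px = 8.33 px/frame and a 500 um / 0.3 um/px =
#' 1667 px wide channel.
#'
#' @param n_motile,n_nonmotile Number of motile / non-motile cells.
#' @param drift_px Mean per-frame X displacement bias of motile cells
#'   (px/frame); positive pushes towards larger X.
#' @param sigma_px Per-frame Gaussian X noise SD of motile cells (px).
#' @param run_px Run speed of motile cells (px/frame).
#' @param tumble_prob Per-frame probability that a run reverses direction.
#' @param flow_px Per-frame Y advection (px/frame).
#' @param channel_px Channel width (px).
#' @param n_frames Number of frames.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `detections` (data frame `frame`, `x`, `y`, `area`,
#'   `eccentricity`), `truth` (data frame `cell_id`, `motile`, `x0`) and
#'   `config` (the arguments).
#' @examples
#' sim <- sim_trajectories(n_motile = 3, n_nonmotile = 2, seed = 7)
#' head(sim$detections)
#' @export
sim_trajectories <- function(n_motile = 40, n_nonmotile = 10, drift_px = 0,
                             sigma_px = 1, run_px = 4, tumble_prob = 0.1,
                             flow_px = 30 / 12 / 0.3,
                             channel_px = 500 / 0.3, n_frames = 60,
                             seed = 1L) {
  stopifnot(n_motile >= 0, n_nonmotile >= 0, channel_px > 0, n_frames >= 1,
            sigma_px >= 0, run_px >= 0, tumble_prob >= 0, tumble_prob <= 1)
  set.seed(seed)

  reflect <- function(x) {
    # fold positions back into [0, channel_px]
    x <- abs(x)
    over <- x > channel_px
    x[over] <- 2 * channel_px - x[over]
    pmin(pmax(x, 0), channel_px)
  }

  n_cells <- n_motile + n_nonmotile
  motile <- rep(c(TRUE, FALSE), c(n_motile, n_nonmotile))
  # cells enter the channel staggered along the flow axis; the jittered
  # 80 px spacing keeps distinct cells outside the linking radius (all are
  # advected at the same flow speed, so down-channel separation persists)
  x0 <- stats::runif(n_cells, 0.05 * channel_px, 0.95 * channel_px)
  y0 <- 80 * (sample(n_cells) - 1 + stats::runif(n_cells, 0, 0.4))

  det <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    if (motile[i]) {
      dir <- sample(c(-1, 1), 1L)
      steps <- numeric(n_frames - 1L)
      if (n_frames > 1L) {
        for (k in seq_len(n_frames - 1L)) {
          if (stats::runif(1) < tumble_prob) dir <- -dir
          steps[k] <- dir * run_px + drift_px +
            stats::rnorm(1, sd = sigma_px)
        }
      }
      x <- reflect(x0[i] + cumsum(c(0, steps)))
      y_noise <- cumsum(c(0, stats::rnorm(max(n_frames - 1L, 0),
                                          sd = sigma_px)))
    } else {
      x <- pmin(pmax(x0[i] + stats::rnorm(n_frames, sd = 0.1), 0), channel_px)
      y_noise <- 0
    }
    y <- y0[i] + flow_px * (seq_len(n_frames) - 1L) + y_noise
    det[[i]] <- data.frame(
      cell_id = i,
      frame = seq_len(n_frames) - 1L,
      x = x, y = y,
      area = stats::rpois(n_frames, 7) + 5,            # >= area_min
      eccentricity = stats::runif(n_frames, 0.3, 0.9)  # < ecc_max
    )
  }
  all <- do.call(rbind, det)
  all <- all[order(all$frame, all$cell_id), , drop = FALSE]
  truth <- data.frame(cell_id = seq_len(n_cells), motile = motile, x0 = x0)
  list(detections = all[, c("frame", "x", "y", "area", "eccentricity")],
       truth = truth,
       config = list(n_motile = n_motile, n_nonmotile = n_nonmotile,
                     drift_px = drift_px, sigma_px = sigma_px,
                     run_px = run_px, tumble_prob = tumble_prob,
                     flow_px = flow_px, channel_px = channel_px,
                     n_frames = n_frames, seed = seed))
}

#' Simulate spurious particle detections
#'
#' Generates detections that the particle filters must remove: `n_small`
#' records with area below 5 px and `n_elongated` with eccentricity above
#' 0.95, scattered over the given frame range.
#'
#' @param n_small,n_elongated Counts of undersized / over-elongated records.
#' @param seed Integer seed.
#' @param n_frames Frames over which to scatter the records.
#' @param channel_px Channel width (px).
#' @return A data frame `frame`, `x`, `y`, `area`, `eccentricity`.
#' @export
sim_spurious_particles <- function(n_small, n_elongated, seed = 1L,
                                   n_frames = 60, channel_px = 500 / 0.3) {
  stopifnot(n_small >= 0, n_elongated >= 0)
  set.seed(seed)
  n <- n_small + n_elongated
  if (n == 0L) {
    return(data.frame(frame = integer(), x = numeric(), y = numeric(),
                      area = numeric(), eccentricity = numeric()))
  }
  small <- rep(c(TRUE, FALSE), c(n_small, n_elongated))
  data.frame(
    frame = sample.int(n_frames, n, replace = TRUE) - 1L,
    x = stats::runif(n, 0, channel_px),
    y = stats::runif(n, 0, 500),
    area = ifelse(small, sample(1:4, n, replace = TRUE),
                  stats::rpois(n, 7) + 5),
    eccentricity = ifelse(small, stats::runif(n, 0.3, 0.9),
                          stats::runif(n, 0.951, 0.999))
  )
}

#' Simulate a logistic growth curve with lag
#'
#' OD600 time series `od(t) = baseline + K / (1 + exp(-r (t - t0)))` with
#' additive Gaussian noise, clipped positive. Defaults emulate plate-reader
#' growth in minimal medium: 15-minute reads over 24 h, carrying capacity
#' 0.5 OD, rate 0.8 per hour, midpoint 12 h, inoculum baseline 0.002 OD.
#'
#' @param K Carrying capacity (OD).
#' @param r Logistic rate (per hour).
#' @param t0 Midpoint, the half-maximum time for a negligible baseline
#'   (hours).
#' @param baseline Inoculum OD.
#' @param sigma Noise SD (OD).
#' @param t_end,dt Sampling horizon and interval (hours).
#' @param seed Integer seed.
#' @return A list with `t`, `od` and `config`.
#' @examples
#' g <- sim_growth_curve(seed = 3)
#' growth_delay_halfmax(g$t, g$od)   # ~ t0
#' @export
sim_growth_curve <- function(K = 0.5, r = 0.8, t0 = 12, baseline = 0.002,
                             sigma = 0.005, t_end = 24, dt = 0.25,
                             seed = 1L) {
  stopifnot(K > 0, r > 0, dt > 0, t_end > dt, sigma >= 0, baseline >= 0)
  set.seed(seed)
  t <- seq(0, t_end, by = dt)
  od <- baseline + K / (1 + exp(-r * (t - t0))) +
    stats::rnorm(length(t), sd = sigma)
  list(t = t, od = pmax(od, 1e-6),
       config = list(K = K, r = r, t0 = t0, baseline = baseline,
                     sigma = sigma, t_end = t_end, dt = dt, seed = seed))
}
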