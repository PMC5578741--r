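check_growth_curve <- function(t, od) {
  if (length(t) != length(od)) {
    stop("`t` and `od` must have equal length", call. = FALSE)
  }
  if (length(t) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("`t` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(od))) stop("`od` must be finite", call. = FALSE)
  invisible(NULL)
}

## OD floor applied before taking logs; blank subtraction is the caller's
## responsibility.
OD_FLOOR <- 1e-4

moving_average <- function(v, k) {
  if (k <= 1L) return(v)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("smoothing window must be odd", call. = FALSE)
  n <- length(v)
  half <- k %/% 2L
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Maximal specific growth rate
#'
#' Fits `ln(OD)` against time by least squares in every contiguous window of
#' `window` points and returns the largest slope together with the centre
#' time of that window. Ties resolve to the earliest window. OD values are
#' floored at 1e-4 before the log.
#'
#' @param t Time since inoculation (hours, strictly increasing).
#' @param od Blanked OD600 readings.
#' @param window Window length in points (default 5).
#' @return A list with `mu_max` (per hour) and `t_mu_max` (hours).
#' @examples
#' t <- seq(0, 10, by = 0.25)
#' max_growth_rate(t, 0.01 * exp(0.6 * t))$mu_max   # 0.6
#' @export
max_growth_rate <- function(t, od, window = 5L) {
  check_growth_curve(t, od)
  window <- as.integer(window)
  if (window < 2L) stop("`window` must be at least 2 points", call. = FALSE)
  if (length(t) < window) {
    stop("fewer time points than the window length", call. = FALSE)
  }
  if (any(od <= 0)) {
    stop("`od` must be positive (subtract the blank first)", call. = FALSE)
  }
  y <- log(pmax(od, OD_FLOOR))
  n_win <- length(t) - window + 1L
  slopes <- vapply(seq_len(n_win), function(i) {
    ix <- i:(i + window - 1L)
    tt <- t[ix]
    yy <- y[ix]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  # earliest window among numerical ties
  best <- which(slopes >= max(slopes) - 1e-9 * max(abs(slopes), 1))[1L]
  centre <- t[best + (window - 1L) %/% 2L]
  list(mu_max = max(slopes[best], 0), t_mu_max = centre,
       slope = slopes[best])
}

#' Growth delay as time to half-maximal OD
#'
#' Time from inoculation (`t = 0`) until the OD first reaches half its
#' maximum, located by log-linear interpolation between the bracketing
#' samples. A light moving-average smoothing (default 5 points) suppresses
#' plate-reader noise that would otherwise bias the first crossing early;
#' `smooth = 1` disables it.
#'
#' @inheritParams max_growth_rate
#' @param smooth Odd moving-average window in points (1 = none).
#' @return Delay in hours, or `NA_real_` (with a warning) when the curve
#'   never reaches half its maximum before the final point.
#' @examples
#' t <- seq(0, 24, by = 0.25)
#' od <- 0.5 / (1 + exp(-0.8 * (t - 12)))
#' growth_delay_halfmax(t, od)            # ~12 h
#' @export
growth_delay_halfmax <- function(t, od, smooth = 5L) {
  check_growth_curve(t, od)
  ods <- pmax(moving_average(od, smooth), OD_FLOOR)
  target <- max(ods) / 2
  above <- which(ods >= target)
  i <- above[[1L]]
  if (i == length(t)) {
    # only the final point reaches half-max: crossing time is ill-determined
    warning("OD reaches half-maximum only at the final point; delay undefined")
    return(NA_real_)
  }
  if (i == 1L) return(t[[1L]])
  y1 <- log(ods[[i - 1L]])
  y2 <- log(ods[[i]])
  if (y2 == y1) return(t[[i]])
  t[[i - 1L]] + (log(target) - y1) / (y2 - y1) * (t[[i]] - t[[i - 1L]])
}

#' Growth delay as time until maximal growth rate
#'
#' Alternative delay definition: the time at which the windowed specific
#' growth rate peaks (see [max_growth_rate()]).
#'
#' @inheritParams max_growth_rate
#' @return Time of maximal growth rate (hours).
#' @export
time_to_max_rate <- function(t, od, window = 5L) {
  max_growth_rate(t, od, window)$t_mu_max
}

#' All growth metrics of one OD600 time series
#'
#' Convenience wrapper returning the maximal specific growth rate, its time,
#' and both delay definitions (half-maximal OD and time to maximal rate).
#' The two delay definitions are both in use in the literature and can
#' differ; neither is privileged here.
#'
#' @inheritParams max_growth_rate
#' @param smooth Passed to [growth_delay_halfmax()].
#' @return A one-row data frame with `mu_max`, `t_mu_max`, `delay_halfmax`,
#'   `delay_maxrate`.
#' @export
growth_metrics <- function(t, od, window = 5L, smooth = 5L) {
  rate <- max_growth_rate(t, od, window)
  data.frame(mu_max = rate$mu_max,
             t_mu_max = rate$t_mu_max,
             delay_halfmax = growth_delay_halfmax(t, od, smooth),
             delay_maxrate = rate$t_mu_max)
}
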