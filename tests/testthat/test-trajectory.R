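make_det <- function(frame, x, y, area = 10, ecc = 0.5) {
  data.frame(frame = frame, x = x, y = y, area = area, eccentricity = ecc)
}

test_that("particle filters apply the strict size and shape thresholds", {
  d <- make_det(0:2, 1:3, 1:3, area = c(4, 10, 10), ecc = c(0.5, 0.99, 0.5))
  kept <- filter_particles(d)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x, 3)
  # boundary records survive: "less than five" and "greater than 0.95" are
  # strict cuts
  b <- make_det(0, 1, 1, area = 5, ecc = 0.95)
  expect_equal(nrow(filter_particles(b)), 1)
  empty <- make_det(integer(), numeric(), numeric(),
                    area = numeric(), ecc = numeric())
  expect_equal(nrow(filter_particles(empty)), 0)
})

test_that("nearest-neighbour linking concatenates drifting detections", {
  # one detection drifting 2 px/frame -> one 10-point track
  d <- make_det(0:9, 2 * (0:9), rep(0, 10))
  tr <- link_nearest_neighbor(d)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
  # two detections always >= 100 px apart -> two tracks, never merged
  d2 <- make_det(rep(0:9, each = 2), rep(c(0, 200), 10),
                 rep(2 * (0:9), each = 2))
  tr2 <- link_nearest_neighbor(d2)
  expect_equal(length(unique(tr2$track_id)), 2)
  expect_true(all(table(tr2$track_id) == 10))
})

test_that("converging pair resolves to the minimal-total-distance pairing", {
  # tracks at (0,0) and (10,0); next frame detections at (2,0) and (9,0)
  d <- rbind(make_det(0, c(0, 10), c(0, 0)), make_det(1, c(2, 9), c(0, 0)))
  tr <- link_nearest_neighbor(d)
  by_track <- split(tr$x, tr$track_id)
  got <- sort(unname(vapply(by_track, paste, character(1), collapse = "->")))
  # brute force over the two pairings: (0->2, 10->9) costs 2+1,
  # (0->9, 10->2) costs 9+8; the greedy ascending-distance pass picks the
  # cheaper one
  expect_equal(got, sort(c("0->2", "10->9")))
})

test_that("linking terminates tracks that jump beyond the radius", {
  d <- rbind(make_det(0, 0, 0), make_det(1, 100, 0))
  tr <- link_nearest_neighbor(d)
  expect_equal(length(unique(tr$track_id)), 2)
})

test_that("motility classification thresholds the position-spread ratio", {
  cfg <- track_config()
  # population sd(x) = 1, sd(y) = 5 -> motile
  expect_true(classify_motile(data.frame(x = c(0, 2), y = c(0, 10)), cfg))
  # ratio 25 -> non-motile
  expect_false(classify_motile(data.frame(x = c(0, 2), y = c(0, 50)), cfg))
  # boundary ratio exactly 18 -> non-motile (strict "below")
  expect_false(classify_motile(data.frame(x = c(0, 2), y = c(0, 36)), cfg))
  # flow-advected cell with constant x
  expect_false(classify_motile(data.frame(x = c(1, 1, 1), y = c(0, 5, 10)),
                               cfg))
  expect_error(classify_motile(data.frame(x = 1, y = 1), cfg), "2 points")
})

test_that("path-length viability uses cumulative travelled distance", {
  cfg <- track_config()
  expect_true(filter_path_length(data.frame(x = c(0, 12), y = c(0, 0)), cfg))
  expect_false(filter_path_length(data.frame(x = c(0, 9.9), y = c(0, 0)),
                                  cfg))
  expect_false(filter_path_length(data.frame(x = 5, y = 5), cfg))
  # back-and-forth motion counts: net displacement 0, path 12
  wiggle <- data.frame(x = c(0, 3, 0, 3, 0), y = 0)
  expect_true(filter_path_length(wiggle, cfg))
  expect_equal(path_length(wiggle), 12)
})

test_that("position histogram is a normalized relative frequency", {
  h <- position_histogram(rep(2.5, 50), bin_edges = 0:5)
  expect_equal(h$freq, c(0, 0, 1, 0, 0))
  set.seed(31)
  x <- runif(10000, 0, 10)
  h2 <- position_histogram(x, bin_edges = 0:10)
  expect_equal(sum(h2$freq), 1, tolerance = 1e-9)
  # binomial sampling bound on each bin
  p <- 0.1
  expect_lt(max(abs(h2$freq - p)), 4 * sqrt(p * (1 - p) / 10000))
  expect_error(position_histogram(numeric(), 0:2), "inside")
})

test_that("TMC matches its formula, with the stated extremes", {
  expect_equal(compute_tmc(rep(0, 10), 0, 1667)$tmc, 1)
  expect_equal(compute_tmc(rep(1667, 10), 0, 1667)$tmc, -1)
  expect_equal(compute_tmc(c(0, 1667), 0, 1667)$tmc, 0)
  set.seed(5)
  for (i in 1:20) {
    x <- runif(200, 10, 400)
    got <- compute_tmc(x, 10, 400)$tmc
    expect_equal(got, oracle_tmc(x, 10, 400), tolerance = 1e-12)
    expect_true(got >= -1 && got <= 1)
    # translation invariance
    expect_equal(compute_tmc(x + 37, 47, 437)$tmc, got, tolerance = 1e-12)
    # antisymmetry under reflection
    expect_equal(compute_tmc(410 - x, 10, 400)$tmc, -got, tolerance = 1e-12)
  }
  expect_equal(compute_tmc(rep(0, 5), 0, 100, warm_positive = TRUE)$tmc, -1)
  expect_error(compute_tmc(1:3, 5, 5), "smaller")
})

test_that("gradient mapping interpolates linearly between the walls", {
  g <- gradient_map(23.5, 41.5, 0, 1667)
  expect_equal(position_to_temperature(0, g), 23.5)
  expect_equal(position_to_temperature(1667, g), 41.5)
  expect_equal(position_to_temperature(1667 / 2, g), 32.5)
  # one third across an 18-degree gradient
  expect_equal(position_to_temperature(1667 / 3, g), 29.5)
  # the shallow gradient used for ligand-adapted cells
  g2 <- gradient_map(34.5, 38.1, 0, 1000)
  expect_equal(position_to_temperature(500, g2), 36.3)
  flat <- gradient_map(30, 30, 0, 100)
  expect_equal(position_to_temperature(c(0, 50, 100), flat), rep(30, 3))
  expect_error(position_to_temperature(-1, g), "outside")
  expect_error(gradient_map(20, 30, 5, 5), "smaller")
})

test_that("pipeline stages only remove or group records", {
  sim <- sim_trajectories(n_motile = 6, n_nonmotile = 2, seed = 2)
  tracks <- analyze_tracks(sim$detections)
  # every output coordinate appears verbatim in the input
  key_in <- paste(sim$detections$frame, sim$detections$x, sim$detections$y)
  key_out <- paste(tracks$frame, tracks$x, tracks$y)
  expect_true(all(key_out %in% key_in))
  expect_lte(nrow(tracks), nrow(sim$detections))
})
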