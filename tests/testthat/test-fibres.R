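test_that("length and speed conversions follow the stretch and pulse constants", {
  expect_equal(track_length_kbp(24.75), 49.5)
  expect_equal(track_length_kbp(0), 0)
  expect_equal(track_length_kbp(125), 250)   # shortest typical combed fibre
  expect_equal(fork_speed(49.5), 1.65)       # human mean
  expect_equal(fork_speed(73.8), 2.46)       # mouse mean
  expect_equal(fork_speed(0), 0)
  # stretch-factor linearity
  expect_equal(track_length_kbp(2 * 24.75), 2 * track_length_kbp(24.75))
  expect_error(track_length_kbp(-1), ">= 0")
  expect_error(fork_speed(10, pulse_minutes = 0), "positive")
})

test_that("deterministic kinematics: zero-sd speeds give closed-form segments", {
  fs <- generate_fibre_set(1, true_rfs = list(mean = 1.65, sd = 0),
                           true_iod = list(mean = 1000, sd = 0),
                           fibre_length = c(400, 400), seed = 3)
  p2 <- fs[fs$label == "pulse2" & !fs$censored, ]
  expect_true(all(abs((p2$end_um - p2$start_um) - 24.75) < 1e-9))
  p1 <- fs[fs$label == "pulse1" & !fs$censored, ]
  expect_true(all(abs((p1$end_um - p1$start_um) - 49.5) < 1e-9))
  expect_equal(estimate_rfs(fs), rep(1.65, nrow(p2)))
})

test_that("fibre tracks respect length bounds, ordering and determinism", {
  fs <- generate_fibre_set(40, seed = 11)
  # no track longer than 250 um at stretch 2 with fibres up to 500 kbp
  expect_lte(max(fs$end_um), 250)
  for (f in unique(fs$fibre_id)) {
    tr <- fs[fs$fibre_id == f, ]
    expect_true(all(diff(tr$start_um) > 0))
    expect_true(all(tr$end_um > tr$start_um))
    # segments tile the fibre without overlap
    expect_true(all(abs(tr$start_um[-1] - tr$end_um[-nrow(tr)]) < 1e-6))
  }
  expect_identical(fs, generate_fibre_set(40, seed = 11))
})

test_that("origin calling measures centre-to-centre IODs", {
  track <- data.frame(
    label = c("pulse2", "pulse1", "pulse2", "gap", "pulse2", "pulse1",
              "pulse2"),
    start_um = c(0, 10, 20, 30, 90, 100, 110),
    end_um = c(10, 20, 30, 90, 100, 110, 120),
    censored = FALSE)
  # origin centres at 15 and 105 um -> 94.35 um would be 188.7 kbp; scale:
  iod <- inter_origin_distances(track)
  expect_equal(iod, (105 - 15) * 2)
  # the human-mean geometry: centres 94.35 um apart -> 188.7 kbp
  track2 <- data.frame(
    label = c("pulse2", "pulse1", "pulse2", "gap", "pulse2", "pulse1",
              "pulse2"),
    start_um = c(0, 10, 20, 30, 94.35, 104.35, 114.35),
    end_um = c(10, 20, 30, 94.35, 104.35, 114.35, 124.35),
    censored = FALSE)
  expect_equal(inter_origin_distances(track2), 188.7)
  # single origin: empty result
  expect_length(inter_origin_distances(track[1:3, ]), 0)
  # unflanked origins are only called with flanked_only = FALSE
  track3 <- track
  track3$label[7] <- "gap"
  expect_length(inter_origin_distances(track3), 0)
  expect_length(inter_origin_distances(track3, flanked_only = FALSE), 1)
})

test_that("estimators recover generator truth within 2 s.e.m.", {
  for (ln in list(list(rfs = list(mean = 1.65, sd = 1.28),
                       iod = list(mean = 188.7, sd = 121.4)),
                  list(rfs = list(mean = 2.46, sd = 0.58),
                       iod = list(mean = 161.7, sd = 100.3)))) {
    fs <- generate_fibre_set(200, true_rfs = ln$rfs, true_iod = ln$iod,
                             seed = 17)
    sr <- summarize_values(estimate_rfs(fs))
    si <- summarize_values(estimate_iod(fs))
    expect_lt(abs(sr$mean - attr(fs, "true_rfs_mean")), 2 * sr$sem + 1e-9)
    expect_lt(abs(si$mean - attr(fs, "true_iod_mean")), 2 * si$sem)
  }
})

test_that("including censored tracks biases fork speed downward", {
  fs <- generate_fibre_set(300, true_rfs = list(mean = 2.46, sd = 0.58),
                           true_iod = list(mean = 161.7, sd = 100.3),
                           seed = 23)
  clean <- estimate_rfs(fs)
  with_cens <- estimate_rfs(fs, include_censored = TRUE)
  expect_gt(length(with_cens), length(clean))
  expect_lt(mean(with_cens), mean(clean))
})

test_that("summarize_values reproduces the published descriptive statistics", {
  # a vector with sd 121.4 and n = 50 (IOD table)
  v <- scale(rnorm(50)) * 121.4 + 188.7
  s <- summarize_values(as.numeric(v))
  expect_equal(s$sd, 121.4, tolerance = 1e-9)
  expect_equal(round(s$sem, 1), 17.2)
  expect_equal(round(s$ci95, 1), 33.7)  # 1.96 * 121.4 / sqrt(50)
  # sd 1.28, n = 122 (fork-speed table)
  v2 <- scale(rnorm(122)) * 1.28 + 1.65
  s2 <- summarize_values(as.numeric(v2))
  expect_equal(round(s2$sem, 2), 0.12)
  expect_equal(round(s2$ci95, 2), 0.23)
  # contract: sem * sqrt(n) = sd exactly
  expect_equal(s2$sem * sqrt(s2$n), s2$sd)
  expect_equal(unclass(summarize_values(rep(5, 10)))[c("sd", "sem", "ci95")],
               list(sd = 0, sem = 0, ci95 = 0))
  expect_error(summarize_values(3), "at least 2")
})

test_that("sliding average has the documented closed forms and convergence", {
  const <- sliding_average(rep(4, 10))
  expect_true(all(const$means == 4))
  expect_true(const$converged)
  alt <- sliding_average(rep(c(1, -1), 5))
  expect_equal(alt$means[1:5], c(1, 0, 1 / 3, 0, 1 / 5))
  win <- sliding_average(1:10, window = 3)
  expect_equal(win$means, as.numeric(2:9))
  expect_error(sliding_average(1:5, window = 9), "window larger")
  # i.i.d. draws at the published sample size converge with high probability
  set.seed(4)
  conv <- replicate(20, sliding_average(rnorm(122, 1.65, 1.28))$converged)
  expect_gte(mean(conv), 0.7)
})
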