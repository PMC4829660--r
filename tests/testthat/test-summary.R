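human <- example_parameters("human")
mouse <- example_parameters("mouse")

test_that("derived replicon quantities reproduce the published calculation", {
  s <- build_summary(human)
  expect_equal(s$total_replicons, 51404)
  expect_equal(round(s$replicon_lifetime_min), 57)
  expect_equal(s$reuse_cycles, 10)
  expect_lt(abs(s$forks_in_parallel - 10298) / 10298, 0.002)
  expect_equal(round(s$replicons_per_focus, 2), 0.92)
  m <- build_summary(mouse)
  expect_equal(m$total_replicons, 70501)
  expect_equal(round(m$replicon_lifetime_min), 33)
  expect_equal(m$reuse_cycles, 17)
  expect_lt(abs(m$forks_in_parallel - 8216) / 8216, 0.002)
  expect_equal(round(m$replicons_per_focus, 2), 0.77)
})

test_that("trivial identities of the calculation chain hold", {
  expect_equal(total_replicons(0.1887, 188.7), 1)
  expect_equal(replicon_lifetime(0, 2), 0)
  expect_equal(reuse_cycles(57.18, 57.18), 1)
  expect_equal(forks_in_parallel(1, 1000, 1)$forks, 1)
  expect_equal(replicons_per_rfi(5000, 5000), 1)
  s <- build_summary(human)
  expect_equal(s$replicons_in_parallel * 2, s$forks_in_parallel)
  # doubling GS doubles the parallel forks, leaves the lifetime unchanged
  h2 <- replication_parameters(2 * 9700, 1.65, 188.7, 570, 5583)
  s2 <- build_summary(h2)
  expect_equal(s2$forks_in_parallel, 2 * s$forks_in_parallel)
  expect_equal(s2$replicon_lifetime_min, s$replicon_lifetime_min)
  expect_error(total_replicons(9700, 0), "positive")
  expect_error(replicon_lifetime(100, 0), "positive")
})

test_that("cross-check: total replicons x lifetime / T_S matches parallel count", {
  for (p in list(human, mouse)) {
    s <- build_summary(p)
    expect_lt(abs(s$total_replicons * s$replicon_lifetime_min /
                    p$values[["t_s_min"]] - s$replicons_in_parallel) /
                s$replicons_in_parallel, 0.02)
  }
})

test_that("firing-schedule simulation is consistent with the parallel count", {
  s <- build_summary(human)
  sim <- simulate_firing_schedule(s$total_replicons, s$replicon_lifetime_min,
                                  human$values[["t_s_min"]],
                                  mode = "uniform_asynchronous", seed = 11)
  expect_lt(abs(sim$average - s$replicons_in_parallel) /
              s$replicons_in_parallel, 0.01)
})

test_that("propagate_mse has its closed forms and matches a Monte-Carlo oracle", {
  expect_equal(propagate_mse(0.92, c(0, 0, 0)), 0)
  expect_equal(propagate_mse(0.92, c(0.1, 0, 0)), 0.092)
  # Monte-Carlo brute force for a product/quotient of independent normals
  set.seed(31)
  n <- 1e5
  x <- list(m = c(9700, 1.65, 570, 5583), s = c(97, 0.12, 9, 162))
  draws <- mapply(function(m, s) rnorm(n, m, s), x$m, x$s)
  q <- draws[, 1] / draws[, 2] / draws[, 3] / draws[, 4] * 1000 / 2
  q0 <- 9700 * 1000 / 1.65 / 570 / 2 / 5583
  mse <- propagate_mse(q0, x$s / x$m)
  expect_lt(abs(sd(q) - mse) / mse, 0.02)
  expect_error(propagate_mse(Inf, 0.1), "finite")
  expect_error(propagate_mse(1, -0.1), ">= 0")
})

test_that("summary serializes to JSON and the printer runs", {
  s <- build_summary(human)
  p <- withr::local_tempfile(fileext = ".json")
  write_summary_json(s, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$total_replicons, 51404)
  expect_equal(round(back$replicons_per_focus, 2), 0.92)
  expect_output(print(s), "Replicons per RFi")
})
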