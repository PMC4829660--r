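test_that("homogeneous frames resolve from temporal context", {
  expect_equal(
    as.character(disambiguate_homogeneous(
      c("M", "homogeneous", "homogeneous", "Se"))[2:3]),
    c("G1", "G1"))
  expect_equal(
    as.character(disambiguate_homogeneous(c("Sl", "homogeneous", "M"))[2]),
    "G2")
  # forward rule when there is no preceding context
  expect_equal(
    as.character(disambiguate_homogeneous(c("homogeneous", "Se"))[1]), "G1")
  expect_equal(
    as.character(disambiguate_homogeneous(c("homogeneous", "M"))[1]), "G2")
  # no context at all: flagged unresolved
  out <- disambiguate_homogeneous(c("homogeneous", "homogeneous"))
  expect_equal(attr(out, "unresolved"), 1:2)
  expect_true(all(out == "homogeneous"))
  expect_error(disambiguate_homogeneous(character(0)), "empty")
})

test_that("stage durations are frame counts times the interval", {
  labs <- c(rep("M", 4), rep("Se", 38))
  d <- stage_durations(labs, 15, pool_s = TRUE)
  expect_equal(unname(d["S"]), 9.5)  # 38 frames at 15 min
  expect_equal(unname(d["M"]), 1.0)
  expect_error(stage_durations(c("M", "homogeneous")), "unresolved")
  expect_warning(stage_durations(c("M", "M", "homogeneous"),
                                 allow_unresolved = TRUE), "dropping")
})

test_that("complete-only durations drop boundary-truncated runs", {
  labs <- c("Se", "Se", "G2", "G2", "G2", "M", "G1", "G1")
  d <- stage_durations(labs, 15, complete_only = TRUE)
  expect_setequal(names(d), c("G2", "M"))
  expect_equal(unname(d["G2"]), 0.75)
})

test_that("population summary aggregates cells and reports doubling time", {
  cells <- list(c(G1 = 9, S = 9.5, G2 = 3.5, M = 1),
                c(G1 = 8.5, S = 9.5, G2 = 4, M = 1))
  ps <- population_summary(cells)
  expect_equal(ps$mean_h[ps$stage == "S"], 9.5)
  expect_equal(ps$sd[ps$stage == "S"], 0)
  expect_equal(attr(ps, "doubling_time_sum_h"), 23)
  expect_equal(attr(ps, "doubling_time_per_cell_h"), 23)
  single <- population_summary(list(c(G1 = 9, S = 9.5)))
  expect_true(all(is.na(single$sd)))
  expect_error(population_summary(list()), "no cells")
})

test_that("round trip: generated labels recover stage durations within one frame", {
  human <- list(G1 = 8.9, S = 9.5, G2 = 3.7, M = 0.9)
  tl <- generate_timelapse_labels(human, n_cells = 16, n_cycles = 2, seed = 9)
  ps <- analyze_timelapse(tl)
  for (st in ps$stage) {
    truth <- switch(st, G1 = 8.9, S = 9.5, G2 = 3.7, M = 0.9)
    expect_lte(abs(ps$mean_h[ps$stage == st] - truth), 0.25)
  }
  # sum of stage means tracks the nominal doubling time (printed per-cell
  # measurement is 22.6 h; the sum of the printed means is 23.0 h)
  expect_lt(abs(attr(ps, "doubling_time_sum_h") - 23.0), 0.5)
})

test_that("conservation: per-cell stage durations sum to the cycle length", {
  human <- list(G1 = 8.9, S = 9.5, G2 = 3.7, M = 0.9)
  tl <- generate_timelapse_labels(human, n_cells = 6, n_cycles = 2, seed = 3)
  fps <- attr(tl, "frames_per_stage")
  cycle_h <- sum(fps) * 15 / 60
  for (cell in unique(tl$cell_id)) {
    d <- tl[tl$cell_id == cell, ]
    resolved <- disambiguate_homogeneous(d$label[order(d$frame)])
    durs <- stage_durations(resolved, 15, complete_only = TRUE)
    if (length(durs) == 4)  # all stages fully observed
      expect_lte(abs(sum(durs) - cycle_h), 0.25)
  }
})
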