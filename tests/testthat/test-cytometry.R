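test_that("G1 peak fitting recovers the generated ratio and CV", {
  h <- generate_dna_histogram(36, 1.527, 0.015, s_fraction = 0.3,
                              g2_fraction = 0.15, n_cells = 20000, seed = 5)
  f <- fit_g1_peaks(h)
  expect_lt(abs(f$ratio - 1.527), 0.01)
  # reference CV below the 2% quality bound
  h2 <- generate_dna_histogram(36, 1.527, 0.019, n_cells = 20000, seed = 6)
  expect_lt(fit_g1_peaks(h2)$reference$cv, 0.02)
  expect_error(fit_g1_peaks(h, reference_window = NULL, sample_window = NULL),
               NA)
  bare <- data.frame(channel = h$channel, count = h$count)
  expect_error(fit_g1_peaks(bare), "annotated")
})

test_that("G1 peak position error stays at or below 0.2%", {
  errs <- vapply(1:15, function(s) {
    h <- generate_dna_histogram(36, 1.527, 0.015, n_cells = 20000, seed = s)
    abs(fit_g1_peaks(h)$sample$mean - 36 * 1.527) / (36 * 1.527)
  }, numeric(1))
  expect_lt(max(errs), 0.002)
})

test_that("peak-fit ratio is unbiased with 1/sqrt(n) dispersion scaling", {
  ratio_sd <- function(n_cells, seeds) {
    r <- vapply(seeds, function(s) {
      h <- generate_dna_histogram(36, 1.527, 0.015, n_cells = n_cells,
                                  seed = s)
      fit_g1_peaks(h)$ratio
    }, numeric(1))
    c(mean = mean(r), sd = sd(r))
  }
  small <- ratio_sd(1500, 1:12)
  big <- ratio_sd(24000, 1:12)
  expect_lt(abs(small[["mean"]] - 1.527), 0.005)
  expect_lt(abs(big[["mean"]] - 1.527), 0.002)
  # dispersion shrinks roughly as 1/sqrt(16) = 4x; allow a loose factor
  expect_lt(big[["sd"]], small[["sd"]] / 1.8)
})

test_that("DNA content conversion reproduces the published table rows", {
  # mouse line: relative 1.798 -> 11.676 pg (within 0.2%)
  expect_lt(abs(dna_content_pg(1.798) - 11.676) / 11.676, 0.002)
  # human line: relative 1.527 -> 9.899 pg (within 0.3%)
  expect_lt(abs(dna_content_pg(1.527) - 9.899) / 9.899, 0.003)
  # identity configuration
  expect_equal(dna_content_pg(2.5, list(human_diploid_pg = 1,
                                        genome_size_factor = 1,
                                        sex_factor = 1)), 2.5)
  expect_error(dna_content_pg(0), "positive")
})

test_that("pg to Mbp conversion uses the 978 Mbp/pg constant", {
  expect_equal(round(pg_to_mbp(11.676)), 11419)
  expect_equal(round(pg_to_mbp(10.007)), 9787)
  expect_equal(pg_to_mbp(0), 0)
  # unit chain is linear
  x <- c(0.5, 1, 2, 4)
  expect_equal(pg_to_mbp(dna_content_pg(x)), x * pg_to_mbp(dna_content_pg(1)))
  expect_error(pg_to_mbp(-1), ">= 0")
})

test_that("measure_genome_size composes the full chain", {
  h <- generate_dna_histogram(36, 1.527, 0.015, n_cells = 20000, seed = 8)
  g <- measure_genome_size(h)
  expect_lt(abs(g$genome_size_mbp - 9682) / 9682, 0.01)
  expect_lt(g$peak_position_uncertainty, 0.005)
})
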