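#' Generate a synthetic DNA flow-cytometry histogram
#'
#' Builds a channel/count histogram containing the G1/G0 peak of a
#' non-cycling reference population (splenocytes), the G1 peak of the sample
#' cell line at \code{reference_peak_channel * sample_relative_amount}, an
#' S-phase plateau between the sample G1 and G2 positions and a G2/M peak at
#' twice the sample G1 position. Peaks are Gaussian with coefficient of
#' variation \code{peak_cv}; cells are drawn individually, so counting noise
#' shrinks as 1/sqrt(n_cells).
#'
#' @param reference_peak_channel mean channel of the reference G1/G0 peak
#'   (e.g. 36, the centre of the 34--38 splenocyte window).
#' @param sample_relative_amount sample G1 DNA amount relative to the
#'   reference (e.g. 1.527).
#' @param peak_cv coefficient of variation of each Gaussian peak (< 0.1).
#' @param s_fraction,g2_fraction fractions of sample cells in S and G2/M;
#'   must lie in [0, 1] and sum to <= 1.
#' @param n_cells cells drawn per population (reference and sample each).
#' @param n_channels number of histogram channels (default 256).
#' @param seed RNG seed.
#' @return A data.frame of class \code{dna_histogram} with columns
#'   \code{channel}, \code{count} and attributes \code{reference_window},
#'   \code{sample_window} (channel ranges used by the peak fitter).
#' @export
generate_dna_histogram <- function(reference_peak_channel = 36,
                                   sample_relative_amount = 1.527,
                                   peak_cv = 0.015,
                                   s_fraction = 0.3, g2_fraction = 0.15,
                                   n_cells = 20000, n_channels = 256,
                                   seed = 1) {
  if (peak_cv <= 0 || peak_cv >= 0.1)
    stop("`peak_cv` must be in (0, 0.1)", call. = FALSE)
  if (s_fraction < 0 || g2_fraction < 0 || s_fraction + g2_fraction > 1)
    stop("S and G2 fractions must be in [0,1] and sum to <= 1", call. = FALSE)
  stop_if_not_positive(sample_relative_amount, "sample_relative_amount")
  if (reference_peak_channel < 1 || reference_peak_channel > n_channels)
    stop("reference channel outside histogram range", call. = FALSE)
  g1_sample <- reference_peak_channel * sample_relative_amount
  g2_sample <- 2 * g1_sample
  if (g2_sample * (1 + 4 * peak_cv) > n_channels)
    stop("sample G2 peak outside histogram range", call. = FALSE)
  # channel binning adds ~1/12 quantization variance; draw with a slightly
  # narrower sd so that `peak_cv` is the CV measured on the histogram
  eff_sd <- function(mu) {
    v <- (peak_cv * mu)^2 - 1 / 12
    if (v > 0) sqrt(v) else peak_cv * mu
  }
  with_rng(seed, {
    ref <- rnorm(n_cells, reference_peak_channel,
                 eff_sd(reference_peak_channel))
    n_g1 <- round(n_cells * (1 - s_fraction - g2_fraction))
    n_s <- round(n_cells * s_fraction)
    n_g2 <- n_cells - n_g1 - n_s
    smp <- c(
      rnorm(n_g1, g1_sample, eff_sd(g1_sample)),
      runif(n_s, g1_sample, g2_sample) +
        rnorm(n_s, 0, peak_cv * g1_sample),
      rnorm(n_g2, g2_sample, eff_sd(g2_sample)))
    all_ch <- pmin(pmax(round(c(ref, smp)), 1), n_channels)
    counts <- tabulate(all_ch, nbins = n_channels)
    out <- data.frame(channel = seq_len(n_channels), count = counts)
    attr(out, "reference_window") <-
      c(floor(reference_peak_channel * (1 - 6 * peak_cv)),
        ceiling(reference_peak_channel * (1 + 6 * peak_cv)))
    attr(out, "sample_window") <-
      c(floor(g1_sample * (1 - 4 * peak_cv)),
        ceiling(g1_sample * (1 + 4 * peak_cv)))
    class(out) <- c("dna_histogram", "data.frame")
    out
  })
}

#' Write / read a DNA histogram as CSV (columns channel, count)
#' @param hist a \code{dna_histogram} (or data.frame with channel, count).
#' @param path CSV path.
#' @export
write_histogram_csv <- function(hist, path) {
  write.csv(as.data.frame(hist)[, c("channel", "count")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @param reference_window,sample_window channel ranges \code{c(lo, hi)} to
#'   annotate on read (required downstream by \code{\link{fit_g1_peaks}}).
#' @export
read_histogram_csv <- function(path, reference_window = NULL,
                               sample_window = NULL) {
  out <- read.csv(path)
  attr(out, "reference_window") <- reference_window
  attr(out, "sample_window") <- sample_window
  class(out) <- c("dna_histogram", "data.frame")
  out
}
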