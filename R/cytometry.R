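#' Fit Gaussian G1 peaks to a DNA histogram
#'
#' Least-squares Gaussian fits (amplitude, mean, sd) within the annotated
#' reference (non-cycling splenocyte G1/G0) and sample (cell line G1)
#' windows; the relative DNA amount is the ratio of the fitted peak
#' positions. Peak-position standard errors come from the fit covariance.
#'
#' @param hist a \code{dna_histogram} (data.frame with \code{channel},
#'   \code{count} and window attributes) or plain data.frame plus explicit
#'   windows.
#' @param reference_window,sample_window channel ranges \code{c(lo, hi)};
#'   default: the histogram's attributes.
#' @return list of class \code{g1_fit}: \code{reference} and \code{sample}
#'   (each \code{mean}, \code{sd}, \code{cv}, \code{mean_se}),
#'   \code{ratio} (sample/reference), \code{ratio_se}.
#' @export
fit_g1_peaks <- function(hist, reference_window = NULL, sample_window = NULL) {
  reference_window <- reference_window %||% attr(hist, "reference_window")
  sample_window <- sample_window %||% attr(hist, "sample_window")
  if (is.null(reference_window) || is.null(sample_window))
    stop("reference and sample windows must be annotated", call. = FALSE)
  fit_one <- function(win) {
    d <- hist[hist$channel >= win[1] & hist$channel <= win[2], ]
    if (nrow(d) < 4 || max(d$count) == 0)
      stop("window contains no usable peak", call. = FALSE)
    w <- d$count / sum(d$count)
    mu0 <- sum(w * d$channel)
    s0 <- max(sqrt(sum(w * (d$channel - mu0)^2)), 0.5)
    fit <- tryCatch(
      nls(count ~ A * exp(-(channel - mu)^2 / (2 * s^2)), data = d,
          start = list(A = max(d$count), mu = mu0, s = s0),
          control = list(warnOnly = TRUE)),
      error = function(e) stop("Gaussian peak fit failed to converge: ",
                               conditionMessage(e), call. = FALSE))
    co <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit)))[["mu"]], error = function(e) NA_real_)
    list(mean = unname(co[["mu"]]), sd = abs(unname(co[["s"]])),
         cv = abs(unname(co[["s"]])) / unname(co[["mu"]]), mean_se = se)
  }
  ref <- fit_one(reference_window)
  smp <- fit_one(sample_window)
  ratio <- smp$mean / ref$mean
  ratio_se <- ratio * sqrt((smp$mean_se / smp$mean)^2 +
                             (ref$mean_se / ref$mean)^2)
  structure(list(reference = ref, sample = smp, ratio = ratio,
                 ratio_se = ratio_se),
            class = "g1_fit")
}

#' @export
print.g1_fit <- function(x, ...) {
  cat(sprintf(
    "<g1_fit> reference peak %.2f (CV %.2f%%), sample peak %.2f (CV %.2f%%), ratio %.4f\n",
    x$reference$mean, 100 * x$reference$cv, x$sample$mean,
    100 * x$sample$cv, x$ratio))
  invisible(x)
}

#' DNA content in picograms from a relative DNA amount
#'
#' Converts a G1-peak ratio (sample / diploid mouse reference) into
#' picograms of genomic DNA, anchored on the DNA amount of a diploid human
#' genome (7 pg) and corrected for the human/mouse genome-size difference
#' (factor 1.06) and the female/male difference of the reference animals
#' (factor 1.016):
#' \code{pg = relative_amount * human_diploid_pg / (genome_size_factor *
#' sex_factor)}. All constants are configurable.
#'
#' @param relative_amount sample/reference G1 peak ratio (> 0).
#' @param reference_context list with \code{human_diploid_pg} (default 7),
#'   \code{genome_size_factor} (default 1.06), \code{sex_factor}
#'   (default 1.016).
#' @return DNA amount in pg.
#' @export
dna_content_pg <- function(relative_amount,
                           reference_context = list(human_diploid_pg = 7,
                                                    genome_size_factor = 1.06,
                                                    sex_factor = 1.016)) {
  stop_if_not_positive(relative_amount, "relative_amount")
  ctx <- reference_context
  stop_if_not_positive(ctx$human_diploid_pg, "human_diploid_pg")
  stop_if_not_positive(ctx$genome_size_factor, "genome_size_factor")
  stop_if_not_positive(ctx$sex_factor, "sex_factor")
  relative_amount * ctx$human_diploid_pg /
    (ctx$genome_size_factor * ctx$sex_factor)
}

#' Convert picograms of DNA to megabase pairs
#'
#' Uses the standard mass-to-length constant 1 pg of DNA = 978 Mbp.
#'
#' @param pg DNA amount in pg (>= 0).
#' @param mbp_per_pg conversion constant (default 978).
#' @return Genome size in Mbp.
#' @export
pg_to_mbp <- function(pg, mbp_per_pg = 978) {
  if (any(pg < 0)) stop("`pg` must be >= 0", call. = FALSE)
  stop_if_not_positive(mbp_per_pg, "mbp_per_pg")
  pg * mbp_per_pg
}

#' Genome size from a DNA histogram
#'
#' Composition of the cytometry chain: fit the reference and sample G1
#' peaks, convert the peak ratio to pg of DNA and then to Mbp.
#'
#' @param hist a \code{dna_histogram} with annotated windows.
#' @param reference_context see \code{\link{dna_content_pg}}.
#' @param mbp_per_pg see \code{\link{pg_to_mbp}}.
#' @return list of class \code{genome_size_result}: \code{fit} (the
#'   \code{g1_fit}), \code{relative_amount}, \code{genomic_dna_pg},
#'   \code{genome_size_mbp}, \code{peak_position_uncertainty} (relative s.e.
#'   of the ratio).
#' @export
measure_genome_size <- function(hist,
                                reference_context = list(
                                  human_diploid_pg = 7,
                                  genome_size_factor = 1.06,
                                  sex_factor = 1.016),
                                mbp_per_pg = 978) {
  fit <- fit_g1_peaks(hist)
  pg <- dna_content_pg(fit$ratio, reference_context)
  structure(
    list(fit = fit, relative_amount = fit$ratio, genomic_dna_pg = pg,
         genome_size_mbp = pg_to_mbp(pg, mbp_per_pg),
         peak_position_uncertainty = fit$ratio_se / fit$ratio),
    class = "genome_size_result")
}

#' @export
print.genome_size_result <- function(x, ...) {
  cat(sprintf(
    "<genome_size> relative DNA amount %.3f -> %.3f pg -> %.3f x 10^3 Mbp\n",
    x$relative_amount, x$genomic_dna_pg, x$genome_size_mbp / 1000))
  invisible(x)
}
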