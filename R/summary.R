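#' Measured replication parameters of one cell line
#'
#' Container for the five experimentally measured quantities from which all
#' genome-duplication parameters derive: genome size (GS), replication fork
#' speed (RFS), inter-origin distance (IOD), S-phase duration and the number
#' of simultaneously active replication foci counted by super-resolution
#' microscopy, each with a standard error.
#'
#' @param gs_mbp genome size in Mbp (e.g. 9700 for a 9.7 Gbp genome).
#' @param rfs_kbp_min fork speed in kbp per minute.
#' @param iod_kbp inter-origin distance in kbp.
#' @param t_s_min S-phase duration in minutes.
#' @param n_rfi counted active RFi at any given time point.
#' @param sem named numeric vector of standard errors with any of the names
#'   \code{gs_mbp}, \code{rfs_kbp_min}, \code{iod_kbp}, \code{t_s_min},
#'   \code{n_rfi} (missing entries default to 0).
#' @param label free-text cell-line label.
#' @return list of class \code{replication_parameters}.
#' @export
replication_parameters <- function(gs_mbp, rfs_kbp_min, iod_kbp, t_s_min,
                                   n_rfi, sem = c(), label = "") {
  vals <- c(gs_mbp = gs_mbp, rfs_kbp_min = rfs_kbp_min, iod_kbp = iod_kbp,
            t_s_min = t_s_min, n_rfi = n_rfi)
  stop_if_not_positive(vals, "replication parameters")
  s <- stats::setNames(rep(0, 5), names(vals))
  if (length(sem)) {
    if (is.null(names(sem)) || !all(names(sem) %in% names(vals)))
      stop("`sem` must be named after the parameters", call. = FALSE)
    if (any(sem < 0)) stop("standard errors must be >= 0", call. = FALSE)
    s[names(sem)] <- sem
  }
  structure(list(values = vals, sem = s, label = label),
            class = "replication_parameters")
}

#' Reference parameter sets for the two study cell lines
#'
#' The measured values for the human HeLa Kyoto and mouse C2C12 cell lines
#' (GS 9.7 / 11.4 x 10^3 Mbp, RFS 1.65 / 2.46 kbp/min, IOD 188.7 / 161.7
#' kbp, S-phase 570 / 564 min, 5,583 / 5,314 active RFi) with their standard
#' errors, usable as worked-example inputs to \code{\link{build_summary}}.
#'
#' @param line \code{"human"} (HeLa Kyoto) or \code{"mouse"} (C2C12).
#' @return A \code{\link{replication_parameters}} object.
#' @export
example_parameters <- function(line = c("human", "mouse")) {
  line <- match.arg(line)
  if (line == "human")
    replication_parameters(
      gs_mbp = 9700, rfs_kbp_min = 1.65, iod_kbp = 188.7, t_s_min = 570,
      n_rfi = 5583,
      sem = c(gs_mbp = 2, rfs_kbp_min = 0.12, iod_kbp = 17.2, t_s_min = 9,
              n_rfi = 162),
      label = "HeLa Kyoto (human)")
  else
    replication_parameters(
      gs_mbp = 11400, rfs_kbp_min = 2.46, iod_kbp = 161.7, t_s_min = 564,
      n_rfi = 5314,
      sem = c(gs_mbp = 6, rfs_kbp_min = 0.11, iod_kbp = 16.3, t_s_min = 23,
              n_rfi = 227),
      label = "C2C12 (mouse)")
}

#' Total number of replicons activated during S-phase
#'
#' Genome size divided by the average inter-origin distance (the IOD
#' approximates the average replicon size), rounded to the nearest integer.
#'
#' @param gs_mbp genome size in Mbp.
#' @param iod_kbp inter-origin distance in kbp (> 0).
#' @return Integer replicon count.
#' @export
total_replicons <- function(gs_mbp, iod_kbp) {
  stop_if_not_positive(iod_kbp, "iod_kbp")
  stop_if_not_positive(gs_mbp, "gs_mbp")
  round(gs_mbp * 1000 / iod_kbp)
}

#' Average replicon lifetime
#'
#' Total synthesis time of an average bidirectional replicon: IOD divided by
#' two times the fork speed (two forks close the inter-origin gap).
#'
#' @param iod_kbp inter-origin distance in kbp (>= 0).
#' @param rfs_kbp_min fork speed in kbp/min (> 0).
#' @return Lifetime in minutes.
#' @export
replicon_lifetime <- function(iod_kbp, rfs_kbp_min) {
  stop_if_not_positive(rfs_kbp_min, "rfs_kbp_min")
  if (any(iod_kbp < 0)) stop("`iod_kbp` must be >= 0", call. = FALSE)
  iod_kbp / (2 * rfs_kbp_min)
}

#' Limiting-factor reuse cycles
#'
#' How many times each limiting-factor molecule can be recycled during
#' S-phase: S-phase duration over the average replicon lifetime, rounded to
#' the nearest integer.
#'
#' @param t_s_min S-phase duration in minutes.
#' @param lifetime_min replicon lifetime in minutes (> 0).
#' @return Integer number of cycles.
#' @export
reuse_cycles <- function(t_s_min, lifetime_min) {
  stop_if_not_positive(lifetime_min, "lifetime_min")
  stop_if_not_positive(t_s_min, "t_s_min")
  round(t_s_min / lifetime_min)
}

#' Replication forks operating in parallel
#'
#' The time a single fork would need to duplicate the genome (GS / RFS)
#' divided by the measured S-phase duration gives the number of forks that
#' must run in parallel; half as many bidirectional replicons are active.
#'
#' @param gs_mbp genome size in Mbp.
#' @param rfs_kbp_min fork speed in kbp/min.
#' @param t_s_min S-phase duration in minutes.
#' @return list: \code{forks} (parallel fork count, full precision),
#'   \code{replicons} (forks / 2), \code{single_fork_hours} (GS / RFS in
#'   hours).
#' @export
forks_in_parallel <- function(gs_mbp, rfs_kbp_min, t_s_min) {
  stop_if_not_positive(c(gs_mbp, rfs_kbp_min, t_s_min),
                       "forks_in_parallel inputs")
  single_fork_min <- gs_mbp * 1000 / rfs_kbp_min
  forks <- single_fork_min / t_s_min
  list(forks = forks, replicons = forks / 2,
       single_fork_hours = single_fork_min / 60)
}

#' Replicons per replication focus
#'
#' The headline quotient: calculated replicons active in parallel divided by
#' the counted number of active RFi.
#'
#' @param replicons_in_parallel calculated parallel replicon count.
#' @param n_rfi counted RFi (> 0).
#' @return The quotient (full precision; round to 2 decimals for reporting).
#' @export
replicons_per_rfi <- function(replicons_in_parallel, n_rfi) {
  stop_if_not_positive(n_rfi, "n_rfi")
  stop_if_not_positive(replicons_in_parallel, "replicons_in_parallel")
  replicons_in_parallel / n_rfi
}

#' First-order (Gaussian) error propagation for a product/quotient
#'
#' For a quantity built purely from products and quotients of independent
#' measurements, the simplified variance formula gives
#' \code{MSE = |q| * sqrt(sum((sigma_i / x_i)^2))}, with relative errors
#' summed in quadrature.
#'
#' @param quotient the derived central value.
#' @param relative_uncertainties vector of sigma_i / x_i for every input.
#' @return The propagated uncertainty (MSE).
#' @export
propagate_mse <- function(quotient, relative_uncertainties) {
  if (any(!is.finite(c(quotient, relative_uncertainties))))
    stop("inputs must be finite", call. = FALSE)
  if (any(relative_uncertainties < 0))
    stop("relative uncertainties must be >= 0", call. = FALSE)
  abs(quotient) * sqrt(sum(relative_uncertainties^2))
}

#' Derived genome-duplication parameters with error propagation
#'
#' Composes the full calculation chain: total replicons (GS / IOD), replicon
#' lifetime (IOD / 2 RFS), limiting-factor reuse cycles (T_S / lifetime),
#' single-fork genome duplication time (GS / RFS), forks and replicons
#' active in parallel (GS / RFS / T_S, halved) and replicons per RFi, with
#' the first-order error of the quotient propagated from the standard errors
#' of GS, RFS, T_S and the RFi count.
#'
#' @param params a \code{\link{replication_parameters}} object.
#' @return list of class \code{replicon_summary} with all derived
#'   quantities; \code{quotient_mse} is the propagated uncertainty of
#'   \code{replicons_per_focus}.
#' @export
build_summary <- function(params) {
  stopifnot(inherits(params, "replication_parameters"))
  v <- params$values
  s <- params$sem
  fp <- forks_in_parallel(v[["gs_mbp"]], v[["rfs_kbp_min"]], v[["t_s_min"]])
  lifetime <- replicon_lifetime(v[["iod_kbp"]], v[["rfs_kbp_min"]])
  quo <- replicons_per_rfi(fp$replicons, v[["n_rfi"]])
  rel <- c(s[["gs_mbp"]] / v[["gs_mbp"]],
           s[["rfs_kbp_min"]] / v[["rfs_kbp_min"]],
           s[["t_s_min"]] / v[["t_s_min"]],
           s[["n_rfi"]] / v[["n_rfi"]])
  structure(
    list(
      params = params,
      total_replicons = total_replicons(v[["gs_mbp"]], v[["iod_kbp"]]),
      replicon_lifetime_min = lifetime,
      reuse_cycles = reuse_cycles(v[["t_s_min"]], lifetime),
      single_fork_hours = fp$single_fork_hours,
      forks_in_parallel = fp$forks,
      replicons_in_parallel = fp$replicons,
      replicons_per_focus = quo,
      quotient_mse = propagate_mse(quo, rel)),
    class = "replicon_summary")
}

#' @export
print.replicon_summary <- function(x, ...) {
  v <- x$params$values
  s <- x$params$sem
  cat(sprintf("Genome duplication parameters%s\n",
              if (nzchar(x$params$label)) paste0(": ", x$params$label) else ""))
  cat("Experimental data (mean +/- s.e.m.)\n")
  cat(sprintf("  RFS, kbp/min                    %8.2f +/- %.2f\n",
              v[["rfs_kbp_min"]], s[["rfs_kbp_min"]]))
  cat(sprintf("  IOD, kbp                        %8.1f +/- %.1f\n",
              v[["iod_kbp"]], s[["iod_kbp"]]))
  cat(sprintf("  GS, 10^3 Mbp                    %8.2f +/- %.3f\n",
              v[["gs_mbp"]] / 1000, s[["gs_mbp"]] / 1000))
  cat(sprintf("  Active RFi at any time point    %8d +/- %d\n",
              round(v[["n_rfi"]]), round(s[["n_rfi"]])))
  cat(sprintf("  S-phase duration, min           %8d +/- %d\n",
              round(v[["t_s_min"]]), round(s[["t_s_min"]])))
  cat("Calculations\n")
  cat(sprintf("  Total replicons (GS/IOD)        %8d\n", x$total_replicons))
  cat(sprintf("  Replicon lifetime, min          %8.1f\n",
              x$replicon_lifetime_min))
  cat(sprintf("  Limiting-factor reuse cycles    %8d\n", x$reuse_cycles))
  cat(sprintf("  Single-fork duplication, h      %8.0f\n",
              x$single_fork_hours))
  cat(sprintf("  Forks active in parallel        %8.0f\n",
              x$forks_in_parallel))
  cat(sprintf("  Replicons active in parallel    %8.0f\n",
              x$replicons_in_parallel))
  cat(sprintf("  Replicons per RFi               %8.2f +/- %.2f (MSE)\n",
              x$replicons_per_focus, x$quotient_mse))
  invisible(x)
}

#' Serialize a replicon summary to JSON
#' @param x a \code{replicon_summary}.
#' @param path output path.
#' @export
write_summary_json <- function(x, path) {
  stopifnot(inherits(x, "replicon_summary"))
  jsonlite::write_json(
    list(label = x$params$label,
         experimental = as.list(x$params$values),
         sem = as.list(x$params$sem),
         total_replicons = x$total_replicons,
         replicon_lifetime_min = x$replicon_lifetime_min,
         reuse_cycles = x$reuse_cycles,
         single_fork_hours = x$single_fork_hours,
         forks_in_parallel = x$forks_in_parallel,
         replicons_in_parallel = x$replicons_in_parallel,
         replicons_per_focus = x$replicons_per_focus,
         quotient_mse = x$quotient_mse),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
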