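#' Convert a stretched-fibre length to kbp
#'
#' Combed fibres are uniformly stretched, so physical length converts to
#' genomic length by a constant stretching factor (2 kbp per um).
#'
#' @param length_um measured length in um (>= 0).
#' @param stretch stretching factor in kbp per um (default 2).
#' @return Length in kbp.
#' @export
track_length_kbp <- function(length_um, stretch = 2) {
  if (any(length_um < 0)) stop("lengths must be >= 0", call. = FALSE)
  stop_if_not_positive(stretch, "stretch")
  length_um * stretch
}

#' Fork speed from a labelled track length
#'
#' A second-pulse track of a fork active through the whole pulse has length
#' speed x pulse duration, so speed = track length / pulse duration.
#'
#' @param track_kbp track length in kbp.
#' @param pulse_minutes labelling pulse duration (default 30).
#' @return Speed in kbp per minute.
#' @export
fork_speed <- function(track_kbp, pulse_minutes = 30) {
  stop_if_not_positive(pulse_minutes, "pulse_minutes")
  if (any(track_kbp < 0)) stop("track lengths must be >= 0", call. = FALSE)
  track_kbp / pulse_minutes
}

#' Inter-origin distances on one fibre
#'
#' Origins are called as first-pulse segments flanked by second-pulse signal
#' (by default on both sides: the bidirectional fork signature); the origin
#' position is the midpoint of the first-pulse segment, and IODs are
#' centre-to-centre distances between consecutive called origins, converted
#' to kbp by the stretching factor.
#'
#' @param track data.frame of one fibre's ordered segments (columns
#'   \code{label}, \code{start_um}, \code{end_um}, optionally
#'   \code{censored}).
#' @param stretch stretching factor kbp/um (default 2).
#' @param flanked_only require second-pulse signal on both sides of the
#'   first-pulse segment (default TRUE); FALSE accepts origins flanked on
#'   one side only.
#' @return Numeric vector of IODs in kbp (empty if < 2 origins called).
#' @export
inter_origin_distances <- function(track, stretch = 2, flanked_only = TRUE) {
  stop_if_not_positive(stretch, "stretch")
  track <- track[order(track$start_um), , drop = FALSE]
  lab <- track$label
  n <- nrow(track)
  centres <- numeric(0)
  for (r in seq_len(n)) {
    if (lab[r] != "pulse1") next
    left <- r > 1 && lab[r - 1] == "pulse2"
    right <- r < n && lab[r + 1] == "pulse2"
    ok <- if (flanked_only) left && right else left || right
    if (isTRUE(track$censored[r])) ok <- FALSE
    if (ok) centres <- c(centres, (track$start_um[r] + track$end_um[r]) / 2)
  }
  if (length(centres) < 2) return(numeric(0))
  diff(sort(centres)) * stretch
}

#' Estimate fork speeds from a fibre set
#'
#' Selects second-pulse segments carrying the signature of a fork that ran
#' freely through the second pulse: adjacent to a first-pulse segment on
#' exactly one side, not fused with a converging fork (which would put
#' first-pulse signal on both sides) and not truncated by a fibre end.
#'
#' @param fibres a \code{fibre_set} data.frame.
#' @param pulse_minutes pulse duration (default: the set's attribute, else 30).
#' @param stretch stretching factor (default: the set's attribute, else 2).
#' @param include_censored also use segments truncated by fibre ends
#'   (default FALSE; including them biases speeds downward, which is the
#'   reason the protocol excludes them).
#' @return Numeric vector of per-fork speeds in kbp/min.
#' @export
estimate_rfs <- function(fibres, pulse_minutes = NULL, stretch = NULL,
                         include_censored = FALSE) {
  pulse_minutes <- pulse_minutes %||% attr(fibres, "pulse_minutes") %||% 30
  stretch <- stretch %||% attr(fibres, "stretch") %||% 2
  speeds <- numeric(0)
  for (f in unique(fibres$fibre_id)) {
    tr <- fibres[fibres$fibre_id == f, , drop = FALSE]
    tr <- tr[order(tr$start_um), , drop = FALSE]
    lab <- tr$label
    n <- nrow(tr)
    for (r in seq_len(n)) {
      if (lab[r] != "pulse2") next
      if (!include_censored && isTRUE(tr$censored[r])) next
      left_p1 <- r > 1 && lab[r - 1] == "pulse1"
      right_p1 <- r < n && lab[r + 1] == "pulse1"
      if (xor(left_p1, right_p1)) {
        len_kbp <- track_length_kbp(tr$end_um[r] - tr$start_um[r], stretch)
        speeds <- c(speeds, fork_speed(len_kbp, pulse_minutes))
      }
    }
  }
  speeds
}

#' Estimate inter-origin distances from a fibre set
#'
#' @param fibres a \code{fibre_set} data.frame.
#' @param stretch stretching factor (default: the set's attribute, else 2).
#' @param flanked_only see \code{\link{inter_origin_distances}}.
#' @return Numeric vector of IODs in kbp pooled over fibres.
#' @export
estimate_iod <- function(fibres, stretch = NULL, flanked_only = TRUE) {
  stretch <- stretch %||% attr(fibres, "stretch") %||% 2
  unlist(lapply(unique(fibres$fibre_id), function(f) {
    inter_origin_distances(fibres[fibres$fibre_id == f, , drop = FALSE],
                           stretch = stretch, flanked_only = flanked_only)
  }), use.names = FALSE)
}

#' Descriptive statistics of a measurement vector
#'
#' Sample mean, standard deviation (n - 1 denominator), standard error of
#' the mean (sd / sqrt(n)) and normal-approximation 95\% confidence-interval
#' half-width (1.96 x s.e.m.).
#'
#' @param values numeric vector, length >= 2.
#' @return list of class \code{summary_stats}: \code{mean}, \code{sd},
#'   \code{sem}, \code{ci95}, \code{n}.
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a standard deviation",
                  call. = FALSE)
  s <- sd(values)
  structure(
    list(mean = mean(values), sd = s, sem = s / sqrt(n),
         ci95 = 1.96 * s / sqrt(n), n = n),
    class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("mean %.4g  s.d. %.4g  s.e.m. %.4g  95%% CI %.4g  n=%d\n",
              x$mean, x$sd, x$sem, x$ci95, x$n))
  invisible(x)
}

#' Sliding-average sample-size diagnostic
#'
#' Running mean of the observations, either cumulatively (the mean after
#' each additional observation) or over a moving window. The series is
#' flagged as converged when every running mean in the final quarter of the
#' sequence stays within \code{tolerance} (as a fraction) of the final mean
#' --- the practical check that the sample size was large enough for a
#' stable estimate.
#'
#' @param values numeric vector, length >= 2.
#' @param window moving-window width, or \code{NULL} for cumulative mode.
#' @param tolerance relative tolerance for the convergence flag
#'   (default 0.05).
#' @return list with \code{means}, \code{converged}, \code{mode},
#'   \code{tolerance}.
#' @export
sliding_average <- function(values, window = NULL, tolerance = 0.05) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  if (is.null(window)) {
    means <- cumsum(values) / seq_len(n)
    mode <- "cumulative"
  } else {
    if (window > n) stop("window larger than the number of values",
                         call. = FALSE)
    means <- vapply(seq_len(n - window + 1),
                    function(i) mean(values[i:(i + window - 1)]), numeric(1))
    mode <- "window"
  }
  m <- length(means)
  final <- means[m]
  last_q <- means[ceiling(3 * m / 4):m]
  converged <- if (final == 0) all(abs(last_q) <= tolerance) else
    all(abs(last_q - final) <= tolerance * abs(final))
  list(means = means, converged = converged, mode = mode,
       tolerance = tolerance)
}
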