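s_labels <- c("Se", "Sm", "Sl", "S", "S_e", "S_m", "S_l")

#' Resolve homogeneous-PCNA frames into G1 or G2
#'
#' Frames with homogeneous nuclear PCNA cannot be assigned to G1 or G2 from
#' the image alone; the temporal context decides: a homogeneous run
#' following mitosis (or preceding S-phase entry) is G1, a run following
#' S-phase (or preceding mitosis) is G2. Runs with no informative neighbour
#' stay \code{"homogeneous"} and their indices are reported in the
#' \code{unresolved} attribute.
#'
#' @param labels character vector of per-frame labels (one cell), using
#'   \code{M}, \code{Se}/\code{Sm}/\code{Sl} (or \code{S}),
#'   \code{homogeneous}, and optionally already-resolved \code{G1}/\code{G2}.
#' @return The label vector with homogeneous runs resolved where possible;
#'   attribute \code{unresolved} holds the indices of frames left ambiguous.
#' @export
disambiguate_homogeneous <- function(labels) {
  if (!length(labels)) stop("empty label sequence", call. = FALSE)
  out <- labels
  n <- length(labels)
  is_h <- labels == "homogeneous"
  if (!any(is_h)) {
    attr(out, "unresolved") <- integer(0)
    return(out)
  }
  runs <- rle(is_h)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  unresolved <- integer(0)
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    prev <- if (i0 > 1) labels[i0 - 1L] else NA_character_
    nxt <- if (i1 < n) labels[i1 + 1L] else NA_character_
    resolved <-
      if (!is.na(prev) && prev == "M") "G1"
      else if (!is.na(prev) && prev %in% s_labels) "G2"
      else if (!is.na(prev) && prev %in% c("G1", "G2")) prev
      else if (!is.na(nxt) && nxt %in% s_labels) "G1"
      else if (!is.na(nxt) && nxt == "M") "G2"
      else if (!is.na(nxt) && nxt %in% c("G1", "G2")) nxt
      else NA_character_
    if (is.na(resolved)) unresolved <- c(unresolved, i0:i1)
    else out[i0:i1] <- resolved
  }
  attr(out, "unresolved") <- unresolved
  out
}

#' Stage durations of one cell from resolved frame labels
#'
#' Duration of each stage is its frame count multiplied by the frame
#' interval. With \code{complete_only = TRUE} only complete stage runs
#' (bounded by a different stage on both sides within the observation) are
#' counted, and multi-cycle sequences report the per-occurrence mean --- the
#' rule that lets cells tracked for less than a full cycle contribute only
#' the stages they were fully observed in.
#'
#' @param labels resolved per-frame labels of one cell.
#' @param frame_interval_min minutes between frames (default 15).
#' @param pool_s report Se/Sm/Sl pooled as one S stage (default TRUE).
#' @param complete_only restrict to fully observed stage runs
#'   (default FALSE).
#' @param allow_unresolved drop remaining \code{homogeneous} frames with a
#'   warning instead of erroring (default FALSE).
#' @return Named numeric vector of durations in hours.
#' @export
stage_durations <- function(labels, frame_interval_min = 15, pool_s = TRUE,
                            complete_only = FALSE,
                            allow_unresolved = FALSE) {
  stop_if_not_positive(frame_interval_min, "frame_interval_min")
  if (!length(labels)) stop("empty label sequence", call. = FALSE)
  labels <- as.character(labels)  # drop disambiguation attributes
  if (any(labels == "homogeneous")) {
    if (!allow_unresolved)
      stop("unresolved homogeneous frames present; run ",
           "disambiguate_homogeneous() first", call. = FALSE)
    warning("dropping unresolved homogeneous frames")
    labels <- labels[labels != "homogeneous"]
  }
  if (pool_s) labels[labels %in% s_labels] <- "S"
  hours_per_frame <- frame_interval_min / 60
  if (!complete_only) {
    tab <- table(labels)
    return(stats::setNames(as.numeric(tab) * hours_per_frame, names(tab)))
  }
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  complete <- starts > 1L & ends < length(labels)
  if (!any(complete)) return(stats::setNames(numeric(0), character(0)))
  stages <- unique(runs$values[complete])
  out <- vapply(stages, function(s) {
    mean(runs$lengths[complete & runs$values == s]) * hours_per_frame
  }, numeric(1))
  stats::setNames(out, stages)
}

#' Population summary of per-cell stage durations
#'
#' Per-stage mean, s.d., s.e.m. and n over cells, plus the doubling time
#' both as the sum of stage means and as the per-cell full-cycle mean
#' (cells contributing all stages).
#'
#' @param per_cell list of named duration vectors (one per cell), as
#'   returned by \code{\link{stage_durations}}.
#' @param stage_order row order of the output (stages absent from every
#'   cell are dropped).
#' @return data.frame of class \code{stage_duration_table} with columns
#'   \code{stage}, \code{mean_h}, \code{sd}, \code{sem}, \code{n};
#'   attributes \code{doubling_time_sum_h} and
#'   \code{doubling_time_per_cell_h}.
#' @export
population_summary <- function(per_cell,
                               stage_order = c("G1", "S", "Se", "Sm", "Sl",
                                               "G2", "M")) {
  if (!length(per_cell)) stop("no cells supplied", call. = FALSE)
  stages <- unique(unlist(lapply(per_cell, names)))
  stages <- c(intersect(stage_order, stages), setdiff(stages, stage_order))
  rows <- lapply(stages, function(s) {
    vals <- unlist(lapply(per_cell, function(x) unname(x[s])))
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    data.frame(stage = s, mean_h = mean(vals),
               sd = if (n > 1) sd(vals) else NA_real_,
               sem = if (n > 1) sd(vals) / sqrt(n) else NA_real_,
               n = n)
  })
  out <- do.call(rbind, rows)
  full <- vapply(per_cell, function(x) {
    if (all(stages %in% names(x))) sum(x[stages]) else NA_real_
  }, numeric(1))
  attr(out, "doubling_time_sum_h") <- sum(out$mean_h)
  attr(out, "doubling_time_per_cell_h") <-
    if (any(!is.na(full))) mean(full, na.rm = TRUE) else NA_real_
  class(out) <- c("stage_duration_table", "data.frame")
  out
}

#' Stage-duration analysis of a time-lapse label table
#'
#' Convenience wrapper: disambiguates each cell's homogeneous frames,
#' extracts complete-run stage durations and summarizes over the
#' population.
#'
#' @param labels a \code{timelapse_labels} data.frame (columns
#'   \code{cell_id}, \code{frame}, \code{label}).
#' @param frame_interval_min frame interval (default: the table's
#'   attribute, else 15).
#' @param pool_s pool S sub-stages (default TRUE).
#' @return A \code{\link{population_summary}} table.
#' @export
analyze_timelapse <- function(labels, frame_interval_min = NULL,
                              pool_s = TRUE) {
  frame_interval_min <- frame_interval_min %||%
    attr(labels, "frame_interval_min") %||% 15
  per_cell <- lapply(split(labels, labels$cell_id), function(d) {
    d <- d[order(d$frame), ]
    resolved <- disambiguate_homogeneous(d$label)
    stage_durations(resolved, frame_interval_min, pool_s = pool_s,
                    complete_only = TRUE, allow_unresolved = TRUE)
  })
  per_cell <- per_cell[vapply(per_cell, length, integer(1)) > 0]
  population_summary(per_cell)
}
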