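#' Generate per-frame cell-cycle stage label sequences
#'
#' Emulates visual frame-by-frame classification of PCNA patterns in a
#' time-lapse movie. Each cell cycles through the biological stage order
#' M -> G1 -> Se -> Sm -> Sl -> G2 -> M; the number of frames per stage is
#' the stage duration divided by the frame interval, rounded half-up.
#' Frames in G1 and G2, where the PCNA distribution is homogeneous and the
#' two stages cannot be told apart without temporal context, are emitted as
#' \code{"homogeneous"}.
#'
#' @param stage_durations named list/vector of stage durations in hours with
#'   names \code{G1, S_e, S_m, S_l, G2, M} (an \code{S} entry is split
#'   evenly over the three sub-stages).
#' @param frame_interval_min minutes between frames (default 15).
#' @param n_cells number of cells.
#' @param n_cycles full cycles emitted per cell (default 1; each sequence
#'   additionally starts at a random phase offset).
#' @param random_start randomize the starting phase of each cell.
#' @param seed RNG seed.
#' @return A data.frame of class \code{timelapse_labels} with columns
#'   \code{cell_id}, \code{frame}, \code{label}; attribute
#'   \code{frame_interval_min}.
#' @export
generate_timelapse_labels <- function(stage_durations = list(
                                        G1 = 8.9, S = 9.5, G2 = 3.7, M = 0.9),
                                      frame_interval_min = 15, n_cells = 1,
                                      n_cycles = 1, random_start = TRUE,
                                      seed = 1) {
  stop_if_not_positive(frame_interval_min, "frame_interval_min")
  sd_ <- as.list(stage_durations)
  s_total <- sd_$S
  if (!is.null(s_total)) {
    sd_$S_e <- sd_$S_m <- sd_$S_l <- s_total / 3
    sd_$S <- NULL
  }
  order_ <- c("M", "G1", "S_e", "S_m", "S_l", "G2")
  durations <- vapply(order_, function(s) sd_[[s]] %||% 0, numeric(1))
  if (any(durations < 0)) stop("durations must be >= 0", call. = FALSE)
  if (all(durations == 0)) stop("all stage durations are zero", call. = FALSE)
  frames_per_stage <- floor(durations * 60 / frame_interval_min + 0.5)
  if (!is.null(s_total)) {
    # when the sub-stages come from one pooled S duration, preserve the
    # rounded total S frame count (rounding thirds independently can
    # otherwise inflate S by up to 1.5 frames)
    s_frames <- floor(s_total * 60 / frame_interval_min + 0.5)
    base <- s_frames %/% 3L
    extra <- s_frames %% 3L
    frames_per_stage[c("S_e", "S_m", "S_l")] <-
      base + c(extra >= 1L, extra >= 2L, FALSE)
  }
  emit <- c(M = "M", G1 = "homogeneous", S_e = "Se", S_m = "Sm",
            S_l = "Sl", G2 = "homogeneous")
  one_cycle <- rep(emit[order_], frames_per_stage)
  cycle_len <- length(one_cycle)
  if (cycle_len == 0L) stop("all stage durations are zero", call. = FALSE)
  with_rng(seed, {
    rows <- lapply(seq_len(n_cells), function(cell) {
      off <- if (random_start) sample.int(cycle_len, 1L) - 1L else 0L
      # n_cycles complete cycles starting at an arbitrary phase; the stage
      # straddling the observation boundary appears as two partial runs
      lab <- rep(one_cycle, n_cycles + 1L)
      lab <- lab[(off + 1L):(off + cycle_len * n_cycles)]
      data.frame(cell_id = cell, frame = seq_along(lab), label = unname(lab))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "frame_interval_min") <- frame_interval_min
    attr(out, "frames_per_stage") <-
      stats::setNames(frames_per_stage, order_)
    class(out) <- c("timelapse_labels", "data.frame")
    out
  })
}

#' Write / read time-lapse label tables as CSV
#' @param labels a \code{timelapse_labels} data.frame.
#' @param path CSV path.
#' @export
write_timelapse_csv <- function(labels, path) {
  write.csv(as.data.frame(labels)[, c("cell_id", "frame", "label")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_timelapse_csv
#' @param frame_interval_min frame interval to attach on read.
#' @export
read_timelapse_csv <- function(path, frame_interval_min = 15) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  attr(out, "frame_interval_min") <- frame_interval_min
  class(out) <- c("timelapse_labels", "data.frame")
  out
}
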