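#' Generate synthetic combed-DNA fibre tracks with known ground truth
#'
#' Emulates a dual-pulse replication labelling experiment on uniformly
#' stretched DNA fibres: origins fire at the start of the first pulse, each
#' producing two diverging forks; positions replicated during the first
#' pulse carry the \code{pulse1} label (IdU analogue), positions replicated
#' during the second pulse carry \code{pulse2} (CldU analogue), and
#' converging forks of adjacent origins terminate where they meet. Fibre
#' ends truncate tracks and truncated segments are flagged as censored (the
#' combing equivalent of molecule breakage).
#'
#' Per-fork speeds and adjacent-origin spacings are drawn from truncated
#' normal distributions with the requested moments. Spacings that would fuse
#' the two first-pulse tracks before the end of the first pulse are redrawn,
#' because such origin pairs are not callable on a real fibre either; the
#' realized means over measurable objects are therefore the quantities an
#' estimator can recover, and they are returned as ground-truth attributes
#' (\code{true_rfs_mean}, \code{true_iod_mean}).
#'
#' @param n_fibres number of fibres.
#' @param true_rfs list \code{(mean, sd)} of per-fork speed, kbp/min.
#' @param true_iod list \code{(mean, sd)} of adjacent-origin spacing, kbp.
#' @param pulse_minutes duration of each of the two pulses (default 30).
#' @param stretch stretching factor, kbp per um (default 2).
#' @param fibre_length length range \code{c(min, max)} in kbp (default
#'   250--500).
#' @param seed RNG seed; identical arguments give identical output.
#' @return A data.frame of class \code{fibre_set} with columns
#'   \code{fibre_id}, \code{segment_index}, \code{label}
#'   (\code{pulse1}/\code{pulse2}/\code{gap}), \code{start_um},
#'   \code{end_um}, \code{censored}; attributes \code{forks} (per-fork
#'   ground truth with clean flags), \code{pairs} (per-origin-pair ground
#'   truth with measurable flags), \code{true_rfs_mean},
#'   \code{true_iod_mean}, \code{pulse_minutes}, \code{stretch}.
#' @export
generate_fibre_set <- function(n_fibres,
                               true_rfs = list(mean = 1.65, sd = 1.28),
                               true_iod = list(mean = 188.7, sd = 121.4),
                               pulse_minutes = 30, stretch = 2,
                               fibre_length = c(250, 500), seed = 1) {
  stop_if_not_positive(pulse_minutes, "pulse_minutes")
  stop_if_not_positive(stretch, "stretch")
  stop_if_not_positive(true_rfs$mean, "true_rfs$mean")
  stop_if_not_positive(true_iod$mean, "true_iod$mean")
  stopifnot(length(fibre_length) == 2, all(fibre_length > 0),
            fibre_length[2] >= fibre_length[1])
  t1 <- pulse_minutes
  t2 <- pulse_minutes
  v_floor <- 0.05
  built <- with_rng(seed, {
    fibres <- vector("list", n_fibres)
    for (f in seq_len(n_fibres)) {
      L <- runif(1, fibre_length[1], fibre_length[2])
      pos <- numeric(0); vL <- numeric(0); vR <- numeric(0)
      iod <- numeric(0)
      x <- runif(1, 0, true_iod$mean)
      v_left_next <- rnorm_trunc(1, true_rfs$mean, true_rfs$sd, v_floor)
      while (x < L) {
        pos <- c(pos, x)
        vL <- c(vL, v_left_next)
        v_right <- rnorm_trunc(1, true_rfs$mean, true_rfs$sd, v_floor)
        vR <- c(vR, v_right)
        v_left_next <- rnorm_trunc(1, true_rfs$mean, true_rfs$sd, v_floor)
        repeat {
          d <- rnorm_trunc(1, true_iod$mean, true_iod$sd, lower = 1)
          if (d > t1 * (v_right + v_left_next) + 1) break
        }
        iod <- c(iod, d)
        x <- x + d
      }
      fibres[[f]] <- list(L = L, pos = pos, vL = vL, vR = vR, iod = iod)
    }
    fibres
  })
  build_fibre_tables(built, t1, t2, stretch)
}

# Turn per-fibre origin geometry into segment tables plus ground truth.
build_fibre_tables <- function(fibres, t1, t2, stretch) {
  seg_list <- list()
  fork_list <- list()
  pair_list <- list()
  tol <- 1e-9
  for (f in seq_along(fibres)) {
    fb <- fibres[[f]]
    L <- fb$L
    n <- length(fb$pos)
    iv <- data.frame(start = numeric(0), end = numeric(0),
                     label = character(0))
    if (n > 0) {
      d <- if (n > 1) diff(fb$pos) else numeric(0)
      t_meet <- if (n > 1) d / (fb$vR[-n] + fb$vL[-1]) else numeric(0)
      tL <- c(Inf, t_meet)   # meeting time on the left of origin i
      tR <- c(t_meet, Inf)   # ... on the right
      for (i in seq_len(n)) {
        c_i <- fb$pos[i]
        p1 <- c(c_i - fb$vL[i] * min(t1, tL[i]),
                c_i + fb$vR[i] * min(t1, tR[i]))
        iv <- rbind(iv, data.frame(start = p1[1], end = p1[2],
                                   label = "pulse1"))
        if (tL[i] > t1)
          iv <- rbind(iv, data.frame(
            start = c_i - fb$vL[i] * min(t1 + t2, tL[i]),
            end = c_i - fb$vL[i] * t1, label = "pulse2"))
        if (tR[i] > t1)
          iv <- rbind(iv, data.frame(
            start = c_i + fb$vR[i] * t1,
            end = c_i + fb$vR[i] * min(t1 + t2, tR[i]), label = "pulse2"))
      }
      # per-fork ground truth: a fork is clean when its second-pulse segment
      # neither terminated nor ran off the fibre
      fork_list[[f]] <- data.frame(
        fibre_id = f,
        origin = rep(seq_len(n), each = 2),
        side = rep(c("L", "R"), n),
        speed = as.vector(rbind(fb$vL, fb$vR)),
        clean = as.vector(rbind(
          tL > t1 + t2 & fb$pos - fb$vL * (t1 + t2) > 0,
          tR > t1 + t2 & fb$pos + fb$vR * (t1 + t2) < L)))
      callable <- fb$pos - fb$vL * t1 > 0 & fb$pos + fb$vR * t1 < L &
        tL > t1 & tR > t1
      if (n > 1)
        pair_list[[f]] <- data.frame(
          fibre_id = f, left_origin = seq_len(n - 1),
          iod_kbp = d,
          measurable = callable[-n] & callable[-1])
    }
    # clip to the fibre, merge touching same-label intervals, insert gaps
    if (nrow(iv) > 0) {
      iv$start <- pmax(iv$start, 0)
      iv$end <- pmin(iv$end, L)
      iv <- iv[iv$end - iv$start > tol, , drop = FALSE]
      iv <- iv[order(iv$start), , drop = FALSE]
      merged <- list()
      for (r in seq_len(nrow(iv))) {
        m <- length(merged)
        if (m > 0 && merged[[m]]$label == iv$label[r] &&
            iv$start[r] <= merged[[m]]$end + tol) {
          merged[[m]]$end <- max(merged[[m]]$end, iv$end[r])
        } else {
          merged[[m + 1]] <- as.list(iv[r, ])
        }
      }
      iv <- do.call(rbind, lapply(merged, as.data.frame))
    }
    segs <- data.frame(start = numeric(0), end = numeric(0),
                       label = character(0))
    cursor <- 0
    if (nrow(iv) > 0) {
      for (r in seq_len(nrow(iv))) {
        if (iv$start[r] > cursor + tol)
          segs <- rbind(segs, data.frame(start = cursor, end = iv$start[r],
                                         label = "gap"))
        segs <- rbind(segs, iv[r, ])
        cursor <- iv$end[r]
      }
    }
    if (cursor < L - tol)
      segs <- rbind(segs, data.frame(start = cursor, end = L, label = "gap"))
    seg_list[[f]] <- data.frame(
      fibre_id = f,
      segment_index = seq_len(nrow(segs)),
      label = segs$label,
      start_um = segs$start / stretch,
      end_um = segs$end / stretch,
      censored = segs$start <= tol | segs$end >= L - tol)
  }
  out <- do.call(rbind, seg_list)
  rownames(out) <- NULL
  forks <- if (length(fork_list)) do.call(rbind, fork_list) else
    data.frame(fibre_id = integer(0), origin = integer(0),
               side = character(0), speed = numeric(0), clean = logical(0))
  pairs <- if (length(pair_list)) do.call(rbind, pair_list) else
    data.frame(fibre_id = integer(0), left_origin = integer(0),
               iod_kbp = numeric(0), measurable = logical(0))
  attr(out, "forks") <- forks
  attr(out, "pairs") <- pairs
  attr(out, "true_rfs_mean") <-
    if (any(forks$clean)) mean(forks$speed[forks$clean]) else NA_real_
  attr(out, "true_iod_mean") <-
    if (any(pairs$measurable)) mean(pairs$iod_kbp[pairs$measurable]) else NA_real_
  attr(out, "pulse_minutes") <- t1
  attr(out, "stretch") <- stretch
  class(out) <- c("fibre_set", "data.frame")
  out
}

#' Write / read fibre track tables as CSV
#'
#' The on-disk schema is \code{fibre_id, segment_index, label, start_um,
#' end_um, censored}; ground-truth attributes are not serialized.
#'
#' @param fibres a \code{fibre_set} (or compatible data.frame).
#' @param path CSV path.
#' @return \code{path} invisibly, or the data.frame read back.
#' @export
write_fibre_csv <- function(fibres, path) {
  write.csv(as.data.frame(fibres)[, c("fibre_id", "segment_index", "label",
                                      "start_um", "end_um", "censored")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fibre_csv
#' @param pulse_minutes,stretch measurement constants to attach on read.
#' @export
read_fibre_csv <- function(path, pulse_minutes = 30, stretch = 2) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  attr(out, "pulse_minutes") <- pulse_minutes
  attr(out, "stretch") <- stretch
  class(out) <- c("fibre_set", "data.frame")
  out
}
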