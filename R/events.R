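# Oculomotor event detection: dispersion-threshold (I-DT) fixations,
# inter-fixation saccades, and blink inference from pupil loss.

#' Detect fixations with a dispersion-threshold algorithm
#'
#' Classic I-DT: a candidate group is seeded with the shortest sample span
#' covering the minimum duration; if its dispersion -- horizontal extent plus
#' vertical extent over valid samples -- stays at or below the threshold
#' (2.5% of the tracking range width), the group is greedily extended sample
#' by sample until the dispersion would be exceeded, then emitted. Groups
#' never reaching the minimum duration of 100 ms are rejected, and fixations
#' with more than 50% erroneous samples are discarded. Dispersion and
#' centroid are computed over valid samples only, so a fixation may bridge a
#' short pupil-loss run.
#'
#' @param rec A marked [gaze_recording()].
#' @param dispersion_threshold Maximum dispersion, in tracking-range units.
#' @param min_duration Minimum fixation duration, seconds.
#' @param max_erroneous Maximum tolerated erroneous-sample share.
#' @return Data frame of fixations: `start`, `end`, `x`, `y` (centroid),
#'   `dispersion`, `pupil_mean`, `pupil_var`, `erroneous_share`.
#' @export
detect_fixations <- function(rec, dispersion_threshold = 0.025,
                             min_duration = 0.100, max_erroneous = 0.5) {
  s <- rec$samples
  n <- nrow(s)
  t <- s$t; x <- s$x; y <- s$y; valid <- s$valid
  if (any(is.na(valid))) stop("apply mark_erroneous_samples() first",
                              call. = FALSE)
  out <- vector("list", 64L); n_out <- 0L
  i <- 1L
  while (i <= n) {
    # smallest j with span >= min_duration
    j <- findInterval(t[i] + min_duration - 1e-9, t) + 1L
    if (j > n) break
    # extent over valid samples in i..j, tracked incrementally
    vi <- which(valid[i:j]) + i - 1L
    if (length(vi) == 0) {
      xmin <- Inf; xmax <- -Inf; ymin <- Inf; ymax <- -Inf
      disp <- 0
    } else {
      xmin <- min(x[vi]); xmax <- max(x[vi])
      ymin <- min(y[vi]); ymax <- max(y[vi])
      disp <- (xmax - xmin) + (ymax - ymin)
    }
    if (disp <= dispersion_threshold) {
      while (j + 1L <= n) {
        k <- j + 1L
        if (valid[k]) {
          nxmin <- min(xmin, x[k]); nxmax <- max(xmax, x[k])
          nymin <- min(ymin, y[k]); nymax <- max(ymax, y[k])
          ndisp <- (nxmax - nxmin) + (nymax - nymin)
          if (is.finite(ndisp) && ndisp > dispersion_threshold) break
          xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
        }
        j <- k
      }
      vi <- which(valid[i:j]) + i - 1L
      disp <- if (length(vi) > 0) {
        (max(x[vi]) - min(x[vi])) + (max(y[vi]) - min(y[vi]))
      } else 0
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- data.frame(
        start = t[i], end = t[j],
        x = if (length(vi) > 0) mean(x[vi]) else NA_real_,
        y = if (length(vi) > 0) mean(y[vi]) else NA_real_,
        dispersion = disp,
        pupil_mean = if (length(vi) > 0) mean(s$pupil[vi]) else NA_real_,
        pupil_var = if (length(vi) > 1) stats::var(s$pupil[vi]) else 0,
        erroneous_share = mean(!valid[i:j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  fx <- if (n_out > 0) do.call(rbind, out[seq_len(n_out)]) else
    data.frame(start = numeric(0), end = numeric(0), x = numeric(0),
               y = numeric(0), dispersion = numeric(0),
               pupil_mean = numeric(0), pupil_var = numeric(0),
               erroneous_share = numeric(0))
  fx <- fx[fx$erroneous_share <= max_erroneous & !is.na(fx$x), , drop = FALSE]
  rownames(fx) <- NULL
  fx
}

#' Detect saccades between consecutive fixations
#'
#' Every movement between two consecutive fixations is a candidate saccade
#' spanning the inter-fixation gap. A candidate is accepted if its duration
#' does not exceed 500 ms and its peak sample-to-sample velocity over valid
#' samples reaches at least 200% of the tracking range per second;
#' candidates with more than 50% erroneous samples in the gap are discarded.
#' Amplitude is the Euclidean distance between the bounding fixation
#' centroids; direction is measured with "up" positive (decreasing y).
#'
#' @param rec A marked [gaze_recording()].
#' @param fixations Output of [detect_fixations()].
#' @param max_duration Maximum saccade duration, seconds.
#' @param min_peak_velocity Minimum peak velocity, range units per second.
#' @param max_erroneous Maximum tolerated erroneous-sample share.
#' @return Data frame of saccades: `start`, `end`, `amplitude`, `direction`
#'   (radians), `peak_velocity`, `erroneous_share`.
#' @export
detect_saccades <- function(rec, fixations, max_duration = 0.500,
                            min_peak_velocity = 2.0, max_erroneous = 0.5) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      amplitude = numeric(0), direction = numeric(0),
                      peak_velocity = numeric(0), erroneous_share = numeric(0))
  if (nrow(fixations) < 2) return(empty)
  s <- rec$samples
  out <- vector("list", nrow(fixations) - 1L)
  for (k in seq_len(nrow(fixations) - 1L)) {
    f1 <- fixations[k, ]; f2 <- fixations[k + 1L, ]
    start <- f1$end; end <- f2$start
    if (end - start > max_duration) next
    idx <- which(s$t >= start - 1e-12 & s$t <= end + 1e-12)
    inner <- idx[s$t[idx] > start + 1e-12 & s$t[idx] < end - 1e-12]
    err_share <- if (length(inner) > 0) mean(!s$valid[inner]) else 0
    if (err_share > max_erroneous) next
    vidx <- idx[s$valid[idx]]
    if (length(vidx) < 2) next
    dt <- diff(s$t[vidx])
    vel <- sqrt(diff(s$x[vidx])^2 + diff(s$y[vidx])^2) / dt
    pv <- max(vel)
    if (pv < min_peak_velocity) next
    dx <- f2$x - f1$x; dy <- f2$y - f1$y
    out[[k]] <- data.frame(
      start = start, end = end,
      amplitude = sqrt(dx^2 + dy^2),
      direction = atan2(-dy, dx),
      peak_velocity = pv,
      erroneous_share = err_share)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  sc <- do.call(rbind, out)
  rownames(sc) <- NULL
  sc
}

#' Detect blinks from pupil loss
#'
#' Maximal runs of consecutive pupil-absent samples whose duration falls in
#' the physiological blink band (75-500 ms by default) are reported as
#' blinks; longer runs are treated as track loss and shorter runs as noise.
#' Run duration is the number of absent samples over the sampling rate.
#'
#' @param rec A [gaze_recording()].
#' @param min_duration,max_duration Blink-band bounds, seconds.
#' @return Data frame of blinks: `start`, `end`.
#' @export
detect_blinks <- function(rec, min_duration = 0.075, max_duration = 0.500) {
  s <- rec$samples
  absent <- is.na(s$pupil)
  r <- rle(absent)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- if (nrow(s) > 1) stats::median(diff(s$t)) else 1 / rec$rate
  keep <- r$values & (r$lengths * dt >= min_duration - 1e-9) &
    (r$lengths * dt <= max_duration + 1e-9)
  data.frame(start = s$t[starts[keep]],
             end = s$t[ends[keep]] + dt)
}

#' Detect all oculomotor events
#'
#' Convenience wrapper running fixation, saccade and blink detection with
#' the standard thresholds.
#'
#' @param rec A marked [gaze_recording()].
#' @param ... Passed on to the individual detectors.
#' @return A list of class `gaze_events` with elements `fixations`,
#'   `saccades`, `blinks`.
#' @export
detect_events <- function(rec, ...) {
  fx <- detect_fixations(rec, ...)
  structure(list(fixations = fx,
                 saccades = detect_saccades(rec, fx),
                 blinks = detect_blinks(rec)),
            class = "gaze_events")
}

#' @export
print.gaze_events <- function(x, ...) {
  cat(sprintf("<gaze_events> %d fixations, %d saccades, %d blinks\n",
              nrow(x$fixations), nrow(x$saccades), nrow(x$blinks)))
  invisible(x)
}

#' Export detected events as one CSV table
#'
#' @param events A `gaze_events` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  rows <- list()
  if (nrow(events$fixations) > 0) {
    f <- events$fixations
    rows$fix <- data.frame(type = "fixation", start = f$start, end = f$end,
                           a1 = f$x, a2 = f$y, a3 = f$dispersion)
  }
  if (nrow(events$saccades) > 0) {
    s <- events$saccades
    rows$sac <- data.frame(type = "saccade", start = s$start, end = s$end,
                           a1 = s$amplitude, a2 = s$direction,
                           a3 = s$peak_velocity)
  }
  if (nrow(events$blinks) > 0) {
    b <- events$blinks
    rows$bl <- data.frame(type = "blink", start = b$start, end = b$end,
                          a1 = NA, a2 = NA, a3 = NA)
  }
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(type = character(0), start = numeric(0), end = numeric(0),
               a1 = numeric(0), a2 = numeric(0), a3 = numeric(0))
  df <- df[order(df$start), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Recall and precision of fixation detection against generator ground truth
#'
#' A ground-truth fixation counts as recoverable when at least half of its
#' samples are valid and its valid span reaches the detector's minimum
#' duration; recall is the share of recoverable truth fixations overlapped
#' for at least half their duration by some detected fixation. Precision is
#' the share of detected fixations that overlap some truth fixation the same
#' way.
#'
#' @param rec A marked [gaze_recording()] carrying generator `truth`.
#' @param fixations Output of [detect_fixations()].
#' @param min_duration Minimum valid span for a truth fixation to count.
#' @return A list with `recall`, `precision`, and the recoverable count.
#' @export
fixation_detection_scores <- function(rec, fixations, min_duration = 0.100) {
  truth <- rec$truth$fixations
  if (is.null(truth)) stop("recording carries no ground truth", call. = FALSE)
  s <- rec$samples
  recoverable <- vapply(seq_len(nrow(truth)), function(i) {
    idx <- which(s$t >= truth$start[i] - 1e-9 & s$t <= truth$end[i] + 1e-9)
    if (length(idx) == 0) return(FALSE)
    share_valid <- mean(s$valid[idx])
    share_valid >= 0.5 &&
      share_valid * (truth$end[i] - truth$start[i]) >= min_duration
  }, logical(1))
  overlap <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))
  hit <- function(t1, t2) {
    if (nrow(fixations) == 0) return(FALSE)
    any(overlap(t1, t2, fixations$start, fixations$end) >= 0.5 * (t2 - t1))
  }
  rec_hits <- mapply(hit, truth$start[recoverable], truth$end[recoverable])
  prec_hits <- vapply(seq_len(nrow(fixations)), function(i) {
    any(overlap(fixations$start[i], fixations$end[i],
                truth$start, truth$end) >=
          0.5 * (fixations$end[i] - fixations$start[i]))
  }, logical(1))
  list(recall = if (sum(recoverable) > 0) mean(rec_hits) else NA_real_,
       precision = if (nrow(fixations) > 0) mean(prec_hits) else NA_real_,
       n_recoverable = sum(recoverable))
}
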