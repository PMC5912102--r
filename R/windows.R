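# Sliding-window segmentation with the window retention rules.

#' Cut a recording into 50%-overlapping sliding windows
#'
#' Windows of the configured size start at 0 and advance by half the size
#' while they still fit inside the recording (the trailing partial window is
#' dropped). Windows are half-open `[start, start + size)`; a sample belongs
#' to the window containing its timestamp and an event to the window
#' containing its midpoint, which prevents double counting across the 50%
#' overlap. A window is retained unless it has more than 50% erroneous
#' samples, fewer than 2 valid samples, or no detected fixation or saccade.
#' Each window carries the context label with the largest time overlap
#' (ties go to the earlier context).
#'
#' @param rec A marked [gaze_recording()].
#' @param events A `gaze_events` list from [detect_events()].
#' @param size Window length in seconds.
#' @return Data frame with one row per candidate window: `start`, `end`,
#'   `context`, `n_samples`, `n_valid`, `erroneous_share`, `n_fixations`,
#'   `n_saccades`, `n_blinks`, the individual discard flags and `retained`.
#' @export
slide_windows <- function(rec, events, size) {
  if (size <= 0) stop("window size must be positive", call. = FALSE)
  duration <- rec$duration
  if (duration < size) {
    starts <- numeric(0)
  } else {
    starts <- seq(0, duration - size + 1e-9, by = size / 2)
  }
  s <- rec$samples
  fx_mid <- (events$fixations$start + events$fixations$end) / 2
  sc_mid <- (events$saccades$start + events$saccades$end) / 2
  bl_mid <- (events$blinks$start + events$blinks$end) / 2
  ctx <- rec$contexts
  rows <- lapply(starts, function(st) {
    en <- st + size
    idx <- which(s$t >= st - 1e-12 & s$t < en - 1e-12)
    n_samples <- length(idx)
    n_valid <- sum(s$valid[idx])
    err <- if (n_samples > 0) mean(!s$valid[idx]) else 1
    n_fix <- sum(fx_mid >= st & fx_mid < en)
    n_sac <- sum(sc_mid >= st & sc_mid < en)
    n_bl <- sum(bl_mid >= st & bl_mid < en)
    ov <- pmax(0, pmin(ctx$end, en) - pmax(ctx$start, st))
    context <- if (all(ov <= 0)) NA_character_ else ctx$label[which.max(ov)]
    too_erroneous <- err > 0.5
    too_few_valid <- n_valid < 2
    no_events <- (n_fix + n_sac) == 0
    data.frame(start = st, end = en, context = context,
               n_samples = n_samples, n_valid = n_valid,
               erroneous_share = err,
               n_fixations = n_fix, n_saccades = n_sac, n_blinks = n_bl,
               too_erroneous = too_erroneous, too_few_valid = too_few_valid,
               no_events = no_events,
               retained = !(too_erroneous || too_few_valid || no_events),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      context = character(0), n_samples = integer(0),
                      n_valid = integer(0), erroneous_share = numeric(0),
                      n_fixations = integer(0), n_saccades = integer(0),
                      n_blinks = integer(0), too_erroneous = logical(0),
                      too_few_valid = logical(0), no_events = logical(0),
                      retained = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
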