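# The per-window feature bank: 34 raw-gaze statistics, a 64-cell gaze
# heatmap, 53 oculomotor event statistics and 56 n-gram histogram features,
# concatenated into one 207-dimensional vector per retained window.

LARGE_SACCADE_AMPLITUDE <- 0.1   # range units; "large" vs "small" saccades
LONG_FIXATION_DURATION <- 0.3    # seconds; "long" vs "short" fixations
SACCADE_RATIO_CAP <- 20          # cap on the large-to-small count ratio

#' Canonical feature inventory
#'
#' Returns the 207 feature names in their fixed order. The order is the
#' concatenation raw (34) + heatmap (64) + event (53) + n-gram (56); the
#' `blocks` attribute maps each feature family to its positions.
#'
#' @return Character vector of length 207 with a `blocks` attribute.
#' @export
feature_names <- function() {
  stat8 <- c("min", "max", "mean", "std", "median", "range", "iqr", "skew")
  raw <- c(as.vector(t(outer(c("x", "y", "speed", "accel"), stat8,
                             function(a, b) paste0("raw_", a, "_", b)))),
           "raw_valid_fraction", "raw_xy_corr")
  heatmap <- sprintf("heatmap_%02d", 0:63)
  ev <- c("fix_count", "fix_rate",
          paste0("fix_dur_", c("min", "max", "mean", "std", "median")),
          paste0("fix_disp_", c("min", "max", "mean", "std", "median")),
          "fix_time_fraction", "fix_speed_mean", "fix_speed_std",
          "sacc_count", "sacc_rate",
          paste0("sacc_dur_", c("min", "max", "mean", "std")),
          paste0("sacc_amp_", c("min", "max", "mean", "std")),
          paste0("sacc_pv_", c("min", "max", "mean", "std")),
          sprintf("sacc_dir_hist_%d", 0:7),
          "sacc_large_small_ratio", "sacc_time_fraction",
          "blink_count", "blink_rate_per_min",
          paste0("blink_dur_", c("min", "max", "mean", "std")),
          paste0("pupil_", c("min", "max", "mean", "std")),
          "fix_pupil_mean_mean", "fix_pupil_mean_std",
          "fix_pupil_var_mean", "fix_pupil_var_std")
  ng <- as.vector(vapply(c("A", "B"), function(enc) {
    vapply(1:4, function(n) {
      paste0("ngram", enc, "_n", n, "_",
             c("distinct", "max", "min", "mean", "var",
               "most_idx", "least_idx"))
    }, character(7))
  }, character(28)))
  nms <- c(raw, heatmap, ev, ng)
  stopifnot(length(nms) == 207)
  attr(nms, "blocks") <- list(raw = seq_along(raw),
                              heatmap = length(raw) + seq_along(heatmap),
                              event = length(raw) + length(heatmap) +
                                seq_along(ev),
                              ngram = length(raw) + length(heatmap) +
                                length(ev) + seq_along(ng))
  nms
}

# 8 summary statistics with the 0-for-degenerate convention; empty -> zeros.
stat_block <- function(v) {
  if (length(v) == 0) return(rep(0, 8))
  c(min(v), max(v), mean(v), safe_sd(v), stats::median(v),
    max(v) - min(v), stats::IQR(v, type = 7), safe_skewness(v))
}

# Sample-to-sample speed (and midpoint acceleration) over valid samples.
sample_kinematics <- function(samples) {
  v <- samples$valid
  t <- samples$t[v]; x <- samples$x[v]; y <- samples$y[v]
  if (length(t) < 2) return(list(speed = numeric(0), accel = numeric(0)))
  dt <- diff(t)
  speed <- sqrt(diff(x)^2 + diff(y)^2) / dt
  accel <- if (length(speed) < 2) numeric(0) else
    diff(speed) / ((t[-(1:2)] - t[seq_len(length(t) - 2)]) / 2)
  list(speed = speed, accel = accel)
}

#' Raw gaze statistics for one window
#'
#' For each of four signals over valid samples -- horizontal gaze, vertical
#' gaze, sample speed and sample acceleration -- the minimum, maximum, mean,
#' standard deviation, median, range, interquartile range and skewness, plus
#' the valid-sample fraction and the x-y Pearson correlation. Degenerate
#' statistics (skewness of a constant signal, correlation with zero
#' variance) are 0.
#'
#' @param samples The window's sample data frame (with `valid` flags).
#' @return Named numeric vector of length 34.
#' @export
raw_gaze_features <- function(samples) {
  v <- samples$valid
  x <- samples$x[v]; y <- samples$y[v]
  kin <- sample_kinematics(samples)
  out <- c(stat_block(x), stat_block(y),
           stat_block(kin$speed), stat_block(kin$accel),
           if (nrow(samples) > 0) mean(v) else 0,
           safe_cor(x, y))
  names(out) <- feature_names()[attr(feature_names(), "blocks")$raw]
  out
}

#' 8x8 gaze heatmap for one window
#'
#' Valid gaze points falling within the per-window intervals spanning 95% of
#' the data on both axes (2.5th to 97.5th percentile) are binned into an 8x8
#' grid spanning those intervals. Cells are enumerated row-major from 0 in
#' the top-left corner to 63 in the bottom-right corner, and counts are
#' normalised to sum 1. If no point survives the percentile filter the
#' histogram is uniform (1/64 everywhere); a zero-width interval puts all
#' mass in row/column 0 on that axis.
#'
#' @param samples The window's sample data frame (with `valid` flags).
#' @return Named numeric vector of length 64 summing to 1.
#' @export
heatmap_features <- function(samples) {
  v <- samples$valid
  x <- samples$x[v]; y <- samples$y[v]
  nms <- feature_names()[attr(feature_names(), "blocks")$heatmap]
  if (length(x) == 0) {
    out <- rep(1 / 64, 64); names(out) <- nms; return(out)
  }
  qx <- stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
  qy <- stats::quantile(y, c(0.025, 0.975), type = 7, names = FALSE)
  keep <- x >= qx[1] & x <= qx[2] & y >= qy[1] & y <= qy[2]
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0) {
    out <- rep(1 / 64, 64); names(out) <- nms; return(out)
  }
  bin <- function(p, lo, hi) {
    if (hi - lo <= 0) return(rep(0L, length(p)))
    pmin(7L, as.integer(floor((p - lo) / (hi - lo) * 8)))
  }
  cell <- bin(y, qy[1], qy[2]) * 8L + bin(x, qx[1], qx[2])
  out <- tabulate(cell + 1L, nbins = 64)
  out <- out / sum(out)
  names(out) <- nms
  out
}

#' Oculomotor event statistics for one window
#'
#' Summaries over the fixations, saccades and blinks whose midpoints fall in
#' the window, plus pupil-diameter statistics: 15 fixation features, 24
#' saccade features (including an 8-bin direction histogram and the
#' large-to-small amplitude ratio), 6 blink features and 8 pupil features.
#' Statistics over empty event sets are 0.
#'
#' @param fixations,saccades,blinks Event subsets for the window.
#' @param samples The window's sample data frame.
#' @param size Window length in seconds (for rates and time fractions).
#' @return Named numeric vector of length 53.
#' @export
event_features <- function(fixations, saccades, blinks, samples, size) {
  stat4 <- function(v) {
    if (length(v) == 0) return(rep(0, 4))
    c(min(v), max(v), mean(v), safe_sd(v))
  }
  stat5 <- function(v) {
    if (length(v) == 0) return(rep(0, 5))
    c(min(v), max(v), mean(v), safe_sd(v), stats::median(v))
  }
  nfx <- nrow(fixations)
  fdur <- fixations$end - fixations$start
  # pooled within-fixation sample speeds
  fspeed <- numeric(0)
  if (nfx > 0) {
    fspeed <- unlist(lapply(seq_len(nfx), function(i) {
      idx <- samples$t >= fixations$start[i] - 1e-12 &
        samples$t <= fixations$end[i] + 1e-12
      sample_kinematics(samples[idx, , drop = FALSE])$speed
    }), use.names = FALSE)
  }
  fix_block <- c(nfx, nfx / size, stat5(fdur), stat5(fixations$dispersion),
                 min(1, sum(fdur) / size),
                 if (length(fspeed) > 0) mean(fspeed) else 0,
                 safe_sd(fspeed))
  nsc <- nrow(saccades)
  sdur <- saccades$end - saccades$start
  dir_hist <- rep(0, 8)
  ratio <- 0
  if (nsc > 0) {
    bins <- saccade_direction_bin(saccades$direction)
    dir_hist <- tabulate(bins + 1L, nbins = 8) / nsc
    n_large <- sum(saccades$amplitude >= LARGE_SACCADE_AMPLITUDE)
    n_small <- nsc - n_large
    ratio <- if (n_small == 0) SACCADE_RATIO_CAP else
      min(SACCADE_RATIO_CAP, n_large / n_small)
  }
  sacc_block <- c(nsc, nsc / size, stat4(sdur), stat4(saccades$amplitude),
                  stat4(saccades$peak_velocity), dir_hist, ratio,
                  min(1, sum(sdur) / size))
  nbl <- nrow(blinks)
  bdur <- blinks$end - blinks$start
  blink_block <- c(nbl, nbl / size * 60, stat4(bdur))
  pup <- samples$pupil[samples$valid]
  pupil_block <- c(stat4(pup),
                   if (nfx > 0) mean(fixations$pupil_mean) else 0,
                   safe_sd(fixations$pupil_mean),
                   if (nfx > 0) mean(fixations$pupil_var) else 0,
                   safe_sd(fixations$pupil_var))
  out <- c(fix_block, sacc_block, blink_block, pupil_block)
  names(out) <- feature_names()[attr(feature_names(), "blocks")$event]
  out
}

# Direction bin 0..7: 45-degree sectors centred on the 8 compass directions,
# 0 = rightwards, 2 = up (decreasing y), counter-clockwise.
saccade_direction_bin <- function(direction) {
  as.integer(round(direction / (pi / 4))) %% 8L
}

#' n-gram configuration
#'
#' Encoding A uses a 16-symbol alphabet of saccades (8 direction sectors x
#' large/small amplitude); encoding B adds short/long fixation symbols for
#' an 18-symbol alphabet over the interleaved fixation-saccade sequence.
#'
#' @param n_values The n-gram orders to compute.
#' @param large_amplitude Amplitude threshold (range units) separating large
#'   from small saccades.
#' @param long_fixation Duration threshold (seconds) separating long from
#'   short fixations.
#' @return A list of class `ngram_config`.
#' @export
ngram_config <- function(n_values = 1:4,
                         large_amplitude = LARGE_SACCADE_AMPLITUDE,
                         long_fixation = LONG_FIXATION_DURATION) {
  structure(list(n_values = n_values, large_amplitude = large_amplitude,
                 long_fixation = long_fixation),
            class = "ngram_config")
}

# Saccade symbols 0..15 = direction_bin * 2 + is_large.
encode_saccades <- function(saccades, cfg) {
  if (nrow(saccades) == 0) return(integer(0))
  saccade_direction_bin(saccades$direction) * 2L +
    as.integer(saccades$amplitude >= cfg$large_amplitude)
}

# Fixation symbols 16 (short) / 17 (long); interleaved by start time.
encode_events <- function(fixations, saccades, cfg) {
  sym_s <- encode_saccades(saccades, cfg)
  sym_f <- if (nrow(fixations) == 0) integer(0) else
    16L + as.integer(fixations$end - fixations$start >= cfg$long_fixation)
  starts <- c(saccades$start, fixations$start)
  syms <- c(sym_s, sym_f)
  syms[order(starts)]
}

# 7 histogram summaries for one (sequence, n, alphabet size): distinct
# count, max/min/mean/variance of the observed (non-zero) entries, and the
# lexicographic indices of the most and least frequent n-gram (ties to the
# smallest index). Sequences shorter than n give zeros with indices -1.
ngram_stats <- function(syms, n, K) {
  L <- length(syms)
  if (L < n) return(c(0, 0, 0, 0, 0, -1, -1))
  G <- L - n + 1L
  idx <- numeric(G)
  for (i in seq_len(n)) {
    idx <- idx + syms[i:(i + G - 1L)] * K^(n - i)
  }
  counts <- table(idx)
  vals <- as.numeric(counts)
  keys <- as.numeric(names(counts))
  c(length(vals), max(vals), min(vals), mean(vals), safe_var(vals),
    min(keys[vals == max(vals)]), min(keys[vals == min(vals)]))
}

#' n-gram histogram features for one window
#'
#' For both encodings and each n in 1..4, the window's symbol sequence is
#' summarised by 7 histogram statistics, giving 2 x 4 x 7 = 56 features.
#'
#' @param fixations,saccades Event subsets for the window, time-ordered.
#' @param cfg An [ngram_config()].
#' @return Named numeric vector of length 56.
#' @export
ngram_features <- function(fixations, saccades, cfg = ngram_config()) {
  seq_a <- encode_saccades(saccades, cfg)
  seq_b <- encode_events(fixations, saccades, cfg)
  out <- c(unlist(lapply(cfg$n_values, function(n) ngram_stats(seq_a, n, 16))),
           unlist(lapply(cfg$n_values, function(n) ngram_stats(seq_b, n, 18))))
  names(out) <- feature_names()[attr(feature_names(), "blocks")$ngram]
  out
}

# Subset events whose midpoint lies in [start, end).
events_in_window <- function(ev, start, end) {
  mid <- (ev$start + ev$end) / 2
  ev[mid >= start & mid < end, , drop = FALSE]
}

#' Extract the 207-dimensional feature vector for one window
#'
#' @param rec A marked [gaze_recording()].
#' @param events A `gaze_events` list.
#' @param start Window start, seconds.
#' @param size Window length, seconds.
#' @param cfg An [ngram_config()].
#' @return Named numeric vector of length 207.
#' @export
extract_feature_vector <- function(rec, events, start, size,
                                   cfg = ngram_config()) {
  end <- start + size
  s <- rec$samples
  sw <- s[s$t >= start - 1e-12 & s$t < end - 1e-12, , drop = FALSE]
  fx <- events_in_window(events$fixations, start, end)
  sc <- events_in_window(events$saccades, start, end)
  bl <- events_in_window(events$blinks, start, end)
  c(raw_gaze_features(sw), heatmap_features(sw),
    event_features(fx, sc, bl, sw, size), ngram_features(fx, sc, cfg))
}

#' Extract features for every retained window of a recording
#'
#' @param rec A marked [gaze_recording()].
#' @param events A `gaze_events` list from [detect_events()].
#' @param size Window length, seconds.
#' @param cfg An [ngram_config()].
#' @return A list of class `window_features`: `X` (matrix, one row per
#'   retained window, 207 columns) and `meta` (data frame with
#'   `participant`, `size`, `start`, `mid`, `context`).
#' @export
extract_features <- function(rec, events, size, cfg = ngram_config()) {
  w <- slide_windows(rec, events, size)
  w <- w[w$retained, , drop = FALSE]
  X <- matrix(0, nrow = nrow(w), ncol = 207,
              dimnames = list(NULL, as.character(feature_names())))
  for (i in seq_len(nrow(w))) {
    X[i, ] <- extract_feature_vector(rec, events, w$start[i], size, cfg)
  }
  meta <- data.frame(participant = rep(rec$participant_id, nrow(w)),
                     size = rep(size, nrow(w)),
                     start = w$start, mid = w$start + size / 2,
                     context = w$context, stringsAsFactors = FALSE)
  structure(list(X = X, meta = meta), class = "window_features")
}

#' Build per-window-size feature sets for a whole cohort
#'
#' Runs event detection once per recording and feature extraction at each
#' candidate window size, concatenating across participants.
#'
#' @param recordings List of marked [gaze_recording()] objects.
#' @param sizes Window sizes in seconds.
#' @param cfg An [ngram_config()].
#' @return Named list (one element per size, keyed by the size) of
#'   `window_features` objects covering the cohort.
#' @export
build_feature_sets <- function(recordings, sizes = c(5, 10, 15, 30, 45, 60),
                               cfg = ngram_config()) {
  events <- lapply(recordings, detect_events)
  sets <- lapply(sizes, function(sz) {
    parts <- lapply(seq_along(recordings), function(i) {
      extract_features(recordings[[i]], events[[i]], sz, cfg)
    })
    structure(list(X = do.call(rbind, lapply(parts, `[[`, "X")),
                   meta = do.call(rbind, lapply(parts, `[[`, "meta"))),
              class = "window_features")
  })
  names(sets) <- as.character(sizes)
  sets
}

#' Write a cohort feature matrix as CSV
#'
#' One row per retained window with participant id, window start and context
#' followed by the 207 feature columns.
#'
#' @param fs A `window_features` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fs, path) {
  df <- cbind(fs$meta, as.data.frame(fs$X))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
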