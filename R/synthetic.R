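# Synthetic gaze-cohort generator: alternating fixation/saccade structure,
# blinks and track loss, pupil dynamics, context segments, Gaussian trait
# scores, and configurable trait-to-oculomotor effect sizes. Defaults mirror
# the everyday-recording regime the analysis assumes: ~12.5 minutes at 60 Hz
# with ~20% track loss and a shop segment covering ~20% of the recording.

#' Oculomotor generator parameters
#'
#' Durations and amplitudes are log-normal (parameterised by mean and SD on
#' the natural scale), saccade directions von Mises around a bias direction,
#' blinks Poisson in time. `loss_fraction` is the total pupil-absent share
#' of samples (blinks plus track loss).
#'
#' @param fix_dur_mean,fix_dur_sd Fixation duration mean/SD, seconds.
#' @param fix_jitter_sd Within-fixation positional jitter SD, range units.
#' @param sacc_amp_mean,sacc_amp_sd Saccade amplitude mean/SD, range units.
#' @param sacc_dir_bias Preferred saccade direction, radians (0 = right).
#' @param sacc_dir_conc von Mises concentration of saccade directions.
#' @param blink_rate Blinks per minute.
#' @param blink_dur_mean Mean blink duration, seconds.
#' @param pupil_base Baseline pupil diameter, mm.
#' @param pupil_sd SD of the slow AR(1) pupil drift, mm.
#' @param loss_fraction Target share of pupil-absent samples.
#' @return A list of class `oculomotor_params`.
#' @export
oculomotor_params <- function(fix_dur_mean = 0.30, fix_dur_sd = 0.12,
                              fix_jitter_sd = 0.003,
                              sacc_amp_mean = 0.15, sacc_amp_sd = 0.08,
                              sacc_dir_bias = 0, sacc_dir_conc = 0.5,
                              blink_rate = 12, blink_dur_mean = 0.15,
                              pupil_base = 4.5, pupil_sd = 0.25,
                              loss_fraction = 0.2) {
  p <- list(fix_dur_mean = fix_dur_mean, fix_dur_sd = fix_dur_sd,
            fix_jitter_sd = fix_jitter_sd,
            sacc_amp_mean = sacc_amp_mean, sacc_amp_sd = sacc_amp_sd,
            sacc_dir_bias = sacc_dir_bias, sacc_dir_conc = sacc_dir_conc,
            blink_rate = blink_rate, blink_dur_mean = blink_dur_mean,
            pupil_base = pupil_base, pupil_sd = pupil_sd,
            loss_fraction = loss_fraction)
  positive <- c("fix_dur_mean", "fix_dur_sd", "fix_jitter_sd",
                "sacc_amp_mean", "sacc_amp_sd", "blink_dur_mean",
                "pupil_base", "pupil_sd")
  for (nm in positive) {
    if (p[[nm]] <= 0) stop(nm, " must be positive", call. = FALSE)
  }
  if (p$blink_rate < 0) stop("blink_rate must be non-negative", call. = FALSE)
  if (p$loss_fraction < 0 || p$loss_fraction >= 0.6) {
    stop("loss_fraction must lie in [0, 0.6)", call. = FALSE)
  }
  structure(p, class = "oculomotor_params")
}

# Admissible bounds used when trait effects shift the baseline parameters.
clamp_params <- function(p) {
  clamp <- function(v, lo, hi) min(hi, max(lo, v))
  p$fix_dur_mean <- clamp(p$fix_dur_mean, 0.12, 1.0)
  p$fix_dur_sd <- clamp(p$fix_dur_sd, 0.01, 0.5)
  p$fix_jitter_sd <- clamp(p$fix_jitter_sd, 5e-4, 0.006)
  p$sacc_amp_mean <- clamp(p$sacc_amp_mean, 0.03, 0.5)
  p$sacc_amp_sd <- clamp(p$sacc_amp_sd, 0.005, 0.3)
  p$blink_rate <- clamp(p$blink_rate, 0.5, 40)
  p$blink_dur_mean <- clamp(p$blink_dur_mean, 0.09, 0.4)
  p$pupil_base <- clamp(p$pupil_base, 2, 8)
  p$pupil_sd <- clamp(p$pupil_sd, 0.02, 1)
  p$loss_fraction <- clamp(p$loss_fraction, 0, 0.45)
  p
}

#' Trait-to-oculomotor effect specification
#'
#' Slopes are expressed per trait standard deviation: a participant whose
#' trait z-score is `z` has `param = baseline + slope * z` (clamped to the
#' admissible range). A zero effect specification yields recordings
#' statistically independent of the traits.
#'
#' @param slopes Named list: trait -> named numeric vector of per-SD slopes
#'   on [oculomotor_params()] fields.
#' @param noise SD of multiplicative log-normal between-participant jitter
#'   applied to the modulated parameters.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(slopes = list(), noise = 0) {
  structure(list(slopes = slopes, noise = noise), class = "effect_spec")
}

#' A strong single-trait effect specification
#'
#' Shifts fixation duration, saccade amplitude, blink rate and baseline
#' pupil diameter by about one within-cohort SD of each parameter per trait
#' SD -- a deliberately strong, recoverable signal for validation studies.
#'
#' @param trait Trait carrying the signal.
#' @param strength Multiplier on the default slopes.
#' @return An [effect_spec()].
#' @export
strong_effects <- function(trait = "extraversion", strength = 1) {
  slopes <- list(c(fix_dur_mean = 0.10, sacc_amp_mean = 0.06,
                   blink_rate = 8, pupil_base = 0.5) * strength)
  names(slopes) <- trait
  effect_spec(slopes = slopes)
}

#' Sample Gaussian trait scores for a cohort
#'
#' Each of the seven traits is drawn i.i.d. Gaussian with configurable mean
#' and SD; deterministic under the seed.
#'
#' @param n Number of participants (at least 3, so tertile binning is
#'   possible).
#' @param seed Integer seed.
#' @param mean,sd Per-trait means and SDs (scalars or named vectors over the
#'   seven traits).
#' @return Data frame with `participant_id` and one column per trait.
#' @export
sample_traits <- function(n, seed, mean = 0, sd = 1) {
  if (n < 3) stop("need at least 3 participants for tertile binning",
                  call. = FALSE)
  means <- rep(mean, length.out = 7); names(means) <- TRAIT_NAMES
  sds <- rep(sd, length.out = 7); names(sds) <- TRAIT_NAMES
  if (!is.null(names(mean))) means[names(mean)] <- mean
  if (!is.null(names(sd))) sds[names(sd)] <- sd
  with_seed(seed, {
    df <- data.frame(participant_id = sprintf("p%03d", seq_len(n)),
                     stringsAsFactors = FALSE)
    for (tr in TRAIT_NAMES) df[[tr]] <- stats::rnorm(n, means[tr], sds[tr])
    df
  })
}

# Log-normal draws parameterised by natural-scale mean and SD.
rlnorm_ms <- function(n, m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# von Mises sampler (Best-Fisher rejection); near-uniform for tiny kappa.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-6) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- cos(pi * stats::runif(1))
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      u2 <- stats::runif(1)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) break
    }
    out[i] <- mu + sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f)))
  }
  out
}

# Reflect a coordinate into [lo, hi].
reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  v <- ifelse(v > span, 2 * span - v, v)
  v + lo
}

#' Generate one synthetic gaze recording
#'
#' Produces an alternating fixation/saccade event schedule (log-normal
#' durations and amplitudes, von Mises directions), renders it to samples --
#' Gaussian jitter around the fixation centroid, straight-line saccades with
#' a smoothstep (bell-shaped velocity) profile -- adds an AR(1)-plus-noise
#' pupil trace, inserts Poisson blinks and additional track-loss runs until
#' the target pupil-absent share is reached, attaches way1/shop/way2 context
#' segments covering 40/20/40% of the duration, and stores the ground-truth
#' fixation schedule under `$truth` so detector recall is computable.
#' Erroneous-sample marking is already applied to the result.
#'
#' @param params An [oculomotor_params()].
#' @param duration Recording length, seconds.
#' @param rate Sampling rate, Hz.
#' @param seed Integer seed.
#' @param participant_id Participant id for the recording.
#' @return A marked [gaze_recording()] with ground truth attached.
#' @export
generate_recording <- function(params, duration = 750, rate = 60, seed = 1,
                               participant_id = "p001") {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (!inherits(params, "oculomotor_params")) {
    params <- do.call(oculomotor_params, params)
  }
  with_seed(seed, {
    n <- round(duration * rate)
    t <- (seq_len(n) - 1) / rate
    x <- numeric(n); y <- numeric(n)
    # --- event schedule -------------------------------------------------
    px <- stats::runif(1, 0.35, 0.65); py <- stats::runif(1, 0.35, 0.65)
    segs <- list(); ns <- 0L
    cur <- 0
    while (cur < duration) {
      fd <- min(2, max(0.04, rlnorm_ms(1, params$fix_dur_mean,
                                       params$fix_dur_sd)))
      ns <- ns + 1L
      segs[[ns]] <- c(1, cur, min(cur + fd, duration), px, py, px, py)
      cur <- cur + fd
      if (cur >= duration) break
      amp <- min(0.8, max(0.01, rlnorm_ms(1, params$sacc_amp_mean,
                                          params$sacc_amp_sd)))
      dir <- rvonmises(1, params$sacc_dir_bias, params$sacc_dir_conc)
      tx <- reflect_into(px + amp * cos(dir), 0.03, 0.97)
      ty <- reflect_into(py - amp * sin(dir), 0.03, 0.97)
      sd_dur <- min(0.12, max(1.6 / rate, 0.02 + 0.1 * amp))
      ns <- ns + 1L
      segs[[ns]] <- c(2, cur, min(cur + sd_dur, duration), px, py, tx, ty)
      cur <- cur + sd_dur
      px <- tx; py <- ty
    }
    segm <- do.call(rbind, segs)
    # --- render samples -------------------------------------------------
    truth_fix <- list(); nf <- 0L
    for (k in seq_len(nrow(segm))) {
      sg <- segm[k, ]
      idx <- which(t >= sg[2] - 1e-12 & t < sg[3] - 1e-12)
      if (sg[1] == 1) {
        x[idx] <- sg[4] + stats::rnorm(length(idx), 0, params$fix_jitter_sd)
        y[idx] <- sg[5] + stats::rnorm(length(idx), 0, params$fix_jitter_sd)
        nf <- nf + 1L
        truth_fix[[nf]] <- data.frame(start = sg[2], end = sg[3],
                                      x = sg[4], y = sg[5])
      } else if (length(idx) > 0) {
        u <- (t[idx] - sg[2]) / (sg[3] - sg[2])
        s <- 3 * u^2 - 2 * u^3
        x[idx] <- sg[4] + (sg[6] - sg[4]) * s +
          stats::rnorm(length(idx), 0, 0.001)
        y[idx] <- sg[5] + (sg[7] - sg[5]) * s +
          stats::rnorm(length(idx), 0, 0.001)
      }
    }
    # --- pupil trace ----------------------------------------------------
    phi <- 0.99
    innov <- stats::rnorm(n, 0, params$pupil_sd * sqrt(1 - phi^2))
    drift <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    pupil <- params$pupil_base + drift + stats::rnorm(n, 0, 0.01)
    # --- blinks and track loss ------------------------------------------
    absent <- rep(FALSE, n)
    nb <- stats::rpois(1, params$blink_rate * duration / 60)
    if (nb > 0) {
      bs <- stats::runif(nb, 0, duration)
      bd <- pmin(0.45, pmax(0.08, rlnorm_ms(nb, params$blink_dur_mean, 0.03)))
      for (k in seq_len(nb)) {
        i0 <- floor(bs[k] * rate) + 1
        i1 <- min(n, i0 + round(bd[k] * rate) - 1)
        absent[i0:i1] <- TRUE
      }
    }
    guard <- 0L
    while (mean(absent) < params$loss_fraction && guard < 100000L) {
      guard <- guard + 1L
      len <- round(stats::runif(1, 0.6, 3.0) * rate)
      remaining <- ceiling((params$loss_fraction - mean(absent)) * n)
      len <- min(len, remaining)
      i0 <- sample.int(max(1, n - len), 1)
      absent[i0:(i0 + len - 1)] <- TRUE
    }
    pupil[absent] <- NA
    contexts <- data.frame(
      label = c("way1", "shop", "way2"),
      start = c(0, 0.4, 0.6) * duration,
      end = c(0.4, 0.6, 1) * duration, stringsAsFactors = FALSE)
    truth <- list(fixations = do.call(rbind, truth_fix))
    rec <- gaze_recording(participant_id,
                          data.frame(t = t, x = x, y = y, pupil = pupil),
                          rate = rate, contexts = contexts, truth = truth)
    mark_erroneous_samples(rec)
  })
}

#' Generate a synthetic cohort with trait-linked oculomotor parameters
#'
#' Samples Gaussian trait scores, shifts each participant's oculomotor
#' parameters by the specified per-SD slopes of their trait z-scores, and
#' generates one recording per participant. Fully reproducible under the
#' seed.
#'
#' @param n Number of participants.
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @param duration,rate Recording length (s) and sampling rate (Hz).
#' @param baseline Baseline [oculomotor_params()].
#' @param trait_mean,trait_sd Trait-score distribution parameters.
#' @return A list with `recordings` (marked recordings with ground truth)
#'   and `traits` (the trait-score data frame).
#' @export
generate_cohort <- function(n, effects = effect_spec(), seed = 1,
                            duration = 750, rate = 60,
                            baseline = oculomotor_params(),
                            trait_mean = 0, trait_sd = 1) {
  seeds <- derive_seeds(seed, n + 2L)
  traits <- sample_traits(n, seed = seeds[n + 1L],
                          mean = trait_mean, sd = trait_sd)
  means <- rep(trait_mean, length.out = 7); names(means) <- TRAIT_NAMES
  sds <- rep(trait_sd, length.out = 7); names(sds) <- TRAIT_NAMES
  noise_draws <- if (effects$noise > 0) {
    with_seed(seeds[n + 2L], matrix(stats::rnorm(n * 12, 0, effects$noise),
                                    nrow = n))
  } else NULL
  recordings <- lapply(seq_len(n), function(i) {
    p <- unclass(baseline)
    for (tr in names(effects$slopes)) {
      z <- (traits[[tr]][i] - means[tr]) / sds[tr]
      sl <- effects$slopes[[tr]]
      for (nm in names(sl)) p[[nm]] <- p[[nm]] + sl[nm] * z
    }
    if (!is.null(noise_draws)) {
      modulated <- unique(unlist(lapply(effects$slopes, names)))
      for (j in seq_along(modulated)) {
        nm <- modulated[j]
        p[[nm]] <- p[[nm]] * exp(noise_draws[i, j])
      }
    }
    p <- clamp_params(p)
    class(p) <- "oculomotor_params"
    generate_recording(p, duration = duration, rate = rate,
                       seed = seeds[i],
                       participant_id = traits$participant_id[i])
  })
  list(recordings = recordings, traits = traits)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes per-participant gaze and context CSVs (the format
#' [read_gaze_recording()] reads) and the cohort trait table.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    write_gaze_recording(
      rec,
      file.path(dir, paste0(rec$participant_id, "_gaze.csv")),
      file.path(dir, paste0(rec$participant_id, "_context.csv")))
  }
  write_trait_scores(cohort$traits, file.path(dir, "traits.csv"))
  invisible(dir)
}
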