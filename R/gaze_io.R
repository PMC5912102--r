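# Gaze data model, file I/O, erroneous-sample marking and participant
# screening.
#
# Coordinates are normalised to the tracking range: [0, 1] on each axis with
# the origin in the top-left corner and y increasing downwards. Samples where
# the pupil could not be detected, or where the estimated gaze direction lies
# beyond 150% of the tracking range (outside [-0.25, 1.25] on either axis),
# are marked erroneous.

TRAIT_NAMES <- c("neuroticism", "extraversion", "openness", "agreeableness",
                 "conscientiousness", "pcs", "cei")

CONTEXT_LABELS <- c("way1", "shop", "way2")

#' Construct a gaze recording
#'
#' A gaze recording holds a per-sample gaze stream for one participant:
#' timestamps in seconds from recording start, horizontal/vertical gaze in
#' tracking-range units, pupil diameter in millimetres (`NA` when the pupil
#' was not detected), and a validity flag filled in by
#' [mark_erroneous_samples()].
#'
#' @param participant_id Participant identifier (string).
#' @param samples Data frame with numeric columns `t`, `x`, `y`, `pupil`.
#' @param rate Nominal sampling rate in Hz.
#' @param contexts Optional data frame `label,start,end` with labels among
#'   `way1`, `shop`, `way2`; defaults to one segment covering the whole
#'   recording (labelled `way1`).
#' @param truth Optional generator ground truth (see [generate_recording()]).
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(participant_id, samples, rate = 60,
                           contexts = NULL, truth = NULL) {
  required <- c("t", "x", "y", "pupil")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(samples$t)) stop("timestamps must be numeric", call. = FALSE)
  bad <- which(diff(samples$t) <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-monotonic timestamps at row %d", bad[1] + 1L),
         call. = FALSE)
  }
  if (any(samples$t < 0)) stop("timestamps must be >= 0", call. = FALSE)
  samples <- samples[, required]
  samples$valid <- NA
  n <- nrow(samples)
  dt <- if (n > 1) stats::median(diff(samples$t)) else 1 / rate
  duration <- if (n > 0) samples$t[n] + dt else 0
  if (is.null(contexts)) {
    contexts <- data.frame(label = "way1", start = 0, end = duration,
                           stringsAsFactors = FALSE)
  } else {
    contexts <- as.data.frame(contexts)[, c("label", "start", "end")]
    if (is.unsorted(contexts$start) ||
        any(contexts$end[-nrow(contexts)] > contexts$start[-1] + 1e-9)) {
      stop("context segments must be ordered and non-overlapping",
           call. = FALSE)
    }
    if (any(contexts$start < -1e-9) ||
        any(contexts$end > duration + 1e-6)) {
      stop("context segments must lie within the recording", call. = FALSE)
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         rate = rate, samples = samples, contexts = contexts,
         duration = duration, truth = truth),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> participant %s: %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, nrow(x$samples), x$rate, x$duration))
  if (!all(is.na(x$samples$valid))) {
    cat(sprintf("  erroneous share: %.3f\n", mean(!x$samples$valid)))
  }
  invisible(x)
}

#' Read a gaze recording from CSV
#'
#' The gaze file must have a header `t,x,y,pupil`; an empty `pupil` field
#' means the pupil was not detected. The optional context file has a header
#' `label,start,end`.
#'
#' @param path Path to the gaze CSV.
#' @param context_path Optional path to a context CSV.
#' @param participant_id Participant id; defaults to the file name stem.
#' @param rate Nominal sampling rate in Hz.
#' @return A [gaze_recording()].
#' @export
read_gaze_recording <- function(path, context_path = NULL,
                                participant_id = NULL, rate = 60) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("t", "x", "y", "pupil")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("parse error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$t)) stop("parse error: timestamps not numeric",
                              call. = FALSE)
  df$pupil <- suppressWarnings(as.numeric(df$pupil))
  contexts <- NULL
  if (!is.null(context_path)) {
    contexts <- utils::read.csv(context_path, stringsAsFactors = FALSE)
  }
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  gaze_recording(participant_id, df, rate = rate, contexts = contexts)
}

#' Write a gaze recording to CSV
#'
#' Writes the gaze stream (and optionally the context table) in the same
#' format [read_gaze_recording()] reads; numeric fields are written with
#' full precision so a read-back round-trips exactly.
#'
#' @param rec A [gaze_recording()].
#' @param path Output path for the gaze CSV.
#' @param context_path Optional output path for the context CSV.
#' @return `path`, invisibly.
#' @export
write_gaze_recording <- function(rec, path, context_path = NULL) {
  s <- rec$samples
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c("t,x,y,pupil",
             paste(fmt(s$t), fmt(s$x), fmt(s$y), fmt(s$pupil), sep = ","))
  writeLines(lines, path)
  if (!is.null(context_path)) {
    ctx <- rec$contexts
    writeLines(c("label,start,end",
                 paste(ctx$label, sprintf("%.17g", ctx$start),
                       sprintf("%.17g", ctx$end), sep = ",")),
               context_path)
  }
  invisible(path)
}

#' Read and write per-participant trait scores
#'
#' Trait tables are CSV with columns `participant_id` and the seven traits
#' `neuroticism, extraversion, openness, agreeableness, conscientiousness,
#' pcs, cei` (NEO-FFI five plus Perceptual Curiosity and the Curiosity and
#' Exploration Inventory).
#'
#' @param path File path.
#' @return `read_trait_scores`: a data frame with one row per participant.
#' @export
read_trait_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("participant_id", TRAIT_NAMES), names(df))
  if (length(missing_cols) > 0) {
    stop("trait table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  df[, c("participant_id", TRAIT_NAMES)]
}

#' @rdname read_trait_scores
#' @param traits Trait-score data frame.
#' @export
write_trait_scores <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mark erroneous gaze samples
#'
#' A sample is erroneous when the pupil was not detected or when the gaze
#' direction was estimated beyond 150% of the tracking range, i.e. outside
#' the interval of length 1.5 centred on the range: `[-0.25, 1.25]` on
#' either axis. All other samples are valid. Idempotent.
#'
#' @param rec A [gaze_recording()].
#' @return The recording with the `valid` flag filled in.
#' @export
mark_erroneous_samples <- function(rec) {
  s <- rec$samples
  erroneous <- is.na(s$pupil) |
    s$x < -0.25 | s$x > 1.25 |
    s$y < -0.25 | s$y > 1.25
  erroneous[is.na(erroneous)] <- TRUE
  rec$samples$valid <- !erroneous
  rec
}

#' Erroneous-sample and gaze-constancy fractions
#'
#' `erroneous_fraction` is the share of samples marked invalid;
#' `constancy_fraction` is the longest plateau of identical consecutive
#' values among valid samples, on either axis, as a share of valid samples.
#' Both require [mark_erroneous_samples()] to have been applied.
#'
#' @param rec A marked [gaze_recording()].
#' @return A fraction in `[0, 1]`.
#' @export
erroneous_fraction <- function(rec) {
  v <- rec$samples$valid
  if (all(is.na(v))) stop("apply mark_erroneous_samples() first",
                          call. = FALSE)
  mean(!v)
}

#' @rdname erroneous_fraction
#' @export
constancy_fraction <- function(rec) {
  v <- rec$samples$valid
  if (all(is.na(v))) stop("apply mark_erroneous_samples() first",
                          call. = FALSE)
  n_valid <- sum(v)
  if (n_valid == 0) return(1)
  longest_run <- function(z) {
    if (length(z) == 0) return(0)
    r <- rle(z)
    max(r$lengths)
  }
  max(longest_run(rec$samples$x[v]), longest_run(rec$samples$y[v])) / n_valid
}

#' Screen a cohort of gaze recordings
#'
#' Excludes participants with more than 50% erroneous samples, and
#' participants whose gaze direction stays constant for more than 30% of
#' valid samples on either axis (the longest plateau of identical values).
#' Erroneous marking must already have been applied.
#'
#' @param cohort List of marked [gaze_recording()] objects.
#' @param max_erroneous Exclusion threshold on the erroneous-sample fraction.
#' @param max_constancy Exclusion threshold on the constancy fraction.
#' @return A list with `retained` (the surviving recordings) and `reports`,
#'   a data frame with one row per participant (`participant_id`,
#'   `erroneous_fraction`, `constancy_fraction`, `excluded`, `reason`).
#' @export
screen_participants <- function(cohort, max_erroneous = 0.5,
                                max_constancy = 0.3) {
  if (length(cohort) == 0) stop("empty cohort", call. = FALSE)
  reports <- do.call(rbind, lapply(cohort, function(rec) {
    ef <- erroneous_fraction(rec)
    cf <- constancy_fraction(rec)
    reason <- ""
    if (ef > max_erroneous) {
      reason <- sprintf("erroneous>%.1f", max_erroneous)
    } else if (cf > max_constancy) {
      reason <- "constant-gaze"
    }
    data.frame(participant_id = rec$participant_id,
               erroneous_fraction = ef, constancy_fraction = cf,
               excluded = nzchar(reason), reason = reason,
               stringsAsFactors = FALSE)
  }))
  rownames(reports) <- NULL
  list(retained = cohort[!reports$excluded], reports = reports)
}
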