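# Data-driven tertile binning of trait scores into low/medium/high ranges.

RANGE_LEVELS <- c("low", "medium", "high")

#' Tertile-bin one trait's scores
#'
#' The middle bin's boundaries are the empirical score percentiles at 1/3
#' and 2/3 (linear-interpolation quantile definition, R type 7), computed
#' once on the full cohort. Scores at or below the lower boundary are
#' `low`, scores above the upper boundary are `high`, the rest `medium`;
#' identical scores are always co-assigned.
#'
#' @param scores Named numeric vector (names = participant ids) or a data
#'   frame with columns `participant_id` and `score`.
#' @param trait Trait name carried along in the result.
#' @return A list of class `trait_bins`: `trait`, `b_low`, `b_high`, and
#'   `assignment`, a factor (levels low/medium/high) named by participant.
#' @export
tertile_bins <- function(scores, trait = "trait") {
  if (is.data.frame(scores)) {
    v <- scores$score
    names(v) <- scores$participant_id
    scores <- v
  }
  if (length(scores) < 3) stop("need at least 3 participants", call. = FALSE)
  if (is.null(names(scores))) names(scores) <- seq_along(scores)
  if (max(scores) == min(scores)) stop("degenerate trait: all scores equal",
                                       call. = FALSE)
  b <- stats::quantile(scores, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  assignment <- factor(ifelse(scores <= b[1], "low",
                              ifelse(scores <= b[2], "medium", "high")),
                       levels = RANGE_LEVELS)
  names(assignment) <- names(scores)
  structure(list(trait = trait, b_low = b[1], b_high = b[2],
                 assignment = assignment),
            class = "trait_bins")
}

#' @export
print.trait_bins <- function(x, ...) {
  cat(sprintf("<trait_bins> %s: boundaries (%.3g, %.3g); sizes %s\n",
              x$trait, x$b_low, x$b_high,
              paste(table(x$assignment), collapse = "/")))
  invisible(x)
}

#' Bin all seven traits of a cohort
#'
#' @param traits Trait-score data frame as returned by [read_trait_scores()]
#'   or [sample_traits()].
#' @return Named list of [tertile_bins()] results, one per trait.
#' @export
bin_traits <- function(traits) {
  out <- lapply(TRAIT_NAMES, function(tr) {
    v <- traits[[tr]]
    names(v) <- traits$participant_id
    tertile_bins(v, trait = tr)
  })
  names(out) <- TRAIT_NAMES
  out
}

#' Export bin assignments and boundaries as CSV
#'
#' @param bins Named list of `trait_bins` (from [bin_traits()]).
#' @param path Output path for the assignment table
#'   (`trait,participant,bin`).
#' @param boundaries_path Optional output path for the boundary table
#'   (`trait,b_low,b_high`).
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path, boundaries_path = NULL) {
  df <- do.call(rbind, lapply(bins, function(b) {
    data.frame(trait = b$trait, participant = names(b$assignment),
               bin = as.character(b$assignment), stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(boundaries_path)) {
    bd <- do.call(rbind, lapply(bins, function(b) {
      data.frame(trait = b$trait, b_low = b$b_low, b_high = b$b_high)
    }))
    utils::write.csv(bd, boundaries_path, row.names = FALSE)
  }
  invisible(path)
}
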