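# Shared fixtures: hand-built recordings, a brute-force I-DT oracle, and
# random stress traces for detector equivalence checks.

# Build a marked recording from explicit coordinate vectors.
make_recording <- function(x, y = 0.5, pupil = 3, rate = 60, id = "p1",
                           contexts = NULL) {
  n <- length(x)
  samples <- data.frame(t = (seq_len(n) - 1) / rate,
                        x = x, y = rep_len(y, n),
                        pupil = rep_len(pupil, n))
  mark_erroneous_samples(gaze_recording(id, samples, rate = rate,
                                        contexts = contexts))
}

# Independent brute-force dispersion-grouping oracle: plain double loop,
# dispersion recomputed from scratch at every step.
oracle_fixations <- function(rec, thr = 0.025, min_dur = 0.100,
                             max_err = 0.5) {
  s <- rec$samples
  n <- nrow(s)
  disp <- function(i, j) {
    idx <- (i:j)[s$valid[i:j]]
    if (length(idx) == 0) return(0)
    (max(s$x[idx]) - min(s$x[idx])) + (max(s$y[idx]) - min(s$y[idx]))
  }
  rows <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && s$t[j] - s$t[i] < min_dur - 1e-9) j <- j + 1L
    if (j > n) break
    if (disp(i, j) <= thr) {
      while (j + 1L <= n && disp(i, j + 1L) <= thr) j <- j + 1L
      idx <- (i:j)[s$valid[i:j]]
      if (length(idx) > 0 && mean(!s$valid[i:j]) <= max_err) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s$t[i], end = s$t[j],
          x = mean(s$x[idx]), y = mean(s$y[idx]),
          dispersion = disp(i, j),
          pupil_mean = mean(s$pupil[idx]),
          pupil_var = if (length(idx) > 1) stats::var(s$pupil[idx]) else 0,
          erroneous_share = mean(!s$valid[i:j]))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0), x = numeric(0),
                      y = numeric(0), dispersion = numeric(0),
                      pupil_mean = numeric(0), pupil_var = numeric(0),
                      erroneous_share = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Random stress trace mixing stable clusters, drifts, jumps and pupil loss;
# deliberately includes dispersions straddling the threshold.
random_trace <- function(seed, duration = 10, rate = 60) {
  set.seed(seed)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- numeric(n); y <- numeric(n)
  i <- 1L
  px <- runif(1, 0.2, 0.8); py <- runif(1, 0.2, 0.8)
  while (i <= n) {
    len <- sample(3:40, 1)
    idx <- i:min(n, i + len - 1L)
    kind <- sample(c("stable", "drift", "noise"), 1,
                   prob = c(0.5, 0.3, 0.2))
    if (kind == "stable") {
      jit <- runif(1, 0.001, 0.012)
      x[idx] <- px + rnorm(length(idx), 0, jit)
      y[idx] <- py + rnorm(length(idx), 0, jit)
    } else if (kind == "drift") {
      tx <- runif(1, 0.1, 0.9); ty <- runif(1, 0.1, 0.9)
      u <- seq(0, 1, length.out = length(idx))
      x[idx] <- px + (tx - px) * u
      y[idx] <- py + (ty - py) * u
      px <- tx; py <- ty
    } else {
      x[idx] <- runif(length(idx), 0, 1)
      y[idx] <- runif(length(idx), 0, 1)
      px <- x[idx[length(idx)]]; py <- y[idx[length(idx)]]
    }
    i <- idx[length(idx)] + 1L
  }
  pupil <- rep(3.5, n)
  pupil[runif(n) < 0.1] <- NA
  make_recording(x, y, pupil = pupil, rate = rate, id = sprintf("t%d", seed))
}

# Lazily built small cohort shared by integration tests.
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(
      9, strong_effects("extraversion"), seed = 11, duration = 90)
    .fixture_env$featsets <- build_feature_sets(
      .fixture_env$cohort$recordings, sizes = c(15, 30))
  }
  list(cohort = .fixture_env$cohort, featsets = .fixture_env$featsets)
}
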