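#' Define a variability profile for simulation
#'
#' A profile fixes the statistical structure the simulator emulates: a mean
#' RR interval, a baseline short-term variability outside analysis windows,
#' and a target RMSSD for each of the 16 (from, to) window cells.
#'
#' @param window_targets Either a 4x4 non-negative matrix (rows = from,
#'   cols = to, order A-D) of target RMSSD values in ms, or a named numeric
#'   vector with the 16 pair keys (`"AA"`, `"AB"`, ...).
#' @param mean_rr_ms Mean RR interval in ms (default 800, i.e. 75 bpm);
#'   must lie in the physiological range \[300, 2000\].
#' @param baseline_rmssd_ms Target RMSSD outside windows (default 30 ms,
#'   ordinary resting short-term variability).
#' @return A `variability_profile` object.
#' @examples
#' variability_profile(matrix(40, 4, 4))
#' @export
variability_profile <- function(window_targets, mean_rr_ms = 800,
                                baseline_rmssd_ms = 30) {
  if (is.matrix(window_targets)) {
    m <- unclass(window_targets)
    stopifnot(all(dim(m) == c(4, 4)))
    dimnames(m) <- list(from = state_labels(), to = state_labels())
  } else {
    cells <- all_cells()
    keys <- paste0(cells$from, cells$to)
    if (!all(keys %in% names(window_targets))) {
      abort("window_targets must name all 16 pair keys AA..DD",
            class = "affectdyn_invalid_config")
    }
    m <- matrix(window_targets[keys], 4, 4, byrow = TRUE,
                dimnames = list(from = state_labels(), to = state_labels()))
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("all window targets must be positive",
          class = "affectdyn_invalid_config")
  }
  if (mean_rr_ms < 300 || mean_rr_ms > 2000 || baseline_rmssd_ms <= 0) {
    abort("mean_rr_ms must be in [300, 2000] and baseline_rmssd_ms > 0",
          class = "affectdyn_invalid_config")
  }
  structure(
    list(mean_rr_ms = mean_rr_ms, baseline_rmssd_ms = baseline_rmssd_ms,
         window_targets = m),
    class = "variability_profile"
  )
}

#' Target transition matrix implied by a profile
#'
#' Markovizing the window targets gives the transition matrix a noiseless
#' pipeline run would recover; it is the ground truth for
#' [recovery_experiment()].
#'
#' @param profile A [variability_profile()].
#' @return A `transition_matrix`.
#' @export
target_matrix <- function(profile) {
  markovize(profile$window_targets)
}

#' Read a variability profile from JSON
#'
#' Layout: `{"mean_rr_ms": ..., "baseline_rmssd_ms": ...,
#' "window_targets": {"AA": ..., ...16 keys...}}`.
#'
#' @param path JSON file.
#' @return A [variability_profile()].
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  variability_profile(unlist(obj$window_targets),
                      mean_rr_ms = obj$mean_rr_ms,
                      baseline_rmssd_ms = obj$baseline_rmssd_ms)
}

#' Simulate an RR-interval recording over the protocol timeline
#'
#' Generates beats covering the 1560-s stimulus period as independent
#' Gaussian levels: each interval is `clip(mean_rr_ms + e)` with `e` a
#' zero-mean normal deviate whose standard deviation is `sigma / sqrt(2)`,
#' where `sigma` is the RMSSD target of the analysis window the beat falls
#' in, or `baseline_rmssd_ms` between windows. For independent levels with
#' variance `sigma^2 / 2` the successive differences have variance
#' `sigma^2`, so the expected RMSSD in each window is approximately its
#' target — the property parameter-recovery tests rely on. The model is a
#' test scaffold with analytically controllable variability, not a
#' physiological heart model.
#'
#' @param schedule A valid `block_schedule`.
#' @param windows The matching `window_set`.
#' @param profile A [variability_profile()].
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param clip_bounds_ms Physiological clip bounds in ms
#'   (default `c(300, 2000)`); clipping bias is negligible for targets up
#'   to ~100 ms at a mean of 800 ms.
#' @return An [rr_series()] whose last beat time is at or past 1560 s.
#' @export
simulate_rr <- function(schedule, windows, profile, seed,
                        clip_bounds_ms = c(300, 2000)) {
  stopifnot(inherits(profile, "variability_profile"))
  if (length(clip_bounds_ms) != 2 || clip_bounds_ms[1] >= clip_bounds_ms[2]) {
    abort("clip_bounds_ms must be an ordered pair",
          class = "affectdyn_invalid_config")
  }
  total_s <- length(schedule$states) * schedule$block_duration_s
  w_start <- windows$t_start_s
  w_end <- windows$t_end_s
  w_sigma <- profile$window_targets[cbind(windows$from_state,
                                          windows$to_state)]
  sigma_at <- function(t) {
    hit <- which(t >= w_start & t < w_end)
    if (length(hit) > 0) w_sigma[hit[1]] else profile$baseline_rmssd_ms
  }
  withr::with_seed(as.integer(seed), {
    t <- 0
    out <- numeric(ceiling(total_s * 1000 / clip_bounds_ms[1]))
    n <- 0L
    while (t < total_s) {
      sd_ms <- sigma_at(t) / sqrt(2)
      rr <- profile$mean_rr_ms + rnorm(1, 0, sd_ms)
      rr <- min(max(rr, clip_bounds_ms[1]), clip_bounds_ms[2])
      n <- n + 1L
      out[n] <- rr
      t <- t + rr / 1000
    }
    rr_series(out[seq_len(n)])
  })
}

#' Inject beat-detection artifacts into an RR series
#'
#' Two canonical artifact shapes: `ectopic_split` replaces a selected
#' interval `RR` by the premature-beat pair `(0.4 RR, 0.6 RR)`, and
#' `missed_merge` replaces two adjacent intervals by their sum (a missed
#' R-peak). Selections are uniform without replacement at the given rate;
#' total recording duration is preserved exactly.
#'
#' @param rr An [rr_series()].
#' @param kind `"ectopic_split"` or `"missed_merge"`.
#' @param rate Fraction of intervals affected, in `[0, 0.2)`.
#' @param seed Integer seed.
#' @return A new [rr_series()] with the artifacts in place.
#' @export
inject_artifacts <- function(rr, kind = c("ectopic_split", "missed_merge"),
                             rate, seed) {
  kind <- match.arg(kind)
  if (!is.numeric(rate) || rate < 0 || rate >= 0.2) {
    abort("rate must lie in [0, 0.2)", class = "affectdyn_invalid_config")
  }
  x <- rr$rr_ms
  origin <- attr(rr, "origin_offset_s") %||% 0
  n <- length(x)
  n_events <- floor(rate * n)
  if (n_events == 0) return(rr)
  withr::with_seed(as.integer(seed), {
    if (kind == "ectopic_split") {
      idx <- sort(sample.int(n, n_events))
      pieces <- lapply(seq_len(n), function(i) {
        if (i %in% idx) c(0.4 * x[i], 0.6 * x[i]) else x[i]
      })
      rr_series(unlist(pieces), origin_offset_s = origin)
    } else {
      # merge pairs (i, i+1); draw starts among odd positions so no two
      # merges share an interval
      starts <- seq(1L, n - 1L, by = 2L)
      idx <- sort(sample(starts, min(n_events, length(starts))))
      drop <- idx + 1L
      y <- x
      y[idx] <- x[idx] + x[drop]
      rr_series(y[-drop], origin_offset_s = origin)
    }
  })
}

#' Parameter-recovery experiment for the full pipeline
#'
#' Runs simulate -> (optional artifact injection) -> artifact correction ->
#' windowed RMSSD -> Markovization once per seed and summarises, per matrix
#' cell, how well the recovered transition probabilities match the
#' profile's target matrix.
#'
#' @param profile A [variability_profile()].
#' @param n_seeds Number of replicate simulations (at least 10).
#' @param schedule_seed Seed for the block schedule (one schedule shared by
#'   all replicates, as in a real session; default 1).
#' @param artifact_rate If positive, inject artifacts at this rate before
#'   correction (half ectopic splits, half missed merges).
#' @param correction_level Level passed to [correct_artifacts()]
#'   (default `"none"`, matching artifact-free data).
#' @return A `recovery_summary` tibble with one row per cell: `from`, `to`,
#'   `target`, `median_estimate`, `median_abs_error`, `median_rel_error`;
#'   the per-seed recovered matrices are kept in attribute `"estimates"`.
#' @export
recovery_experiment <- function(profile, n_seeds, schedule_seed = 1,
                                artifact_rate = 0, correction_level = "none") {
  if (!is.numeric(n_seeds) || n_seeds < 10) {
    abort("n_seeds must be at least 10 for stable medians",
          class = "affectdyn_invalid_config")
  }
  schedule <- generate_schedule(schedule_seed)
  windows <- place_windows(schedule)
  target <- target_matrix(profile)
  ests <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    est <- tryCatch({
      rr <- simulate_rr(schedule, windows, profile, seed = s)
      if (artifact_rate > 0) {
        rr <- inject_artifacts(rr, "ectopic_split", artifact_rate / 2,
                               seed = s * 2L)
        rr <- inject_artifacts(rr, "missed_merge", artifact_rate / 2,
                               seed = s * 2L + 1L)
      }
      rr <- correct_artifacts(rr, correction_level)$rr
      markovize(windowed_rmssd(rr, windows))
    }, error = function(e) {
      abort(sprintf("pipeline failed at seed %d: %s", s,
                    conditionMessage(e)),
            class = "affectdyn_recovery_error", parent = e)
    })
    ests[[s]] <- unclass(est)
  }
  arr <- simplify2array(ests)
  cells <- all_cells()
  per_cell <- function(f) {
    vapply(seq_len(16), function(k) {
      i <- match(cells$from[k], state_labels())
      j <- match(cells$to[k], state_labels())
      f(arr[i, j, ], unclass(target)[i, j])
    }, numeric(1))
  }
  out <- tibble::tibble(
    from = cells$from, to = cells$to,
    target = unclass(target)[cbind(cells$from, cells$to)],
    median_estimate = per_cell(function(e, t) median(e)),
    median_abs_error = per_cell(function(e, t) median(abs(e - t))),
    median_rel_error = per_cell(function(e, t) median(abs(e - t) / t))
  )
  attr(out, "estimates") <- arr
  class(out) <- c("recovery_summary", class(out))
  out
}
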