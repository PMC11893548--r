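#' Construct an RR-interval series
#'
#' An `rr_series` is a tibble of consecutive beat-to-beat intervals with the
#' derived time of each interval's terminating beat. Beat times are the
#' cumulative interval sums in seconds, shifted by `origin_offset_s`, which
#' aligns the recording clock to the protocol clock (t = 0 at
#' first-stimulus onset).
#'
#' @param intervals_ms Numeric vector of positive RR intervals in ms.
#' @param origin_offset_s Recording time of the series start relative to
#'   protocol t = 0 (default 0).
#' @param beat_times_s Optional explicit terminating-beat times (s); must be
#'   strictly increasing and consistent with the intervals.
#' @return A tibble of class `rr_series` with columns `beat_time_s`, `rr_ms`
#'   and attribute `origin_offset_s`.
#' @examples
#' rr_series(c(800, 810, 790))
#' @export
rr_series <- function(intervals_ms, origin_offset_s = 0, beat_times_s = NULL) {
  intervals_ms <- as.numeric(intervals_ms)
  if (length(intervals_ms) == 0) {
    abort("RR series is empty", class = "affectdyn_parse_error")
  }
  bad <- which(!is.finite(intervals_ms) | intervals_ms <= 0)
  if (length(bad) > 0) {
    abort(sprintf("non-positive or non-numeric RR interval at position %d",
                  bad[1]),
          class = "affectdyn_parse_error")
  }
  if (is.null(beat_times_s)) {
    beat_times_s <- origin_offset_s + cumsum(intervals_ms) / 1000
  } else {
    if (any(diff(beat_times_s) <= 0)) {
      abort("beat times must be strictly increasing",
            class = "affectdyn_parse_error")
    }
  }
  out <- tibble::tibble(beat_time_s = beat_times_s, rr_ms = intervals_ms)
  attr(out, "origin_offset_s") <- origin_offset_s
  class(out) <- c("rr_series", class(out))
  out
}

#' Read an RR-interval recording
#'
#' Two plain-text layouts are supported: `plain` has one interval in ms per
#' line (beat times derived cumulatively from `origin_offset_s`), and
#' `timed_csv` has a header `beat_time_s,rr_ms` with explicit beat times.
#'
#' @param path File path.
#' @param format `"plain"` or `"timed_csv"`.
#' @param origin_offset_s Protocol-clock offset of the recording start,
#'   used by the `plain` format (default 0).
#' @return An [rr_series()].
#' @examples
#' f <- tempfile()
#' writeLines(c("800", "810", "790"), f)
#' read_rr(f)
#' @export
read_rr <- function(path, format = c("plain", "timed_csv"),
                    origin_offset_s = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "affectdyn_io_error")
  }
  if (format == "plain") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    keep <- nzchar(lines)
    if (!any(keep)) abort("empty RR file", class = "affectdyn_parse_error")
    line_no <- which(keep)
    vals <- suppressWarnings(as.numeric(lines[keep]))
    bad <- which(!is.finite(vals) | vals <= 0)
    if (length(bad) > 0) {
      abort(sprintf("invalid RR interval %s at line %d",
                    lines[keep][bad[1]], line_no[bad[1]]),
            class = "affectdyn_parse_error")
    }
    rr_series(vals, origin_offset_s = origin_offset_s)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(beat_time_s = "d",
                                                  rr_ms = "d"))
    if (nrow(df) == 0) abort("empty RR file", class = "affectdyn_parse_error")
    if (any(!is.finite(df$rr_ms) | df$rr_ms <= 0)) {
      bad <- which(!is.finite(df$rr_ms) | df$rr_ms <= 0)[1]
      abort(sprintf("invalid RR interval at line %d", bad + 1L),
            class = "affectdyn_parse_error")
    }
    rr_series(df$rr_ms, origin_offset_s = df$beat_time_s[1] -
                df$rr_ms[1] / 1000,
              beat_times_s = df$beat_time_s)
  }
}

artifact_thresholds <- c(very_low = 450, low = 350, medium = 250,
                         strong = 150, very_strong = 50)

#' Correct artifact beats with a threshold-level rule
#'
#' Ectopic beats and missed detections show up as RR intervals far from
#' their local context. An interval is flagged when it deviates from the
#' median of its 11-beat neighbourhood (5 beats each side, the interval
#' itself excluded) by more than the level's threshold: `very_low` 450 ms,
#' `low` 350 ms, `medium` 250 ms, `strong` 150 ms, `very_strong` 50 ms.
#' Flagged intervals are replaced by linear interpolation between the
#' nearest unflagged neighbours; unflagged intervals are returned unchanged.
#' Level `"none"` is the identity.
#'
#' @param rr An [rr_series()] of at least 5 intervals.
#' @param level Correction level, one of `"none"`, `"very_low"`, `"low"`,
#'   `"medium"`, `"strong"`, `"very_strong"`.
#' @return A list with `rr` (corrected series, beat times recomputed) and
#'   `report` (an `artifact_report`: `n_flagged`, `flagged_indices`,
#'   `correction_level`, `threshold_ms`).
#' @examples
#' rr <- rr_series(c(rep(800, 10), 1600, rep(800, 10)))
#' correct_artifacts(rr, "medium")$report$n_flagged
#' @export
correct_artifacts <- function(rr, level = c("medium", "none", "very_low",
                                            "low", "strong", "very_strong")) {
  level <- match.arg(level)
  x <- rr$rr_ms
  origin <- attr(rr, "origin_offset_s") %||% 0
  if (level == "none") {
    report <- new_artifact_report(integer(0), level, NA_real_)
    return(list(rr = rr, report = report))
  }
  n <- length(x)
  if (n < 5) {
    abort("need at least 5 intervals for neighbourhood medians",
          class = "affectdyn_insufficient_beats")
  }
  thr <- artifact_thresholds[[level]]
  local_med <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - 5L):min(n, i + 5L)
    median(x[setdiff(idx, i)])
  }, numeric(1))
  flagged <- which(abs(x - local_med) > thr)
  if (length(flagged) == n) {
    abort("every interval flagged as artifact; series uncorrectable",
          class = "affectdyn_uncorrectable_series")
  }
  y <- x
  if (length(flagged) > 0) {
    good <- setdiff(seq_len(n), flagged)
    y[flagged] <- stats::approx(good, x[good], xout = flagged,
                                rule = 2)$y
  }
  list(rr = rr_series(y, origin_offset_s = origin),
       report = new_artifact_report(flagged, level, thr))
}

new_artifact_report <- function(flagged, level, threshold_ms) {
  structure(
    list(n_flagged = length(flagged), flagged_indices = as.integer(flagged),
         correction_level = level, threshold_ms = threshold_ms),
    class = "artifact_report"
  )
}

#' Root mean square of successive differences (RMSSD)
#'
#' The time-domain HRV index reflecting vagally mediated beat-to-beat
#' variability: `sqrt(mean((RR[i+1] - RR[i])^2))` over the N - 1 successive
#' differences of N intervals, in ms.
#'
#' @param x Numeric vector of RR intervals in ms, or an [rr_series()].
#' @return RMSSD in ms (non-negative scalar).
#' @examples
#' rmssd(c(800, 810, 790)) # sqrt(250)
#' @export
rmssd <- function(x) {
  if (inherits(x, "rr_series")) x <- x$rr_ms
  x <- as.numeric(x)
  if (length(x) < 2) {
    abort("RMSSD needs at least 2 intervals",
          class = "affectdyn_insufficient_beats")
  }
  sqrt(mean(diff(x)^2))
}

#' Mean heart rate and equivalent mean RR
#'
#' @param x Numeric RR intervals in ms, or an [rr_series()].
#' @return A one-row tibble with `hr_bpm` (= 60000 / mean RR) and
#'   `rr_mean_ms`.
#' @examples
#' mean_hr(c(600, 1000)) # 75 bpm
#' @export
mean_hr <- function(x) {
  if (inherits(x, "rr_series")) x <- x$rr_ms
  x <- as.numeric(x)
  if (length(x) < 1) {
    abort("need at least one interval", class = "affectdyn_insufficient_beats")
  }
  rr_mean <- mean(x)
  tibble::tibble(hr_bpm = 60000 / rr_mean, rr_mean_ms = rr_mean)
}

#' Windowed RMSSD over the protocol's analysis windows
#'
#' For each of the 16 analysis windows, selects the intervals whose
#' terminating beat time lies in `[t_start_s, t_end_s)` and computes RMSSD
#' over them, writing the value into cell (from_state, to_state) of a 4x4
#' matrix. Every cell is filled exactly once.
#'
#' @param rr A corrected [rr_series()].
#' @param windows A `window_set` from [place_windows()].
#' @param min_intervals Minimum intervals per window (default 3); a window
#'   with fewer is an error, since RMSSD from a single difference is
#'   meaningless.
#' @return An `rmssd_matrix`: 4x4 numeric matrix, rows = from-state,
#'   columns = to-state, ordered A-D.
#' @export
windowed_rmssd <- function(rr, windows, min_intervals = 3) {
  stopifnot(nrow(windows) == 16)
  m <- matrix(NA_real_, 4, 4,
              dimnames = list(from = state_labels(), to = state_labels()))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    sel <- rr$rr_ms[rr$beat_time_s >= w$t_start_s &
                      rr$beat_time_s < w$t_end_s]
    if (length(sel) < min_intervals) {
      abort(sprintf(
        "window %s->%s [%g, %g) has %d interval(s), below min_intervals = %d",
        w$from_state, w$to_state, w$t_start_s, w$t_end_s, length(sel),
        min_intervals),
        class = "affectdyn_sparse_window")
    }
    m[w$from_state, w$to_state] <- rmssd(sel)
  }
  new_rmssd_matrix(m)
}

new_rmssd_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)),
            all(is.finite(m)), all(m >= 0))
  dimnames(m) <- list(from = state_labels(), to = state_labels())
  class(m) <- c("rmssd_matrix", "matrix", "array")
  m
}

#' Write a 4x4 matrix as labelled CSV
#'
#' @param m An `rmssd_matrix` or `transition_matrix`.
#' @param path File path; the state labels form the header row and first
#'   column.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(unclass(m), .name_repair = "minimal")
  names(df) <- state_labels()
  df <- dplyr::bind_cols(tibble::tibble(state = state_labels()), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a 4x4 labelled matrix CSV
#'
#' @param path CSV with a `state` label column and columns `A`-`D`.
#' @return A plain numeric 4x4 matrix (validate with [markovize()] or
#'   [as_transition_matrix()]).
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, state_labels()])
  rownames(m) <- df[[1]]
  m <- m[state_labels(), state_labels()]
  dimnames(m) <- list(from = state_labels(), to = state_labels())
  m
}
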