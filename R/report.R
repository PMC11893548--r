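#' Run the full analysis pipeline on a recording
#'
#' Reads the RR recording and block schedule, places the analysis windows,
#' corrects artifacts, computes windowed RMSSD, Markovizes, extracts the
#' grouped indexes and computes the steady state by both methods. When
#' `out_dir` is given, writes `report.json`, `rmssd_matrix.csv`,
#' `transition_matrix.csv` and `transition_graph.dot` there; outputs are
#' deterministic, so identical inputs give byte-identical files.
#'
#' @param rr_path RR recording file.
#' @param schedule_path Schedule JSON (see [write_schedule()]).
#' @param rr_format Format of `rr_path` (see [read_rr()]).
#' @param correction_level Artifact-correction level (default `"medium"`).
#' @param protocol_start_s Recording time at first-stimulus onset; the
#'   recording is shifted so analysis time 0 is that instant (default 0).
#' @param steps Power-iteration steps (default 10).
#' @param min_intervals Minimum beats per window (see [windowed_rmssd()]).
#' @param out_dir Optional output directory, created if needed.
#' @return An `affect_report` object: list with `rmssd_matrix`,
#'   `transition_matrix`, `indexes`, `steady_power`, `steady_eigen`,
#'   `artifact_report`, `provenance`.
#' @export
run_pipeline <- function(rr_path, schedule_path, rr_format = "plain",
                         correction_level = "medium", protocol_start_s = 0,
                         steps = 10, min_intervals = 3, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)),
            class = c(paste0("affectdyn_stage_", name), "affectdyn_stage_error"),
            parent = e)
    })
  }
  schedule <- stage("schedule", read_schedule(schedule_path))
  windows <- stage("windowing", place_windows(schedule))
  rr <- stage("read", read_rr(rr_path, format = rr_format,
                              origin_offset_s = -protocol_start_s))
  corrected <- stage("correction", correct_artifacts(rr, correction_level))
  rmat <- stage("windowing", windowed_rmssd(corrected$rr, windows,
                                            min_intervals = min_intervals))
  P <- stage("markovization", markovize(rmat))
  report <- structure(
    list(
      rmssd_matrix = rmat,
      transition_matrix = P,
      indexes = grouped_indexes(P),
      steady_power = steady_state_power(P, steps = steps),
      steady_eigen = steady_state_eigen(P),
      artifact_report = corrected$report,
      provenance = list(
        rr_path = rr_path, schedule_path = schedule_path,
        correction_level = correction_level,
        protocol_start_s = protocol_start_s, steps = steps,
        package_version = as.character(utils::packageVersion("affectdyn"))
      )
    ),
    class = "affect_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(out_dir, "report.json"))
    write_matrix_csv(rmat, file.path(out_dir, "rmssd_matrix.csv"))
    write_matrix_csv(P, file.path(out_dir, "transition_matrix.csv"))
    export_graph(P, file.path(out_dir, "transition_graph.dot"))
  }
  report
}

#' Serialize an analysis report to JSON
#'
#' The layout mirrors the report object: the raw and Markovized matrices
#' (row-major, labelled), the four index groups, both steady-state results
#' and the artifact report. No timestamps, so serialization is
#' deterministic and round-trips losslessly.
#'
#' @param report An `affect_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  mat_list <- function(m) {
    m <- unclass(as.matrix(m))
    stats::setNames(lapply(seq_len(4), function(i) {
      as.list(stats::setNames(m[i, ], state_labels()))
    }), state_labels())
  }
  ss_list <- function(ss) {
    list(method = ss$method,
         n_steps = if (is.na(ss$n_steps)) NULL else ss$n_steps,
         distribution = as.list(unclass(ss$distribution)),
         converged = ss$converged,
         max_abs_change = ss$max_abs_change)
  }
  obj <- list(
    rmssd_matrix = mat_list(report$rmssd_matrix),
    transition_matrix = mat_list(report$transition_matrix),
    indexes = lapply(unclass(report$indexes), as.list),
    steady_state = list(power = ss_list(report$steady_power),
                        eigen = ss_list(report$steady_eigen)),
    artifact_report = list(
      n_flagged = report$artifact_report$n_flagged,
      flagged_indices = report$artifact_report$flagged_indices,
      correction_level = report$artifact_report$correction_level,
      threshold_ms = report$artifact_report$threshold_ms
    ),
    provenance = report$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

group_colors <- c(vertical = "green", horizontal = "yellow",
                  oblique = "orange", self = "gray")

#' Export the transition graph in Graphviz DOT format
#'
#' Emits a digraph with four nodes (state letter plus quadrant name) and
#' all 16 directed edges including self-loops. Each edge is labelled with
#' its probability to two decimals, carries the percentage as a secondary
#' external label, and is coloured by transition group: vertical green,
#' horizontal yellow, oblique orange, self gray.
#'
#' @param P A `transition_matrix`.
#' @param path Output `.dot` file.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".dot")
#' export_graph(markovize(matrix(1, 4, 4)), f)
#' @export
export_graph <- function(P, path) {
  m <- unclass(as.matrix(P))
  st <- affect_states()
  lines <- c("digraph affect_transitions {",
             "  rankdir=LR;",
             "  node [shape=circle, style=filled, fillcolor=white];")
  for (i in seq_len(4)) {
    lines <- c(lines, sprintf('  %s [label="%s\\n%s"];',
                              st$state[i], st$state[i], st$name[i]))
  }
  cells <- all_cells()
  for (k in seq_len(16)) {
    from <- cells$from[k]
    to <- cells$to[k]
    g <- transition_group(from, to)
    p <- m[from, to]
    lines <- c(lines, sprintf(
      '  %s -> %s [label="%.2f" xlabel="%.0f%%" color=%s];',
      from, to, p, 100 * p, group_colors[[g]]))
  }
  lines <- c(lines, "}")
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot write DOT file: %s", path),
          class = "affectdyn_io_error")
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @export
print.affect_report <- function(x, ...) {
  cat("Affect-dynamics analysis report\n")
  cat("Transition matrix (rows = from, cols = to):\n")
  print(round(unclass(x$transition_matrix), 2))
  cat(sprintf("Artifacts: %d beat(s) corrected at level '%s'\n",
              x$artifact_report$n_flagged,
              x$artifact_report$correction_level))
  p <- x$steady_power$distribution
  cat(sprintf("Steady state (power, %d steps): %s\n", x$steady_power$n_steps,
              paste(sprintf("%s=%.2f", names(p), p), collapse = " ")))
  invisible(x)
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s%s): %s\n", x$method,
              if (!is.na(x$n_steps)) sprintf(", %d steps", x$n_steps) else "",
              paste(sprintf("%s=%.3f", names(x$distribution),
                            x$distribution), collapse = " ")))
  invisible(x)
}
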