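#' Tidy a transition or RMSSD matrix into long form
#'
#' @param x A `transition_matrix` or `rmssd_matrix`.
#' @param ... Unused.
#' @return A 16-row tibble with `from`, `to`, `pair`, `group` and the value
#'   column (`prob` for transition matrices, `rmssd_ms` for RMSSD matrices).
#' @export
tidy.transition_matrix <- function(x, ...) {
  out <- all_cells()
  out$pair <- paste0(out$from, out$to)
  out$group <- transition_group(out$from, out$to)
  out$prob <- unclass(x)[cbind(out$from, out$to)]
  out
}

#' @rdname tidy.transition_matrix
#' @export
tidy.rmssd_matrix <- function(x, ...) {
  out <- all_cells()
  out$pair <- paste0(out$from, out$to)
  out$group <- transition_group(out$from, out$to)
  out$rmssd_ms <- unclass(x)[cbind(out$from, out$to)]
  out
}

#' Tidy a steady-state result
#'
#' @param x A `steady_state`.
#' @param ... Unused.
#' @return A 4-row tibble with `state` and `prob`.
#' @export
tidy.steady_state <- function(x, ...) {
  tibble::tibble(state = state_labels(),
                 prob = as.numeric(x$distribution))
}

#' One-row summary of a steady-state computation
#'
#' @param x A `steady_state`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_steps`, `converged`,
#'   `max_abs_change`.
#' @export
glance.steady_state <- function(x, ...) {
  tibble::tibble(method = x$method, n_steps = x$n_steps,
                 converged = x$converged, max_abs_change = x$max_abs_change)
}

#' Tidy the grouped transition indexes
#'
#' @param x A `markov_indexes`.
#' @param ... Unused.
#' @return A 16-row tibble with `group`, `pair`, `from`, `to`, `prob`.
#' @export
tidy.markov_indexes <- function(x, ...) {
  purrr::map_dfr(names(unclass(x)), function(g) {
    v <- x[[g]]
    tibble::tibble(group = g, pair = names(v),
                   from = substr(names(v), 1, 1),
                   to = substr(names(v), 2, 2),
                   prob = as.numeric(v))
  })
}

#' Heatmap of a transition matrix
#'
#' @param object A `transition_matrix`.
#' @param ... Unused.
#' @return A ggplot: 4x4 tile plot with probabilities printed to two
#'   decimals, rows = origin state (top to bottom A-D).
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tidy.transition_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to,
                                   y = factor(.data$from,
                                              levels = rev(state_labels())),
                                   fill = .data$prob)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "to state", y = "from state", fill = "P",
                  title = "Affective transition probabilities") +
    ggplot2::theme_minimal()
}

#' Tachogram of an RR series
#'
#' @param object An `rr_series`.
#' @param windows Optional `window_set` shaded behind the trace.
#' @param ... Unused.
#' @return A ggplot of RR interval against beat time.
#' @export
autoplot.rr_series <- function(object, windows = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$beat_time_s, y = .data$rr_ms))
  if (!is.null(windows)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(windows),
      ggplot2::aes(xmin = .data$t_start_s, xmax = .data$t_end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$kind),
      alpha = 0.2, inherit.aes = FALSE)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "RR (ms)", title = "Tachogram") +
    ggplot2::theme_minimal()
}

#' Bar chart of a steady-state distribution
#'
#' @param object A `steady_state`.
#' @param ... Unused.
#' @return A ggplot of per-state long-run probabilities.
#' @export
autoplot.steady_state <- function(object, ...) {
  df <- tidy.steady_state(object)
  df$name <- affect_states()$name
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob)),
                       vjust = -0.4) +
    ggplot2::labs(x = "state", y = "long-run probability",
                  title = sprintf("Steady state (%s)", object$method)) +
    ggplot2::theme_minimal()
}
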