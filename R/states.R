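#' The circumplex affect state space
#'
#' The four quadrants of the valence-arousal circumplex used throughout the
#' package: stress (A: high arousal, negative valence), engagement (B: high
#' arousal, positive), boredom (C: low arousal, negative) and relaxation
#' (D: low arousal, positive). The mapping is a fixed constant of the method,
#' not a tunable.
#'
#' @return A tibble with columns `state`, `name`, `arousal`, `valence`.
#' @examples
#' affect_states()
#' @export
affect_states <- function() {
  tibble::tibble(
    state   = c("A", "B", "C", "D"),
    name    = c("stress", "engagement", "boredom", "relaxation"),
    arousal = c("high", "high", "low", "low"),
    valence = c("negative", "positive", "negative", "positive")
  )
}

state_labels <- function() c("A", "B", "C", "D")

#' Classify a directed state pair into its transition group
#'
#' Transitions between quadrants fall into four named groups: `self`
#' (no change), `vertical` (same valence, opposite arousal: AC, CA, BD, DB),
#' `horizontal` (same arousal, opposite valence: AB, BA, CD, DC) and
#' `oblique` (both axes change: AD, DA, BC, CB).
#'
#' @param from,to Character vectors of state labels in `A`-`D` (recycled).
#' @return Character vector of group names.
#' @examples
#' transition_group("A", "C") # vertical
#' transition_group(c("A", "D"), c("B", "C"))
#' @export
transition_group <- function(from, to) {
  st <- affect_states()
  stopifnot(all(from %in% st$state), all(to %in% st$state))
  n <- max(length(from), length(to))
  from <- rep_len(from, n)
  to <- rep_len(to, n)
  ar <- stats::setNames(st$arousal, st$state)
  va <- stats::setNames(st$valence, st$state)
  dplyr::case_when(
    from == to ~ "self",
    va[from] == va[to] ~ "vertical",
    ar[from] == ar[to] ~ "horizontal",
    .default = "oblique"
  )
}

# all 16 directed cells in fixed row-major order A..D x A..D
all_cells <- function() {
  tibble::tibble(
    from = rep(state_labels(), each = 4),
    to = rep(state_labels(), times = 4)
  )
}
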