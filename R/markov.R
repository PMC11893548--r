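#' Markovize a windowed RMSSD matrix
#'
#' Row-relativizes the 4x4 matrix of window-wise RMSSD values into a
#' row-stochastic transition matrix: `P[i, j] = raw[i, j] / sum(raw[i, ])`,
#' the self cell included in the denominator. Each row then gives the
#' relative share of short-term cardiac variability that state `i` exhibits
#' toward each destination state, read as the probability of the affective
#' transition `i -> j`.
#'
#' @param raw An `rmssd_matrix` or any 4x4 non-negative matrix with strictly
#'   positive row sums.
#' @return A `transition_matrix` (4x4, rows summing to 1).
#' @examples
#' m <- matrix(c(10, 20, 30, 40), 4, 4, byrow = TRUE)
#' markovize(m)
#' @export
markovize <- function(raw) {
  m <- unclass(as.matrix(raw))
  stopifnot(all(dim(m) == c(4, 4)))
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("RMSSD matrix entries must be finite and non-negative",
          class = "affectdyn_invalid_input")
  }
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort(sprintf("zero-sum row for state %s: cannot normalize",
                  state_labels()[which(rs <= 0)[1]]),
          class = "affectdyn_degenerate_row")
  }
  new_transition_matrix(m / rs)
}

new_transition_matrix <- function(m) {
  dimnames(m) <- list(from = state_labels(), to = state_labels())
  class(m) <- c("transition_matrix", "matrix", "array")
  m
}

#' Validate (and optionally renormalize) a transition matrix
#'
#' Accepts a user-supplied 4x4 probability matrix. Published matrices are
#' typically rounded to two decimals, so rows may sum to slightly off 1;
#' row sums within `tol` of 1 are accepted. By default rows are then
#' renormalized to sum exactly 1; with `renormalize = FALSE` the entries are
#' kept as given, which is what exact reproduction of figures computed from
#' rounded values requires.
#'
#' @param x A 4x4 numeric matrix of probabilities.
#' @param renormalize Divide each row by its sum (default `TRUE`).
#' @param tol Acceptable absolute deviation of a row sum from 1
#'   (default 0.02, two units in the last printed decimal place).
#' @return A `transition_matrix`.
#' @export
as_transition_matrix <- function(x, renormalize = TRUE, tol = 0.02) {
  m <- unclass(as.matrix(x))
  stopifnot(all(dim(m) == c(4, 4)))
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    abort("entries must be probabilities in [0, 1]",
          class = "affectdyn_invalid_input")
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    abort(sprintf("row sum for state %s is %.4f, outside 1 +/- %g",
                  state_labels()[which.max(abs(rs - 1))],
                  rs[which.max(abs(rs - 1))], tol),
          class = "affectdyn_invalid_input")
  }
  if (renormalize) m <- m / rs
  new_transition_matrix(m)
}

#' The uniform initial state distribution
#'
#' The a-priori state vector used before any stimulus: equiprobability over
#' the four quadrants, (0.25, 0.25, 0.25, 0.25).
#'
#' @return A `state_distribution` (named numeric vector over A-D).
#' @examples
#' uniform_initial()
#' @export
uniform_initial <- function() {
  new_state_distribution(rep(0.25, 4))
}

new_state_distribution <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 4)
  names(p) <- state_labels()
  class(p) <- c("state_distribution", "numeric")
  p
}

#' One Markov step: distribution times transition matrix
#'
#' @param pi A `state_distribution` (or numeric 4-vector).
#' @param P A `transition_matrix`.
#' @return The row-vector product `pi %*% P` as a `state_distribution`.
#' @examples
#' step_distribution(uniform_initial(), markovize(matrix(1, 4, 4)))
#' @export
step_distribution <- function(pi, P) {
  new_state_distribution(as.numeric(unclass(pi) %*% unclass(P)))
}

#' Steady state by power iteration
#'
#' Iterates `pi <- pi %*% P` for `steps` steps from `pi0`, mirroring the
#' clinical read-out of "where does the patient end up after n hypothetical
#' transitions". Convergence is declared when the last step changes no
#' entry by more than `tol` (sup norm). By default the final vector is
#' renormalized to sum 1, guarding against drift when the rows of `P` carry
#' rounding error; set `renormalize = FALSE` to keep the raw product, as
#' published figures computed from two-decimal matrices do.
#'
#' @param P A `transition_matrix`.
#' @param pi0 Initial distribution (default [uniform_initial()]).
#' @param steps Number of multiplications (default 10).
#' @param tol Sup-norm convergence tolerance (default 1e-8).
#' @param renormalize Rescale the final vector to sum 1 (default `TRUE`).
#' @return A `steady_state` object: list with `distribution`, `method =
#'   "power"`, `n_steps`, `converged`, `max_abs_change`.
#' @examples
#' P <- markovize(matrix(runif(16), 4, 4))
#' steady_state_power(P)
#' @export
steady_state_power <- function(P, pi0 = uniform_initial(), steps = 10,
                               tol = 1e-8, renormalize = TRUE) {
  stopifnot(steps >= 1)
  pi <- unclass(pi0)
  change <- NA_real_
  for (k in seq_len(steps)) {
    nxt <- as.numeric(pi %*% unclass(P))
    change <- max(abs(nxt - pi))
    pi <- nxt
  }
  if (renormalize) pi <- pi / sum(pi)
  structure(
    list(distribution = new_state_distribution(pi), method = "power",
         n_steps = as.integer(steps), converged = change <= tol,
         max_abs_change = change),
    class = "steady_state"
  )
}

#' Steady state by the eigenvector method
#'
#' The stationary distribution is the left eigenvector of `P` for
#' eigenvalue 1, normalized to sum 1. It is unique when the chain is
#' irreducible and aperiodic, which is checked through the spectral gap:
#' a second eigenvalue of modulus (numerically) 1 means a reducible or
#' periodic chain and is an error rather than an arbitrary answer.
#'
#' @param P A `transition_matrix` with rows summing to 1.
#' @return A `steady_state` object (`method = "eigen"`, no `n_steps`); its
#'   distribution satisfies `max(abs(pi %*% P - pi)) <= 1e-8`.
#' @examples
#' steady_state_eigen(markovize(matrix(1, 4, 4)))
#' @export
steady_state_eigen <- function(P) {
  m <- unclass(as.matrix(P))
  if (max(abs(rowSums(m) - 1)) > 1e-6) {
    abort("rows must sum to 1; renormalize first (as_transition_matrix)",
          class = "affectdyn_invalid_input")
  }
  e <- eigen(t(m))
  mods <- Mod(e$values)
  ord <- order(mods, decreasing = TRUE)
  if (mods[ord[2]] >= 1 - 1e-8) {
    abort("chain is reducible or periodic: steady state not unique",
          class = "affectdyn_non_unique_steady_state")
  }
  v <- Re(e$vectors[, ord[1]])
  v <- v / sum(v)
  v <- pmax(v, 0)
  v <- v / sum(v)
  structure(
    list(distribution = new_state_distribution(v), method = "eigen",
         n_steps = NA_integer_, converged = TRUE,
         max_abs_change = max(abs(as.numeric(v %*% m) - v))),
    class = "steady_state"
  )
}

#' Grouped descriptive transition indexes
#'
#' Partitions the 16 transition probabilities into the four clinically read
#' groups: vertical (AC, CA, BD, DB: same valence, opposite arousal),
#' horizontal (AB, BA, CD, DC: same arousal, opposite valence), oblique
#' (AD, DA, BC, CB: both change) and self (AA, BB, CC, DD: staying put).
#'
#' @param P A `transition_matrix`.
#' @return A `markov_indexes` object: list of four named numeric vectors
#'   keyed by pair (e.g. `"DC"`), jointly covering all 16 cells.
#' @examples
#' grouped_indexes(markovize(matrix(1, 4, 4)))$self
#' @export
grouped_indexes <- function(P) {
  m <- unclass(as.matrix(P))
  cells <- all_cells()
  cells$pair <- paste0(cells$from, cells$to)
  cells$group <- transition_group(cells$from, cells$to)
  cells$prob <- m[cbind(cells$from, cells$to)]
  out <- lapply(
    stats::setNames(nm = c("vertical", "horizontal", "oblique", "self")),
    function(g) {
      sub <- cells[cells$group == g, ]
      stats::setNames(sub$prob, sub$pair)
    })
  structure(out, class = "markov_indexes")
}

#' Example clinical transition matrix
#'
#' The 4x4 affective transition matrix measured in an illustrative clinical
#' case (a hospitalized patient with anorexia nervosa) with this protocol,
#' as published to two decimals. Bundled so the descriptive and predictive
#' indexes can be recomputed and the report formats exercised without any
#' recording. Rows sum to 0.99-1.00 because of the rounding; pass the
#' result through [as_transition_matrix()] with the `renormalize` choice
#' you need.
#'
#' @return A plain 4x4 numeric matrix (rows/cols A-D).
#' @examples
#' example_case_matrix()
#' @export
example_case_matrix <- function() {
  path <- system.file("extdata", "example_case_matrix.csv",
                      package = "affectdyn")
  read_matrix_csv(path)
}
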