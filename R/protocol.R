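#' Classify stimulus ratings into circumplex quadrants
#'
#' Assigns each stimulus to one of the four affect quadrants from its mean
#' valence and arousal ratings on the 9-point SAM (Self-Assessment Manikin)
#' scale. A dimension counts as high when the mean exceeds `high_cut` and low
#' when below `low_cut` (strict inequalities); stimuli with either dimension
#' in the ambiguous middle band are marked `"EXCLUDED"` and carry no quadrant.
#'
#' @param ratings A data frame with columns `image_id`, `valence_mean` and
#'   `arousal_mean`, both ratings in `[1, 9]`.
#' @param high_cut,low_cut Classification cuts on the SAM scale; defaults 6
#'   and 4 give the conventional high (> 6) / low (< 4) selection with a
#'   two-point dead zone.
#' @return The input as a tibble with an added `state` column: `"A"`-`"D"`
#'   or `"EXCLUDED"`.
#' @examples
#' classify_stimuli(tibble::tibble(
#'   image_id = c("i1", "i2", "i3"),
#'   valence_mean = c(7.2, 2.0, 5.0),
#'   arousal_mean = c(6.8, 7.0, 5.0)
#' ))
#' @export
classify_stimuli <- function(ratings, high_cut = 6, low_cut = 4) {
  ratings <- tibble::as_tibble(ratings)
  need <- c("image_id", "valence_mean", "arousal_mean")
  if (!all(need %in% names(ratings))) {
    abort(paste("ratings must have columns:", paste(need, collapse = ", ")),
          class = "affectdyn_invalid_input")
  }
  if (!is.numeric(low_cut) || !is.numeric(high_cut) || low_cut >= high_cut) {
    abort("low_cut must be strictly below high_cut",
          class = "affectdyn_invalid_input")
  }
  v <- ratings$valence_mean
  a <- ratings$arousal_mean
  bad <- which(!is.finite(v) | !is.finite(a) | v < 1 | v > 9 | a < 1 | a > 9)
  if (length(bad) > 0) {
    abort(sprintf("ratings outside [1, 9] at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "affectdyn_invalid_input")
  }
  pol <- function(x) dplyr::case_when(x > high_cut ~ "high",
                                      x < low_cut ~ "low",
                                      .default = NA_character_)
  ap <- pol(a)
  vp <- pol(v)
  st <- affect_states()
  key <- stats::setNames(st$state, paste(st$arousal, st$valence))
  lab <- unname(key[paste(ap, ifelse(vp == "high", "positive", "negative"))])
  dplyr::mutate(ratings,
                state = dplyr::if_else(is.na(ap) | is.na(vp),
                                       "EXCLUDED", lab))
}

#' Classify a single stimulus rating
#'
#' Scalar convenience wrapper around [classify_stimuli()].
#'
#' @param valence_mean,arousal_mean SAM means in `[1, 9]`.
#' @inheritParams classify_stimuli
#' @return A single state label or `"EXCLUDED"`.
#' @examples
#' classify_stimulus(7.2, 6.8) # "B"
#' @export
classify_stimulus <- function(valence_mean, arousal_mean,
                              high_cut = 6, low_cut = 4) {
  classify_stimuli(
    tibble::tibble(image_id = "x", valence_mean = valence_mean,
                   arousal_mean = arousal_mean),
    high_cut = high_cut, low_cut = low_cut
  )$state
}

#' Generate the 13-block transition schedule
#'
#' Builds the block order for the affect-induction protocol: 13 two-minute
#' blocks whose 12 consecutive ordered pairs realize each of the 12 directed
#' transitions between distinct quadrants exactly once. Such an order is an
#' Eulerian circuit on the complete directed graph over the four states
#' (every node has in-degree = out-degree = 3, so a circuit always exists);
#' the traversal is a randomized Hierholzer walk, reproducible from `seed`.
#'
#' @param seed Integer seed; the same seed always yields the same schedule
#'   and different seeds sample different valid circuits.
#' @return A `block_schedule` object: a list with the 13-element `states`
#'   sequence, protocol constants (`block_duration_s = 120`,
#'   `images_per_block = 12`, `image_duration_s = 10`, 120-s pre/post
#'   baselines) and a `blocks` tibble (`index`, `state`, `t_start_s`,
#'   list-column `images`). Times are relative to first-stimulus onset.
#' @examples
#' sch <- generate_schedule(seed = 1)
#' sch$states
#' @export
generate_schedule <- function(seed) {
  states <- withr::with_seed(as.integer(seed), hierholzer_circuit())
  new_block_schedule(states)
}

# Randomized Hierholzer traversal of the complete digraph on A-D.
# Start from a random node, walk random unused edges until returning with
# none left (guaranteed: the graph is balanced and connected), splicing in
# sub-cycles at nodes that still have unused out-edges.
hierholzer_circuit <- function() {
  labels <- state_labels()
  remaining <- lapply(stats::setNames(labels, labels),
                      function(s) sample(setdiff(labels, s)))
  walk_from <- function(start) {
    path <- start
    node <- start
    while (length(remaining[[node]]) > 0) {
      nxt <- remaining[[node]][1]
      remaining[[node]] <<- remaining[[node]][-1]
      path <- c(path, nxt)
      node <- nxt
    }
    path
  }
  circuit <- walk_from(sample(labels, 1))
  repeat {
    open <- which(vapply(circuit, function(s) length(remaining[[s]]) > 0,
                         logical(1)))
    if (length(open) == 0) break
    k <- open[1]
    sub <- walk_from(circuit[k])
    circuit <- c(head(circuit, k - 1), sub, tail(circuit, -k))
  }
  unname(circuit)
}

new_block_schedule <- function(states, image_assignment = NULL) {
  blocks <- tibble::tibble(
    index = seq_along(states),
    state = states,
    t_start_s = 120 * (seq_along(states) - 1),
    images = image_assignment %||% rep(list(character(0)), length(states))
  )
  structure(
    list(states = states, block_duration_s = 120, images_per_block = 12,
         image_duration_s = 10, baseline_pre_s = 120, baseline_post_s = 120,
         blocks = blocks),
    class = "block_schedule"
  )
}

#' Validate a block schedule
#'
#' Checks the defining invariants: 13 states, and the 12 consecutive ordered
#' pairs are exactly the 12 distinct directed transitions, each once.
#'
#' @param schedule A `block_schedule` or a character vector of 13 labels.
#' @return `TRUE` invisibly; aborts with a description otherwise.
#' @examples
#' validate_schedule(c("A","B","A","C","A","D","B","C","B","D","C","D","A"))
#' @export
validate_schedule <- function(schedule) {
  states <- if (inherits(schedule, "block_schedule")) schedule$states
            else as.character(schedule)
  if (length(states) != 13 || !all(states %in% state_labels())) {
    abort("schedule must contain 13 states labelled A-D",
          class = "affectdyn_invalid_input")
  }
  pairs <- paste0(head(states, -1), tail(states, -1))
  expected <- with(all_cells()[all_cells()$from != all_cells()$to, ],
                   paste0(from, to))
  if (!setequal(pairs, expected) || anyDuplicated(pairs)) {
    abort("the 12 consecutive pairs must cover each directed transition once",
          class = "affectdyn_invalid_input")
  }
  invisible(TRUE)
}

#' Assign stimulus images to schedule blocks
#'
#' Deals 12 images to every block, drawn without replacement from the pool
#' of its block's quadrant; no image is reused anywhere in the session.
#'
#' @param schedule A `block_schedule`.
#' @param pools Named list `state -> character vector of image ids`; each
#'   pool must hold at least 12 images per block of that state.
#' @param seed Integer seed making the shuffle reproducible.
#' @return The schedule with the `images` list-column of `$blocks` filled.
#' @examples
#' pools <- lapply(stats::setNames(LETTERS[1:4], LETTERS[1:4]),
#'                 function(s) paste0(s, 1:48))
#' sch <- assign_images(generate_schedule(1), pools, seed = 2)
#' lengths(sch$blocks$images)
#' @export
assign_images <- function(schedule, pools, seed) {
  validate_schedule(schedule)
  states <- schedule$states
  need <- table(states) * schedule$images_per_block
  for (s in names(need)) {
    pool <- pools[[s]]
    if (is.null(pool) || length(pool) < need[[s]]) {
      abort(sprintf("image pool for state %s has %d images, needs %d",
                    s, length(pools[[s]]), need[[s]]),
            class = "affectdyn_pool_exhausted")
    }
    if (anyDuplicated(pool)) {
      abort(sprintf("image pool for state %s contains duplicates", s),
            class = "affectdyn_invalid_input")
    }
  }
  assignment <- withr::with_seed(as.integer(seed), {
    shuffled <- lapply(pools, sample)
    used <- stats::setNames(integer(length(shuffled)), names(shuffled))
    lapply(states, function(s) {
      idx <- used[[s]] + seq_len(schedule$images_per_block)
      used[[s]] <<- used[[s]] + schedule$images_per_block
      shuffled[[s]][idx]
    })
  })
  new_block_schedule(states, image_assignment = assignment)
}

#' Place the 16 RMSSD analysis windows on the protocol timeline
#'
#' Emits one 30-s transition window straddling each of the 12 block
#' boundaries (`120k - 15` to `120k + 15` seconds for boundary `k`) and one
#' 30-s self window centred `self_center_s` into the first-occurring block of
#' each state (`start + 45` to `start + 75` with defaults). All times are
#' seconds from first-stimulus onset; baselines carry no windows.
#'
#' @param schedule A valid `block_schedule`.
#' @param half_width_s Half-width of every window in seconds (default 15,
#'   i.e. 30-s windows); values of 60 or more would make transition windows
#'   overlap and are rejected.
#' @param self_center_s Centre of the self window within its block (default
#'   60, the block midpoint).
#' @return A `window_set` tibble with columns `from_state`, `to_state`,
#'   `kind` (`"transition"` or `"self"`), `t_start_s`, `t_end_s`: 16 rows
#'   labelling every cell of the 4x4 transition matrix exactly once.
#' @examples
#' w <- place_windows(generate_schedule(1))
#' table(w$kind)
#' @export
place_windows <- function(schedule, half_width_s = 15, self_center_s = 60) {
  validate_schedule(schedule)
  if (half_width_s >= 60) {
    abort("half_width_s must be below 60 or adjacent windows overlap",
          class = "affectdyn_overlapping_windows")
  }
  if (self_center_s - half_width_s < 0 ||
      self_center_s + half_width_s > schedule$block_duration_s) {
    abort("self window must fit inside its block",
          class = "affectdyn_overlapping_windows")
  }
  states <- schedule$states
  trans <- tibble::tibble(
    from_state = head(states, -1),
    to_state = tail(states, -1),
    kind = "transition",
    t_start_s = 120 * seq_len(12) - half_width_s,
    t_end_s = 120 * seq_len(12) + half_width_s
  )
  first_block <- unname(vapply(state_labels(),
                               function(s) which(states == s)[1],
                               integer(1)))
  self <- tibble::tibble(
    from_state = state_labels(),
    to_state = state_labels(),
    kind = "self",
    t_start_s = 120 * (first_block - 1) + self_center_s - half_width_s,
    t_end_s = 120 * (first_block - 1) + self_center_s + half_width_s
  )
  out <- dplyr::arrange(dplyr::bind_rows(trans, self),
                        .data$t_start_s)
  class(out) <- c("window_set", class(out))
  out
}

#' Read a stimulus-ratings table
#'
#' @param path CSV file with header `image_id,valence_mean,arousal_mean`.
#' @return A tibble with those columns.
#' @export
read_ratings <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(image_id = "c",
                                                valence_mean = "d",
                                                arousal_mean = "d"))
  tibble::as_tibble(df)
}

#' Write and read a schedule as JSON
#'
#' The JSON layout records the state sequence, the protocol constants and a
#' per-block array with start times and assigned image ids.
#'
#' @param schedule A `block_schedule`.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns a validated `block_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  obj <- list(
    states = schedule$states,
    block_duration_s = schedule$block_duration_s,
    images_per_block = schedule$images_per_block,
    image_duration_s = schedule$image_duration_s,
    baseline_pre_s = schedule$baseline_pre_s,
    baseline_post_s = schedule$baseline_post_s,
    blocks = lapply(seq_len(nrow(schedule$blocks)), function(i) {
      b <- schedule$blocks[i, ]
      list(index = b$index, state = b$state, t_start_s = b$t_start_s,
           images = b$images[[1]])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  images <- NULL
  if (!is.null(obj$blocks) && length(obj$blocks) > 0) {
    im <- obj$blocks$images
    if (!is.null(im)) images <- lapply(im, as.character)
  }
  sch <- new_block_schedule(as.character(obj$states),
                            image_assignment = images)
  validate_schedule(sch)
  sch
}

#' Write the window set as CSV
#'
#' @param windows A `window_set`.
#' @param path File path; columns
#'   `from_state,to_state,kind,t_start_s,t_end_s`.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  readr::write_csv(tibble::as_tibble(windows)[
    , c("from_state", "to_state", "kind", "t_start_s", "t_end_s")], path)
  invisible(path)
}
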