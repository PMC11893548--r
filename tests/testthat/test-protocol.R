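test_that("stimulus classification maps SAM ratings to quadrants", {
  cases <- tibble::tribble(
    ~valence, ~arousal, ~state,
    7.2, 6.8, "B",        # high arousal, positive valence
    2.0, 7.0, "A",        # high arousal, negative valence
    2.5, 2.5, "C",        # low arousal, negative valence
    8.0, 3.0, "D",        # low arousal, positive valence
    5.0, 5.0, "EXCLUDED", # both in the dead zone
    6.0, 7.0, "EXCLUDED", # valence exactly on the cut: strict inequality
    7.0, 4.0, "EXCLUDED"  # arousal exactly on the cut
  )
  got <- classify_stimuli(tibble::tibble(
    image_id = paste0("i", seq_len(nrow(cases))),
    valence_mean = cases$valence, arousal_mean = cases$arousal))
  expect_equal(got$state, cases$state)
  expect_equal(classify_stimulus(7.2, 6.8), "B")
})

test_that("classification partitions the rating square with no overlap", {
  grid <- expand.grid(valence_mean = seq(1, 9, by = 0.5),
                      arousal_mean = seq(1, 9, by = 0.5))
  grid$image_id <- as.character(seq_len(nrow(grid)))
  got <- classify_stimuli(grid)
  expect_true(all(got$state %in% c("A", "B", "C", "D", "EXCLUDED")))
  # quadrant membership is determined: same rating never maps to two states
  again <- classify_stimuli(grid)
  expect_identical(got$state, again$state)
  # polarity spot check against the constant state table
  hi_neg <- got$state[got$valence_mean < 4 & got$arousal_mean > 6]
  expect_true(all(hi_neg == "A"))
})

test_that("out-of-range ratings are rejected", {
  expect_error(classify_stimulus(0.5, 5), class = "affectdyn_invalid_input")
  expect_error(classify_stimulus(5, 9.5), class = "affectdyn_invalid_input")
})

test_that("generated schedules are Eulerian circuits for every seed", {
  for (seed in 1:25) {
    sch <- generate_schedule(seed)
    expect_length(sch$states, 13)
    expect_true(is_eulerian_circuit(sch$states))
    expect_silent(validate_schedule(sch))
  }
  # determinism and seed coverage of multiple circuits
  expect_identical(generate_schedule(3)$states, generate_schedule(3)$states)
  distinct <- unique(vapply(1:25, function(s)
    paste(generate_schedule(s)$states, collapse = ""), character(1)))
  expect_gt(length(distinct), 5)
})

test_that("the reference 13-block sequence validates as a circuit", {
  ref <- c("A", "B", "A", "C", "A", "D", "B", "C", "B", "D", "C", "D", "A")
  expect_true(is_eulerian_circuit(ref))
  expect_silent(validate_schedule(ref))
  # and a broken one does not
  bad <- ref
  bad[2] <- "C"
  expect_false(is_eulerian_circuit(bad))
  expect_error(validate_schedule(bad), class = "affectdyn_invalid_input")
})

test_that("schedule constants reproduce the protocol bookkeeping", {
  sch <- generate_schedule(11)
  expect_equal(sch$images_per_block * sch$image_duration_s,
               sch$block_duration_s)
  expect_equal(length(sch$states) * sch$block_duration_s, 1560)
  expect_equal(sch$blocks$t_start_s, 120 * (0:12))
})

test_that("image assignment deals 12 unique images per block", {
  pools <- lapply(stats::setNames(nm = c("A", "B", "C", "D")),
                  function(s) paste0(s, 1:48))
  sch <- assign_images(generate_schedule(1), pools, seed = 5)
  imgs <- unlist(sch$blocks$images)
  expect_length(imgs, 156)
  expect_false(anyDuplicated(imgs) > 0)
  expect_true(all(lengths(sch$blocks$images) == 12))
  # every image sits in a block of its own quadrant
  for (i in 1:13) {
    expect_true(all(startsWith(sch$blocks$images[[i]], sch$blocks$state[i])))
  }
  # determinism
  sch2 <- assign_images(generate_schedule(1), pools, seed = 5)
  expect_identical(sch$blocks$images, sch2$blocks$images)
})

test_that("image assignment fails cleanly on an exhausted pool", {
  pools <- lapply(stats::setNames(nm = c("A", "B", "C", "D")),
                  function(s) paste0(s, 1:48))
  pools$B <- pools$B[1:11] # fewer than one block's worth
  expect_error(assign_images(generate_schedule(1), pools, seed = 5),
               class = "affectdyn_pool_exhausted")
})

test_that("window placement tiles the 4x4 matrix with 30-s windows", {
  for (seed in c(1, 9, 42)) {
    sch <- generate_schedule(seed)
    w <- place_windows(sch)
    expect_equal(nrow(w), 16)
    expect_equal(sum(w$kind == "transition"), 12)
    expect_equal(sum(w$kind == "self"), 4)
    expect_true(all(abs((w$t_end_s - w$t_start_s) - 30) < 1e-12))
    expect_true(all((w$from_state == w$to_state) == (w$kind == "self")))
    # the 16 (from, to) labels tile the matrix exactly
    expect_setequal(paste0(w$from_state, w$to_state),
                    paste0(rep(LETTERS[1:4], each = 4),
                           rep(LETTERS[1:4], 4)))
    # transition windows straddle block boundaries at 120k +/- 15
    tr <- w[w$kind == "transition", ]
    expect_setequal(tr$t_start_s, 120 * (1:12) - 15)
    # and do not overlap each other
    tr <- tr[order(tr$t_start_s), ]
    expect_true(all(diff(tr$t_start_s) >= 30))
  }
})

test_that("self windows sit at 60 +/- 15 of each state's first block", {
  sch <- generate_schedule(1)
  w <- place_windows(sch)
  self <- w[w$kind == "self", ]
  first_block <- vapply(c("A", "B", "C", "D"),
                        function(s) which(sch$states == s)[1], integer(1))
  expect_equal(self$t_start_s[match(names(first_block), self$from_state)],
               unname(120 * (first_block - 1) + 45))
  # first block's self window is [45, 75]
  s0 <- self[self$from_state == sch$states[1], ]
  expect_equal(c(s0$t_start_s, s0$t_end_s), c(45, 75))
  # first boundary window is [105, 135]
  tr1 <- w[w$kind == "transition", ][1, ]
  expect_equal(c(tr1$t_start_s, tr1$t_end_s), c(105, 135))
})

test_that("degenerate window geometry is rejected", {
  sch <- generate_schedule(1)
  expect_error(place_windows(sch, half_width_s = 60),
               class = "affectdyn_overlapping_windows")
  expect_error(place_windows(sch, half_width_s = 50, self_center_s = 30),
               class = "affectdyn_overlapping_windows")
})

test_that("schedule JSON and windows CSV round-trip", {
  pools <- lapply(stats::setNames(nm = c("A", "B", "C", "D")),
                  function(s) paste0(s, 1:48))
  sch <- assign_images(generate_schedule(4), pools, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_schedule(sch, f)
  back <- read_schedule(f)
  expect_identical(back$states, sch$states)
  expect_identical(back$blocks$images, sch$blocks$images)
  wf <- withr::local_tempfile(fileext = ".csv")
  write_windows(place_windows(sch), wf)
  w2 <- readr::read_csv(wf, show_col_types = FALSE)
  expect_equal(nrow(w2), 16)
  expect_named(w2, c("from_state", "to_state", "kind", "t_start_s",
                     "t_end_s"))
})
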