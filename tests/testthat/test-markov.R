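test_that("markovize divides each row by its sum", {
  m <- matrix(c(10, 20, 30, 40), 4, 4, byrow = TRUE)
  P <- markovize(m)
  for (i in 1:4) expect_equal(unname(unclass(P)[i, ]), c(0.1, 0.2, 0.3, 0.4))
  # equal raw values give equal shares
  expect_equal(unname(unclass(markovize(matrix(7, 4, 4)))[1, ]), rep(0.25, 4))
})

test_that("markovize rejects degenerate and invalid input", {
  m <- matrix(1, 4, 4)
  m[3, ] <- 0
  expect_error(markovize(m), "C", class = "affectdyn_degenerate_row")
  m[3, ] <- c(-1, 1, 1, 1)
  expect_error(markovize(m), class = "affectdyn_invalid_input")
})

test_that("markovize output is row-stochastic on random matrices", {
  withr::with_seed(21, {
    for (k in 1:1000) {
      m <- matrix(runif(16, 0, 100), 4, 4)
      expect_true(max(abs(rowSums(unclass(markovize(m))) - 1)) < 1e-9)
    }
  })
})

test_that("markovize is invariant to row-wise rescaling", {
  withr::with_seed(22, {
    for (k in 1:50) {
      m <- matrix(runif(16, 1, 50), 4, 4)
      scaled <- m * runif(4, 0.1, 10) # row-wise scale factors
      expect_equal(unclass(markovize(scaled)), unclass(markovize(m)),
                   tolerance = 1e-12)
    }
  })
})

test_that("as_transition_matrix accepts rounded rows and can keep them raw", {
  m <- case_matrix() # published rows sum to 0.99-1.00
  P <- as_transition_matrix(m)
  expect_equal(unname(rowSums(unclass(P))), rep(1, 4), tolerance = 1e-12)
  raw <- as_transition_matrix(m, renormalize = FALSE)
  expect_equal(unclass(raw)["A", "C"], 0.26)
  expect_equal(unname(rowSums(unclass(raw))), c(0.99, 1, 0.99, 1))
  bad <- m
  bad[1, 1] <- 0.5
  expect_error(as_transition_matrix(bad), class = "affectdyn_invalid_input")
})

test_that("the uniform initial vector is the equiprobable distribution", {
  pi0 <- uniform_initial()
  expect_equal(unname(unclass(pi0)), rep(0.25, 4))
  expect_equal(sum(pi0), 1)
  # fixed point of the identity chain
  eye <- diag(4)
  expect_equal(unclass(step_distribution(pi0, eye)), unclass(pi0))
})

test_that("one step from uniform on the published case matrix", {
  P <- as_transition_matrix(case_matrix(), renormalize = FALSE)
  pi1 <- step_distribution(uniform_initial(), P)
  expect_equal(unname(unclass(pi1)), c(0.185, 0.320, 0.255, 0.235),
               tolerance = 1e-12)
})

test_that("stepping preserves the simplex", {
  withr::with_seed(31, {
    for (k in 1:200) {
      P <- random_transition_matrix()
      pi <- runif(4)
      pi <- pi / sum(pi)
      nxt <- step_distribution(pi, P)
      expect_true(all(nxt >= 0))
      expect_equal(sum(nxt), 1, tolerance = 1e-12)
    }
  })
})

test_that("power iteration finds fixed points and absorbing states", {
  pi0 <- uniform_initial()
  ss <- steady_state_power(diag(4), pi0, steps = 3)
  expect_equal(unclass(ss$distribution), unclass(pi0))
  expect_true(ss$converged)
  # single absorbing state: all rows point at state C
  P <- matrix(0, 4, 4)
  P[, 3] <- 1
  ss <- steady_state_power(P, pi0, steps = 10)
  expect_equal(unname(unclass(ss$distribution)), c(0, 0, 1, 0))
  # matches the naive iteration oracle on random chains
  withr::with_seed(41, {
    for (k in 1:20) {
      Pk <- random_transition_matrix()
      ss <- steady_state_power(Pk, pi0, steps = 10, renormalize = FALSE)
      expect_equal(unname(unclass(ss$distribution)),
                   naive_iterate(pi0, Pk, 10), tolerance = 1e-12)
    }
  })
})

test_that("power iteration contracts on strictly positive chains", {
  change_at <- function(P, n) {
    pi <- unclass(uniform_initial())
    ch <- NA
    for (k in seq_len(n)) {
      nxt <- as.numeric(pi %*% P)
      ch <- max(abs(nxt - pi))
      pi <- nxt
    }
    ch
  }
  withr::with_seed(42, {
    for (k in 1:50) {
      P <- random_transition_matrix()
      expect_lte(change_at(P, 10), change_at(P, 2))
    }
  })
})

test_that("eigen steady state solves pi P = pi", {
  # symmetric uniform chain
  ss <- steady_state_eigen(markovize(matrix(1, 4, 4)))
  expect_equal(unname(unclass(ss$distribution)), rep(0.25, 4))
  # doubly stochastic chains have the uniform steady state
  P <- matrix(c(0.1, 0.2, 0.3, 0.4,
                0.2, 0.1, 0.4, 0.3,
                0.3, 0.4, 0.1, 0.2,
                0.4, 0.3, 0.2, 0.1), 4, 4, byrow = TRUE)
  ss <- steady_state_eigen(P)
  expect_equal(unname(unclass(ss$distribution)), rep(0.25, 4),
               tolerance = 1e-10)
  expect_lte(ss$max_abs_change, 1e-8)
})

test_that("eigen and long power iteration agree on the case matrix", {
  P <- as_transition_matrix(case_matrix())
  ss_e <- steady_state_eigen(P)
  ss_p <- steady_state_power(P, steps = 200)
  expect_equal(unclass(ss_e$distribution), unclass(ss_p$distribution),
               tolerance = 1e-6)
})

test_that("reducible chains are refused by the eigen method", {
  P <- matrix(0, 4, 4) # two disconnected 2-state blocks
  P[1:2, 1:2] <- 0.5
  P[3:4, 3:4] <- 0.5
  expect_error(steady_state_eigen(P),
               class = "affectdyn_non_unique_steady_state")
  # periodic two-cycle embedded in four states
  P2 <- matrix(0, 4, 4)
  P2[1, 2] <- P2[2, 1] <- P2[3, 4] <- P2[4, 3] <- 1
  expect_error(steady_state_eigen(P2),
               class = "affectdyn_non_unique_steady_state")
})

test_that("grouped indexes reproduce the published case values", {
  P <- as_transition_matrix(case_matrix(), renormalize = FALSE)
  idx <- grouped_indexes(P)
  expect_equal(idx$vertical,
               c(AC = 0.26, BD = 0.32, CA = 0.13, DB = 0.24))
  expect_equal(idx$self, c(AA = 0.23, BB = 0.24, CC = 0.13, DD = 0.19))
  expect_equal(idx$horizontal,
               c(AB = 0.22, BA = 0.23, CD = 0.15, DC = 0.42))
  expect_equal(idx$oblique,
               c(AD = 0.28, BC = 0.21, CB = 0.58, DA = 0.15))
})

test_that("the four groups partition the 16 cells", {
  withr::with_seed(51, {
    P <- random_transition_matrix()
    idx <- grouped_indexes(markovize(P))
    pairs <- unlist(lapply(unclass(idx), names), use.names = FALSE)
    expect_length(pairs, 16)
    expect_false(anyDuplicated(pairs) > 0)
    expect_setequal(pairs, paste0(rep(LETTERS[1:4], each = 4),
                                  rep(LETTERS[1:4], 4)))
  })
})

test_that("tidiers expose matrices and steady states as tibbles", {
  P <- as_transition_matrix(case_matrix(), renormalize = FALSE)
  td <- tidy(P)
  expect_equal(nrow(td), 16)
  expect_equal(td$prob[td$pair == "DC"], 0.42)
  expect_equal(td$group[td$pair == "DC"], "horizontal")
  ss <- steady_state_eigen(as_transition_matrix(case_matrix()))
  expect_equal(tidy(ss)$state, c("A", "B", "C", "D"))
  expect_equal(sum(tidy(ss)$prob), 1, tolerance = 1e-9)
  g <- glance(ss)
  expect_equal(g$method, "eigen")
  ti <- tidy(grouped_indexes(P))
  expect_equal(nrow(ti), 16)
  expect_setequal(unique(ti$group),
                  c("vertical", "horizontal", "oblique", "self"))
})
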