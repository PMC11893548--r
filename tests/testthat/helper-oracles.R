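# Independent oracles, deliberately naive, used to cross-check the
# implementation on small inputs.

# RMSSD by an explicit two-pass loop
naive_rmssd <- function(x) {
  total <- 0
  for (i in seq_len(length(x) - 1)) total <- total + (x[i + 1] - x[i])^2
  sqrt(total / (length(x) - 1))
}

# Brute-force Eulerian-circuit check: enumerate the consecutive pairs of a
# 13-state sequence and compare the multiset against all 12 ordered pairs.
is_eulerian_circuit <- function(states) {
  if (length(states) != 13) return(FALSE)
  if (states[1] != states[13]) return(FALSE)
  pairs <- character(0)
  for (k in 1:12) {
    if (states[k] == states[k + 1]) return(FALSE)
    pairs <- c(pairs, paste0(states[k], states[k + 1]))
  }
  expected <- c()
  for (i in c("A", "B", "C", "D")) for (j in c("A", "B", "C", "D")) {
    if (i != j) expected <- c(expected, paste0(i, j))
  }
  identical(sort(pairs), sort(expected))
}

# Distribution after n steps by explicit repeated multiplication
naive_iterate <- function(pi0, P, n) {
  pi <- as.numeric(pi0)
  for (k in seq_len(n)) {
    nxt <- numeric(4)
    for (j in 1:4) for (i in 1:4) nxt[j] <- nxt[j] + pi[i] * P[i, j]
    pi <- nxt
  }
  pi
}

random_transition_matrix <- function() {
  m <- matrix(runif(16, min = 0.05, max = 1), 4, 4)
  m / rowSums(m)
}

# the transition probabilities published for the illustrative clinical case
case_probs <- c(AA = 0.23, AB = 0.22, AC = 0.26, AD = 0.28,
                BA = 0.23, BB = 0.24, BC = 0.21, BD = 0.32,
                CA = 0.13, CB = 0.58, CC = 0.13, CD = 0.15,
                DA = 0.15, DB = 0.24, DC = 0.42, DD = 0.19)

case_matrix <- function() {
  matrix(case_probs, 4, 4, byrow = TRUE,
         dimnames = list(from = c("A", "B", "C", "D"),
                         to = c("A", "B", "C", "D")))
}
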