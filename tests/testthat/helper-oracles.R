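# Independent oracles and shared fixtures. Oracles deliberately re-derive
# results from first principles (prose rules, exhaustive enumeration) rather
# than calling the implementation paths they check.

# -- brute-force legal-move oracle -------------------------------------------
# Applies the task prose directly: a held weight can be passed to the other
# student or hung by its holder on the holder's side; a hung weight can be
# removed to the side owner's hand or shifted to another position on the
# same side.
oracle_legal_moves <- function(code) {
  slots <- drop(state_decode(code))
  labels <- bb_slots()
  moves <- list()
  for (i in 1:4) {
    s <- labels[slots[i] + 1]
    if (s == "HELD_A") {
      moves[[length(moves) + 1]] <- data.frame(w = i, src = s,
        dst = c("HELD_B", "A1", "A2", "A3", "A4"))
    } else if (s == "HELD_B") {
      moves[[length(moves) + 1]] <- data.frame(w = i, src = s,
        dst = c("HELD_A", "B1", "B2", "B3", "B4"))
    } else if (startsWith(s, "A")) {
      moves[[length(moves) + 1]] <- data.frame(w = i, src = s,
        dst = c("HELD_A", setdiff(c("A1", "A2", "A3", "A4"), s)))
    } else {
      moves[[length(moves) + 1]] <- data.frame(w = i, src = s,
        dst = c("HELD_B", setdiff(c("B1", "B2", "B3", "B4"), s)))
    }
  }
  do.call(rbind, moves)
}

# -- combinatorial target oracle ---------------------------------------------
# Builds the target set constructively: one weight hung per side with equal
# torque, the remaining two weights in either hand.
oracle_targets <- function() {
  weights <- bb_weights()
  labels <- bb_slots()
  out <- integer(0)
  for (wa in 1:4) for (wb in 1:4) {
    if (wa == wb) next
    for (pa in 1:4) for (pb in 1:4) {
      if (weights[wa] * pa != weights[wb] * pb) next
      rest <- setdiff(1:4, c(wa, wb))
      for (h1 in 0:1) for (h2 in 0:1) {
        slots <- integer(4)
        slots[wa] <- 1L + pa          # A-side slots are indices 2..5
        slots[wb] <- 5L + pb          # B-side slots are indices 6..9
        slots[rest[1]] <- h1
        slots[rest[2]] <- h2
        out <- c(out, state_encode(slots))
      }
    }
  }
  sort(unique(out))
}

# -- exhaustive-path DTW oracle ----------------------------------------------
# Minimum path cost over all monotone warping paths by plain recursion
# (no DP reuse across subproblems beyond the call tree), diagonal steps
# weighted 1 (symmetric1) or 2 (symmetric2), including the entry step.
oracle_dtw <- function(x, y, symmetric2 = FALSE) {
  wdiag <- if (symmetric2) 2 else 1
  best <- function(i, j) {
    cost <- abs(x[i] - y[j])
    if (i == 1 && j == 1) return(wdiag * cost)
    cands <- c()
    if (i > 1) cands <- c(cands, best(i - 1, j) + cost)
    if (j > 1) cands <- c(cands, best(i, j - 1) + cost)
    if (i > 1 && j > 1) cands <- c(cands, best(i - 1, j - 1) + wdiag * cost)
    min(cands)
  }
  best(length(x), length(y))
}

# -- step-up BH oracle --------------------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# -- exhaustive PAM oracle ----------------------------------------------------
# Global optimum of the k-medoid objective by enumerating all medoid subsets.
oracle_pam_objective <- function(D, k) {
  n <- nrow(D)
  combos <- utils::combn(n, k)
  best <- Inf
  for (j in seq_len(ncol(combos))) {
    med <- combos[, j]
    obj <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# verifies 1-swap optimality: no single medoid/non-medoid exchange improves
# the objective (PAM's termination guarantee; a 1-swap optimum may still be
# globally suboptimal)
oracle_one_swap_optimal <- function(D, medoids, objective, eps = 1e-9) {
  n <- nrow(D)
  for (m in seq_along(medoids)) {
    for (cand in setdiff(seq_len(n), medoids)) {
      trial <- medoids
      trial[m] <- cand
      obj <- sum(apply(D[, trial, drop = FALSE], 1, min))
      if (obj < objective - eps) return(FALSE)
    }
  }
  TRUE
}

# -- hand silhouette oracle ---------------------------------------------------
oracle_silhouette <- function(D, assignment) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(assignment), assignment[i]),
                    function(c) mean(D[i, assignment == c]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# -- shared fixtures ----------------------------------------------------------
fixtures <- new.env()

# small planted two-ability cohort reused by the ngram / clustering /
# acceptance tests
planted_cohort <- function() {
  if (is.null(fixtures$cohort)) {
    fixtures$cohort <- simulate_cohort(
      n_groups = 80, theta = rep(c(-0.3, 1.2), each = 40),
      max_len = 60, seed = 20260926)
  }
  fixtures$cohort
}

planted_encoded <- function(representation) {
  key <- paste0("enc_", representation)
  if (is.null(fixtures[[key]])) {
    fixtures[[key]] <- encode_sequences(planted_cohort()$log, representation)
  }
  fixtures[[key]]
}
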