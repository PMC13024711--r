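# Synthetic cohort simulator: seeded softmax random walks on the task graph
# with a per-group ability parameter theta. At each step the probability of
# a legal move is proportional to exp(theta * delta), where delta is the
# move's transition effectiveness; theta = 0 gives a uniform walk, large
# theta a near-greedy walk that solves the task in d_initial = 3 steps.

#' Softmax move policy
#'
#' Probability distribution over the legal moves of a state:
#' `P(move) proportional to exp(theta * delta(move))`.
#'
#' @param code A state code.
#' @param theta Ability parameter (real; 0 = uniform).
#' @param eff An `effectiveness_map`.
#' @return The [legal_moves()] tibble with columns `delta` and `prob` added.
#' @export
#' @examples
#' p <- softmax_policy(initial_state(), theta = 0)
#' all.equal(p$prob, rep(0.05, 20))
softmax_policy <- function(code, theta, eff = state_effectiveness()) {
  moves <- legal_moves(code)
  moves$delta <- eff_d(eff, moves$state_pre) - eff_d(eff, moves$state_post)
  w <- exp(theta * moves$delta)
  moves$prob <- w / sum(w)
  moves
}

# Precomputed walk context: for every state, the row indices of its outgoing
# edges in the (src-sorted) graph, plus per-edge softmax-ready deltas. Makes
# a simulation step a handful of vector lookups.
walk_context <- function(eff) {
  if (!is.null(the$walk) && identical(the$walk$eff, unclass(eff))) {
    return(the$walk)
  }
  g <- build_transition_graph()          # already sorted by src
  d <- unclass(eff)
  ctx <- list(
    graph = g,
    dst = g$dst,
    delta = d[g$src + 1L] - d[g$dst + 1L],
    idx = unname(split(seq_len(nrow(g)), g$src)),
    d = d,
    eff = d
  )
  the$walk <- ctx
  ctx
}

# one softmax walk; returns the graph row indices of the moves taken
walk_rows <- function(theta, max_len, stop_rule, continue_prob, ctx) {
  code <- initial_state()
  rows <- integer(max_len)
  n <- 0L
  repeat {
    if (ctx$d[code + 1L] == 0L &&
        (stop_rule == "absorb" || stats::runif(1) > continue_prob)) {
      break
    }
    if (n >= max_len) break
    out_rows <- ctx$idx[[code + 1L]]
    w <- exp(theta * ctx$delta[out_rows])
    i <- out_rows[sample.int(length(out_rows), 1L, prob = w)]
    n <- n + 1L
    rows[n] <- i
    code <- ctx$dst[i]
  }
  list(rows = rows[seq_len(n)], final = code)
}

#' Simulate one group's action sequence
#'
#' Random walk from the initial state under the softmax policy. With the
#' `"absorb"` stop rule the walk ends on reaching a balanced target (or at
#' `max_len`); with `"continue"` the group keeps acting after reaching a
#' target with probability `continue_prob` per step.
#'
#' @param theta Ability parameter of the group.
#' @param max_len Maximum number of actions (sequence length cap).
#' @param stop_rule `"absorb"` or `"continue"`.
#' @param continue_prob Probability of continuing after a target state under
#'   the `"continue"` rule.
#' @param eff An `effectiveness_map`.
#' @return A tibble of action records (`step`, `actor`, `kind`, `weight`,
#'   `src_slot`, `dst_slot`) with attribute `success` (final state is a
#'   target). Uses the current RNG stream.
#' @export
simulate_group <- function(theta, max_len = 120,
                           stop_rule = c("absorb", "continue"),
                           continue_prob = 0.2,
                           eff = state_effectiveness()) {
  stop_rule <- match.arg(stop_rule)
  stopifnot(max_len >= 3)
  ctx <- walk_context(eff)
  walk <- walk_rows(theta, max_len, stop_rule, continue_prob, ctx)
  out <- ctx$graph[walk$rows,
                   c("actor", "kind", "weight", "src_slot", "dst_slot")]
  out <- dplyr::mutate(out, step = dplyr::row_number(), .before = 1)
  attr(out, "success") <- ctx$d[walk$final + 1L] == 0L
  out
}

#' Simulate a cohort of collaborative action logs
#'
#' Generates `n_groups` independent sequences with per-group abilities drawn
#' from `Normal(theta_mean, theta_sd)` (or fixed via `theta`). Each group
#' gets its own child RNG seed derived from `seed`, so cohorts are
#' reproducible regardless of generation order.
#'
#' @param n_groups Number of groups (sequences).
#' @param theta Optional fixed ability vector (length 1 or `n_groups`);
#'   overrides the normal draw.
#' @param theta_mean,theta_sd Mean and SD of the ability distribution.
#' @param max_len Maximum sequence length.
#' @param stop_rule,continue_prob See [simulate_group()].
#' @param seed Integer root seed; fully determines the cohort.
#' @param eff An `effectiveness_map`.
#' @return A list of class `bb_cohort` with elements `log` (tidy action
#'   records: `group_id`, `step`, `actor`, `kind`, `weight`, `src_slot`,
#'   `dst_slot`) and `truth` (per group: `group_id`, `theta`, `length`,
#'   `success`).
#' @export
#' @examples
#' cohort <- simulate_cohort(n_groups = 5, seed = 1)
#' cohort$truth
simulate_cohort <- function(n_groups = 422, theta = NULL, theta_mean = 0.8,
                            theta_sd = 0.5, max_len = 120,
                            stop_rule = c("absorb", "continue"),
                            continue_prob = 0.2, seed = 1,
                            eff = state_effectiveness()) {
  stop_rule <- match.arg(stop_rule)
  if (n_groups < 1L) stop("n_groups must be at least 1", call. = FALSE)
  seed <- as.integer(seed)
  withr::local_seed(seed)
  if (is.null(theta)) {
    theta <- stats::rnorm(n_groups, theta_mean, theta_sd)
  } else {
    theta <- rep_len(theta, n_groups)
  }
  child_seeds <- sample.int(.Machine$integer.max, n_groups)
  logs <- vector("list", n_groups)
  success <- logical(n_groups)
  for (g in seq_len(n_groups)) {
    withr::local_seed(child_seeds[g])
    seq_g <- simulate_group(theta[g], max_len = max_len,
                            stop_rule = stop_rule,
                            continue_prob = continue_prob, eff = eff)
    success[g] <- attr(seq_g, "success")
    attr(seq_g, "success") <- NULL
    seq_g$group_id <- sprintf("g%04d", g)
    logs[[g]] <- seq_g
  }
  log <- dplyr::relocate(dplyr::bind_rows(logs), "group_id")
  truth <- tibble::tibble(
    group_id = sprintf("g%04d", seq_len(n_groups)),
    theta = theta,
    length = vapply(logs, nrow, integer(1)),
    success = success
  )
  structure(list(log = log, truth = truth), class = "bb_cohort",
            seed = seed)
}

#' @export
print.bb_cohort <- function(x, ...) {
  cat("<bb_cohort>", nrow(x$truth), "groups,", nrow(x$log), "actions;",
      "completion rate", format(mean(x$truth$success), digits = 3),
      "; mean length", format(mean(x$truth$length), digits = 4), "\n")
  invisible(x)
}
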