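# Distance-based effectiveness indicators.
#
# The state effectiveness d_s of a problem state is the minimum number of
# transitions needed to reach any balanced target state; the transition
# effectiveness of a move s -> s' is delta = d_s - d_s' in {-1, 0, +1}
# (+1 approaches the target, 0 neutral, -1 regresses). Because every move is
# reversible, |d_s - d_s'| <= 1 along every edge.

#' Compute state effectiveness for all problem states
#'
#' Runs a multi-source breadth-first search from the target set over the
#' transition graph (edges have unit cost and the edge set is symmetric, so
#' this equals the shortest distance from each state to its nearest target).
#' For the Balance Beam instance the distances span 0 (targets) to 5.
#'
#' @param graph The transition graph from [build_transition_graph()];
#'   defaults to building (and caching) it.
#' @param targets Integer codes of the target states; defaults to
#'   [enumerate_targets()].
#' @return An integer vector of length 10,000, class `effectiveness_map`:
#'   element `code + 1` is d of state `code`.
#' @export
#' @examples
#' eff <- state_effectiveness()
#' eff[initial_state() + 1]  # 3
state_effectiveness <- function(graph = build_transition_graph(),
                                targets = enumerate_targets()) {
  if (length(targets) == 0L) {
    stop("target set is empty; cannot compute effectiveness", call. = FALSE)
  }
  if (!is.null(the$eff) && missing(graph) && missing(targets)) {
    return(the$eff)
  }
  n <- 10000L
  d <- rep(NA_integer_, n)
  d[targets + 1L] <- 0L
  # reversed edges equal forward edges up to relabeling (symmetric edge set),
  # but walk dst -> src explicitly so the code stays correct for any graph
  src <- graph$dst
  dst <- graph$src
  frontier <- logical(n)
  frontier[targets + 1L] <- TRUE
  level <- 0L
  while (any(frontier)) {
    level <- level + 1L
    reach <- dst[frontier[src + 1L]]
    reach <- unique(reach[is.na(d[reach + 1L])])
    frontier <- logical(n)
    if (length(reach)) {
      d[reach + 1L] <- level
      frontier[reach + 1L] <- TRUE
    }
  }
  if (anyNA(d)) {
    stop("some states cannot reach a target; the graph is disconnected",
         call. = FALSE)
  }
  structure(d, class = "effectiveness_map")
}

#' @export
print.effectiveness_map <- function(x, ...) {
  cat("<effectiveness_map> d over", length(x), "states; range",
      min(x), "-", max(x), "\n")
  print(table(d = unclass(x)))
  invisible(x)
}

#' Tidy an effectiveness map
#'
#' @param x An `effectiveness_map`.
#' @param ... Unused.
#' @return A tibble with columns `state` (code) and `d`.
#' @export
tidy.effectiveness_map <- function(x, ...) {
  tibble::tibble(state = 0:9999, d = as.integer(unclass(x)))
}

# fast lookup helper
eff_d <- function(eff, code) as.integer(unclass(eff)[code + 1L])

#' Transition effectiveness of a single move
#'
#' @param code A state code.
#' @inheritParams apply_move
#' @param eff An `effectiveness_map`.
#' @return `d(s) - d(s')`, an integer in `{-1, 0, 1}`.
#' @export
#' @examples
#' eff <- state_effectiveness()
#' # Student B removes the 100 g weight from position 1 in the state where
#' # B has 100 g at B1 and 300 g at B2 while A holds 50 g and 500 g: -1
#' s <- state_encode(c(0, 6, 7, 0))
#' transition_delta(s, "B", "REMOVE", 100, "B1", "HELD_B", eff)
transition_delta <- function(code, actor, kind, weight, src_slot, dst_slot,
                             eff = state_effectiveness()) {
  post <- apply_move(code, actor, kind, weight, src_slot, dst_slot)
  eff_d(eff, code) - eff_d(eff, post)
}

# ---- sequence encoding ------------------------------------------------------

#' Re-represent action sequences under the three formats
#'
#' Replays each group's moves from the initial state (validating legality),
#' annotates every step with the pre/post state effectiveness, and attaches
#' the representation tokens:
#'
#' * `token` — the role-tagged string used for n-gram selection:
#'   the human-readable action (`representation = "raw"`), `"A: 1"` style
#'   transition effectiveness (`"delta"`), or `"A: 3->2"` style
#'   state-effectiveness pairs (`"state_pair"`).
#' * `value` — the numeric series used for DTW clustering: the collapsed
#'   1..84 action code (`"raw"`, treated as an ordinal number), the delta
#'   value (`"delta"`), or the post-transition d (`"state_pair"`; the
#'   optimal three-step solution yields 2, 1, 0).
#'
#' @param log A tibble of action records with columns `group_id`, `step`,
#'   `actor`, `kind`, `weight`, `src_slot`, `dst_slot` (see
#'   [read_action_log()] or [simulate_cohort()]).
#' @param representation `"raw"`, `"delta"`, or `"state_pair"`.
#' @param eff An `effectiveness_map`.
#' @return A tibble: the input plus `state_pre`, `state_post`, `d_pre`,
#'   `d_post`, `delta`, `token`, `value`.
#' @export
encode_sequences <- function(log,
                             representation = c("raw", "delta", "state_pair"),
                             eff = state_effectiveness()) {
  representation <- match.arg(representation)
  log <- replay_log(log)
  log$d_pre <- eff_d(eff, log$state_pre)
  log$d_post <- eff_d(eff, log$state_post)
  log$delta <- log$d_pre - log$d_post
  if (representation == "raw") {
    log$value <- as.numeric(action_code(log, "collapsed"))
    log$token <- action_code(log, "tagged")
  } else if (representation == "delta") {
    log$value <- as.numeric(log$delta)
    log$token <- paste0(log$actor, ": ", log$delta)
  } else {
    log$value <- as.numeric(log$d_post)
    log$token <- paste0(log$actor, ": ", log$d_pre, "->", log$d_post)
  }
  attr(log, "representation") <- representation
  log
}

# Replay all groups' moves from the initial state, computing state_pre and
# state_post and raising on the first illegal step. Internal workhorse shared
# by encode_sequences() and the log validator.
replay_log <- function(log) {
  required <- c("group_id", "step", "actor", "kind", "weight",
                "src_slot", "dst_slot")
  missing_cols <- setdiff(required, names(log))
  if (length(missing_cols)) {
    stop("action log lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  log <- dplyr::arrange(tibble::as_tibble(log), .data$group_id, .data$step)
  out <- dplyr::group_modify(dplyr::group_by(log, .data$group_id),
    function(df, key) {
      pre <- integer(nrow(df))
      post <- integer(nrow(df))
      s <- initial_state()
      for (i in seq_len(nrow(df))) {
        pre[i] <- s
        s <- tryCatch(
          apply_move(s, df$actor[i], df$kind[i], df$weight[i],
                     df$src_slot[i], df$dst_slot[i]),
          error = function(e) {
            stop("group ", key$group_id, ", step ", df$step[i], ": ",
                 conditionMessage(e), call. = FALSE)
          })
        post[i] <- s
      }
      df$state_pre <- pre
      df$state_post <- post
      df
    })
  dplyr::ungroup(out)
}

#' Per-sequence effectiveness summaries
#'
#' Computes, for each group, the sequence length, the mean transition
#' effectiveness (which telescopes to `(d_initial - d_final) / length`), the
#' proportions of forward / still / backward moves, the mean post-move state
#' effectiveness, and the success label.
#'
#' @param encoded Output of [encode_sequences()] (any representation).
#' @param success_rule `"final"` (default): success iff the final state is a
#'   target; `"ever"`: success iff any visited state is a target.
#' @return A tibble with one row per group: `group_id`, `length`,
#'   `mean_delta`, `prop_forward`, `prop_still`, `prop_backward`, `mean_d`,
#'   `success`.
#' @export
summarize_sequences <- function(encoded, success_rule = c("final", "ever")) {
  success_rule <- match.arg(success_rule)
  dplyr::summarise(
    dplyr::group_by(encoded, .data$group_id),
    length = dplyr::n(),
    mean_delta = mean(.data$delta),
    prop_forward = mean(.data$delta == 1),
    prop_still = mean(.data$delta == 0),
    prop_backward = mean(.data$delta == -1),
    mean_d = mean(.data$d_post),
    success = if (success_rule == "final") {
      .data$d_post[dplyr::n()] == 0L
    } else {
      any(.data$d_post == 0L)
    },
    .groups = "drop"
  )
}
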