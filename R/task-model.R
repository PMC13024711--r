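#' @useDynLib procfx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

# ---- task constants ---------------------------------------------------------
#
# The Balance Beam task: two students (A, B) share four weights and a beam
# with four hanging positions on each side. Each weight occupies exactly one
# of ten slots: held by A, held by B, or hanging at position 1-4 on either
# side. A problem state is the slot assignment of all four weights; there are
# 10^4 = 10,000 states. Slots are indexed 0..9 internally in the order below.

BB_WEIGHTS <- c(50L, 100L, 300L, 500L)

BB_SLOTS <- c("HELD_A", "HELD_B", "A1", "A2", "A3", "A4", "B1", "B2", "B3", "B4")

#' Weights and slots of the Balance Beam task
#'
#' `bb_weights()` returns the four weight masses in grams; `bb_slots()` the
#' ten slot labels each weight can occupy (two hands plus four lever
#' positions per side).
#'
#' @return An integer vector of masses, or a character vector of slot labels.
#' @export
#' @examples
#' bb_weights()
#' bb_slots()
bb_weights <- function() BB_WEIGHTS

#' @rdname bb_weights
#' @export
bb_slots <- function() BB_SLOTS

# side of a slot index (0-based): "H" held, "A"/"B" hanging sides
slot_side <- function(slot) {
  c("H", "H", "A", "A", "A", "A", "B", "B", "B", "B")[slot + 1L]
}

# lever position (1..4) of a hanging slot index, 0 for held slots
slot_pos <- function(slot) {
  c(0L, 0L, 1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L)[slot + 1L]
}

# ---- state codec ------------------------------------------------------------

#' Encode and decode problem states
#'
#' A problem state assigns each of the four weights (50, 100, 300, 500 g) to
#' one of ten slots. States are encoded as integers in `[0, 9999]` by a
#' mixed-radix (base-10) code: digit `i` (least significant first) is the
#' 0-based slot index of the `i`-th weight in `bb_weights()` order. The all
#' weights held-by-A initial state has code 0.
#'
#' @param slots An integer matrix with one row per state and four columns of
#'   0-based slot indices (or a length-4 vector for a single state).
#' @param code An integer vector of state codes in `[0, 9999]`.
#' @return `state_encode()` returns an integer code vector; `state_decode()`
#'   an n x 4 integer matrix of slot indices.
#' @export
#' @examples
#' state_encode(c(0, 0, 0, 0))
#' state_decode(6100)
state_encode <- function(slots) {
  if (is.null(dim(slots))) slots <- matrix(as.integer(slots), nrow = 1L)
  stopifnot(ncol(slots) == 4L)
  if (any(slots < 0L | slots > 9L)) {
    stop("slot indices must be in 0..9", call. = FALSE)
  }
  as.integer(slots %*% c(1L, 10L, 100L, 1000L))
}

#' @rdname state_encode
#' @export
state_decode <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L | code > 9999L)) {
    stop("state codes must be integers in 0..9999", call. = FALSE)
  }
  m <- cbind(
    code %% 10L,
    (code %/% 10L) %% 10L,
    (code %/% 100L) %% 10L,
    (code %/% 1000L) %% 10L
  )
  colnames(m) <- paste0("w", BB_WEIGHTS)
  m
}

#' The initial problem state
#'
#' At the start of the task Student A holds all four weights; the state code
#' is 0.
#'
#' @return The integer code of the initial state.
#' @export
initial_state <- function() 0L

#' Enumerate all problem states
#'
#' @return An integer vector of the 10,000 state codes, `0:9999`.
#' @export
enumerate_states <- function() 0:9999

#' Render a state as a human-readable tibble
#'
#' @param code A single state code.
#' @return A tibble with one row per weight: `weight`, `slot`, `side`,
#'   `position` (0 for held slots).
#' @export
#' @examples
#' describe_state(6100)
describe_state <- function(code) {
  stopifnot(length(code) == 1L)
  slots <- drop(state_decode(code))
  tibble::tibble(
    weight = BB_WEIGHTS,
    slot = BB_SLOTS[slots + 1L],
    side = slot_side(slots),
    position = slot_pos(slots)
  )
}

# ---- moves ------------------------------------------------------------------

# Slot-to-slot move templates: which destination slots are reachable from each
# source slot, who acts, and what kind of move it is. These encode the task
# rules: a held weight can be passed to the partner or hung on the holder's
# side; a hung weight can be removed back to the side owner's hand or shifted
# to another position on the same side.
move_templates <- function() {
  tpl <- list()
  # held by A: pass to B, hang at A1..A4
  tpl[[1]] <- data.frame(src = 0L, dst = c(1L, 2:5), actor = "A",
                         kind = c("PASS", rep("HANG", 4)))
  # held by B: pass to A, hang at B1..B4
  tpl[[2]] <- data.frame(src = 1L, dst = c(0L, 6:9), actor = "B",
                         kind = c("PASS", rep("HANG", 4)))
  for (s in 2:5) {                       # hung on side A
    tpl[[length(tpl) + 1]] <- data.frame(
      src = s, dst = c(0L, setdiff(2:5, s)), actor = "A",
      kind = c("REMOVE", rep("SHIFT", 3)))
  }
  for (s in 6:9) {                       # hung on side B
    tpl[[length(tpl) + 1]] <- data.frame(
      src = s, dst = c(1L, setdiff(6:9, s)), actor = "B",
      kind = c("REMOVE", rep("SHIFT", 3)))
  }
  do.call(rbind, tpl)
}

the <- new.env(parent = emptyenv())

get_move_templates <- function() {
  if (is.null(the$templates)) the$templates <- move_templates()
  the$templates
}

#' Legal moves from a problem state
#'
#' Applies the task rules to a single state: each held weight admits 5 moves
#' (1 pass + 4 hangs on the holder's side), each hung weight 4 (1 removal
#' back to the side owner's hand + 3 shifts on the same side), so the
#' out-degree of any state lies in `[16, 20]`.
#'
#' @param code A single state code.
#' @return A tibble with one row per legal move: `actor`, `kind`, `weight`,
#'   `src_slot`, `dst_slot`, `state_pre`, `state_post`.
#' @export
#' @examples
#' nrow(legal_moves(initial_state()))  # 20
legal_moves <- function(code) {
  stopifnot(length(code) == 1L)
  slots <- drop(state_decode(code))
  tpl <- get_move_templates()
  out <- lapply(1:4, function(i) {
    rows <- tpl[tpl$src == slots[i], , drop = FALSE]
    tibble::tibble(
      actor = rows$actor,
      kind = rows$kind,
      weight = BB_WEIGHTS[i],
      src_slot = BB_SLOTS[rows$src + 1L],
      dst_slot = BB_SLOTS[rows$dst + 1L],
      state_pre = as.integer(code),
      state_post = as.integer(code + (rows$dst - rows$src) * 10L^(i - 1L))
    )
  })
  dplyr::bind_rows(out)
}

#' Apply a move to a problem state
#'
#' Validates the move against the task rules and returns the resulting state
#' code. Every move is reversible: hanging then removing the same weight, or
#' shifting it back, restores the original state.
#'
#' @param code A single state code.
#' @param actor `"A"` or `"B"`.
#' @param kind One of `"PASS"`, `"HANG"`, `"REMOVE"`, `"SHIFT"`.
#' @param weight A mass in `bb_weights()`.
#' @param src_slot,dst_slot Slot labels from `bb_slots()`.
#' @return The integer code of the resulting state.
#' @export
#' @examples
#' apply_move(0, "A", "PASS", 100, "HELD_A", "HELD_B")
apply_move <- function(code, actor, kind, weight, src_slot, dst_slot) {
  stopifnot(length(code) == 1L)
  w <- match(weight, BB_WEIGHTS)
  if (is.na(w)) stop("unknown weight: ", weight, call. = FALSE)
  src <- match(src_slot, BB_SLOTS) - 1L
  dst <- match(dst_slot, BB_SLOTS) - 1L
  if (is.na(src) || is.na(dst)) {
    stop("unknown slot: ", src_slot, " or ", dst_slot, call. = FALSE)
  }
  slots <- drop(state_decode(code))
  if (slots[w] != src) {
    stop("illegal move: the ", weight, " g weight is in ",
         BB_SLOTS[slots[w] + 1L], ", not ", src_slot, call. = FALSE)
  }
  tpl <- get_move_templates()
  row <- tpl[tpl$src == src & tpl$dst == dst, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("illegal move: no ", src_slot, " -> ", dst_slot,
         " transition exists", call. = FALSE)
  }
  if (row$kind != kind) {
    stop("illegal move: ", src_slot, " -> ", dst_slot, " is a ", row$kind,
         ", not a ", kind, call. = FALSE)
  }
  if (row$actor != actor) {
    stop("illegal move: only student ", row$actor, " may perform ",
         kind, " ", src_slot, " -> ", dst_slot, call. = FALSE)
  }
  as.integer(code + (dst - src) * 10L^(w - 1L))
}

# ---- target predicate -------------------------------------------------------

#' Balanced target states
#'
#' A state is a target when exactly one weight hangs on each side and the
#' lever torques agree: `mass_A * position_A == mass_B * position_B`
#' (integer arithmetic; the remaining two weights are held by either
#' student). No balanced configuration uses the 500 g weight.
#'
#' @param code A vector of state codes.
#' @return `is_target()` returns a logical vector; `enumerate_targets()` the
#'   sorted integer codes of all target states.
#' @export
#' @examples
#' # 50 g at A2, 100 g at B1, others held by A
#' is_target(state_encode(c(3, 6, 0, 0)))
is_target <- function(code) {
  m <- state_decode(code)
  on_a <- m >= 2L & m <= 5L
  on_b <- m >= 6L & m <= 9L
  pos <- matrix(slot_pos(m), nrow = nrow(m))
  mass <- matrix(BB_WEIGHTS, nrow = nrow(m), ncol = 4L, byrow = TRUE)
  torque_a <- rowSums(mass * pos * on_a)
  torque_b <- rowSums(mass * pos * on_b)
  rowSums(on_a) == 1L & rowSums(on_b) == 1L & torque_a == torque_b
}

#' @rdname is_target
#' @export
enumerate_targets <- function() {
  if (is.null(the$targets)) {
    all <- enumerate_states()
    the$targets <- all[is_target(all)]
  }
  the$targets
}

# ---- mirror symmetry --------------------------------------------------------

#' Mirror a problem state across the fulcrum
#'
#' Swaps the two students' roles and sides: held-by-A with held-by-B and each
#' `Ap` slot with `Bp`. The mirror map is an involution and a graph
#' automorphism that maps the target set onto itself; it underlies the
#' role-collapsed action coding.
#'
#' @param code A vector of state codes.
#' @return The mirrored state codes.
#' @export
#' @examples
#' mirror_state(0)  # all weights held by B
mirror_state <- function(code) {
  m <- state_decode(code)
  mm <- ifelse(m < 2L, 1L - m, ifelse(m <= 5L, m + 4L, m - 4L))
  state_encode(mm)
}

# ---- transition graph -------------------------------------------------------

#' Build the full transition graph
#'
#' Enumerates every directed legal transition over all 10,000 states:
#' 168,000 edges. The edge set is symmetric (every move has an inverse).
#' The graph is cached within the session.
#'
#' @return A tibble with one row per directed edge: `src`, `dst` (state
#'   codes), `actor`, `kind`, `weight`, `src_slot`, `dst_slot`.
#' @export
#' @examples
#' g <- build_transition_graph()
#' nrow(g)  # 168000
build_transition_graph <- function() {
  if (!is.null(the$graph)) return(the$graph)
  tpl <- get_move_templates()
  codes <- enumerate_states()
  digit <- state_decode(codes)
  parts <- vector("list", 4L * nrow(tpl))
  k <- 0L
  for (w in 1:4) {
    pow <- 10L^(w - 1L)
    for (r in seq_len(nrow(tpl))) {
      src_codes <- codes[digit[, w] == tpl$src[r]]
      k <- k + 1L
      parts[[k]] <- tibble::tibble(
        src = src_codes,
        dst = src_codes + (tpl$dst[r] - tpl$src[r]) * pow,
        actor = tpl$actor[r],
        kind = tpl$kind[r],
        weight = BB_WEIGHTS[w],
        src_slot = BB_SLOTS[tpl$src[r] + 1L],
        dst_slot = BB_SLOTS[tpl$dst[r] + 1L]
      )
    }
  }
  g <- dplyr::arrange(dplyr::bind_rows(parts), .data$src, .data$dst,
                      .data$weight)
  the$graph <- g
  g
}

# ---- action coding ----------------------------------------------------------

# 0-based ordered shift-pair index among the 12 ordered (p, q) position pairs,
# lexicographic in (p, q)
shift_pair_index <- function(p, q) {
  (p - 1L) * 3L + q - 1L - as.integer(q > p)
}

#' Role-collapsed and role-tagged action codes
#'
#' Maps moves to tokens. In `"collapsed"` mode each move gets an
#' actor-relative integer code 1..84: mirror-image moves by the two students
#' share a code, and per weight there are 21 move types (1 pass + 4 hangs +
#' 4 removals + 12 ordered position shifts). In `"tagged"` mode the token is
#' a human-readable string prefixed by the acting role, e.g.
#' `"B hangs 500 g at position 2"` (up to 168 distinct tokens).
#'
#' @param moves A tibble of moves with columns `actor`, `kind`, `weight`,
#'   `src_slot`, `dst_slot` (as returned by [legal_moves()]).
#' @param role_mode `"collapsed"` or `"tagged"`.
#' @return An integer vector of codes (collapsed) or a character vector of
#'   tokens (tagged), one per move.
#' @export
#' @examples
#' action_code(legal_moves(initial_state()), "tagged")[1:3]
action_code <- function(moves, role_mode = c("collapsed", "tagged")) {
  role_mode <- match.arg(role_mode)
  w <- match(moves$weight, BB_WEIGHTS)
  src <- match(moves$src_slot, BB_SLOTS) - 1L
  dst <- match(moves$dst_slot, BB_SLOTS) - 1L
  if (any(is.na(w)) || any(is.na(src)) || any(is.na(dst))) {
    stop("unknown weight or slot in moves", call. = FALSE)
  }
  p <- slot_pos(src)
  q <- slot_pos(dst)
  within <- integer(nrow(moves))
  within[moves$kind == "PASS"] <- 1L
  within[moves$kind == "HANG"] <- 1L + q[moves$kind == "HANG"]
  within[moves$kind == "REMOVE"] <- 5L + p[moves$kind == "REMOVE"]
  sh <- moves$kind == "SHIFT"
  within[sh] <- 10L + shift_pair_index(p[sh], q[sh])
  code <- (w - 1L) * 21L + within
  if (role_mode == "collapsed") {
    return(code)
  }
  paste(moves$actor, describe_move(moves))
}

#' Human-readable rendering of moves
#'
#' @param moves A tibble of moves (see [action_code()]).
#' @return A character vector, e.g. `"passes 100 g to the partner"`.
#' @export
describe_move <- function(moves) {
  p <- slot_pos(match(moves$src_slot, BB_SLOTS) - 1L)
  q <- slot_pos(match(moves$dst_slot, BB_SLOTS) - 1L)
  dplyr::case_when(
    moves$kind == "PASS" ~ sprintf("passes %d g to the partner", moves$weight),
    moves$kind == "HANG" ~ sprintf("hangs %d g at position %d", moves$weight, q),
    moves$kind == "REMOVE" ~ sprintf("removes %d g from position %d",
                                     moves$weight, p),
    TRUE ~ sprintf("shifts %d g from position %d to position %d",
                   moves$weight, p, q)
  )
}
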