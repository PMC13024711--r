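# Reading, writing and validating action logs and result tables.
#
# The on-disk action-log schema is a CSV (header required) or JSON-lines
# file with columns group_id, step, actor, weight, src_slot, dst_slot and an
# optional timestamp. The move kind is implied by the slot pair and is
# recomputed on read. Timestamps are carried through but never used in any
# computation. Empirical datasets with other schemas can be mapped onto this
# one with a user-supplied adapter function (`adapter` argument).

log_cols <- c("group_id", "step", "actor", "weight", "src_slot", "dst_slot")

# kind and acting role implied by a (src, dst) slot pair; NA when illegal
move_kind_of <- function(src_slot, dst_slot) {
  tpl <- get_move_templates()
  key <- paste(match(src_slot, BB_SLOTS) - 1L, match(dst_slot, BB_SLOTS) - 1L)
  idx <- match(key, paste(tpl$src, tpl$dst))
  list(kind = tpl$kind[idx], actor = tpl$actor[idx])
}

#' Validate an action log against the task rules
#'
#' Replays each group's records from the initial state. Records that violate
#' move legality (wrong source slot, impossible slot pair, wrong actor) or
#' step continuity are either dropped (`mode = "filter"`, the replay then
#' continues from the unchanged state) or raised as errors
#' (`mode = "strict"`). Steps are renumbered contiguously after filtering.
#'
#' @param log A tibble with columns `group_id`, `step`, `actor`, `weight`,
#'   `src_slot`, `dst_slot` (`kind` is recomputed from the slot pair).
#' @param mode `"filter"` or `"strict"`.
#' @return The validated log (with `kind` filled in), with attribute
#'   `"report"`: a tibble of drop counts per reason (empty in strict mode).
#' @export
validate_action_log <- function(log, mode = c("filter", "strict")) {
  mode <- match.arg(mode)
  missing_cols <- setdiff(log_cols, names(log))
  if (length(missing_cols)) {
    stop("action log lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  log <- tibble::as_tibble(log)
  bad_slot <- !(log$src_slot %in% BB_SLOTS) | !(log$dst_slot %in% BB_SLOTS)
  bad_weight <- !(log$weight %in% BB_WEIGHTS)
  bad_actor <- !(log$actor %in% c("A", "B"))
  if (any(bad_slot | bad_weight | bad_actor)) {
    bad <- which(bad_slot | bad_weight | bad_actor)[1]
    stop("record ", bad, ": unknown ",
         if (bad_slot[bad]) "slot" else if (bad_weight[bad]) "weight"
         else "actor", " vocabulary", call. = FALSE)
  }
  log <- dplyr::arrange(log, .data$group_id, .data$step)
  drops <- list()
  keep_rows <- vector("list", 0)
  for (gid in unique(log$group_id)) {
    df <- log[log$group_id == gid, ]
    s <- initial_state()
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      reason <- NULL
      # steps must run 1..n contiguously in arrival order
      if (df$step[i] != i) {
        reason <- "discontinuous step index"
      }
      mk <- move_kind_of(df$src_slot[i], df$dst_slot[i])
      if (is.null(reason) && is.na(mk$kind)) {
        reason <- "impossible slot pair"
      }
      if (is.null(reason) && mk$actor != df$actor[i]) {
        reason <- "wrong actor for slot pair"
      }
      if (is.null(reason)) {
        w <- match(df$weight[i], BB_WEIGHTS)
        cur <- drop(state_decode(s))[w]
        if (BB_SLOTS[cur + 1L] != df$src_slot[i]) {
          reason <- "weight not at source slot"
        }
      }
      if (is.null(reason)) {
        keep[i] <- TRUE
        s <- apply_move(s, df$actor[i], mk$kind, df$weight[i],
                        df$src_slot[i], df$dst_slot[i])
      } else if (mode == "strict") {
        stop("group ", gid, ", step ", df$step[i], ": ", reason,
             call. = FALSE)
      } else {
        drops[[length(drops) + 1]] <- tibble::tibble(group_id = gid,
                                                     step = df$step[i],
                                                     reason = reason)
      }
    }
    df <- df[keep, ]
    if (nrow(df)) df$step <- seq_len(nrow(df))
    keep_rows[[length(keep_rows) + 1]] <- df
  }
  out <- dplyr::bind_rows(keep_rows)
  mk <- move_kind_of(out$src_slot, out$dst_slot)
  out$kind <- mk$kind
  out <- dplyr::relocate(out, "kind", .after = "actor")
  report <- if (length(drops)) {
    dplyr::count(dplyr::bind_rows(drops), .data$reason, name = "dropped")
  } else {
    tibble::tibble(reason = character(), dropped = integer())
  }
  attr(out, "report") <- report
  out
}

#' Read an action log
#'
#' Reads a CSV (header required) or JSON-lines action log, optionally maps
#' it through an adapter, and validates it with [validate_action_log()].
#'
#' @param path File path; format is inferred from the extension (`.csv` vs
#'   `.json`/`.jsonl`) unless `format` is given.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @param mode Validation mode, see [validate_action_log()].
#' @param adapter Optional function applied to the raw tibble before
#'   validation, for mapping foreign schemas onto the standard columns.
#' @return A validated action-log tibble (see [validate_action_log()]).
#' @export
read_action_log <- function(path, format = c("auto", "csv", "jsonl"),
                            mode = c("filter", "strict"), adapter = NULL) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    tibble::as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
  }
  if (!is.null(adapter)) raw <- adapter(raw)
  raw$step <- as.integer(raw$step)
  raw$weight <- as.integer(raw$weight)
  validate_action_log(raw, mode = mode)
}

#' Write an action log
#'
#' Deterministic column order (`group_id`, `step`, `actor`, `weight`,
#' `src_slot`, `dst_slot`, plus `timestamp` if present), UTF-8.
#'
#' @param log An action-log tibble.
#' @param path Output path (`.csv` or `.jsonl` by extension).
#' @return `path`, invisibly.
#' @export
write_action_log <- function(log, path) {
  cols <- intersect(c(log_cols, "timestamp"), names(log))
  out <- log[cols]
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(out), con, verbose = FALSE)
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' Write a results table with run metadata
#'
#' Writes the tibble as CSV and a sidecar JSON (`<path>.meta.json`) holding
#' the package version, the supplied seed/configuration, and a hash of the
#' result contents (timestamps excluded from the hash).
#'
#' @param x A data frame of results.
#' @param path Output CSV path.
#' @param meta A named list of run metadata (e.g. `list(seed = 7)`).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, meta = list()) {
  readr::write_csv(tibble::as_tibble(x), path)
  meta$package_version <- as.character(utils::packageVersion("procfx"))
  meta$content_hash <- rlang::hash(x)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Export the transition graph
#'
#' Writes the directed edge list as TSV (`src_code`, `dst_code`, `actor`,
#' `kind`, `weight`, `src_slot`, `dst_slot`), node attributes (state code,
#' effectiveness, target flag) as CSV, and the target-state codes as CSV.
#'
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_graph <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- build_transition_graph()
  readr::write_tsv(
    dplyr::rename(g, src_code = "src", dst_code = "dst"),
    file.path(dir, "edges.tsv"))
  eff <- state_effectiveness()
  nodes <- tidy.effectiveness_map(eff)
  nodes$target <- is_target(nodes$state)
  readr::write_csv(nodes, file.path(dir, "nodes.csv"))
  readr::write_csv(tibble::tibble(state = enumerate_targets()),
                   file.path(dir, "targets.csv"))
  invisible(dir)
}
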