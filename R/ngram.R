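# N-gram chi-square feature selection with TF-ISF weighting.
#
# Each n-gram (n = 1 or 2 consecutive tokens) is weighted per sequence by
# TF-ISF = (1 + log tf) * log(N / sf) and tested in a 2x2 table whose rows
# are this n-gram vs all other n-grams (of the same order and representation)
# and whose columns are successful vs failed sequences; cells hold summed
# TF-ISF mass. Chi-square (df = 1, no continuity correction), phi, and
# Benjamini-Hochberg adjustment across the n-grams of one representation
# yield the "key action segment" flags.

#' Extract n-gram counts from encoded sequences
#'
#' Bigrams are consecutive token pairs within a sequence (actor changes do
#' not break them); the two tokens are joined with `" ; "`.
#'
#' @param encoded Output of [encode_sequences()]: a tibble with `group_id`,
#'   `step`, `token`.
#' @param n 1 or 2.
#' @return A tibble of per-sequence term frequencies (`ngram`, `group_id`,
#'   `tf`) with attributes `sf` (named integer: sequences containing each
#'   n-gram) and `n_seq` (total sequences, counting those too short to
#'   contribute).
#' @export
extract_ngrams <- function(encoded, n = 1) {
  stopifnot(n %in% c(1L, 2L))
  n_seq <- dplyr::n_distinct(encoded$group_id)
  df <- dplyr::arrange(encoded, .data$group_id, .data$step)
  if (n == 2L) {
    df <- dplyr::mutate(dplyr::group_by(df, .data$group_id),
                        nxt = dplyr::lead(.data$token))
    df <- dplyr::filter(dplyr::ungroup(df), !is.na(.data$nxt))
    df <- dplyr::mutate(df, ngram = paste(.data$token, .data$nxt, sep = " ; "))
  } else {
    df <- dplyr::mutate(df, ngram = .data$token)
  }
  counts <- dplyr::count(df, .data$ngram, .data$group_id, name = "tf")
  sf_tbl <- dplyr::count(dplyr::distinct(counts, .data$ngram, .data$group_id),
                         .data$ngram, name = "sf")
  sf <- stats::setNames(sf_tbl$sf, sf_tbl$ngram)
  structure(counts, sf = sf, n_seq = n_seq)
}

#' Term frequency-inverse sequence frequency weight
#'
#' `(1 + log(tf)) * log(N / sf)` for `tf >= 1` and 0 for `tf = 0`. An n-gram
#' occurring in every sequence (`sf = N`) gets weight 0 regardless of `tf`.
#'
#' @param tf Within-sequence count(s) of the n-gram.
#' @param n_seq Total number of sequences `N`.
#' @param sf Number of sequences containing the n-gram.
#' @param base Logarithm base; natural log by default.
#' @return Numeric weight(s).
#' @export
#' @examples
#' tfisf_weight(1, 10, 2)  # log(5)
tfisf_weight <- function(tf, n_seq, sf, base = exp(1)) {
  stopifnot(n_seq >= 1, all(sf >= 0), all(sf <= n_seq), all(tf >= 0))
  if (any(tf >= 1 & sf == 0)) {
    stop("inconsistent counts: tf >= 1 with sf = 0", call. = FALSE)
  }
  ifelse(tf == 0, 0,
         (1 + log(tf, base = base)) * log(n_seq / pmax(sf, 1), base = base))
}

#' Chi-square and phi of a 2x2 mass table
#'
#' Pearson chi-square from observed vs margin-expected cells, df = 1, no
#' continuity correction; works on continuous (TF-ISF) masses. Phi is
#' `sqrt(chi2 / total)`. The direction is the sign of `O[1,1] - E[1,1]`:
#' positive means the first row is overrepresented in the first column.
#'
#' @param tab A 2x2 numeric matrix of non-negative masses with positive row
#'   and column margins.
#' @return A list with `chi2`, `phi`, `p`, `direction` (+1, 0 or -1).
#' @export
#' @examples
#' chisq_phi(matrix(c(10, 10, 0, 20), 2))
chisq_phi <- function(tab) {
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs <= 0) || any(cs <= 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  total <- sum(tab)
  expected <- outer(rs, cs) / total
  chi2 <- sum((tab - expected)^2 / expected)
  list(
    chi2 = chi2,
    phi = sqrt(chi2 / total),
    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    direction = sign(tab[1, 1] - expected[1, 1])
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (via [stats::p.adjust()]) with
#' significance flags at `alpha`.
#'
#' @param p A vector of p-values.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `p`, `p_adj`, `significant`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  p_adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = p_adj, significant = p_adj <= alpha)
}

#' Select key action segments by TF-ISF chi-square
#'
#' Ranks the n-grams of one representation by the chi-square of their 2x2
#' TF-ISF mass table (this n-gram vs all others of the same order, success
#' vs failure) and flags those surviving Benjamini-Hochberg correction as
#' key segments. Direction `+1` marks overrepresentation in the successful
#' group. N-grams whose table has a zero margin (e.g. total weight 0
#' because they occur in every sequence) are skipped with a warning.
#'
#' @param encoded Output of [encode_sequences()].
#' @param outcome A tibble with `group_id` and logical `success` (e.g. from
#'   [summarize_sequences()] or a simulation truth table).
#' @param n N-gram order, 1 or 2.
#' @param alpha Significance level after correction.
#' @param base Logarithm base of the TF-ISF weight.
#' @return An object of class `ngram_selection`: a tibble with one row per
#'   n-gram (`ngram`, `tf_total`, `sf`, `mass_success`, `mass_failure`,
#'   `chi2`, `phi`, `p`, `p_adj`, `direction`, `key`), sorted by decreasing
#'   chi-square (ties broken lexicographically). Use [glance()] for the
#'   total/key summary.
#' @export
select_key_segments <- function(encoded, outcome, n = 1, alpha = 0.05,
                                base = exp(1)) {
  stopifnot(all(c("group_id", "success") %in% names(outcome)))
  if (length(unique(outcome$success)) < 2L) {
    stop("outcome labels are degenerate: need both successes and failures",
         call. = FALSE)
  }
  counts <- extract_ngrams(encoded, n = n)
  sf <- attr(counts, "sf")
  n_seq <- attr(counts, "n_seq")
  counts$weight <- tfisf_weight(counts$tf, n_seq, sf[counts$ngram],
                                base = base)
  counts <- dplyr::left_join(counts, outcome[c("group_id", "success")],
                             by = "group_id")
  mass <- dplyr::summarise(
    dplyr::group_by(counts, .data$ngram),
    tf_total = sum(.data$tf),
    mass_success = sum(.data$weight[.data$success]),
    mass_failure = sum(.data$weight[!.data$success]),
    .groups = "drop"
  )
  mass$sf <- as.integer(sf[mass$ngram])
  tot_succ <- sum(mass$mass_success)
  tot_fail <- sum(mass$mass_failure)
  stats_list <- purrr::pmap(
    list(mass$mass_success, mass$mass_failure, mass$ngram),
    function(ms, mf, ng) {
      tab <- matrix(c(ms, tot_succ - ms, mf, tot_fail - mf), nrow = 2)
      tryCatch(chisq_phi(tab), error = function(e) NULL)
    })
  skipped <- purrr::map_lgl(stats_list, is.null)
  if (any(skipped)) {
    warning(sum(skipped), " n-gram(s) skipped: zero margin in the 2x2 table",
            call. = FALSE)
  }
  res <- mass[!skipped, ]
  if (nrow(res) == 0L) {
    stop("no testable n-grams: every n-gram has zero TF-ISF mass ",
         "(all occur in every sequence)", call. = FALSE)
  }
  st <- dplyr::bind_rows(purrr::map(stats_list[!skipped], tibble::as_tibble))
  res <- dplyr::bind_cols(res, st)
  adj <- bh_adjust(res$p, alpha = alpha)
  res$p_adj <- adj$p_adj
  res$key <- adj$significant
  res <- dplyr::arrange(res, dplyr::desc(.data$chi2), .data$ngram)
  res <- res[, c("ngram", "tf_total", "sf", "mass_success", "mass_failure",
                 "chi2", "phi", "p", "p_adj", "direction", "key")]
  structure(res,
            class = c("ngram_selection", class(res)),
            n = as.integer(n),
            representation = attr(encoded, "representation"),
            alpha = alpha,
            n_seq = n_seq)
}

#' @export
print.ngram_selection <- function(x, ...) {
  cat("<ngram_selection> ", attr(x, "n"), "-grams, representation = ",
      attr(x, "representation") %||% "?", ", ", nrow(x), " segments (",
      sum(x$key), " key at alpha = ", attr(x, "alpha"), ")\n", sep = "")
  NextMethod()
}

#' Tidy and summarize an n-gram selection
#'
#' `tidy()` returns the per-n-gram table as a plain tibble; `glance()` one
#' row with the counts and the mean chi-square / phi over all and over key
#' segments (the layout used to compare representations).
#'
#' @param x An `ngram_selection`.
#' @param ... Unused.
#' @export
tidy.ngram_selection <- function(x, ...) {
  tibble::as_tibble(unclass_selection(x))
}

#' @rdname tidy.ngram_selection
#' @export
glance.ngram_selection <- function(x, ...) {
  key <- x[x$key, ]
  tibble::tibble(
    representation = attr(x, "representation") %||% NA_character_,
    n = attr(x, "n"),
    total_count = nrow(x),
    total_chi2 = mean(x$chi2),
    total_phi = mean(x$phi),
    key_count = nrow(key),
    key_chi2 = if (nrow(key)) mean(key$chi2) else NA_real_,
    key_phi = if (nrow(key)) mean(key$phi) else NA_real_
  )
}

unclass_selection <- function(x) {
  class(x) <- setdiff(class(x), "ngram_selection")
  attr(x, "n") <- NULL
  attr(x, "representation") <- NULL
  attr(x, "alpha") <- NULL
  attr(x, "n_seq") <- NULL
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
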