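toy_encoded <- function(tokens_by_group) {
  tibble::tibble(
    group_id = rep(names(tokens_by_group), lengths(tokens_by_group)),
    step = unlist(lapply(tokens_by_group, seq_along), use.names = FALSE),
    token = unlist(tokens_by_group, use.names = FALSE)
  )
}

test_that("n-gram extraction counts consecutive runs exhaustively", {
  enc <- toy_encoded(list(g1 = c("a", "b", "a"), g2 = c("b", "b")))
  uni <- extract_ngrams(enc, 1)
  expect_identical(uni$tf[uni$ngram == "a" & uni$group_id == "g1"], 2L)
  expect_identical(attr(uni, "sf")[["b"]], 2L)
  expect_identical(attr(uni, "n_seq"), 2L)

  bi <- extract_ngrams(enc, 2)
  expect_setequal(bi$ngram[bi$group_id == "g1"], c("a ; b", "b ; a"))
  expect_identical(bi$ngram[bi$group_id == "g2"], "b ; b")
  # a length-1 sequence contributes no bigrams
  short <- extract_ngrams(toy_encoded(list(g1 = "a", g2 = c("a", "b"))), 2)
  expect_identical(unique(short$group_id), "g2")
  expect_identical(attr(short, "n_seq"), 2L)
})

test_that("representation vocabularies have the expected bounds", {
  de <- extract_ngrams(planted_encoded("delta"), 1)
  expect_lte(length(attr(de, "sf")), 6L)   # 3 delta values x 2 roles
  sp <- extract_ngrams(planted_encoded("state_pair"), 1)
  expect_lte(length(attr(sp, "sf")), 38L)  # 19 realizable pairs x 2 roles
  raw <- extract_ngrams(planted_encoded("raw"), 1)
  expect_lte(length(attr(raw, "sf")), 168L)
})

test_that("TF-ISF follows its defining formula and monotonicities", {
  expect_identical(tfisf_weight(0, 10, 2), 0)
  expect_identical(tfisf_weight(3, 10, 10), 0)
  expect_equal(tfisf_weight(1, 10, 2), log(5))
  expect_equal(tfisf_weight(5, 12, 3), (1 + log(5)) * log(4))
  expect_equal(tfisf_weight(10, 100, 7, base = 10),
               (1 + log10(10)) * log10(100 / 7))
  # strictly increasing in tf, decreasing in sf away from the boundary
  expect_true(tfisf_weight(4, 10, 2) > tfisf_weight(3, 10, 2))
  expect_true(tfisf_weight(4, 10, 2) > tfisf_weight(4, 10, 3))
  expect_error(tfisf_weight(2, 10, 0), "inconsistent")
})

test_that("the 2x2 chi-square matches the textbook computation", {
  ind <- chisq_phi(matrix(c(5, 50, 5, 50), 2))
  expect_equal(ind$chi2, 0)
  expect_equal(ind$phi, 0)

  tab <- matrix(c(10, 10, 0, 20), 2)
  got <- chisq_phi(tab)
  want <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(got$chi2, unname(want$statistic))
  expect_equal(got$p, want$p.value)
  expect_equal(got$phi, sqrt(got$chi2 / sum(tab)))
  expect_identical(got$direction, 1)
  # swapping columns flips the direction, preserves chi-square
  swapped <- chisq_phi(tab[, 2:1])
  expect_equal(swapped$chi2, got$chi2)
  expect_identical(swapped$direction, -1)
  # invariant to scaling all cells
  expect_equal(chisq_phi(3.7 * tab)$phi, got$phi)
  expect_equal(chisq_phi(3.7 * tab)$chi2, 3.7 * got$chi2)
  expect_error(chisq_phi(matrix(c(0, 0, 1, 2), 2)), "zero margin")
})

test_that("BH adjustment equals an independent step-up implementation", {
  expect_equal(bh_adjust(0.01)$p_adj, 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9))$p_adj, c(0.03, 0.03, 0.9))
  expect_equal(bh_adjust(rep(0.2, 5))$p_adj, rep(0.2, 5))
  set.seed(42)
  for (i in 1:200) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj$p_adj, oracle_bh(p))
    expect_true(all(adj$p_adj >= adj$p))
  }
})

test_that("key-segment selection flags discriminative n-grams with direction", {
  enc <- toy_encoded(list(
    s1 = c("x", "a", "b"), s2 = c("x", "b", "a"), s3 = c("x", "a", "a"),
    f1 = c("y", "b", "b"), f2 = c("y", "a", "b"), f3 = c("b", "y", "a")
  ))
  outcome <- tibble::tibble(group_id = c("s1", "s2", "s3", "f1", "f2", "f3"),
                            success = rep(c(TRUE, FALSE), each = 3))
  sel <- select_key_segments(enc, outcome, n = 1)
  x_row <- sel[sel$ngram == "x", ]
  y_row <- sel[sel$ngram == "y", ]
  expect_identical(x_row$direction, 1)   # only in successes
  expect_identical(y_row$direction, -1)  # only in failures
  expect_identical(x_row$sf, 3L)
  # sorted by decreasing chi-square
  expect_true(!is.unsorted(rev(sel$chi2)))
  expect_error(
    select_key_segments(enc, dplyr::mutate(outcome, success = TRUE), 1),
    "degenerate")

  gl <- glance(sel)
  expect_identical(gl$total_count, nrow(sel))
  expect_identical(gl$key_count, sum(sel$key))
  expect_equal(gl$total_chi2, mean(sel$chi2))
})

test_that("label-independent corpora keep the key-flag rate within the FDR bound", {
  set.seed(99)
  flagged <- 0L
  tested <- 0L
  for (r in 1:120) {
    n <- 40
    enc <- toy_encoded(stats::setNames(
      lapply(1:n, function(i) sample(letters[1:20], 15, replace = TRUE)),
      sprintf("g%02d", 1:n)))
    outcome <- tibble::tibble(group_id = sprintf("g%02d", 1:n),
                              success = rep(c(TRUE, FALSE), each = n / 2))
    sel <- suppressWarnings(select_key_segments(enc, outcome, n = 1))
    flagged <- flagged + sum(sel$key)
    tested <- tested + nrow(sel)
  }
  expect_lte(flagged / tested, 0.05 + 0.02)
})

test_that("planted-ability cohorts yield forward-move key segments, state pairs >= raw", {
  out <- planted_cohort()$truth
  sel_sp <- select_key_segments(planted_encoded("state_pair"), out, n = 1)
  sel_raw <- select_key_segments(planted_encoded("raw"), out, n = 1)
  # the target-entering transitions are key and success-directed
  finishers <- sel_sp[sel_sp$ngram %in% c("A: 1->0", "B: 1->0"), ]
  expect_true(all(finishers$key))
  expect_true(all(finishers$direction == 1))
  expect_gte(sum(sel_sp$key), sum(sel_raw$key))
})
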