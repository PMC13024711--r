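test_that("DTW satisfies metric-like basics and the single-cell case", {
  expect_identical(dtw_distance(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_identical(dtw_distance(1, 2), 1)
  expect_identical(dtw_distance(c(1, 3), c(1, 2, 3)), 1)
  expect_error(dtw_distance(numeric(0), 1), "non-empty")
  set.seed(3)
  for (i in 1:20) {
    x <- stats::rnorm(sample(2:6, 1))
    y <- stats::rnorm(sample(2:6, 1))
    expect_gte(dtw_distance(x, y), 0)
    expect_identical(dtw_distance(x, y), dtw_distance(y, x))
  }
})

test_that("DTW equals the exhaustive warping-path oracle on short series", {
  alphabet <- c(0, 1, 3)
  series <- unlist(lapply(1:4, function(len) {
    grid <- expand.grid(rep(list(alphabet), len))
    lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
  }), recursive = FALSE)
  set.seed(8)
  pairs <- cbind(sample(length(series), 400, replace = TRUE),
                 sample(length(series), 400, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    x <- series[[pairs[r, 1]]]
    y <- series[[pairs[r, 2]]]
    expect_equal(dtw_distance(x, y), oracle_dtw(x, y))
    expect_equal(dtw_distance(x, y, "symmetric2"),
                 oracle_dtw(x, y, symmetric2 = TRUE))
  }
})

test_that("the DTW matrix is symmetric, zero-diagonal, order-independent", {
  set.seed(14)
  seqs <- lapply(1:7, function(i) stats::rnorm(sample(3:9, 1)))
  D <- dtw_matrix(seqs)
  expect_identical(D, t(D))
  expect_identical(unname(diag(D)), rep(0, 7))
  perm <- sample(7)
  expect_equal(dtw_matrix(seqs[perm]), D[perm, perm], ignore_attr = TRUE)
  same <- dtw_matrix(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_identical(unname(same), matrix(0, 3, 3))
  expect_error(dtw_matrix(list(c(1, 2))), "at least 2")
})

test_that("PAM recovers planted pairs and attains the exhaustive optimum", {
  D <- as.matrix(stats::dist(c(0, 1, 10, 11)))
  fit <- pam_cluster(D, 2)
  expect_identical(fit$assignment, c(1L, 1L, 2L, 2L))
  expect_identical(fit$objective, oracle_pam_objective(D, 2))
  # repeated runs are identical
  expect_identical(pam_cluster(D, 2)$medoids, fit$medoids)
  # k = number of distinct points drives the objective to zero
  expect_identical(pam_cluster(D, 3)$objective,
                   oracle_pam_objective(D, 3))
  expect_error(pam_cluster(D, 1), "k must satisfy")
  expect_error(pam_cluster(D, 4), "k must satisfy")

  set.seed(21)
  n_global <- 0L
  for (i in 1:15) {
    n <- sample(5:8, 1)
    pts <- stats::rnorm(n)
    Dr <- as.matrix(stats::dist(pts))
    k <- sample(2:3, 1)
    fit <- pam_cluster(Dr, k)
    global <- oracle_pam_objective(Dr, k)
    if (isTRUE(all.equal(fit$objective, global))) {
      n_global <- n_global + 1L
    } else {
      # a rare swap-terminated local optimum: must still be 1-swap optimal
      expect_true(oracle_one_swap_optimal(Dr, fit$medoids, fit$objective))
    }
    expect_gte(fit$objective, global - 1e-9)
  }
  expect_gte(n_global, 12L)  # the global optimum is found almost always
})

test_that("silhouette matches the hand formula; random labels score near zero", {
  # two pairs: within-distance 1, between-distance 10
  D <- matrix(10, 4, 4) - diag(10, 4)
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  lab <- c(1L, 1L, 2L, 2L)
  expect_equal(silhouette_mean(D, lab), 0.9)
  expect_equal(silhouette_mean(D, lab), oracle_silhouette(D, lab))
  expect_error(silhouette_mean(D, rep(1L, 4)), "two clusters")

  set.seed(31)
  n <- 40
  Dr <- as.matrix(stats::dist(stats::rnorm(n)))
  sils <- replicate(50, {
    lab <- sample(rep(1:2, each = n / 2))
    s <- silhouette_mean(Dr, lab)
    expect_equal(s, oracle_silhouette(Dr, lab))
    s
  })
  expect_true(all(abs(sils) <= 1))
  expect_lt(mean(abs(sils)), 0.2)
})

test_that("the medoid-based CH index follows its formula and rewards separation", {
  # points 0, 1, 10, 11: medoids {1, 3}, global medoid index 2;
  # W = 0 + 1 + 0 + 1 = 2, B = 2*1^2 + 2*9^2 = 164, CH = 164 / (2/2)
  D <- as.matrix(stats::dist(c(0, 1, 10, 11)))
  lab <- c(1L, 1L, 2L, 2L)
  expect_equal(ch_index(D, lab, medoids = c(1L, 3L)), 164)
  expect_equal(ch_index(D, lab), 164)  # medoids recomputed internally
  # relabeling clusters leaves the index unchanged
  expect_equal(ch_index(D, 3L - lab), 164)
  # a good split beats a bad split of the same data
  expect_gt(ch_index(D, lab), ch_index(D, c(1L, 2L, 1L, 2L)))
  expect_warning(ch_index(matrix(0, 4, 4), lab), "infinite")
})

test_that("k-scan flags the planted two-population structure", {
  set.seed(77)
  seqs <- c(lapply(1:12, function(i) stats::rnorm(8, mean = 0, sd = 0.3)),
            lapply(1:12, function(i) stats::rnorm(8, mean = 5, sd = 0.3)))
  D <- dtw_matrix(seqs)
  ks <- scan_k(D, 2:5)
  expect_identical(nrow(ks), 4L)
  expect_identical(ks$k[ks$best_silhouette], 2L)
  single <- scan_k(D, 2)
  expect_identical(nrow(single), 1L)
  # planted silhouette beats label permutations decisively
  fit <- pam_cluster(D, 2)
  set.seed(78)
  perm <- replicate(100, silhouette_mean(D, sample(fit$assignment)))
  expect_true(mean(perm >= fit$silhouette) < 0.01)
})

test_that("cluster feature comparisons use pooled t, BH, and Cohen's d", {
  set.seed(55)
  x <- stats::rnorm(30)
  feats <- tibble::tibble(f_same = c(x, x),
                          f_shift = c(x, x + 1),
                          f_const = 1)
  lab <- rep(1:2, each = 30)
  expect_warning(res <- compare_cluster_features(feats, lab), "skipped")
  expect_false("f_const" %in% res$feature)
  same <- res[res$feature == "f_same", ]
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)
  shift <- res[res$feature == "f_shift", ]
  expect_identical(shift$df, 58)
  # equal-n pooled d with unit shift and common sd: d = -1 / sd(x)
  expect_equal(shift$cohens_d, -1 / stats::sd(x))
  expect_error(compare_cluster_features(feats, rep(1, 60)), "exactly two")
})

test_that("effectiveness encodings cluster the planted cohort at least as well as raw codes", {
  fit_sp <- cluster_sequences(planted_encoded("state_pair"), k = 2)
  fit_raw <- cluster_sequences(planted_encoded("raw"), k = 2)
  expect_gte(fit_sp$silhouette, fit_raw$silhouette)
  expect_identical(sort(unique(fit_sp$assignment)), 1:2)
  td <- tidy(fit_sp)
  expect_identical(nrow(td), 80L)
  expect_identical(sum(td$is_medoid), 2L)
  expect_identical(glance(fit_sp)$silhouette, fit_sp$silhouette)
})
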