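# DTW distance matrices over numeric encoded sequences, PAM K-medoids, and
# cluster diagnostics (mean silhouette, a medoid-based Calinski-Harabasz
# generalization for distance matrices), plus cluster-interpretation t-tests.

#' Dynamic time warping distance
#'
#' Unnormalized DTW over monotone warping paths with absolute-difference
#' local cost. The default `"symmetric1"` recurrence is
#' `D(i,j) = |x_i - y_j| + min(D(i-1,j), D(i,j-1), D(i-1,j-1))`;
#' `"symmetric2"` doubles the local cost on the diagonal step. No warping
#' window or endpoint relaxation is applied.
#'
#' @param x,y Non-empty numeric series.
#' @param step_pattern `"symmetric1"` (default) or `"symmetric2"`.
#' @return The DTW distance (non-negative scalar).
#' @export
#' @examples
#' dtw_distance(c(1, 3), c(1, 2, 3))  # 1
dtw_distance <- function(x, y, step_pattern = c("symmetric1", "symmetric2")) {
  step_pattern <- match.arg(step_pattern)
  dtw_dist_cpp(as.numeric(x), as.numeric(y), step_pattern == "symmetric2")
}

#' Pairwise DTW distance matrix
#'
#' @param seqs A list of non-empty numeric series.
#' @inheritParams dtw_distance
#' @return A symmetric matrix with zero diagonal.
#' @export
dtw_matrix <- function(seqs, step_pattern = c("symmetric1", "symmetric2")) {
  step_pattern <- match.arg(step_pattern)
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  D <- dtw_matrix_cpp(lapply(seqs, as.numeric), step_pattern == "symmetric2")
  dimnames(D) <- list(names(seqs), names(seqs))
  D
}

#' K-medoids (PAM) clustering of a distance matrix
#'
#' Partitioning around medoids via [cluster::pam()] on the precomputed
#' dissimilarity matrix (deterministic BUILD initialization followed by SWAP
#' until no improving single swap remains).
#'
#' @param D A symmetric distance matrix.
#' @param k Number of clusters, `2 <= k < n`.
#' @return An object of class `seq_clustering`: a list with `k`, `medoids`
#'   (indices into `D`), `assignment`, `objective` (total distance of points
#'   to their medoids), `silhouette` (mean), `ch` (Calinski-Harabasz).
#'   [tidy()] gives per-sequence assignments, [glance()] the index row.
#' @export
pam_cluster <- function(D, k) {
  n <- nrow(D)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n", call. = FALSE)
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE,
                      keep.diss = FALSE)
  medoids <- as.integer(fit$id.med)
  assignment <- as.integer(fit$clustering)
  objective <- sum(D[cbind(seq_len(n), medoids[assignment])])
  structure(
    list(
      k = as.integer(k),
      medoids = medoids,
      assignment = assignment,
      objective = objective,
      silhouette = silhouette_mean(D, assignment),
      ch = ch_index(D, assignment, medoids)
    ),
    class = "seq_clustering",
    labels = rownames(D)
  )
}

#' @export
print.seq_clustering <- function(x, ...) {
  cat("<seq_clustering> k =", x$k, "over", length(x$assignment),
      "sequences\n")
  cat("  sizes:", paste(tabulate(x$assignment, x$k), collapse = "/"),
      " objective:", format(x$objective, digits = 6), "\n")
  cat("  mean silhouette:", format(x$silhouette, digits = 4),
      " Calinski-Harabasz:", format(x$ch, digits = 6), "\n")
  invisible(x)
}

#' Tidy and summarize a clustering
#'
#' @param x A `seq_clustering`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with `sequence` (label or index), `cluster`,
#'   `is_medoid`; `glance()`: one row with `k`, cluster sizes, `objective`,
#'   `silhouette`, `ch`.
#' @export
tidy.seq_clustering <- function(x, ...) {
  labels <- attr(x, "labels")
  tibble::tibble(
    sequence = if (is.null(labels)) seq_along(x$assignment) else labels,
    cluster = x$assignment,
    is_medoid = seq_along(x$assignment) %in% x$medoids
  )
}

#' @rdname tidy.seq_clustering
#' @export
glance.seq_clustering <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    sizes = paste(tabulate(x$assignment, x$k), collapse = "/"),
    objective = x$objective,
    silhouette = x$silhouette,
    ch = x$ch
  )
}

#' Mean silhouette width of a partition
#'
#' Per point: `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean
#' within-cluster distance (excluding self) and `b` the smallest mean
#' distance to another cluster; points in singleton clusters score 0
#' (computed via [cluster::silhouette()]).
#'
#' @param D A symmetric distance matrix.
#' @param assignment Integer cluster ids, at least two non-empty clusters.
#' @return The mean silhouette width in `[-1, 1]`.
#' @export
silhouette_mean <- function(D, assignment) {
  if (length(unique(assignment)) < 2L) {
    stop("silhouette requires at least two clusters", call. = FALSE)
  }
  sil <- cluster::silhouette(assignment, dmatrix = as.matrix(D))
  mean(sil[, "sil_width"])
}

#' Medoid-based Calinski-Harabasz index for a distance matrix
#'
#' A generalization of the variance-ratio criterion to arbitrary
#' dissimilarities: within-dispersion `W = sum_c sum_{i in c} D[i, m_c]^2`
#' uses squared distances to cluster medoids, between-dispersion
#' `B = sum_c n_c * D[m_c, m*]^2` uses the global medoid `m*` (the point
#' minimizing the total distance to all points). The index is
#' `(B / (k - 1)) / (W / (n - k))`; `W = 0` yields `Inf` with a warning.
#'
#' @param D A symmetric distance matrix.
#' @param assignment Integer cluster ids.
#' @param medoids Indices of the cluster medoids, one per cluster id in
#'   sorted order; if `NULL`, medoids are recomputed as each cluster's
#'   minimizer of summed within-cluster distance.
#' @return The index value (non-negative, possibly `Inf`).
#' @export
ch_index <- function(D, assignment, medoids = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  ids <- sort(unique(assignment))
  k <- length(ids)
  if (k < 2L) stop("CH index requires at least two clusters", call. = FALSE)
  if (is.null(medoids)) {
    medoids <- vapply(ids, function(c) {
      members <- which(assignment == c)
      members[which.min(colSums(D[members, members, drop = FALSE]))]
    }, integer(1))
  }
  global_medoid <- which.min(colSums(D))
  W <- 0
  B <- 0
  for (j in seq_len(k)) {
    members <- which(assignment == ids[j])
    W <- W + sum(D[members, medoids[j]]^2)
    B <- B + length(members) * D[medoids[j], global_medoid]^2
  }
  if (W == 0) {
    warning("zero within-cluster dispersion; CH index is infinite",
            call. = FALSE)
    return(Inf)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Scan candidate numbers of clusters
#'
#' Runs [pam_cluster()] for each `k` and tabulates the mean silhouette and
#' Calinski-Harabasz index, flagging the maximizer of each.
#'
#' @param D A symmetric distance matrix.
#' @param k_range Candidate cluster counts (default `2:6`).
#' @return A tibble of class `kscan` with columns `k`, `silhouette`, `ch`,
#'   `best_silhouette`, `best_ch`.
#' @export
scan_k <- function(D, k_range = 2:6) {
  rows <- purrr::map(k_range, function(k) {
    fit <- pam_cluster(D, k)
    tibble::tibble(k = k, silhouette = fit$silhouette, ch = fit$ch)
  })
  out <- dplyr::bind_rows(rows)
  out$best_silhouette <- out$silhouette == max(out$silhouette)
  out$best_ch <- out$ch == max(out$ch)
  class(out) <- c("kscan", class(out))
  out
}

#' Cluster encoded sequences end to end
#'
#' Convenience wrapper: collects each group's numeric `value` series from an
#' encoded log, computes the DTW distance matrix, and runs PAM.
#'
#' @param encoded Output of [encode_sequences()].
#' @param k Number of clusters.
#' @inheritParams dtw_distance
#' @return A `seq_clustering` (see [pam_cluster()]); the distance matrix is
#'   attached as attribute `"D"`.
#' @export
cluster_sequences <- function(encoded, k = 2,
                              step_pattern = c("symmetric1", "symmetric2")) {
  seqs <- sequence_values(encoded)
  D <- dtw_matrix(seqs, step_pattern = step_pattern)
  fit <- pam_cluster(D, k)
  attr(fit, "D") <- D
  fit
}

# split an encoded log into the per-group numeric series used by DTW
sequence_values <- function(encoded) {
  df <- dplyr::arrange(encoded, .data$group_id, .data$step)
  split(df$value, df$group_id)
}

#' Compare per-sequence features across two clusters
#'
#' Pooled-variance two-sided t-tests on each feature column, Benjamini-
#' Hochberg correction across the family, and Cohen's d with the pooled
#' standard deviation. Features with zero pooled variance are skipped with a
#' warning.
#'
#' @param features A tibble of per-sequence numeric features with a
#'   `group_id` column (e.g. unigram frequencies joined to
#'   [summarize_sequences()] output).
#' @param assignment Integer cluster ids (exactly two clusters), aligned
#'   with the rows of `features`.
#' @param alpha Significance level after correction.
#' @return A tibble with one row per feature: means, `t`, `df`, `p`,
#'   `p_adj`, `cohens_d`, `significant`.
#' @export
compare_cluster_features <- function(features, assignment, alpha = 0.05) {
  stopifnot(length(assignment) == nrow(features))
  ids <- sort(unique(assignment))
  if (length(ids) != 2L) {
    stop("feature comparison requires exactly two clusters", call. = FALSE)
  }
  num <- features[vapply(features, is.numeric, logical(1))]
  num <- num[setdiff(names(num), "group_id")]
  g1 <- assignment == ids[1]
  g2 <- assignment == ids[2]
  n1 <- sum(g1)
  n2 <- sum(g2)
  rows <- purrr::map(names(num), function(f) {
    x <- num[[f]][g1]
    y <- num[[f]][g2]
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    if (!is.finite(sp2) || sp2 <= 0) return(NULL)
    tt <- stats::t.test(x, y, var.equal = TRUE)
    tibble::tibble(
      feature = f,
      mean_1 = mean(x), mean_2 = mean(y),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value,
      cohens_d = (mean(x) - mean(y)) / sqrt(sp2)
    )
  })
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped)) {
    warning(sum(skipped), " feature(s) skipped: zero pooled variance",
            call. = FALSE)
  }
  out <- dplyr::bind_rows(rows[!skipped])
  adj <- bh_adjust(out$p, alpha = alpha)
  out$p_adj <- adj$p_adj
  out$significant <- adj$significant
  out
}
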