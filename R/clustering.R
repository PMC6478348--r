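#' Multi-restart k-means
#'
#' Runs k-means from `n_starts` random initializations and keeps the solution
#' with the lowest total within-cluster sum of squares. Deterministic given
#' `seed`.
#'
#' @param x A [feature_matrix()] or numeric matrix.
#' @param k Number of clusters, `2 <= k < n`.
#' @param n_starts Number of random restarts (default 50).
#' @param seed Integer seed.
#' @return A `cluster_assignment`: list with `labels` (named integer vector in
#'   `1..k`), `centers`, `total_wss`, `membership` (NULL for hard k-means),
#'   `method`.
#' @export
kmeans_multi <- function(x, k, n_starts = 50L, seed = 1L) {
  x <- as_matrix_checked(x)
  n <- nrow(x)
  k <- check_count(k, "k", min = 2L)
  if (k >= n) stop_config("'k' must be smaller than the number of observations")
  set.seed(check_count(seed, "seed", min = 0L))
  km <- stats::kmeans(x, centers = k, nstart = check_count(n_starts, "n_starts"),
                      iter.max = 100L)
  cluster_assignment(labels = km$cluster, centers = km$centers,
                     total_wss = km$tot.withinss, method = "kmeans")
}

cluster_assignment <- function(labels, centers, total_wss, membership = NULL,
                               method = "kmeans") {
  structure(list(labels = labels, centers = centers, total_wss = total_wss,
                 membership = membership, method = method),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(x$method, "partition:", paste(table(x$labels), collapse = "/"),
      "observations; total WSS", format(x$total_wss, digits = 6), "\n")
  invisible(x)
}

#' Order cluster indices by mean abundance
#'
#' Cluster indices returned by k-means are arbitrary; analyses that speak of
#' "the most abundant cluster" need a canonical order. Returns cluster indices
#' sorted by decreasing mean of `abundance` over members, along with the
#' relabeled sizes.
#'
#' @param assignment A `cluster_assignment`.
#' @param abundance Per-observation abundance (e.g. mean normalized count).
#' @return List with `order` (original indices, most abundant first) and
#'   `sizes` (cluster sizes in that order).
#' @export
clusters_by_abundance <- function(assignment, abundance) {
  means <- tapply(abundance, assignment$labels, mean)
  ord <- as.integer(names(sort(means, decreasing = TRUE)))
  list(order = ord, sizes = as.integer(table(assignment$labels)[as.character(ord)]))
}

#' Select the number of clusters
#'
#' Computes, over `k = 1..kmax` (multi-restart k-means throughout), the total
#' within-cluster sum of squares, the mean silhouette width (k >= 2), and the
#' gap statistic with `gap_B` uniform reference sets drawn inside the data's
#' bounding box. Three selections are reported: the wss elbow (the k whose
#' point on the wss curve is farthest from the chord joining k = 1 and
#' k = kmax), the silhouette maximizer, and the gap choice under Tibshirani's
#' 1-SE rule (smallest k with `gap(k) >= gap(k+1) - se(k+1)`); the consensus
#' is the rounded mean of the three.
#'
#' @param x A [feature_matrix()] or numeric matrix.
#' @param kmax Largest k to examine (default 10); must be < n.
#' @param n_starts k-means restarts per k.
#' @param gap_B Number of uniform reference datasets for the gap statistic.
#' @param seed Integer seed.
#' @return A `k_selection`: list with `table` (per-k wss, mean silhouette, gap,
#'   gap se), `elbow_k`, `silhouette_k`, `gap_k`, `consensus_k`.
#' @export
select_k <- function(x, kmax = 10L, n_starts = 50L, gap_B = 100L, seed = 1L) {
  x <- as_matrix_checked(x)
  n <- nrow(x)
  kmax <- check_count(kmax, "kmax", min = 2L)
  if (kmax >= n) stop_config("'kmax' must be smaller than the number of observations")
  seed <- check_count(seed, "seed", min = 0L)

  wss <- numeric(kmax)
  sil <- rep(NA_real_, kmax)
  dm <- stats::dist(x)
  for (k in seq_len(kmax)) {
    set.seed(seed + k)
    km <- stats::kmeans(x, centers = k, nstart = n_starts, iter.max = 100L)
    wss[k] <- km$tot.withinss
    if (k >= 2L)
      sil[k] <- mean(cluster::silhouette(km$cluster, dm)[, "sil_width"])
  }

  set.seed(seed)
  gp <- cluster::clusGap(x, FUNcluster = function(xx, kk)
                           stats::kmeans(xx, kk, nstart = n_starts, iter.max = 100L),
                         K.max = kmax, B = check_count(gap_B, "gap_B"),
                         spaceH0 = "original", verbose = FALSE)
  gap <- gp$Tab[, "gap"]
  gap_se <- gp$Tab[, "SE.sim"]

  elbow_k <- .elbow_chord(wss)
  silhouette_k <- which.max(sil)
  gap_k <- cluster::maxSE(gap, gap_se, method = "Tibs2001SEmax")
  consensus_k <- as.integer(round(mean(c(elbow_k, silhouette_k, gap_k))))

  structure(list(
    table = data.frame(k = seq_len(kmax), wss = wss, silhouette = sil,
                       gap = gap, gap_se = gap_se),
    elbow_k = as.integer(elbow_k), silhouette_k = as.integer(silhouette_k),
    gap_k = as.integer(gap_k), consensus_k = consensus_k
  ), class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("k selection: elbow", x$elbow_k, "| silhouette", x$silhouette_k,
      "| gap", x$gap_k, "-> consensus", x$consensus_k, "\n")
  invisible(x)
}

# elbow: k maximizing perpendicular distance to the chord from (1, wss_1) to
# (kmax, wss_kmax)
.elbow_chord <- function(wss) {
  k <- seq_along(wss)
  x1 <- k[1]; y1 <- wss[1]; x2 <- k[length(k)]; y2 <- wss[length(k)]
  num <- abs((y2 - y1) * k - (x2 - x1) * wss + x2 * y1 - y2 * x1)
  which.max(num / sqrt((y2 - y1)^2 + (x2 - x1)^2))
}

#' Hierarchical clustering on principal components
#'
#' Ward-linkage hierarchical clustering of the PCA factor scores, followed by
#' a k-means consolidation seeded at the cluster barycenters (which can only
#' lower the within-cluster inertia). When `k` is not given, the tree is cut
#' at the k in `2..min(10, n - 1)` with the largest relative jump in merge
#' height (the standard automatic reading of "where the tree wants to be
#' cut").
#'
#' @param pca An `exonml_pca` object (>= 2 retained components).
#' @param k Number of clusters; chosen from the tree when NULL.
#' @param consolidate Run the k-means consolidation step (default TRUE).
#' @return A `cluster_assignment` with extra fields `tree` (the hclust) and
#'   `wss_before` (inertia of the pre-consolidation partition).
#' @export
hcpc <- function(pca, k = NULL, consolidate = TRUE) {
  stopifnot(inherits(pca, "exonml_pca"))
  scores <- pca$scores
  n <- nrow(scores)
  if (n < 3L) stop_config("HCPC needs at least 3 observations")
  if (ncol(scores) < 2L) stop_config("HCPC needs at least 2 retained components")
  tree <- stats::hclust(stats::dist(scores), method = "ward.D2")
  if (is.null(k)) {
    kmax <- min(10L, n - 1L)
    heights <- rev(tree$height)   # heights[j] = merge closing the j+1 -> j step
    ratios <- heights[seq_len(kmax - 1L)] /
      heights[seq_len(kmax - 1L) + 1L]
    k <- which.max(ratios) + 1L
  }
  k <- check_count(k, "k", min = 1L)
  labels <- stats::cutree(tree, k = min(k, n))
  centers <- .barycenters(scores, labels)
  wss_before <- .partition_wss(scores, labels, centers)
  if (consolidate && k > 1L && k < n) {
    km <- stats::kmeans(scores, centers = centers, iter.max = 100L)
    labels <- km$cluster
    centers <- km$centers
    wss_after <- km$tot.withinss
  } else {
    wss_after <- wss_before
  }
  out <- cluster_assignment(labels = labels, centers = centers,
                            total_wss = wss_after, method = "hcpc")
  out$tree <- tree
  out$wss_before <- wss_before
  out
}

.barycenters <- function(x, labels) {
  ctr <- apply(x, 2, function(col) tapply(col, labels, mean))
  if (is.null(dim(ctr)))
    ctr <- matrix(ctr, nrow = 1, dimnames = list(names(table(labels)), colnames(x)))
  ctr
}

.partition_wss <- function(x, labels, centers) {
  sum(vapply(seq_len(nrow(x)), function(i) {
    sum((x[i, ] - centers[as.character(labels[i]), ])^2)
  }, numeric(1)))
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means (alternating membership/center updates, Euclidean
#' distance). Every observation receives a membership coefficient for each
#' cluster (rows sum to 1); hard labels are the membership argmax.
#'
#' @param x A [feature_matrix()] or numeric matrix.
#' @param k Number of clusters, `2 <= k < n`.
#' @param fuzzifier Fuzziness exponent m > 1 (default 2).
#' @param seed Integer seed (initial memberships are random).
#' @param tol Relative convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1000); non-convergence returns the
#'   best iterate with a warning.
#' @return A `cluster_assignment` with `membership` filled in and
#'   `method = "fcm"`.
#' @export
fuzzy_cmeans <- function(x, k, fuzzifier = 2, seed = 1L, tol = 1e-6,
                         max_iter = 1000L) {
  x <- as_matrix_checked(x)
  n <- nrow(x)
  k <- check_count(k, "k", min = 2L)
  if (k >= n) stop_config("'k' must be smaller than the number of observations")
  if (!is.numeric(fuzzifier) || fuzzifier <= 1)
    stop_config("'fuzzifier' must be > 1")
  set.seed(check_count(seed, "seed", min = 0L))
  fit <- e1071::cmeans(x, centers = k, m = fuzzifier,
                       iter.max = check_count(max_iter, "max_iter"),
                       control = list(reltol = tol))
  if (fit$iter >= max_iter)
    warning("fuzzy c-means hit the iteration cap; returning the best iterate",
            call. = FALSE)
  labels <- apply(fit$membership, 1, which.max)
  names(labels) <- rownames(x)
  wss <- sum(vapply(seq_len(n), function(i)
    sum((x[i, ] - fit$centers[labels[i], ])^2), numeric(1)))
  cluster_assignment(labels = labels, centers = fit$centers, total_wss = wss,
                     membership = fit$membership, method = "fcm")
}

as_matrix_checked <- function(x) {
  m <- as.matrix(unclass(x))
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_config("input matrix must not contain missing values")
  m
}
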