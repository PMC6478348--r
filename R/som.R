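#' Fit a self-organizing map
#'
#' Online Kohonen training on a rectangular grid: at each step one randomly
#' drawn observation updates its best-matching unit and neighbors under a
#' Gaussian neighborhood whose radius decays linearly from half the larger
#' grid dimension to 0.5 over training; the learning rate is constant. One
#' epoch presents one randomly drawn observation. After training the codebook
#' vectors are hierarchically clustered (Ward) so the map can be partitioned
#' into a requested number of clusters via [som_partition()].
#'
#' The map is refused when the data cannot populate it: training requires at
#' least `nodes / 3` observations and at least 3 variables, otherwise most
#' nodes stay empty and the map cannot learn the data.
#'
#' @param x A [feature_matrix()] or numeric matrix.
#' @param grid `c(rows, cols)` of the node grid. Default: close-to-square grid
#'   with about `5 * sqrt(n)` nodes.
#' @param learning_rate Constant learning rate (default 0.01).
#' @param epochs Training steps (default 15000).
#' @param seed Integer seed.
#' @return A `som_result`: list with `codebook` (nodes x variables), `grid`,
#'   `training_curve` (mean observation-to-BMU distance at 11 checkpoints from
#'   start to end of training), `node_assignments`, `node_tree` (Ward hclust
#'   of codebook vectors).
#' @export
som_fit <- function(x, grid = NULL, learning_rate = 0.01, epochs = 15000L,
                    seed = 1L) {
  x <- as_matrix_checked(x)
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(grid)) {
    total <- ceiling(5 * sqrt(n))
    cols <- ceiling(sqrt(total))
    grid <- c(ceiling(total / cols), cols)
  }
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L))
    stop_config("'grid' must be c(rows, cols) of positive integers")
  n_nodes <- prod(grid)
  if (p < 3L || n < n_nodes / 3)
    stop_config("insufficient observations for SOM: need >= ", ceiling(n_nodes / 3),
                " observations for a ", grid[1], "x", grid[2],
                " map and >= 3 variables (got n = ", n, ", p = ", p, ")")
  epochs <- check_count(epochs, "epochs", min = 10L)
  set.seed(check_count(seed, "seed", min = 0L))

  node_xy <- cbind(rep(seq_len(grid[1]), times = grid[2]),
                   rep(seq_len(grid[2]), each = grid[1]))
  grid_d2 <- cross_dist2(node_xy, node_xy)
  # uniform random initialization inside the data's bounding box
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  codebook <- vapply(seq_len(p), function(j) stats::runif(n_nodes, lo[j], hi[j]),
                     numeric(n_nodes))
  dimnames(codebook) <- list(paste0("node", seq_len(n_nodes)), colnames(x))

  r0 <- max(grid) / 2
  checkpoints <- unique(round(seq(0, epochs, length.out = 11L)))
  curve <- numeric(length(checkpoints))
  ci <- 1L
  mean_bmu_dist <- function() {
    d2 <- cross_dist2(x, codebook)
    mean(sqrt(apply(d2, 1, min)))
  }
  draw <- sample.int(n, epochs, replace = TRUE)
  for (t in seq_len(epochs)) {
    if (ci <= length(checkpoints) && (t - 1L) == checkpoints[ci]) {
      curve[ci] <- mean_bmu_dist()
      ci <- ci + 1L
    }
    obs <- x[draw[t], ]
    bmu <- which.min(colSums((t(codebook) - obs)^2))
    radius <- max(0.5, r0 * (1 - t / epochs))
    h <- exp(-grid_d2[bmu, ] / (2 * radius^2))
    active <- h > 1e-3
    codebook[active, ] <- codebook[active, ] +
      learning_rate * h[active] * sweep(-codebook[active, , drop = FALSE], 2,
                                        obs, "+")
  }
  if (ci <= length(checkpoints)) curve[ci] <- mean_bmu_dist()

  d2 <- cross_dist2(x, codebook)
  node_assignments <- apply(d2, 1, which.min)
  names(node_assignments) <- rownames(x)
  node_tree <- stats::hclust(stats::dist(codebook), method = "ward.D2")
  structure(list(codebook = codebook, grid = grid, training_curve = curve,
                 node_assignments = node_assignments, node_tree = node_tree),
            class = "som_result")
}

#' Partition SOM observations via the codebook dendrogram
#'
#' Cuts the Ward tree of codebook vectors at `k` clusters and maps every
#' observation to its node's cluster.
#'
#' @param som A `som_result`.
#' @param k Number of clusters.
#' @return Named integer vector of per-observation cluster labels.
#' @export
som_partition <- function(som, k) {
  stopifnot(inherits(som, "som_result"))
  node_cluster <- stats::cutree(som$node_tree, k = check_count(k, "k", min = 1L))
  labels <- node_cluster[som$node_assignments]
  names(labels) <- names(som$node_assignments)
  labels
}

#' @export
print.som_result <- function(x, ...) {
  cat(sprintf("SOM %dx%d (%d nodes); mean BMU distance %.3f -> %.3f\n",
              x$grid[1], x$grid[2], prod(x$grid),
              x$training_curve[1], x$training_curve[length(x$training_curve)]))
  invisible(x)
}
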