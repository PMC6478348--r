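#' Hopkins statistic of spatial randomness
#'
#' Assesses cluster tendency by comparing nearest-neighbor distances of real
#' observations against uniform probe points. Per repeat: `m` real
#' observations are sampled without replacement and `m` probe points are drawn
#' uniformly inside the per-variable range of the data; `sum_y` is the summed
#' nearest-neighbor distance of the sampled real points to the *remaining*
#' real data, `sum_x` the summed nearest-neighbor distance of the probes to
#' that same remaining set (both probe kinds face the same number of candidate
#' neighbors, so the statistic is centered at 0.5 under uniformity), and the
#' repeat's statistic is
#' `H = sum_y / (sum_x + sum_y)`. The reported `H` is the mean over repeats.
#'
#' Orientation: spatially uniform data give `H ~ 0.5` (real and probe
#' neighbor distances agree); strongly clustered data give `H -> 0` (real
#' points sit much closer to each other than uniform probes do).
#'
#' @param x A [feature_matrix()] or numeric matrix (n >= 3).
#' @param m Real points sampled per repeat; default `max(2, ceiling(0.1 * n))`,
#'   must satisfy `m < n`.
#' @param repeats Number of repeats to average (default 100).
#' @param seed Integer seed.
#' @param frame Optional sampling frame for the uniform probes: a 2-row matrix
#'   of per-variable `c(low, high)` bounds. Defaults to the observed
#'   per-variable range of `x`. When the data's true support is known (e.g.
#'   for a synthetic uniform reference), passing it here removes the
#'   small-sample shrinkage of the observed bounding box, which otherwise
#'   biases H upward in high dimension.
#' @return A `hopkins_result`: list with `H`, `m`, `repeats`, `per_repeat`,
#'   `sum_x`, `sum_y` (totals over repeats; `H` is recomputable per repeat
#'   from the stored per-repeat sums in `detail`).
#' @export
hopkins <- function(x, m = NULL, repeats = 100L, seed = 1L, frame = NULL) {
  x <- as_matrix_checked(x)
  n <- nrow(x)
  if (n < 3L) stop_config("Hopkins needs at least 3 observations")
  m <- m %||% max(2L, ceiling(0.1 * n))
  m <- check_count(m, "m", min = 1L)
  if (m >= n) stop_config("'m' must be smaller than the number of observations")
  repeats <- check_count(repeats, "repeats", min = 1L)
  set.seed(check_count(seed, "seed", min = 0L))
  if (is.null(frame)) {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
  } else {
    frame <- as.matrix(frame)
    if (nrow(frame) != 2L || ncol(frame) != ncol(x) || any(frame[1, ] > frame[2, ]))
      stop_config("'frame' must be a 2-row matrix of ordered per-variable bounds")
    lo <- frame[1, ]
    hi <- frame[2, ]
  }
  if (all(hi == lo)) {
    warning("all observations identical; Hopkins statistic set to 0",
            call. = FALSE)
    return(structure(list(H = 0, m = m, repeats = repeats,
                          per_repeat = rep(0, repeats), sum_x = 0, sum_y = 0,
                          detail = NULL),
                     class = "hopkins_result"))
  }
  detail <- t(vapply(seq_len(repeats), function(r) {
    idx <- sample.int(n, m)
    y <- sqrt(apply(cross_dist2(x[idx, , drop = FALSE],
                                x[-idx, , drop = FALSE]), 1, min))
    probes <- vapply(seq_along(lo), function(j) stats::runif(m, lo[j], hi[j]),
                     numeric(m))
    if (m == 1L) probes <- matrix(probes, nrow = 1L)
    xx <- sqrt(apply(cross_dist2(probes, x[-idx, , drop = FALSE]), 1, min))
    c(sum_x = sum(xx), sum_y = sum(y))
  }, c(sum_x = 0, sum_y = 0)))
  denom <- detail[, "sum_x"] + detail[, "sum_y"]
  per_repeat <- ifelse(denom > 0, detail[, "sum_y"] / denom, 0)
  structure(list(H = mean(per_repeat), m = m, repeats = repeats,
                 per_repeat = per_repeat,
                 sum_x = sum(detail[, "sum_x"]), sum_y = sum(detail[, "sum_y"]),
                 detail = as.data.frame(detail)),
            class = "hopkins_result")
}

#' @export
print.hopkins_result <- function(x, ...) {
  cat(sprintf("Hopkins statistic H = %.3f (m = %d, %d repeats)\n",
              x$H, x$m, x$repeats))
  invisible(x)
}

#' Visual assessment of cluster tendency (VAT) ordering
#'
#' Reorders the Euclidean dissimilarity matrix along a Prim-style
#' minimum-spanning-tree traversal so that clustered data show dark diagonal
#' blocks when the ordered matrix is rendered as a heatmap. The traversal
#' starts from one endpoint of the maximal-dissimilarity pair and repeatedly
#' appends the unvisited observation closest to the visited set.
#'
#' @param x A [feature_matrix()], numeric matrix, or `dist` object (n >= 2).
#' @return A `vat_result`: list with `ordering` (a permutation of `1..n`) and
#'   `ordered_dissimilarity` (the permuted symmetric matrix).
#' @export
vat <- function(x) {
  d <- if (inherits(x, "dist")) as.matrix(x) else {
    m <- as_matrix_checked(x)
    as.matrix(stats::dist(m))
  }
  n <- nrow(d)
  if (n < 2L) stop_config("VAT needs at least 2 observations")
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  order_out <- integer(n)
  visited <- logical(n)
  order_out[1] <- far[["row"]]
  visited[order_out[1]] <- TRUE
  # min distance of each unvisited point to the visited set, updated greedily
  mindist <- d[order_out[1], ]
  for (i in seq_len(n - 1L)) {
    mindist[visited] <- Inf
    nxt <- which.min(mindist)
    order_out[i + 1L] <- nxt
    visited[nxt] <- TRUE
    mindist <- pmin(mindist, d[nxt, ])
  }
  structure(list(ordering = order_out,
                 ordered_dissimilarity = d[order_out, order_out]),
            class = "vat_result")
}
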