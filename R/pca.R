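#' Principal component analysis with observation diagnostics
#'
#' PCA of a standardized feature matrix in the French-school convention:
#' columns are standardized to unit *population* variance (divisor n), so the
#' eigenvalues sum to the number of variables. Besides scores and variable
#' loadings it returns the two per-observation diagnostics this workflow relies
#' on: the **contribution** of observation i to component j,
#' `100 * score(i,j)^2 / (n * eigenvalue_j)` (each component's contributions
#' sum to 100), and the **cos2** quality of representation,
#' `score(i,j)^2 / sum_c score(i,c)^2` (each observation's cos2 values sum
#' to 1 over all computed components). If the input carries a qualitative
#' label, category barycenters of the scores are returned as supplementary
#' centroids (they play no part in the fit).
#'
#' @param x A scaled [feature_matrix()] with >= 3 observations and >= 2
#'   variables.
#' @param ncp Number of components to keep in `scores`/`loadings` (diagnostics
#'   always use all computed components). Default: all.
#' @return An object of class `exonml_pca`: list with `eigenvalues`, `scores`,
#'   `loadings` (variable coordinates, i.e. correlations with components),
#'   `cos2`, `contributions`, `supplementary_centroids`, `n_obs`, `n_var`.
#' @export
run_pca <- function(x, ncp = NULL) {
  stopifnot(inherits(x, "feature_matrix"))
  if (!is_scaled(x))
    stop_config("PCA expects standardized input; ",
                "use build_feature_matrix(scale = TRUE) or scale_features()")
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3L) stop_config("PCA needs at least 3 observations")
  if (p < 2L) stop_config("PCA needs at least 2 variables")
  # re-standardize to population variance so sum(eigenvalues) == p exactly
  xs <- sweep(unclass(x), 2, colMeans(x))
  pop_sd <- sqrt(colMeans(xs^2))
  xs <- sweep(xs, 2, pop_sd, "/")
  sv <- svd(xs)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  eig <- d^2 / n
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  dimnames(scores) <- list(rownames(x), paste0("Dim.", seq_along(d)))
  loadings <- sweep(sv$v[, keep, drop = FALSE], 2, sqrt(eig), "*")
  dimnames(loadings) <- list(colnames(x), colnames(scores))
  contrib <- 100 * sweep(scores^2, 2, n * eig, "/")
  cos2 <- scores^2 / rowSums(scores^2)
  ncp <- min(ncp %||% length(d), length(d))
  centroids <- NULL
  qual <- attr(x, "qualitative")
  if (!is.null(qual)) {
    centroids <- apply(scores, 2, function(s) tapply(s, qual, mean))
    if (is.null(dim(centroids)))
      centroids <- matrix(centroids, nrow = 1,
                          dimnames = list(unique(qual), colnames(scores)))
  }
  structure(list(eigenvalues = eig,
                 scores = scores[, seq_len(ncp), drop = FALSE],
                 loadings = loadings[, seq_len(ncp), drop = FALSE],
                 cos2 = cos2, contributions = contrib,
                 supplementary_centroids = centroids,
                 n_obs = n, n_var = p),
            class = "exonml_pca")
}

#' @export
print.exonml_pca <- function(x, ...) {
  cat("PCA:", x$n_obs, "observations x", x$n_var, "variables\n")
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat("variance explained (%):",
      paste(sprintf("%s %.1f", names(x$eigenvalues) %||%
                      paste0("Dim.", seq_along(pct)), pct), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rank observations by their contribution to selected components
#'
#' Observations are ranked by their summed contribution over the requested
#' components; ties are broken by observation id (lexicographic), so the
#' ranking is reproducible and invariant to input row order.
#'
#' @param pca An `exonml_pca` object.
#' @param dims Components to sum over (default first two).
#' @param n How many top observations to return; if larger than the number of
#'   observations the full ranking is returned with a warning.
#' @return data.frame with `observation`, one `Dim.<j>` contribution column
#'   per requested component, and `total`.
#' @export
top_contributors <- function(pca, dims = 1:2, n = 50L) {
  stopifnot(inherits(pca, "exonml_pca"))
  if (any(dims > ncol(pca$contributions)))
    stop_config("'dims' exceed the number of computed components")
  contrib <- pca$contributions[, dims, drop = FALSE]
  total <- rowSums(contrib)
  ord <- order(-total, rownames(contrib))
  if (n > length(total)) {
    warning("fewer observations than requested; returning the full ranking",
            call. = FALSE)
    n <- length(total)
  }
  sel <- ord[seq_len(n)]
  out <- data.frame(observation = rownames(contrib)[sel],
                    contrib[sel, , drop = FALSE], total = total[sel],
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
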