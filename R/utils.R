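# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(sprintf("'%s' must be a single value in [0, 1]", name))
  x
}

check_range <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2])
    stop_config(sprintf("'%s' must be an ordered pair c(low, high)", name))
  if (positive && any(x <= 0))
    stop_config(sprintf("'%s' must be strictly positive", name))
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_config(sprintf("'%s' must be an integer >= %d", name, min))
  as.integer(x)
}

# Uniform integer draws from an inclusive range; immune to sample()'s
# scalar expansion when low == high.
sample_range <- function(range, n) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# Squared Euclidean distances from each row of p (m x d) to each row of q (n x d);
# returns an m x n matrix. Small inputs only; used by Hopkins, VAT and SOM.
cross_dist2 <- function(p, q) {
  pp <- rowSums(p^2)
  qq <- rowSums(q^2)
  d2 <- outer(pp, qq, "+") - 2 * tcrossprod(p, q)
  d2[d2 < 0] <- 0
  d2
}

# Empirical Kolmogorov distance of a sample against Uniform(0, 1).
ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  i <- seq_len(n)
  max(pmax(abs(i / n - p), abs((i - 1) / n - p)))
}
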