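# Independent oracles and small data builders used across tests.

# Brute-force BH step-up: adjusted p_(i) = min(1, min_{j >= i} m * p_(j) / j).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * sorted[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force hypergeometric upper tail P(X >= ov).
hyper_oracle <- function(ov, K, n, N) {
  if (ov <= 0) return(1)
  hi <- min(K, n)
  if (ov > hi) return(0)
  sum(stats::dhyper(ov:hi, K, N - K, n))
}

# Kolmogorov distance of a sample against Uniform(0, 1).
ks_uniform_stat <- function(p) {
  p <- sort(p)
  n <- length(p)
  i <- seq_len(n)
  max(pmax(abs(i / n - p), abs((i - 1) / n - p)))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Gaussian blobs with known labels.
make_blobs <- function(centers, n_per, sd = 0.3, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(stats::rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  rownames(x) <- paste0("b", seq_len(nrow(x)))
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  list(x = feature_matrix(x),
       labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Catalog with one term per requested size over a g1..gN universe; term i is
# the first sizes[i] genes.
make_catalog <- function(N, sizes, n_meta = 1) {
  universe <- paste0("g", seq_len(N))
  sets <- lapply(sizes, function(K) universe[seq_len(K)])
  names(sets) <- paste0("T", seq_along(sizes))
  meta <- data.frame(term_id = names(sets),
                     meta_group = rep_len(paste0("meta_", seq_len(n_meta)),
                                          length(sets)))
  annotation_catalog(sets, universe, meta)
}

# Small two-condition count table with hand-set counts (one gene).
toy_counts <- function(mat, gene = "G1") {
  n_exon <- nrow(mat)
  data.frame(gene_id = rep(gene, n_exon),
             exon_id = sprintf("%s:E%03d", gene, seq_len(n_exon)),
             chrom = "chr1", start = seq_len(n_exon) * 1000L,
             end = seq_len(n_exon) * 1000L + 199L, strand = "+",
             as.data.frame(mat), stringsAsFactors = FALSE)
}
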