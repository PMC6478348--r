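#' Median-of-ratios size factors
#'
#' Library-size normalization in the DESeq/DEXSeq family: each sample's factor
#' is the median, over exons with all-positive counts, of the ratio of that
#' sample's count to the exon's geometric mean across samples. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Exon count table (see [read_exon_counts()]) or a numeric
#'   count matrix with samples in columns.
#' @return Named numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- if (is.data.frame(counts)) count_matrix(counts) else as.matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop_config("no exon has positive counts in every sample; ",
                "median-of-ratios needs at least one all-positive row ",
                "(consider a pseudo-reference on filtered data)")
  logm <- log(m[pos, , drop = FALSE])
  logref <- rowMeans(logm)
  sf <- apply(exp(logm - logref), 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (monotone-enforced, capped at 1), with input
#' validation.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))
    stop_config("p-values must all lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Filter results at an FDR threshold
#'
#' @param results DEU result data.frame with a `p_bh` column.
#' @param fdr FDR cutoff; rows with `p_bh < fdr` are kept (strict), preserving
#'   the input order. Default 0.1, the threshold every downstream analysis in
#'   this package assumes.
#' @return The filtered data.frame.
#' @export
filter_significant <- function(results, fdr = 0.1) {
  if (!is.numeric(fdr) || length(fdr) != 1L || fdr < 0 || fdr > 1)
    stop_config("'fdr' must be a single value in [0, 1]")
  results[results$p_bh < fdr, , drop = FALSE]
}

#' Test differential exon usage
#'
#' A simplified DEXSeq-style test. For each exon of a multi-exon gene, the
#' counts of "this exon" and of "the sum of the gene's other exons" are modeled
#' with a negative-binomial GLM (log link, size factors as offsets):
#' the full model has sample and exon-bin effects plus a condition:exon
#' interaction, the reduced model drops the interaction, and the p-value comes
#' from the chi-squared(1) likelihood-ratio statistic. Dispersion is estimated
#' per exon by method-of-moments on the normalized counts (within-condition
#' moments) and then moderated by averaging with the dataset-wide mean
#' dispersion, floored at 1e-8; with two replicates per condition the raw
#' per-exon estimate is far too noisy to keep the chi-squared reference
#' honest, and this equal-weight shrinkage restores type-I calibration.
#' Exon usage coefficients are the fitted exon-bin effect per condition
#' (reference condition: the exon effect itself; other condition: exon effect
#' plus interaction).
#'
#' The fold change is reported as `log2fc = log2(mean_ref / mean_other)` on
#' normalized condition means (pseudocount 0.5), so with `ref = "control"` an
#' exon that alcohol up-regulates has a negative `log2fc`.
#'
#' @param counts Exon count table (data.frame layout of [read_exon_counts()]).
#' @param conditions Named character vector mapping every sample column to one
#'   of exactly two condition labels, each with >= 2 samples.
#' @param size_factors Optional named size factors; estimated from `counts`
#'   when omitted.
#' @param ref Reference (numerator) condition for the fold change; defaults to
#'   `"control"` when present, otherwise the first label alphabetically.
#' @return A data.frame with one row per testable exon: `exon_id`, `gene_id`,
#'   coordinates when present in `counts`, `base_mean`, `norm_<sample>`
#'   normalized counts, `usage_<condition>` coefficients, `log2fc`, `p_raw`,
#'   `p_bh`, `dispersion`, `converged`. Single-exon genes are skipped with a
#'   warning.
#' @export
test_differential_usage <- function(counts, conditions, size_factors = NULL,
                                    ref = NULL) {
  samples <- count_samples(counts)
  if (!all(samples %in% names(conditions)))
    stop_config("every sample column needs a condition label")
  conditions <- conditions[samples]
  levs <- sort(unique(conditions))
  if (length(levs) != 2L)
    stop_config("exactly two condition labels are required")
  if (any(table(conditions) < 2L))
    stop_config("each condition needs at least two samples")
  ref <- ref %||% if ("control" %in% levs) "control" else levs[1]
  if (!ref %in% levs) stop_config("'ref' must be one of the condition labels")
  alt <- setdiff(levs, ref)

  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  size_factors <- size_factors[samples]
  m <- count_matrix(counts)
  norm <- sweep(m, 2, size_factors, "/")
  gene <- counts$gene_id

  single <- names(which(table(gene) < 2L))
  if (length(single))
    warning(length(single), " single-exon gene(s) skipped: cannot test usage",
            call. = FALSE)
  testable <- gene %in% setdiff(unique(gene), single)

  n_s <- length(samples)
  is_alt <- as.numeric(conditions == alt)
  # design shared by every exon: 2*n_s observations (this exon, then others)
  sample_f <- factor(rep(samples, 2L), levels = samples)
  exon_this <- rep(c(1, 0), each = n_s)
  x_red <- cbind(stats::model.matrix(~sample_f), exon_this = exon_this)
  x_full <- cbind(x_red, interaction = exon_this * rep(is_alt, 2L))
  offs <- rep(log(size_factors), 2L)
  fam_cache <- new.env(parent = emptyenv())

  # moderated dispersion: per-exon MOM averaged with the dataset-wide mean
  mom_raw <- apply(norm, 1, .mom_raw, conditions = conditions)
  alpha_common <- mean(mom_raw, na.rm = TRUE)
  if (!is.finite(alpha_common)) alpha_common <- 1e-8
  alpha_common <- max(alpha_common, 1e-8)
  mom_filled <- ifelse(is.na(mom_raw), alpha_common, mom_raw)
  dispersion <- pmax((mom_filled + alpha_common) / 2, 1e-8)

  gene_rows <- split(which(testable), gene[testable])
  res <- vector("list", length(gene_rows))
  gi <- 0L
  for (g in names(gene_rows)) {
    rows <- gene_rows[[g]]
    gene_tot <- colSums(m[rows, , drop = FALSE])
    exon_res <- lapply(rows, function(r) {
      this <- m[r, ]
      other <- gene_tot - this
      nrm <- norm[r, ]
      mu_ref <- mean(nrm[conditions == ref])
      mu_alt <- mean(nrm[conditions == alt])
      disp <- dispersion[r]
      y <- c(this, other)
      fit <- .nb_lrt(x_full, x_red, y, offs, disp, fam_cache)
      data.frame(
        exon_id = counts$exon_id[r], gene_id = g,
        base_mean = mean(nrm),
        t(stats::setNames(nrm, paste0("norm_", samples))),
        stats::setNames(list(fit$usage_ref, fit$usage_alt),
                        paste0("usage_", c(ref, alt))),
        log2fc = log2((mu_ref + 0.5) / (mu_alt + 0.5)),
        p_raw = fit$p, dispersion = disp, converged = fit$converged,
        stringsAsFactors = FALSE, check.names = FALSE
      )
    })
    gi <- gi + 1L
    res[[gi]] <- do.call(rbind, exon_res)
  }
  out <- do.call(rbind, res)
  coord_cols <- intersect(c("chrom", "start", "end", "strand"), names(counts))
  if (length(coord_cols)) {
    idx <- match(out$exon_id, counts$exon_id)
    out <- cbind(out[, c("exon_id", "gene_id")], counts[idx, coord_cols],
                 out[, setdiff(names(out), c("exon_id", "gene_id"))])
  }
  out$p_bh <- adjust_bh(out$p_raw)
  rownames(out) <- NULL
  out
}

# Raw method-of-moments NB dispersion on normalized counts (mean of the
# within-condition estimates); may be negative, NA when no condition has a
# positive mean.
.mom_raw <- function(nrm, conditions) {
  ests <- vapply(unique(conditions), function(cc) {
    v <- nrm[conditions == cc]
    mu <- mean(v)
    if (mu <= 0) return(NA_real_)
    (stats::var(v) - mu) / mu^2
  }, numeric(1))
  ests <- ests[!is.na(ests)]
  if (length(ests) == 0L) return(NA_real_)
  mean(ests)
}

# Full-vs-reduced NB GLM likelihood-ratio test with fixed dispersion.
.nb_lrt <- function(x_full, x_red, y, offs, disp, fam_cache) {
  theta <- 1 / disp
  key <- format(theta, digits = 12)
  fam <- fam_cache[[key]]
  if (is.null(fam)) {
    fam <- MASS::negative.binomial(theta = theta)
    fam_cache[[key]] <- fam
  }
  out <- list(p = 1, usage_ref = 0, usage_alt = 0, converged = FALSE)
  if (all(y[seq_len(length(y) / 2)] == y[1]) && stats::var(y) == 0) return(out)
  fit_full <- tryCatch(
    suppressWarnings(stats::glm.fit(x_full, y, family = fam, offset = offs)),
    error = function(e) NULL)
  fit_red <- tryCatch(
    suppressWarnings(stats::glm.fit(x_red, y, family = fam, offset = offs)),
    error = function(e) NULL)
  if (is.null(fit_full) || is.null(fit_red) ||
      !isTRUE(fit_full$converged) || !isTRUE(fit_red$converged)) return(out)
  lr <- max(0, fit_red$deviance - fit_full$deviance)
  cf <- fit_full$coefficients
  usage_ref <- unname(cf["exon_this"])
  usage_alt <- usage_ref + unname(cf["interaction"])
  if (anyNA(c(usage_ref, usage_alt))) return(out)
  list(p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
       usage_ref = usage_ref, usage_alt = usage_alt, converged = TRUE)
}
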