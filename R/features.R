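#' Feature matrix container
#'
#' A numeric observations-by-variables matrix, the substrate of every
#' unsupervised-learning stage, carrying two attributes: whether its columns
#' have been standardized, and an optional qualitative per-observation label
#' (used as the supplementary variable in PCA).
#'
#' @param x Numeric matrix with row and column names; no missing values.
#' @param qualitative Optional character/factor of per-observation categories.
#' @param scaled Whether columns are already standardized.
#' @return An object of class `feature_matrix` (a matrix).
#' @export
feature_matrix <- function(x, qualitative = NULL, scaled = FALSE) {
  x <- as.matrix(x)
  # rebuild to shed any stray attributes carried in from upstream objects
  x <- matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
  if (anyNA(x)) stop_config("feature matrix must not contain missing values")
  if (is.null(rownames(x))) rownames(x) <- paste0("obs", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!is.null(qualitative)) {
    if (length(qualitative) != nrow(x))
      stop_config("'qualitative' must have one label per observation")
    qualitative <- as.character(qualitative)
  }
  structure(x, class = c("feature_matrix", "matrix", "array"),
            qualitative = qualitative, scaled = isTRUE(scaled))
}

#' @rdname feature_matrix
#' @export
is_scaled <- function(x) isTRUE(attr(x, "scaled"))

#' Standardize a feature matrix
#'
#' Z-scores every column (mean 0, unit variance). Constant columns cannot be
#' standardized and are dropped with a warning.
#'
#' @param x A [feature_matrix()].
#' @return The standardized `feature_matrix` (attribute `scaled = TRUE`); the
#'   original column means and standard deviations are kept in attributes
#'   `"center"` and `"scale"` so scaling can be undone.
#' @export
scale_features <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0 | is.na(sds)
  if (all(constant)) stop_config("all columns are constant; nothing to scale")
  if (any(constant)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
    x <- x[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  ctr <- colMeans(x)
  out <- sweep(sweep(unclass(x), 2, ctr), 2, sds, "/")
  fm <- feature_matrix(out, qualitative = attr(x, "qualitative"), scaled = TRUE)
  attr(fm, "center") <- ctr
  attr(fm, "scale") <- sds
  fm
}

#' @rdname scale_features
#' @export
unscale_features <- function(x) {
  stopifnot(inherits(x, "feature_matrix"), is_scaled(x))
  ctr <- attr(x, "center")
  sds <- attr(x, "scale")
  if (is.null(ctr) || is.null(sds))
    stop_config("no stored center/scale; matrix was not scaled by scale_features()")
  out <- sweep(sweep(unclass(x), 2, sds, "*"), 2, ctr, "+")
  feature_matrix(out, qualitative = attr(x, "qualitative"), scaled = FALSE)
}

#' Build a feature matrix from differential-usage results
#'
#' One row per exon; the variables are the per-sample normalized counts and
#' the per-condition exon usage coefficients, optionally extended by the exon
#' and gene log2 fold-change columns (the layout of the miRNA exon table).
#'
#' @param results DEU result data.frame from [test_differential_usage()].
#' @param scale Standardize columns (see [scale_features()]).
#' @param include_log2fc Also include `log2fc` (and `gene_log2fc` if present).
#' @param qualitative Optional per-exon category (e.g. meta-KEGG label).
#' @return A [feature_matrix()] with exon ids as rownames.
#' @export
build_feature_matrix <- function(results, scale = FALSE, include_log2fc = FALSE,
                                 qualitative = NULL) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop_config("'results' must be a non-empty DEU result data.frame")
  norm_cols <- grep("^norm_", names(results), value = TRUE)
  usage_cols <- grep("^usage_", names(results), value = TRUE)
  cols <- c(norm_cols, usage_cols)
  if (include_log2fc)
    cols <- c(cols, intersect(c("log2fc", "gene_log2fc"), names(results)))
  if (length(cols) == 0L)
    stop_config("no feature columns (norm_*/usage_*) found in 'results'")
  x <- as.matrix(results[, cols, drop = FALSE])
  rownames(x) <- results$exon_id
  fm <- feature_matrix(x, qualitative = qualitative)
  if (scale) fm <- scale_features(fm)
  fm
}

#' Assign meta-KEGG group labels to exons
#'
#' An exon inherits the meta-groups of every catalog term containing its gene.
#' Because a multi-exon gene can map to dozens of terms, the union is truncated
#' to at most `max_labels` groups, keeping the most frequent ones (frequency
#' rank, ties broken alphabetically); this averts the hyper-annotation that
#' arises when every exon of a gene receives every pathway of that gene.
#' Exons whose gene matches no term get the single label `"unannotated"`.
#'
#' @param results DEU result data.frame (needs `gene_id`), or a character
#'   vector of gene ids. Composite ids (`"ENSG...+ENSG..."`) are split on `"+"`
#'   and each part is looked up.
#' @param catalog An [annotation_catalog()].
#' @param max_labels Maximum number of labels per exon (1-5).
#' @return A list of character vectors, one per exon, each of length 1 to
#'   `max_labels`.
#' @export
assign_meta_kegg <- function(results, catalog, max_labels = 5L) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  max_labels <- check_count(max_labels, "max_labels")
  if (max_labels > 5L) stop_config("'max_labels' must be at most 5")
  genes <- if (is.data.frame(results)) results$gene_id else as.character(results)
  term_groups <- split(catalog$meta_map$meta_group, catalog$meta_map$term_id)
  lapply(genes, function(g) {
    parts <- strsplit(g, "+", fixed = TRUE)[[1]]
    hit <- names(catalog$term_sets)[vapply(catalog$term_sets,
                                           function(s) any(parts %in% s),
                                           logical(1))]
    if (length(hit) == 0L) return("unannotated")
    groups <- unlist(term_groups[hit], use.names = FALSE)
    freq <- sort(table(groups), decreasing = TRUE)
    ord <- names(freq)[order(-freq, names(freq))]
    utils::head(ord, max_labels)
  })
}

#' Extract FDR-passing miRNA host exons
#'
#' Applies the three locus rules that define a miRNA host exon: the miRNA is
#' (i) contained within a single significant exon, (ii) spans the boundary of
#' two exons (both overlapped exons must be significant; each is reported,
#' which is why one miRNA can contribute several rows), or (iii) lies in an
#' intron whose two flanking exons are both significant. Overlaps are computed
#' on matching chromosome and strand, 1-based inclusive coordinates.
#'
#' @param results DEU result data.frame carrying `chrom`, `start`, `end`,
#'   `strand` columns (as produced when the count table has coordinates).
#' @param mirna_annotation data.frame with columns `mirna_id`, `chrom`,
#'   `start`, `end`, `strand` (and optionally `host_gene`).
#' @param fdr BH threshold defining "significant" (default 0.1).
#' @return A data.frame pairing exon rows with `mirna_id` and
#'   `rule` in `c("single-exon", "spans-two-exons", "intron-flanking")`.
#' @export
extract_mirna_exons <- function(results, mirna_annotation, fdr = 0.1) {
  needed <- c("chrom", "start", "end", "strand", "p_bh", "exon_id", "gene_id")
  if (!all(needed %in% names(results)))
    stop_config("'results' must carry columns: ", paste(needed, collapse = ", "))
  out <- list()
  res <- results[order(results$gene_id, results$start), , drop = FALSE]
  for (i in seq_len(nrow(mirna_annotation))) {
    m <- mirna_annotation[i, ]
    if (is.na(m$start) || is.na(m$end) || m$start > m$end) {
      warning("skipping malformed miRNA interval: ", m$mirna_id, call. = FALSE)
      next
    }
    cand <- res[res$chrom == m$chrom & res$strand == m$strand, , drop = FALSE]
    if (nrow(cand) == 0L) next
    ov <- cand$start <= m$end & cand$end >= m$start
    hit <- cand[ov, , drop = FALSE]
    if (nrow(hit) >= 2L) {
      # miRNA crosses an exon boundary: all overlapped exons must pass the FDR
      if (all(hit$p_bh < fdr))
        out[[length(out) + 1L]] <- cbind(hit, mirna_id = m$mirna_id,
                                         rule = "spans-two-exons")
    } else if (nrow(hit) == 1L) {
      contained <- m$start >= hit$start && m$end <= hit$end
      if (hit$p_bh < fdr)
        out[[length(out) + 1L]] <- cbind(hit, mirna_id = m$mirna_id,
                                         rule = if (contained) "single-exon"
                                                else "spans-two-exons")
    } else {
      # intronic: find the flanking exon pair within one gene
      for (g in unique(cand$gene_id)) {
        ex <- cand[cand$gene_id == g, , drop = FALSE]
        left <- ex[ex$end < m$start, , drop = FALSE]
        right <- ex[ex$start > m$end, , drop = FALSE]
        if (nrow(left) == 0L || nrow(right) == 0L) next
        fl <- left[which.max(left$end), , drop = FALSE]
        fr <- right[which.min(right$start), , drop = FALSE]
        if (fl$p_bh < fdr && fr$p_bh < fdr) {
          out[[length(out) + 1L]] <- cbind(rbind(fl, fr), mirna_id = m$mirna_id,
                                           rule = "intron-flanking")
        }
      }
    }
  }
  if (length(out) == 0L) {
    empty <- res[0, , drop = FALSE]
    empty$mirna_id <- character(0)
    empty$rule <- character(0)
    return(empty)
  }
  out <- do.call(rbind, out)
  out <- out[!duplicated(out[, c("exon_id", "mirna_id")]), , drop = FALSE]
  out <- out[order(out$mirna_id, out$exon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
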