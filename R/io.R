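#' Read an exon count table
#'
#' Reads a featureCounts-style tab-separated exon count table. The first six
#' columns are `gene_id`, `exon_id`, `chrom`, `start`, `end`, `strand`
#' (coordinates 1-based inclusive); every remaining column is a sample's raw
#' counts.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with the six annotation columns followed by one integer
#'   column per sample.
#' @export
read_exon_counts <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("gene_id", "exon_id", "chrom", "start", "end", "strand")
  if (!all(required %in% names(x)[seq_along(required)]))
    stop_config("exon count table must start with columns: ",
                paste(required, collapse = ", "))
  x
}

#' Write an exon count table
#'
#' @param counts A data.frame as returned by [generate_exon_counts()] or
#'   [read_exon_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_exon_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample names of an exon count table
#' @param counts An exon count table.
#' @return Character vector of sample column names.
#' @export
count_samples <- function(counts) {
  setdiff(names(counts), c("gene_id", "exon_id", "chrom", "start", "end", "strand"))
}

count_matrix <- function(counts) {
  m <- as.matrix(counts[, count_samples(counts), drop = FALSE])
  rownames(m) <- counts$exon_id
  storage.mode(m) <- "double"
  m
}

#' Read a GMT gene-set file
#'
#' Standard GMT layout: one term per line, tab-separated
#' `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character gene vectors; descriptions are kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character gene vectors.
#' @param path Output path.
#' @param descriptions Optional per-term description; defaults to the term id.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a term-to-meta-group mapping
#'
#' Two-column TSV (`term_id`, `meta_group`); a term may appear on several
#' lines, one per meta-group it belongs to.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `term_id` and `meta_group`.
#' @export
read_meta_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "meta_group") %in% names(x)))
    stop_config("meta-group map needs columns 'term_id' and 'meta_group'")
  x
}

#' @rdname read_meta_map
#' @param meta_map A data.frame with columns `term_id` and `meta_group`.
#' @export
write_meta_map <- function(meta_map, path) {
  utils::write.table(meta_map[, c("term_id", "meta_group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a differential exon usage result table
#'
#' @param results DEU result data.frame from [test_differential_usage()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_deu_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deu_results
#' @export
read_deu_results <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
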