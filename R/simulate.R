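#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic exon-count generator.
#' The defaults emulate the study design the package targets: two conditions
#' (alcohol-exposed vs saline control) with two pooled replicates each,
#' negative-binomial exon counts over multi-exon genes, a planted fraction of
#' differentially used exons, and a sprinkling of miRNA-hosting exons.
#'
#' @param n_genes Number of simulated genes.
#' @param exons_per_gene Integer range `c(low, high)` of exons per gene.
#' @param n_replicates Replicates per condition (pooled samples); must be >= 2.
#' @param nb_mean_range Range `c(low, high)` of per-exon baseline means.
#' @param nb_dispersion Negative-binomial dispersion alpha in
#'   `Var = mu + alpha * mu^2`.
#' @param frac_deu_exons Fraction of exons with planted differential usage.
#' @param deu_log2_effect Absolute log2 usage shift of planted exons; signs
#'   alternate within a gene so gene totals stay roughly balanced, emulating
#'   genes whose up- and down-regulated exons cancel at gene level.
#' @param frac_mirna_host Fraction of exons that host a simulated miRNA locus.
#' @param size_factor_range Range of per-sample library size factors.
#' @param seed Integer seed; the same config always regenerates identical data.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200,
                              exons_per_gene = c(2L, 8L),
                              n_replicates = 2L,
                              nb_mean_range = c(20, 2000),
                              nb_dispersion = 0.05,
                              frac_deu_exons = 0.1,
                              deu_log2_effect = 1,
                              frac_mirna_host = 0.05,
                              size_factor_range = c(0.7, 1.4),
                              seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    exons_per_gene = check_range(exons_per_gene, "exons_per_gene", positive = TRUE),
    n_replicates = check_count(n_replicates, "n_replicates", min = 2L),
    nb_mean_range = check_range(nb_mean_range, "nb_mean_range", positive = TRUE),
    nb_dispersion = nb_dispersion,
    frac_deu_exons = check_fraction(frac_deu_exons, "frac_deu_exons"),
    deu_log2_effect = deu_log2_effect,
    frac_mirna_host = check_fraction(frac_mirna_host, "frac_mirna_host"),
    size_factor_range = check_range(size_factor_range, "size_factor_range",
                                    positive = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop_config("'nb_dispersion' must be a positive real")
  if (cfg$frac_deu_exons > 0 && cfg$deu_log2_effect == 0)
    stop_config("'deu_log2_effect' must be nonzero when 'frac_deu_exons' > 0")
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic exon count table with planted truth
#'
#' Draws negative-binomial exon counts for a two-condition design with
#' per-sample size factors. A configured fraction of exons receives a planted
#' usage shift of `deu_log2_effect` applied to the alcohol condition; the
#' planted sign alternates within each affected gene, so a gene can carry both
#' up- and down-regulated exons whose gene-level fold change cancels. The truth
#' table records, for every exon, whether it was planted, the true effect on
#' the control-over-alcohol log2 scale, and any hosted miRNA.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#'   * `counts` — exon count table (see [read_exon_counts()] for the layout),
#'   * `truth` — data.frame `exon_id`, `gene_id`, `is_deu`, `true_log2_effect`,
#'     `is_mirna_host`, `mirna_id`,
#'   * `conditions` — named character vector sample -> `"control"`/`"alcohol"`,
#'   * `size_factors` — the true simulated per-sample factors,
#'   * `mirna_loci` — locus annotation for the hosted miRNAs (usable with
#'     [extract_mirna_exons()]).
#' @export
generate_exon_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nrep <- config$n_replicates
  samples <- c(paste0("ALC", seq_len(nrep)), paste0("CONT", seq_len(nrep)))
  conditions <- stats::setNames(rep(c("alcohol", "control"), each = nrep), samples)

  n_exons_per_gene <- sample_range(config$exons_per_gene, config$n_genes)
  gene_id <- rep(sprintf("SIMG%05d", seq_len(config$n_genes)), n_exons_per_gene)
  exon_rank <- unlist(lapply(n_exons_per_gene, seq_len), use.names = FALSE)
  exon_id <- sprintf("%s:E%03d", gene_id, exon_rank)
  n_exons <- length(exon_id)

  # genomic layout: one chromosome block per gene, 200 bp exons, 500 bp introns
  widths <- sample(80:400, n_exons, replace = TRUE)
  start <- integer(n_exons)
  offset <- 1L
  for (i in seq_len(n_exons)) {
    if (exon_rank[i] == 1L) offset <- offset + 10000L
    start[i] <- offset
    offset <- offset + widths[i] + 500L
  }
  chrom <- rep(sample(paste0("chr", 1:28), config$n_genes, replace = TRUE),
               n_exons_per_gene)
  strand <- rep(sample(c("+", "-"), config$n_genes, replace = TRUE),
                n_exons_per_gene)

  mu <- exp(stats::runif(n_exons, log(config$nb_mean_range[1]),
                         log(config$nb_mean_range[2])))
  size_factors <- stats::runif(length(samples), config$size_factor_range[1],
                               config$size_factor_range[2])
  names(size_factors) <- samples

  # plant DEU exons; alternate signs within a gene so gene totals can balance
  is_deu <- stats::runif(n_exons) < config$frac_deu_exons
  true_effect <- numeric(n_exons)
  for (g in unique(gene_id[is_deu])) {
    idx <- which(gene_id == g & is_deu)
    signs <- rep(c(1, -1), length.out = length(idx))
    true_effect[idx] <- signs * abs(config$deu_log2_effect)
  }

  is_host <- stats::runif(n_exons) < config$frac_mirna_host
  mirna_id <- rep(NA_character_, n_exons)
  mirna_id[is_host] <- sprintf("sim-mir-%04d", seq_len(sum(is_host)))

  counts <- matrix(0, n_exons, length(samples),
                   dimnames = list(exon_id, samples))
  for (s in samples) {
    # convention: true_log2_effect is control-over-alcohol, so the alcohol
    # condition mean is shifted by 2^(-effect)
    shift <- if (conditions[[s]] == "alcohol") 2^(-true_effect) else 1
    counts[, s] <- stats::rnbinom(n_exons, mu = mu * shift * size_factors[[s]],
                                  size = 1 / config$nb_dispersion)
  }

  counts_df <- data.frame(gene_id = gene_id, exon_id = exon_id, chrom = chrom,
                          start = start, end = start + widths - 1L,
                          strand = strand, stringsAsFactors = FALSE)
  counts_df <- cbind(counts_df, as.data.frame(counts))
  rownames(counts_df) <- NULL

  truth <- data.frame(exon_id = exon_id, gene_id = gene_id, is_deu = is_deu,
                      true_log2_effect = true_effect, is_mirna_host = is_host,
                      mirna_id = mirna_id, stringsAsFactors = FALSE)

  host <- counts_df[is_host, , drop = FALSE]
  mirna_loci <- data.frame(
    mirna_id = mirna_id[is_host],
    chrom = host$chrom,
    start = host$start + pmin(10L, host$end - host$start),
    end = pmin(host$end, host$start + 80L),
    strand = host$strand,
    host_gene = host$gene_id,
    stringsAsFactors = FALSE
  )

  list(counts = counts_df, truth = truth, conditions = conditions,
       size_factors = size_factors, mirna_loci = mirna_loci)
}

#' Generate a uniformly random feature matrix
#'
#' Draws an observations-by-variables matrix with i.i.d. uniform entries inside
#' per-variable ranges. This is the spatial-randomness reference used by the
#' Hopkins statistic and VAT: it has the same dimensions and the same numeric
#' ranges as a real feature matrix but no cluster structure.
#'
#' @param n_obs Number of observations (rows); >= 2.
#' @param column_ranges A 2-row matrix, a data.frame, or a list of `c(low, high)`
#'   pairs, one per variable. Column names are reused for the output. Passing a
#'   [feature_matrix()] (or any numeric matrix) uses its per-column ranges.
#' @param seed Integer seed.
#' @return A [feature_matrix()] (unscaled).
#' @export
generate_random_matrix <- function(n_obs, column_ranges, seed = 1L) {
  n_obs <- check_count(n_obs, "n_obs", min = 2L)
  if (is.matrix(column_ranges) && nrow(column_ranges) > 2L)
    column_ranges <- apply(column_ranges, 2, range)
  if (is.data.frame(column_ranges)) column_ranges <- as.matrix(column_ranges)
  if (is.list(column_ranges))
    column_ranges <- vapply(column_ranges, function(r) r, numeric(2))
  if (!is.matrix(column_ranges) || nrow(column_ranges) != 2L)
    stop_config("'column_ranges' must give a c(low, high) pair per variable")
  lo <- column_ranges[1, ]
  hi <- column_ranges[2, ]
  if (any(hi <= lo))
    stop_config("degenerate column range: every range needs low < high")
  set.seed(check_count(seed, "seed", min = 0L))
  x <- vapply(seq_along(lo), function(j) stats::runif(n_obs, lo[j], hi[j]),
              numeric(n_obs))
  colnames(x) <- colnames(column_ranges) %||% paste0("V", seq_along(lo))
  rownames(x) <- paste0("obs", seq_len(n_obs))
  feature_matrix(x)
}

#' Generate a synthetic gene-set annotation catalog
#'
#' Builds a KEGG-like catalog: terms are gene sets sampled from a gene
#' universe, and each term is assigned between one and five meta-groups
#' (functional super-clusters); a term may belong to several meta-groups.
#'
#' @param universe Character vector of gene ids, or a single count to generate
#'   `SIMG`-style ids.
#' @param n_terms Number of terms.
#' @param genes_per_term Range `c(low, high)` of genes per term.
#' @param n_meta_groups Number of meta-group labels; must be <= `n_terms`.
#' @param seed Integer seed.
#' @return An object of class `annotation_catalog`: list with `term_sets`
#'   (named list of gene vectors), `universe`, and `meta_map` (data.frame
#'   `term_id`, `meta_group`).
#' @export
generate_annotation_catalog <- function(universe, n_terms = 20L,
                                        genes_per_term = c(5L, 40L),
                                        n_meta_groups = 5L, seed = 1L) {
  if (is.numeric(universe) && length(universe) == 1L)
    universe <- sprintf("SIMG%05d", seq_len(check_count(universe, "universe")))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_config("empty gene universe")
  n_terms <- check_count(n_terms, "n_terms")
  n_meta_groups <- check_count(n_meta_groups, "n_meta_groups")
  if (n_meta_groups > n_terms)
    stop_config("'n_meta_groups' must not exceed 'n_terms'")
  genes_per_term <- check_range(genes_per_term, "genes_per_term", positive = TRUE)

  set.seed(check_count(seed, "seed", min = 0L))
  term_ids <- sprintf("TERM%03d", seq_len(n_terms))
  sizes <- pmin(length(universe), sample_range(genes_per_term, n_terms))
  term_sets <- lapply(sizes, function(k) sort(sample(universe, k)))
  names(term_sets) <- term_ids

  groups <- paste0("meta_", seq_len(n_meta_groups))
  # every group gets at least one term, then each term draws 1-5 groups
  first <- sample(term_ids, n_meta_groups)
  meta <- data.frame(term_id = first, meta_group = groups,
                     stringsAsFactors = FALSE)
  for (t in term_ids) {
    extra <- sample(groups, sample.int(min(5L, n_meta_groups), 1L))
    extra <- setdiff(extra, meta$meta_group[meta$term_id == t])
    if (length(extra))
      meta <- rbind(meta, data.frame(term_id = t, meta_group = extra,
                                     stringsAsFactors = FALSE))
  }
  meta <- meta[order(meta$term_id, meta$meta_group), ]
  rownames(meta) <- NULL
  annotation_catalog(term_sets, universe, meta)
}

#' Construct an annotation catalog
#'
#' @param term_sets Named list of character gene vectors.
#' @param universe Character gene universe; every term set must be a subset.
#' @param meta_map data.frame `term_id`, `meta_group`; every term must appear.
#' @return An `annotation_catalog` object.
#' @export
annotation_catalog <- function(term_sets, universe, meta_map) {
  stopifnot(is.list(term_sets), !is.null(names(term_sets)))
  universe <- unique(as.character(universe))
  bad <- vapply(term_sets, function(s) !all(s %in% universe), logical(1))
  if (any(bad))
    stop_config("term sets outside the universe: ",
                paste(names(term_sets)[bad], collapse = ", "))
  missing <- setdiff(names(term_sets), meta_map$term_id)
  if (length(missing))
    stop_config("terms without a meta-group: ", paste(missing, collapse = ", "))
  per_term <- table(meta_map$term_id)
  if (any(per_term > 5L))
    stop_config("a term may carry at most 5 meta-groups")
  structure(list(term_sets = term_sets, universe = universe,
                 meta_map = meta_map),
            class = "annotation_catalog")
}
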