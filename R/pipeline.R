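#' Pipeline configuration
#'
#' Collects paths, thresholds and per-stage seeds for the end-to-end workflow
#' (simulate -> differential usage -> unsupervised ML -> enrichment). Defaults
#' mirror the analysis this package reproduces: FDR 0.1, top 50 contributors,
#' k examined over 1..10, 50 k-means restarts, 1000 random null lists.
#'
#' @param out_dir Output directory; created if absent.
#' @param fdr BH threshold for significance (default 0.1).
#' @param top_n Number of top PCA contributors to report (default 50).
#' @param kmax Largest k for cluster-number selection (default 10).
#' @param kmeans_starts k-means restarts (default 50).
#' @param null_reps Random gene lists for the enrichment null (default 1000).
#' @param seeds Named list of per-stage seeds (`simulate`, `ml`, `enrichment`).
#' @param sim Optional [simulation_config()] for [run_simulate()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, fdr = 0.1, top_n = 50L, kmax = 10L,
                            kmeans_starts = 50L, null_reps = 1000L,
                            seeds = list(simulate = 1L, ml = 2L,
                                         enrichment = 3L),
                            sim = simulation_config()) {
  check_fraction(fdr, "fdr")
  if (fdr <= 0 || fdr >= 1) stop_config("'fdr' must lie strictly in (0, 1)")
  cfg <- list(out_dir = out_dir, fdr = fdr,
              top_n = check_count(top_n, "top_n"),
              kmax = check_count(kmax, "kmax", min = 2L),
              kmeans_starts = check_count(kmeans_starts, "kmeans_starts"),
              null_reps = check_count(null_reps, "null_reps"),
              seeds = seeds, sim = sim)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(config, stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

write_stage_meta <- function(config, stage, extra = list()) {
  meta <- c(list(stage = stage, config_hash = config_hash(config),
                 seeds = config$seeds), extra)
  jsonlite::write_json(meta, file.path(config$out_dir,
                                       paste0(stage, "_meta.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the simulation stage
#'
#' Generates the synthetic dataset of the configured design and writes the
#' count table, truth table, miRNA locus annotation, a KEGG-like GMT catalog
#' and its meta-group map into the output directory.
#'
#' @param config A [pipeline_config()].
#' @return The dataset list from [generate_exon_counts()] (invisibly), with
#'   `catalog` attached.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_cfg <- config$sim
  sim_cfg$seed <- config$seeds$simulate %||% sim_cfg$seed
  ds <- generate_exon_counts(sim_cfg)
  write_exon_counts(ds$counts, file.path(config$out_dir, "counts.tsv"))
  utils::write.table(ds$truth, file.path(config$out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$mirna_loci, file.path(config$out_dir, "mirna_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(ds$conditions), condition = ds$conditions),
    file.path(config$out_dir, "conditions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  catalog <- generate_annotation_catalog(unique(ds$counts$gene_id),
                                         seed = sim_cfg$seed)
  write_gmt(catalog$term_sets, file.path(config$out_dir, "catalog.gmt"))
  write_meta_map(catalog$meta_map, file.path(config$out_dir, "meta_map.tsv"))
  ds$catalog <- catalog
  write_stage_meta(config, "simulate",
                   list(n_exons = nrow(ds$counts),
                        n_deu = sum(ds$truth$is_deu)))
  stage_log(config, "simulate", nrow(ds$counts), " exons, ",
            sum(ds$truth$is_deu), " planted DEU")
  invisible(ds)
}

#' Run the differential exon usage stage
#'
#' @param config A [pipeline_config()].
#' @param dataset Dataset list from [run_simulate()]; read back from
#'   `out_dir` when omitted.
#' @return The full DEU result data.frame (invisibly); the full and
#'   FDR-filtered tables are written as TSV.
#' @export
run_deu <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) {
    counts <- read_exon_counts(file.path(config$out_dir, "counts.tsv"))
    cond <- utils::read.delim(file.path(config$out_dir, "conditions.tsv"),
                              stringsAsFactors = FALSE)
    conditions <- stats::setNames(cond$condition, cond$sample)
  } else {
    counts <- dataset$counts
    conditions <- dataset$conditions
  }
  res <- withCallingHandlers(
    test_differential_usage(counts, conditions),
    warning = function(w) {
      stage_log(config, "deu", "warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sig <- filter_significant(res, config$fdr)
  write_deu_results(res, file.path(config$out_dir, "deu_full.tsv"))
  write_deu_results(sig, file.path(config$out_dir, "deu_significant.tsv"))
  up_alc <- sum(sig$log2fc < 0)
  stage_log(config, "deu", nrow(sig), " significant exons (",
            up_alc, " up in alcohol, ", nrow(sig) - up_alc, " down) across ",
            length(unique(sig$gene_id)), " genes")
  write_stage_meta(config, "deu",
                   list(n_significant = nrow(sig), n_up_alcohol = up_alc,
                        n_genes = length(unique(sig$gene_id))))
  invisible(res)
}

#' Run the unsupervised-learning stage
#'
#' PCA with top contributors, HCPC, cluster-number selection, k-means and
#' fuzzy c-means at the consensus k, Hopkins statistic and VAT ordering, on
#' the FDR-filtered exon feature matrix.
#'
#' @param config A [pipeline_config()].
#' @param results DEU results; read back from `out_dir` when omitted.
#' @return List of stage outputs (invisibly); reports are written as TSV.
#' @export
run_ml <- function(config, results = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(results))
    results <- read_deu_results(file.path(config$out_dir, "deu_full.tsv"))
  sig <- filter_significant(results, config$fdr)
  seed <- config$seeds$ml %||% 1L
  if (nrow(sig) < 3L) {
    stage_log(config, "ml", "skipped: fewer than 3 significant exons")
    return(invisible(NULL))
  }
  fm <- build_feature_matrix(sig, scale = TRUE)
  pca <- run_pca(fm)
  top <- top_contributors(pca, dims = 1:2,
                          n = min(config$top_n, nrow(fm)))
  utils::write.table(top, file.path(config$out_dir, "top_contributors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hc <- hcpc(pca)
  ks <- select_k(fm, kmax = min(config$kmax, nrow(fm) - 1L),
                 n_starts = config$kmeans_starts, seed = seed)
  km <- kmeans_multi(fm, k = max(2L, ks$consensus_k),
                     n_starts = config$kmeans_starts, seed = seed)
  fc <- fuzzy_cmeans(fm, k = max(2L, ks$consensus_k), seed = seed)
  hop <- hopkins(fm, seed = seed)
  vt <- vat(fm)
  utils::write.table(ks$table, file.path(config$out_dir, "k_selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  labels <- data.frame(exon_id = rownames(fm), hcpc = hc$labels,
                       kmeans = km$labels, fcm = fc$labels)
  utils::write.table(labels, file.path(config$out_dir, "cluster_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(vt$ordered_dissimilarity,
                     file.path(config$out_dir, "vat_ordered.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)
  write_stage_meta(config, "ml",
                   list(hopkins = hop$H, elbow_k = ks$elbow_k,
                        silhouette_k = ks$silhouette_k, gap_k = ks$gap_k,
                        consensus_k = ks$consensus_k, seed = seed))
  stage_log(config, "ml", "H = ", round(hop$H, 3), "; consensus k = ",
            ks$consensus_k)
  invisible(list(pca = pca, top = top, hcpc = hc, k_selection = ks,
                 kmeans = km, fcm = fc, hopkins = hop, vat = vt))
}

#' Run the enrichment stage
#'
#' Fisher enrichment of a gene list with a size-matched random-list null and
#' term verdicts.
#'
#' @param config A [pipeline_config()].
#' @param gene_list Character vector of genes (e.g. significant DEU genes).
#' @param catalog An [annotation_catalog()]; read back from `out_dir` when
#'   omitted.
#' @return List with `enrichment`, `null`, `verdicts` (invisibly); per-term
#'   TSV and a JSON verdict summary are written.
#' @export
run_enrichment <- function(config, gene_list, catalog = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(catalog)) {
    sets <- read_gmt(file.path(config$out_dir, "catalog.gmt"))
    meta <- read_meta_map(file.path(config$out_dir, "meta_map.tsv"))
    catalog <- annotation_catalog(sets, unique(unlist(sets)), meta)
  }
  gene_list <- intersect(unique(gene_list), catalog$universe)
  if (length(gene_list) == 0L)
    stop_config("gene list and catalog universe are disjoint")
  seed <- config$seeds$enrichment %||% 1L
  obs <- fisher_enrichment(gene_list, catalog)
  null <- random_null(catalog, list_size = length(gene_list),
                      reps = config$null_reps, seed = seed)
  verdicts <- flag_terms(obs, null)
  utils::write.table(merge(obs, verdicts[, c("term_id", "verdict")],
                           by = "term_id"),
                     file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = seed,
         n_lists = null$n_lists, list_size = null$list_size,
         verdicts = verdicts),
    file.path(config$out_dir, "enrichment_verdicts.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log(config, "enrichment",
            sum(verdicts$verdict == "validated-enriched"),
            " validated-enriched term(s) of ", nrow(obs))
  invisible(list(enrichment = obs, null = null, verdicts = verdicts))
}
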