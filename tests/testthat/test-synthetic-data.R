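test_that("simulation config validates its parameters", {
  expect_error(simulation_config(nb_dispersion = 0), "dispersion")
  expect_error(simulation_config(nb_mean_range = c(100, 10)), "ordered pair")
  expect_error(simulation_config(nb_mean_range = c(-5, 10)), "positive")
  expect_error(simulation_config(frac_deu_exons = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(n_replicates = 1), ">= 2")
  expect_error(simulation_config(frac_deu_exons = 0.2, deu_log2_effect = 0),
               "nonzero")
  expect_s3_class(simulation_config(), "simulation_config")
})

test_that("count generation is deterministic and honors the truth contract", {
  cfg <- simulation_config(n_genes = 50, seed = 7)
  a <- generate_exon_counts(cfg)
  b <- generate_exon_counts(cfg)
  expect_identical(a, b)

  expect_equal(nrow(a$counts), nrow(a$truth))
  expect_identical(a$counts$exon_id, a$truth$exon_id)
  expect_true(all((abs(a$truth$true_log2_effect) > 0) == a$truth$is_deu))
  expect_true(all(a$truth$true_log2_effect[!a$truth$is_deu] == 0))
  expect_true(all(!is.na(a$truth$mirna_id[a$truth$is_mirna_host])))

  null_ds <- generate_exon_counts(simulation_config(n_genes = 30,
                                                    frac_deu_exons = 0,
                                                    seed = 3))
  expect_equal(sum(null_ds$truth$is_deu), 0L)
})

test_that("planted signs alternate within a gene so totals can balance", {
  cfg <- simulation_config(n_genes = 100, frac_deu_exons = 0.5,
                           deu_log2_effect = 2, seed = 11)
  ds <- generate_exon_counts(cfg)
  per_gene <- split(ds$truth$true_log2_effect[ds$truth$is_deu],
                    ds$truth$gene_id[ds$truth$is_deu])
  multi <- per_gene[lengths(per_gene) >= 2]
  expect_true(length(multi) > 0)
  # alternating +/- means any even-count gene sums exactly to zero
  even <- multi[lengths(multi) %% 2 == 0]
  expect_true(all(vapply(even, sum, numeric(1)) == 0))
})

test_that("NB counts match the mean/dispersion parameterization", {
  mu <- 300
  alpha <- 0.08
  cfg <- simulation_config(n_genes = 1200, exons_per_gene = c(3, 3),
                           frac_deu_exons = 0, nb_mean_range = c(mu, mu),
                           nb_dispersion = alpha,
                           size_factor_range = c(1, 1) + c(-1e-9, 1e-9),
                           seed = 5)
  ds <- generate_exon_counts(cfg)
  draws <- as.numeric(as.matrix(ds$counts[, names(ds$conditions)]))
  expect_gt(length(draws), 1e4)
  expect_equal(mean(draws), mu, tolerance = 0.02)
  expect_equal(var(draws), mu + alpha * mu^2, tolerance = 0.05)
})

test_that("random matrices are uniform within the requested ranges", {
  ranges <- cbind(a = c(0, 10), b = c(-5, 5), c = c(100, 200))
  x <- generate_random_matrix(22, ranges, seed = 4)
  expect_s3_class(x, "feature_matrix")
  expect_equal(dim(unclass(x)), c(22L, 3L))
  expect_identical(x, generate_random_matrix(22, ranges, seed = 4))
  expect_false(identical(x, generate_random_matrix(22, ranges, seed = 5)))

  expect_error(generate_random_matrix(10, cbind(c(0, 0))), "degenerate")
  expect_error(generate_random_matrix(1, ranges), ">= 2")

  big <- generate_random_matrix(1e4, ranges, seed = 9)
  mid <- (ranges[1, ] + ranges[2, ]) / 2
  expect_equal(unname(colMeans(big)), unname(mid), tolerance = 0.02)
  expect_true(all(sweep(big, 2, ranges[1, ], ">=")) &&
                all(sweep(big, 2, ranges[2, ], "<=")))
})

test_that("a feature matrix can seed the ranges of its own uniform reference", {
  fm <- mirna_feature_matrix()
  u <- generate_random_matrix(nrow(fm), unclass(fm), seed = 1)
  expect_equal(dim(unclass(u)), dim(unclass(fm)))
  expect_true(all(apply(u, 2, min) >= apply(fm, 2, min)))
  expect_true(all(apply(u, 2, max) <= apply(fm, 2, max)))
})

test_that("annotation catalogs respect universe, meta coverage and determinism", {
  cat1 <- generate_annotation_catalog(100, n_terms = 20, n_meta_groups = 5,
                                      seed = 2)
  expect_identical(cat1, generate_annotation_catalog(100, n_terms = 20,
                                                     n_meta_groups = 5,
                                                     seed = 2))
  expect_true(all(unlist(cat1$term_sets) %in% cat1$universe))
  expect_setequal(unique(cat1$meta_map$term_id), names(cat1$term_sets))
  expect_true(all(table(cat1$meta_map$term_id) <= 5))
  expect_setequal(unique(cat1$meta_map$meta_group), paste0("meta_", 1:5))

  bij <- generate_annotation_catalog(50, n_terms = 20, n_meta_groups = 20,
                                     seed = 3)
  expect_equal(length(unique(bij$meta_map$meta_group)), 20L)
  expect_error(generate_annotation_catalog(character(0), 5, n_meta_groups = 2),
               "empty")
  expect_error(generate_annotation_catalog(50, n_terms = 3, n_meta_groups = 4),
               "exceed")
})

test_that("the miRNA fixture matches its printed source", {
  fx <- load_mirna_fixture()
  expect_equal(nrow(fx), 23L)
  expect_false(anyDuplicated(fx$ensembl_exon_id) > 0)
  expect_true(all(fx$bh_p < 0.1))
  # the printed table carries 17 distinct mirbase ids (several miRNAs span
  # more than one exon)
  expect_equal(length(unique(fx$mirbase_id)), 17L)
  row <- fx[fx$ensembl_exon_id == "ENSGALG00000009621+ENSGALG00000027736:E005", ]
  expect_equal(unlist(row[, c("alc1", "alc2", "cont1", "cont2")],
                      use.names = FALSE), c(1446, 1349, 2016, 1972))
  expect_identical(row$mirbase_id, "gga-mir-3533")
})

test_that("fixture round-trips losslessly through TSV", {
  fx <- load_mirna_fixture()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(fx, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(tmp, stringsAsFactors = FALSE)
  expect_equal(back, fx)
})

test_that("exon count tables round-trip through TSV", {
  ds <- generate_exon_counts(simulation_config(n_genes = 10, seed = 1))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_exon_counts(ds$counts, tmp)
  back <- read_exon_counts(tmp)
  expect_equal(back, ds$counts)
  expect_identical(count_samples(back), names(ds$conditions))
})

test_that("GMT and meta-map files round-trip", {
  cat1 <- generate_annotation_catalog(40, n_terms = 8, n_meta_groups = 3,
                                      seed = 6)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(cat1$term_sets, gmt)
  back <- read_gmt(gmt)
  expect_equal(back[names(cat1$term_sets)], cat1$term_sets,
               ignore_attr = TRUE)
  mm <- withr::local_tempfile(fileext = ".tsv")
  write_meta_map(cat1$meta_map, mm)
  expect_equal(read_meta_map(mm), cat1$meta_map)
})
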