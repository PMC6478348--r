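test_that("scaling standardizes columns and is invertible", {
  set.seed(1)
  fm <- feature_matrix(matrix(rnorm(60, 5, 3), 12, 5))
  sc <- scale_features(fm)
  expect_true(is_scaled(sc))
  expect_true(all(abs(colMeans(sc)) < 1e-8))
  expect_true(all(abs(apply(sc, 2, sd) - 1) < 1e-8))
  back <- unscale_features(sc)
  expect_equal(unclass(back), unclass(fm), tolerance = 1e-8)
})

test_that("constant columns are dropped with a warning under scaling", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(sc <- scale_features(feature_matrix(x)), "constant")
  expect_identical(colnames(sc), "a")
  expect_error(scale_features(feature_matrix(cbind(b = c(2, 2, 2)))),
               "constant")
  expect_error(feature_matrix(cbind(a = c(1, NA))), "missing")
})

test_that("feature matrices assemble normalized counts and usage columns", {
  ds <- generate_exon_counts(simulation_config(n_genes = 30, seed = 2))
  res <- suppressWarnings(test_differential_usage(ds$counts, ds$conditions))
  fm <- build_feature_matrix(res)
  expect_equal(ncol(fm), length(ds$conditions) + 2L)
  expect_identical(rownames(fm), res$exon_id)
  fm_fc <- build_feature_matrix(res, include_log2fc = TRUE)
  expect_true("log2fc" %in% colnames(fm_fc))
  expect_error(build_feature_matrix(res[0, ]), "non-empty")
  expect_error(build_feature_matrix(data.frame(x = 1)), "feature columns")
})

test_that("the printed miRNA table yields the 22 x 6 clustering matrix", {
  fm <- mirna_feature_matrix()
  expect_equal(dim(unclass(fm)), c(22L, 6L))
  expect_false(any(grepl("3064 E001", rownames(fm))))
  full <- mirna_feature_matrix(drop_outlier = FALSE)
  expect_equal(nrow(full), 23L)
  sc <- mirna_feature_matrix(scale = TRUE)
  expect_true(all(abs(colMeans(sc)) < 1e-8))
})

test_that("meta-group labels cover, collapse and cap at five", {
  universe <- paste0("g", 1:60)
  # gene g1 sits in 45 terms that collapse to 3 meta-groups
  sets <- c(lapply(1:45, function(i) c("g1", paste0("g", 1 + i))),
            list(c("g50", "g51")))
  names(sets) <- c(paste0("T", 1:45), "Tsolo")
  meta <- data.frame(
    term_id = c(paste0("T", 1:45), "Tsolo"),
    meta_group = c(rep(c("grpA", "grpB", "grpC"), 15), "grpSolo"))
  catalog <- annotation_catalog(sets, universe, meta)

  labels <- assign_meta_kegg(c("g1", "g50", "g59"), catalog)
  expect_setequal(labels[[1]], c("grpA", "grpB", "grpC"))
  expect_length(labels[[1]], 3)
  expect_identical(labels[[2]], "grpSolo")
  expect_identical(labels[[3]], "unannotated")
  expect_true(all(lengths(labels) >= 1 & lengths(labels) <= 5))
})

test_that("composite gene ids are split before annotation lookup", {
  catalog <- make_catalog(20, sizes = c(4, 10))
  labels <- assign_meta_kegg("gX+g2", catalog)
  expect_false(identical(labels[[1]], "unannotated"))
})

test_that("miRNA host exons follow the three locus rules", {
  res <- data.frame(
    exon_id = paste0("G1:E", 1:4),
    gene_id = "G1", chrom = "chr1",
    start = c(1000, 2000, 3000, 4000), end = c(1199, 2199, 3199, 4199),
    strand = "+",
    p_bh = c(0.01, 0.02, 0.5, 0.03), stringsAsFactors = FALSE)
  ann <- data.frame(
    mirna_id = c("mir-single", "mir-span", "mir-intron-good",
                 "mir-intron-bad", "mir-wrong-strand"),
    chrom = "chr1",
    start = c(1050, 2150, 1300, 2300, 1050),
    end = c(1100, 3050, 1400, 2400, 1100),
    strand = c("+", "+", "+", "+", "-"), stringsAsFactors = FALSE)

  out <- extract_mirna_exons(res, ann, fdr = 0.1)
  expect_identical(out$rule[out$mirna_id == "mir-single"], "single-exon")
  # mir-span overlaps E2 (significant) and E3 (not): excluded
  expect_false("mir-span" %in% out$mirna_id)
  # intron between E1/E2 with both flanks significant: both rows emitted
  ig <- out[out$mirna_id == "mir-intron-good", ]
  expect_equal(nrow(ig), 2L)
  expect_setequal(ig$exon_id, c("G1:E1", "G1:E2"))
  expect_true(all(ig$rule == "intron-flanking"))
  # intron between E2/E3: E3 fails the FDR filter
  expect_false("mir-intron-bad" %in% out$mirna_id)
  expect_false("mir-wrong-strand" %in% out$mirna_id)
  expect_true(all(out$p_bh < 0.1))
})

test_that("a boundary-spanning miRNA emits every overlapped significant exon", {
  res <- data.frame(
    exon_id = c("G1:E1", "G1:E2"), gene_id = "G1", chrom = "chr2",
    start = c(100, 300), end = c(250, 450), strand = "-",
    p_bh = c(0.01, 0.05), stringsAsFactors = FALSE)
  ann <- data.frame(mirna_id = "mir-x", chrom = "chr2", start = 200, end = 350,
                    strand = "-", stringsAsFactors = FALSE)
  out <- extract_mirna_exons(res, ann)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$rule == "spans-two-exons"))
})

test_that("miRNA extraction is idempotent and order-independent", {
  ds <- generate_exon_counts(simulation_config(n_genes = 60,
                                               frac_mirna_host = 0.2,
                                               seed = 21))
  res <- suppressWarnings(test_differential_usage(ds$counts, ds$conditions))
  out1 <- extract_mirna_exons(res, ds$mirna_loci)
  out2 <- extract_mirna_exons(res[sample(nrow(res)), ], ds$mirna_loci)
  expect_equal(out1, out2)
  out3 <- extract_mirna_exons(res, ds$mirna_loci[sample(nrow(ds$mirna_loci)), ])
  expect_equal(out1, out3)
  expect_warning(
    extract_mirna_exons(res, data.frame(mirna_id = "bad", chrom = "chr1",
                                        start = 10, end = 5, strand = "+")),
    "malformed")
})
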