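test_that("size factors recover median-of-ratios on closed-form toys", {
  identical_mat <- cbind(A1 = c(10, 50, 200), A2 = c(10, 50, 200),
                         B1 = c(10, 50, 200), B2 = c(10, 50, 200))
  sf <- estimate_size_factors(toy_counts(identical_mat))
  expect_equal(unname(sf), rep(1, 4))

  # sample B doubles sample A everywhere: factors (1, 2) / geometric mean
  doubled <- cbind(A = c(100, 200, 300), B = c(200, 400, 600))
  sf <- estimate_size_factors(toy_counts(doubled))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(exp(mean(log(sf))), 1)

  zero_sample <- cbind(A = c(5, 8), B = c(0, 0))
  expect_error(estimate_size_factors(toy_counts(zero_sample)), "all-positive")
})

test_that("BH adjustment matches hand-computed and brute-force oracles", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(1), 1)
  expect_equal(adjust_bh(numeric(0)), numeric(0))
  expect_error(adjust_bh(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(0.2, -0.1)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    expect_equal(adjust_bh(p), bh_oracle(p))
  }
  sorted <- sort(runif(15))
  expect_true(all(diff(adjust_bh(sorted)) >= 0))
})

test_that("FDR filtering is strict, order-preserving and vacuous at bounds", {
  fx <- load_mirna_fixture()
  fx$p_bh <- fx$bh_p
  expect_equal(nrow(filter_significant(fx, 0.1)), 23L)
  expect_equal(nrow(filter_significant(fx, 0)), 0L)
  expect_equal(filter_significant(fx, 1), fx)
  shuffled <- fx[sample(nrow(fx)), ]
  expect_identical(filter_significant(shuffled, 0.05)$ensembl_exon_id,
                   shuffled$ensembl_exon_id[shuffled$p_bh < 0.05])
})

test_that("a flat exon is null and single-exon genes are skipped", {
  mat <- cbind(ALC1 = c(500, 300, 400), ALC2 = c(500, 310, 390),
               CONT1 = c(500, 290, 410), CONT2 = c(500, 305, 395))
  counts <- rbind(toy_counts(mat, "G1"),
                  toy_counts(mat[1, , drop = FALSE], "G2"))
  conditions <- c(ALC1 = "alcohol", ALC2 = "alcohol",
                  CONT1 = "control", CONT2 = "control")
  expect_warning(res <- test_differential_usage(counts, conditions),
                 "single-exon")
  expect_false("G2" %in% res$gene_id)
  flat <- res[res$exon_id == "G1:E001", ]
  expect_equal(flat$log2fc, 0, tolerance = 0.02)
  expect_gt(flat$p_raw, 0.5)
  expect_true(all(res$p_bh >= res$p_raw))
  expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
})

test_that("condition labels are validated", {
  ds <- generate_exon_counts(simulation_config(n_genes = 5, seed = 1))
  bad <- ds$conditions
  bad[] <- "one_condition"
  expect_error(test_differential_usage(ds$counts, bad), "two condition")
  expect_error(test_differential_usage(ds$counts, ds$conditions[-1]),
               "condition label")
})

test_that("planting an exon up in alcohol always yields a negative log2fc", {
  for (seed in 1:5) {
    ds <- generate_exon_counts(simulation_config(
      n_genes = 6, exons_per_gene = c(3, 3), frac_deu_exons = 0,
      nb_mean_range = c(400, 600), seed = seed))
    alc <- names(ds$conditions)[ds$conditions == "alcohol"]
    set.seed(seed)
    ds$counts[1, alc] <- rnbinom(length(alc), mu = 4 * 500, size = 20)
    res <- suppressWarnings(test_differential_usage(ds$counts, ds$conditions))
    expect_lt(res$log2fc[res$exon_id == ds$counts$exon_id[1]], 0)
  }
})

test_that("planted usage effects are recovered in magnitude and direction", {
  ds <- generate_exon_counts(simulation_config(
    n_genes = 100, exons_per_gene = c(3, 4), frac_deu_exons = 0,
    nb_mean_range = c(200, 2000), seed = 7))
  tr <- ds$truth
  set.seed(9)
  idx <- sample(nrow(tr), 100)
  tr$is_deu[idx] <- TRUE
  tr$true_log2_effect[idx] <- sample(c(-1, 1), 100, TRUE) * runif(100, 0.5, 3)
  mu <- runif(nrow(tr), 200, 2000)
  for (s in names(ds$conditions)) {
    shift <- if (ds$conditions[[s]] == "alcohol")
      2^(-tr$true_log2_effect) else rep(1, nrow(tr))
    ds$counts[[s]] <- rnbinom(nrow(tr), mu = mu * shift, size = 20)
  }
  res <- suppressWarnings(test_differential_usage(ds$counts, ds$conditions))
  m <- merge(res, tr, by = "exon_id")
  deu <- m[m$is_deu, ]
  rho <- cor(abs(deu$log2fc), abs(deu$true_log2_effect), method = "spearman")
  expect_gt(rho, 0.8)
  strong <- deu[abs(deu$true_log2_effect) >= 1, ]
  expect_true(all(sign(strong$log2fc) == sign(strong$true_log2_effect)))
})

test_that("usage coefficients separate conditions for a planted exon", {
  ds <- generate_exon_counts(simulation_config(
    n_genes = 10, exons_per_gene = c(3, 3), frac_deu_exons = 0,
    nb_mean_range = c(500, 500), seed = 13))
  alc <- names(ds$conditions)[ds$conditions == "alcohol"]
  set.seed(13)
  ds$counts[1, alc] <- rnbinom(length(alc), mu = 8 * 500, size = 20)
  res <- suppressWarnings(test_differential_usage(ds$counts, ds$conditions))
  hit <- res[res$exon_id == ds$counts$exon_id[1], ]
  expect_gt(hit$usage_alcohol, hit$usage_control)
  expect_true(all(c("usage_control", "usage_alcohol",
                    paste0("norm_", names(ds$conditions))) %in% names(res)))
})
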