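test_that("enrichment p-values equal the hypergeometric summation oracle", {
  set.seed(17)
  for (N in c(8, 15, 22, 30)) {
    sizes <- unique(pmin(N, c(1, 2, sample(2:N, 4, replace = TRUE), N)))
    catalog <- make_catalog(N, sizes)
    for (rep in 1:4) {
      n <- sample(1:N, 1)
      lst <- sample(catalog$universe, n)
      res <- fisher_enrichment(lst, catalog)
      for (i in seq_len(nrow(res))) {
        expect_equal(res$p[i],
                     hyper_oracle(res$overlap[i], res$term_size[i],
                                  res$list_size[i], res$universe_size[i]),
                     tolerance = 1e-12)
      }
      expect_true(all(res$overlap <= pmin(res$list_size, res$term_size)))
      expect_equal(res$fold_enrichment,
                   (res$overlap / res$list_size) /
                     (res$term_size / res$universe_size))
    }
  }
})

test_that("disjoint, identical and EASE-adjusted overlaps behave correctly", {
  catalog <- make_catalog(20, sizes = c(5, 8))
  # list disjoint from T1 (g1..g5)
  res <- fisher_enrichment(paste0("g", 16:20), catalog)
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$p, 1)
  expect_equal(r1$fold_enrichment, 0)
  # list == term: minimal achievable p for that term size
  res2 <- fisher_enrichment(paste0("g", 1:5), catalog)
  expect_equal(res2$p[res2$term_id == "T1"],
               hyper_oracle(5, 5, 5, 20), tolerance = 1e-12)
  # EASE decrements the overlap, so it is never more significant
  ease <- fisher_enrichment(paste0("g", 1:5), catalog, ease = TRUE)
  expect_true(all(ease$p >= res2$p))
  expect_equal(ease$p[ease$term_id == "T1"],
               hyper_oracle(4, 5, 5, 20), tolerance = 1e-12)
  expect_warning(fisher_enrichment(c("g1", "not-a-gene"), catalog), "dropped")
  expect_error(suppressWarnings(fisher_enrichment("not-a-gene", catalog)),
               "empty")
})

test_that("random-list nulls are uniform for large terms, discrete for tiny ones", {
  catalog <- make_catalog(2000, sizes = c(600, 3))
  null <- random_null(catalog, list_size = 300, reps = 400, seed = 8)
  expect_equal(dim(null$p_values), c(2L, 400L))
  s <- null$summary
  expect_lt(s$uniformity_stat[s$term_id == "T1"], 0.1)
  expect_identical(s$flag[s$term_id == "T1"], "clean")
  # a 3-gene term has a coarse null that piles mass at low p
  expect_gt(s$uniformity_stat[s$term_id == "T2"], 0.1)
  expect_identical(s$flag[s$term_id == "T2"], "enrichment-prone")
  # determinism
  null2 <- random_null(catalog, list_size = 300, reps = 400, seed = 8)
  expect_identical(null$p_values, null2$p_values)
  expect_warning(random_null(catalog, list_size = 5, reps = 20, seed = 1),
                 "unstable")
})

test_that("null distributions depend only on term size, not identity", {
  universe <- paste0("g", 1:150)
  sets <- list(TA = universe[1:25], TB = universe[101:125])
  meta <- data.frame(term_id = c("TA", "TB"), meta_group = "m1")
  catalog <- annotation_catalog(sets, universe, meta)
  null <- random_null(catalog, list_size = 25, reps = 500, seed = 3)
  ks <- suppressWarnings(stats::ks.test(null$p_values["TA", ],
                                        null$p_values["TB", ]))
  expect_gt(ks$p.value, 0.01)
})

test_that("verdicts separate validated from false-discovery-prone terms", {
  observed <- data.frame(term_id = c("T1", "T2", "T3"),
                         p = c(0.001, 0.001, 0.9))
  null <- structure(list(
    p_values = rbind(T1 = seq(0.001, 1, length.out = 1000),
                     T2 = c(rep(0.01, 300), seq(0.001, 1, length.out = 700)),
                     T3 = seq(0.001, 1, length.out = 1000)),
    n_lists = 1000L, list_size = 20L,
    summary = data.frame(term_id = c("T1", "T2", "T3"),
                         uniformity_stat = c(0.02, 0.3, 0.02),
                         frac_low = c(0.05, 0.3, 0.05),
                         flag = c("clean", "enrichment-prone", "clean"))),
    class = "null_ensemble")
  v <- flag_terms(observed, null)
  expect_identical(v$verdict, c("validated-enriched", "false-discovery-prone",
                                "not-enriched"))
  expect_error(flag_terms(data.frame(term_id = "TX", p = 0.01), null),
               "missing")
})

test_that("shrinking alpha never promotes a term to validated-enriched", {
  set.seed(6)
  catalog <- make_catalog(120, sizes = c(40, 25, 3))
  null <- random_null(catalog, list_size = 20, reps = 300, seed = 2)
  obs <- fisher_enrichment(sample(catalog$universe, 20), catalog)
  for (alpha_small in c(0.01, 0.005)) {
    v_big <- flag_terms(obs, null, alpha = 0.05)
    v_small <- flag_terms(obs, null, alpha = alpha_small)
    promoted <- v_big$verdict == "not-enriched" &
      v_small$verdict == "validated-enriched"
    expect_false(any(promoted))
  }
})

test_that("per-miRNA profiles validate planted terms and are functional", {
  set.seed(11)
  universe <- paste0("g", 1:2000)
  planted <- universe[1:600]
  sets <- list(Tplanted = planted, Tother = universe[1001:1400])
  meta <- data.frame(term_id = names(sets), meta_group = "m1")
  catalog <- annotation_catalog(sets, universe, meta)
  targets <- list(mirA = planted[1:300],
                  mirB = planted[1:300],
                  mirEmpty = c("nope1", "nope2"))
  expect_warning(
    prof <- mirna_pathway_profile(targets, catalog, reps = 400, seed = 4),
    "no in-universe")
  expect_setequal(names(prof), c("mirA", "mirB"))
  expect_true("Tplanted" %in% prof$mirA$validated$term_id)
  expect_identical(prof$mirA$enrichment, prof$mirB$enrichment)
  expect_identical(prof$mirA$verdicts, prof$mirB$verdicts)
})
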