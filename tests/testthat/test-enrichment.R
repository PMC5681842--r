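test_that("hypergeometric tails match the closed-form single-term case", {
  # all 6 draws are effect alleles: only the k=6 term, choose(10,6)/choose(20,6)
  expect_equal(
    hypergeom_tail_p(6, 6, 10, 20, "enrichment"),
    210 / 38760,
    tolerance = 1e-12
  )
  # complement-allele symmetry oracle: zero effect alleles, depletion side
  expect_equal(
    hypergeom_tail_p(0, 6, 10, 20, "depletion"),
    210 / 38760,
    tolerance = 1e-12
  )
  # saturated table: every allele is an effect allele
  expect_equal(hypergeom_tail_p(20, 20, 20, 20, "enrichment"), 1)
  expect_equal(hypergeom_tail_p(20, 20, 20, 20, "depletion"), 1)
  expect_error(hypergeom_tail_p(7, 6, 10, 20, "enrichment"), "Inconsistent")
})

test_that("tails agree with brute-force enumeration for all instances with N <= 60", {
  for (N in c(2:10, 20, 35, 60)) {
    for (K in 0:N) {
      for (n in seq(0, N, by = 3)) {
        ks <- max(0, n - (N - K)):min(n, K)
        pe <- hypergeom_tail_p(ks, n, K, N, "enrichment")
        pd <- hypergeom_tail_p(ks, n, K, N, "depletion")
        pe_brute <- vapply(ks, brute_tail_p, 0, n = n, K = K, N = N,
          direction = "enrichment")
        pd_brute <- vapply(ks, brute_tail_p, 0, n = n, K = K, N = N,
          direction = "depletion")
        expect_equal(pe, pe_brute, tolerance = 1e-12)
        expect_equal(pd, pd_brute, tolerance = 1e-12)
        # the two tails overlap in exactly the point mass at k
        expect_equal(pe + pd, 1 + dhyper(ks, K, N - K, n), tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment of the effect allele equals depletion of the other allele", {
  set.seed(31)
  for (i in 1:200) {
    N <- sample(10:500, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    ks <- max(0, n - (N - K)):min(n, K)
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(
      hypergeom_tail_p(k, n, K, N, "enrichment"),
      hypergeom_tail_p(n - k, n, N - K, N, "depletion"),
      tolerance = 1e-12
    )
  }
})

test_that("enrichment p is non-increasing in k at fixed (N, K, n)", {
  ks <- 0:50
  p <- hypergeom_tail_p(ks, 50, 100, 300, "enrichment")
  expect_true(all(diff(p) <= 1e-15))
})

test_that("the FWER cutoff divides alpha by the total number of one-sided tests", {
  expect_equal(fwer_cutoff(0.01, 225, 26), 0.01 / 11700)
  expect_equal(fwer_cutoff(0.01, 1, 1), 0.005)
})

test_that("signed log10 encoding is positive for enrichment, negative for depletion", {
  expect_equal(signed_log10_value(1e-3, 0.9), 3)
  expect_equal(signed_log10_value(0.9, 1e-4), -4)
  expect_equal(signed_log10_value(0.5, 0.5), 0)
  # vectorized with elementwise sign decisions
  expect_equal(
    signed_log10_value(c(1e-3, 0.9), c(0.9, 1e-4)),
    c(3, -4)
  )
  expect_error(signed_log10_value(0, 0.5))
})

test_that("a cell is never flagged both enriched and depleted", {
  cfg <- toy_config(seed = 37)
  res <- enrichment_test(simulate_cohort(cfg))
  expect_false(any(res$enriched & res$depleted))
  expect_true(all(res$p_enrich > 0 & res$p_enrich <= 1))
  expect_true(all(res$p_deplete > 0 & res$p_deplete <= 1))
  expect_true(all(
    (res$signed_log10 > 0) == (res$p_enrich < res$p_deplete)
  ))
})

test_that("classification partitions the SNP set and finds planted signal", {
  # all-ones p-values: nothing significant, everything in `neither`
  counts <- tidyr::expand_grid(
    rsid = sprintf("r%02d", 1:8),
    stratum = c("A", "B")
  ) |>
    dplyr::mutate(k = 10L, m = 20L)
  res0 <- enrichment_test_counts(counts)
  cls0 <- classify_snps(res0)
  expect_equal(cls0$any_significant, 0)
  expect_equal(cls0$neither, 8)
  expect_equal(
    cls0$both + cls0$enriched_only + cls0$depleted_only + cls0$neither,
    cls0$n_snps
  )

  # planted +0.4 shift in one population is recovered as enriched-only
  pops <- tibble::tibble(
    pop = sprintf("P%02d", 1:26),
    super_pop = rep(c("G1", "G2"), each = 13),
    n = 100
  )
  cfg <- sim_config(
    populations = pops, n_snps = 40, fst_within = 1e-4, fst_between = NULL,
    ancestral_freq_range = c(0.3, 0.5), ld_blocks = list(),
    n_significant = 40, n_effect_sizes = 0, seed = 41
  )
  truth <- simulate_population_frequencies(cfg)
  truth <- plant_enrichment(truth, "P05", "snp0007", 0.4)
  ds <- simulate_genotypes(truth, cfg)
  res <- enrichment_test(ds, alpha = 0.01)
  classes <- snp_classes(res)
  expect_equal(classes$class[classes$rsid == "snp0007"], "enriched_only")
  expect_true(all(classes$class[classes$rsid != "snp0007"] == "neither"))
  hit <- dplyr::filter(res, rsid == "snp0007", stratum == "P05")
  expect_true(hit$enriched)
})

test_that("null calibration: undifferentiated data stays at or below nominal rates", {
  pops <- tibble::tibble(
    pop = sprintf("P%02d", 1:26),
    super_pop = rep(c("G1", "G2"), each = 13),
    n = 60
  )
  cfg <- sim_config(
    populations = pops, n_snps = 150, fst_within = 1e-6, fst_between = NULL,
    ancestral_freq_range = c(0.2, 0.8), ld_blocks = list(),
    n_significant = 150, n_effect_sizes = 0, seed = 43
  )
  ds <- simulate_cohort(cfg)
  res <- enrichment_test(ds)
  n_tests <- 2 * nrow(res)
  for (alpha in c(0.05, 0.01)) {
    hits <- sum(res$p_enrich < alpha) + sum(res$p_deplete < alpha)
    bound <- alpha + 3 * sqrt(alpha * (1 - alpha) / n_tests)
    # hypergeometric tests are conservative on discrete support
    expect_lte(hits / n_tests, bound)
  }
})
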