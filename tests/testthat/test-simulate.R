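test_that("Balding-Nichols draws have the right mean, variance and limits", {
  # closed form: Var(freq) = F p (1-p)
  cfg <- sim_config(
    populations = tibble::tibble(pop = "P1", super_pop = "G1", n = 10),
    n_snps = 100000, fst_within = 0.1, fst_between = NULL,
    ancestral_freq_range = c(0.5, 0.5),
    ld_blocks = list(), n_significant = 0, n_effect_sizes = 0, seed = 42
  )
  truth <- simulate_population_frequencies(cfg)
  expect_equal(var(truth$freq), 0.1 * 0.5 * 0.5, tolerance = 0.05)
  expect_equal(mean(truth$freq), 0.5, tolerance = 0.01)
  expect_true(all(truth$freq >= 0 & truth$freq <= 1))

  # no-drift limit: F -> 0 pins every population at the ancestral frequency
  cfg0 <- sim_config(
    populations = toy_populations(), n_snps = 250,
    fst_within = 1e-6, fst_between = NULL,
    ld_blocks = list(), n_significant = 0, n_effect_sizes = 0, seed = 1
  )
  truth0 <- simulate_population_frequencies(cfg0)
  expect_lt(max(abs(truth0$freq - truth0$ancestral)), 0.01)
})

test_that("degenerate differentiation parameters are rejected", {
  expect_error(toy_config(fst_within = 0), "strictly in \\(0, 1\\)")
  expect_error(toy_config(fst_within = 1), "strictly in \\(0, 1\\)")
  expect_error(toy_config(fst_between = 1), "strictly in \\(0, 1\\)")
})

test_that("the same seed reproduces every simulated output bit-for-bit", {
  cfg <- toy_config(seed = 7)
  t1 <- simulate_population_frequencies(cfg)
  t2 <- simulate_population_frequencies(cfg)
  expect_identical(t1, t2)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(d1$hap1, d2$hap1)
  expect_identical(d1$hap2, d2$hap2)
  expect_identical(d1$annotations, d2$annotations)
  # and identical VCF bytes
  f1 <- write_fixture(d1, file.path(tempdir(), "det_a"))
  f2 <- write_fixture(d2, file.path(tempdir(), "det_b"))
  expect_identical(readLines(f1["vcf"]), readLines(f2["vcf"]))
})

test_that("observed population frequencies recover the truth at O(1/sqrt(n))", {
  for (n in c(50, 200, 1000)) {
    cfg <- sim_config(
      populations = tibble::tibble(pop = "P1", super_pop = "G1", n = n),
      n_snps = 40, fst_within = 0.05, fst_between = NULL,
      ld_blocks = list(), n_significant = 0, n_effect_sizes = 0, seed = n
    )
    truth <- simulate_population_frequencies(cfg)
    ds <- simulate_genotypes(truth, cfg)
    obs <- allele_frequencies(count_effect_alleles(ds, by = "population"))
    joined <- dplyr::inner_join(
      obs, truth,
      by = c(rsid = "rsid", stratum = "pop")
    )
    # binomial sampling error: 3 SDs of sqrt(f(1-f)/2n), floored for rare alleles
    tol <- pmax(3 * sqrt(joined$freq.y * (1 - joined$freq.y) / (2 * n)), 0.02)
    expect_true(all(abs(joined$freq.x - joined$freq.y) <= tol))
  }
})

test_that("LD copying chain produces perfect LD at copy probability 1", {
  cfg <- toy_config(ld_blocks = list(c(6, 1.0)), n_snps = 10, seed = 3)
  ds <- simulate_cohort(cfg)
  block_snps <- colnames(ds$hap1)[1:6]
  m <- ld_matrix(ds, block_snps, stratum = "P1", by = "population")
  off <- m[upper.tri(m)]
  expect_true(all(off[!is.na(off)] == 1))
})

test_that("with copy probability 0 mean pairwise r2 matches the null 1/(2n)", {
  # null expectation of r2 for independent SNPs is ~ 1/(#haplotypes);
  # estimated here by brute-force resampling over many simulated pairs
  n <- 50 # 100 haplotypes
  cfg <- sim_config(
    populations = tibble::tibble(pop = "P1", super_pop = "G1", n = n),
    n_snps = 200, fst_within = 0.05, fst_between = NULL,
    ancestral_freq_range = c(0.3, 0.7),
    ld_blocks = list(c(200, 0.0)), n_significant = 0, n_effect_sizes = 0,
    seed = 5
  )
  ds <- simulate_cohort(cfg)
  snps <- colnames(ds$hap1)
  r2s <- vapply(seq(1, 199, by = 2), function(i) {
    pairwise_r2(
      c(ds$hap1[, snps[i]], ds$hap2[, snps[i]]),
      c(ds$hap1[, snps[i + 1]], ds$hap2[, snps[i + 1]])
    )
  }, 0)
  r2s <- r2s[!is.na(r2s)]
  se <- sd(r2s) / sqrt(length(r2s))
  expect_lt(abs(mean(r2s) - 1 / (2 * n)), 3 * se + 1e-3)
})

test_that("plant_enrichment shifts only the target cells and validates ids", {
  cfg <- toy_config(seed = 9)
  truth <- simulate_population_frequencies(cfg)
  expect_identical(plant_enrichment(truth, "P1", "snp0001", 0), truth)
  shifted <- plant_enrichment(truth, "P2", c("snp0001", "snp0002"), 0.4)
  hit <- shifted$pop == "P2" & shifted$rsid %in% c("snp0001", "snp0002")
  expect_true(all(shifted$freq[hit] >= truth$freq[hit]))
  expect_identical(shifted$freq[!hit], truth$freq[!hit])
  expect_true(all(shifted$freq >= 0.01 & shifted$freq <= 0.99 | !hit))
  expect_error(plant_enrichment(truth, "NOPE", "snp0001", 0.1), "Unknown population")
  expect_error(plant_enrichment(truth, "P1", "rs_absent", 0.1), "Unknown SNP")
})

test_that("annotation model plants the configured GWAS p-value split", {
  cfg <- toy_config(n_snps = 50, n_significant = 20, seed = 13)
  ann <- simulate_snp_annotations(cfg)
  expect_equal(sum(ann$gwas_pvalue < 5e-8), 20)
  expect_true(all(ann$gwas_pvalue > 0 & ann$gwas_pvalue < 9e-6))
  expect_equal(sum(!is.na(ann$effect_size)), 5)
  # effect sizes only on genome-wide-significant SNPs
  expect_true(all(ann$gwas_pvalue[!is.na(ann$effect_size)] < 5e-8))
})
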