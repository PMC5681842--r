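test_that("genome-wide significance filter is strict and warns on missing p", {
  ann <- tibble::tibble(
    rsid = c("a", "b", "c", "d"),
    gwas_pvalue = c(5e-8, 4.9e-8, NA, 1e-10)
  )
  expect_warning(out <- select_genomewide_significant(ann), "without a GWAS p-value")
  expect_equal(out$rsid, c("b", "d")) # boundary value excluded, order kept
})

test_that("composite score has the documented extremes and arithmetic", {
  expect_equal(
    composite_score_from_dosage(rbind(c(2, 2, 2), c(0, 0, 0), c(2, 0, 1))),
    c(1, 0, 0.5)
  )
  # missing SNPs drop out of the denominator
  expect_equal(composite_score_from_dosage(rbind(c(2, NA))), 1)
  expect_error(
    composite_score_from_dosage(rbind(c(NA, NA))),
    "I' = 0"
  )
  expect_error(composite_score_from_dosage(rbind(c(3, 0))), "Dosages")
  # bounds hold on simulated data, and score 1 iff homozygous everywhere
  cfg <- toy_config(seed = 101)
  sc <- composite_risk_score(simulate_cohort(cfg))
  expect_true(all(sc$score >= 0 & sc$score <= 1))
})

test_that("random dosages give mean score 1/2", {
  set.seed(103)
  x <- matrix(sample(0:2, 2000 * 20, replace = TRUE), 2000, 20)
  s <- composite_score_from_dosage(x)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 0.5), 3 * se)
})

test_that("population summaries follow the stated quantile and whisker conventions", {
  scores <- structure(
    tibble::tibble(
      sample = sprintf("S%02d", 1:10),
      pop = "P1", super_pop = "G1",
      score = seq(0.1, 1.0, by = 0.1),
      n_snps_used = 10L, n_missing = 0L
    ),
    class = c("risk_scores", class(tibble::tibble()))
  )
  s <- population_score_summary(scores)
  expect_equal(s$median, 0.55)
  # linear-interpolation quantiles
  expect_equal(s$q25, 0.325)
  expect_equal(s$q75, 0.775)
  expect_equal(s$whisker_low, 0.325 - 1.5 * 0.45)
  expect_equal(s$whisker_high, 0.775 + 1.5 * 0.45)

  # all-equal scores: degenerate box
  scores$score <- rep(0.4, 10)
  s2 <- population_score_summary(scores)
  expect_equal(s2$mean, 0.4)
  expect_equal(s2$median, 0.4)
  expect_equal(s2$q75 - s2$q25, 0)
})

test_that("population mean score equals population mean EAF on complete data", {
  cfg <- toy_config(seed = 107)
  ds <- simulate_cohort(cfg)
  id <- verify_mean_identity(ds, by = "population")
  expect_true(all(id$exact))
  expect_true(all(id$abs_diff < 1e-12))
  # single individual, single SNP, one effect allele: score = EAF = 0.5
  one <- dataset_from_dosage(rbind(1), "P1")
  id1 <- verify_mean_identity(one, by = "population")
  expect_equal(id1$mean_score, 0.5)
  expect_equal(id1$mean_eaf, 0.5)
})

test_that("missing data breaks the identity and is flagged", {
  ds <- dataset_from_dosage(rbind(c(2, NA), c(0, 0)), rep("P1", 2))
  id <- verify_mean_identity(ds, by = "population")
  expect_false(id$exact)
  expect_gt(id$abs_diff, 0.1)
})

test_that("a group with planted lower frequencies ranks lowest by mean score", {
  pops <- tibble::tibble(
    pop = c("E1", "E2", "U1", "U2", "A1", "A2"),
    super_pop = c("EAS", "EAS", "EUR", "EUR", "AFR", "AFR"),
    n = 50
  )
  cfg <- sim_config(
    populations = pops, n_snps = 40, fst_within = 0.01, fst_between = NULL,
    ancestral_freq_range = c(0.4, 0.6), ld_blocks = list(),
    n_significant = 40, n_effect_sizes = 0, seed = 109
  )
  truth <- simulate_population_frequencies(cfg)
  for (p in c("E1", "E2")) {
    truth <- plant_enrichment(truth, p, unique(truth$rsid), -0.25)
  }
  ds <- simulate_genotypes(truth, cfg)
  summ <- population_score_summary(composite_risk_score(ds, snps = unique(truth$rsid)))
  bottom2 <- utils::tail(summ$stratum, 2)
  expect_setequal(bottom2, c("E1", "E2"))
})

test_that("prevalence correlation pools individuals and fits OLS", {
  cfg <- toy_config(seed = 113)
  ds <- simulate_cohort(cfg)
  sc <- composite_risk_score(ds)
  pop_means <- population_score_summary(sc)

  # perfectly linear synthetic relation: R^2 = 1
  m <- setNames(pop_means$mean, pop_means$stratum)
  prevalence <- tibble::tibble(
    country = c("C1", "C2", "C3", "C4"),
    prevalence_pct = 100 * (m[c("P1", "P2", "P3", "P4")] - 0.2),
    pops = c("P1", "P2", "P3", "P4")
  )
  fit <- prevalence_correlation(sc, prevalence)
  # a perfect fit makes summary.lm grumble; the R^2 itself is what matters
  expect_equal(
    suppressWarnings(glance(fit)$r.squared), 1,
    tolerance = 1e-9
  )

  # pooling two populations pools their individuals, not their means
  pooled <- tibble::tibble(
    country = c("C12", "C3", "C4"),
    prevalence_pct = c(10, 20, 30),
    pops = c("P1, P2", "P3", "P4")
  )
  fit2 <- prevalence_correlation(sc, pooled)
  expect_equal(
    fit2$data$mean_score[fit2$data$country == "C12"],
    mean(sc$score[sc$pop %in% c("P1", "P2")])
  )
  expect_equal(
    fit2$data$n_individuals[fit2$data$country == "C12"],
    sum(sc$pop %in% c("P1", "P2"))
  )

  # constant prevalence: R^2 = 0, p reported as 1
  const <- dplyr::mutate(prevalence, prevalence_pct = 15)
  g <- suppressWarnings(glance(prevalence_correlation(sc, const)))
  expect_equal(g$r.squared, 0)
  expect_equal(g$p.value, 1)

  expect_error(
    prevalence_correlation(sc, prevalence[1:2, ]),
    "at least 3"
  )
  expect_error(
    prevalence_correlation(
      sc,
      dplyr::mutate(prevalence, pops = c("P1, P1", "P2", "P3", "P4"))
    ),
    "twice"
  )
})

test_that("neighbor counting includes the SNP itself with a closed window", {
  all_snps <- tibble::tibble(
    rsid = c("s1", "s2", "s3", "s4", "s5"),
    chrom = c("1", "1", "1", "2", "2"),
    pos = c(1e6, 2e6, 10e6, 1e6, 5e6)
  )
  ind <- tibble::tibble(
    rsid = c("s1", "s3", "s4"),
    chrom = c("1", "1", "2"),
    pos = c(1e6, 10e6, 1e6),
    effect_size = c(0.3, 0.2, 0.1)
  )
  fit <- neighbor_effect_correlation(ind, all_snps, window = 1e6)
  counts <- setNames(fit$data$n_neighbors, fit$data$rsid)
  expect_equal(counts[["s1"]], 2L) # itself + s2 exactly 1 Mb away (closed)
  expect_equal(counts[["s3"]], 1L) # isolated: itself only
  expect_equal(counts[["s4"]], 1L) # s5 is 4 Mb away on the same chromosome
})

test_that("a planted linear count-effect relationship is recovered", {
  # effect sizes exactly proportional to neighbor counts: r = 1
  pos_groups <- list(1, 1:2, 1:3, 1:4)
  rows <- purrr::imap(pos_groups, function(offsets, i) {
    tibble::tibble(
      rsid = sprintf("c%d_%d", i, offsets),
      chrom = as.character(i),
      pos = 1e6 + offsets * 1000
    )
  })
  all_snps <- dplyr::bind_rows(rows)
  ind <- purrr::imap_dfr(pos_groups, function(offsets, i) {
    tibble::tibble(
      rsid = sprintf("c%d_1", i), chrom = as.character(i), pos = 1e6 + 1000,
      effect_size = 0.1 * length(offsets)
    )
  })
  fit <- neighbor_effect_correlation(ind, all_snps)
  expect_equal(glance(fit)$r, 1, tolerance = 1e-12)
  expect_equal(fit$data$n_neighbors, c(1L, 2L, 3L, 4L))
})

test_that("SNP-set bias comparison: ratios, t-tests, reproducible augmentation", {
  cfg <- toy_config(seed = 127, n_snps = 40, n_significant = 40)
  truth <- simulate_population_frequencies(cfg)
  snps <- unique(truth$rsid)
  set1 <- snps[1:10]
  set2 <- snps[11:30]
  # P1 planted far above P2 on set1 only: ratio(set1) > ratio(set2)
  truth <- plant_enrichment(truth, "P1", set1, 0.35)
  ds <- simulate_genotypes(truth, cfg)
  cmp <- subset_bias_comparison(
    ds, list(biased = set1, broad = set2), "P1", "P2"
  )
  expect_gt(cmp$ratio[cmp$set == "biased"], cmp$ratio[cmp$set == "broad"])
  expect_lt(cmp$p.value[cmp$set == "biased"], 0.01)

  # identical score distributions: ratio 1, p = 1
  ds_dup <- ds
  p1 <- ds$manifest$pop == "P1"
  p2 <- ds$manifest$pop == "P2"
  ds_dup$hap1[p2, ] <- ds$hap1[p1, ]
  ds_dup$hap2[p2, ] <- ds$hap2[p1, ]
  same <- subset_bias_comparison(
    ds_dup, list(a = set1, b = set2), "P1", "P2"
  )
  expect_equal(same$ratio, c(1, 1))
  expect_true(all(same$p.value > 0.99))

  # augmentation draw is reproducible under the seed and bounded by the pool
  a1 <- augment_snp_set(set1, snps, 5, seed = 42)
  a2 <- augment_snp_set(set1, snps, 5, seed = 42)
  expect_identical(a1, a2)
  expect_equal(length(a1), 15)
  expect_false(any(duplicated(a1)))
  expect_error(augment_snp_set(set1, snps, 100, seed = 1), "candidates")
})
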