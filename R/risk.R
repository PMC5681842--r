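#' Select genome-wide-significant SNPs
#'
#' Filters an annotation table to SNPs whose GWAS association p-value lies
#' strictly below the genome-wide significance threshold (default 5e-8; a
#' p-value exactly at the threshold is excluded). SNPs with a missing
#' p-value are excluded with a warning. The input ordering is preserved.
#'
#' @param annotations Annotation tibble with a `gwas_pvalue` column.
#' @param threshold Significance threshold (strict `<`).
#' @return The filtered annotation tibble.
#' @export
select_genomewide_significant <- function(annotations, threshold = 5e-8) {
  stopifnot("gwas_pvalue" %in% names(annotations))
  miss <- is.na(annotations$gwas_pvalue)
  if (any(miss)) {
    warn(paste0(
      sum(miss), " SNP(s) without a GWAS p-value excluded: ",
      paste(head(annotations$rsid[miss], 5), collapse = ", ")
    ))
  }
  annotations[!miss & annotations$gwas_pvalue < threshold, , drop = FALSE]
}

#' Composite score from an allele-dosage matrix
#'
#' The unweighted composite genetic risk score of an individual is the
#' fraction of their alleles over a SNP panel that are effect alleles:
#' `sum(X_i) / (2 I')`, where `X_i` in \{0, 1, 2\} counts effect-allele
#' copies at SNP i and `I'` is the number of SNPs with a non-missing
#' genotype for that individual (the denominator adapts to missingness so
#' missing calls do not deflate the score). A score of 1 means two effect
#' alleles at every scored SNP; 0 means none.
#'
#' @param x Integer matrix of allele dosages (individuals x SNPs, values
#'   0/1/2 or NA).
#' @return Numeric vector of scores in \[0, 1\], one per row of `x`.
#' @examples
#' composite_score_from_dosage(rbind(c(2, 2), c(0, 0), c(2, 0))) # 1, 0, 0.5
#' @export
composite_score_from_dosage <- function(x) {
  x <- as.matrix(x)
  if (any(!is.na(x) & !(x %in% 0:2))) {
    abort("Dosages must be 0, 1, 2 or NA.")
  }
  used <- rowSums(!is.na(x))
  if (any(used == 0)) {
    abort("Individual(s) with no non-missing SNP: score undefined (I' = 0).")
  }
  rowSums(x, na.rm = TRUE) / (2 * used)
}

#' Composite genetic risk scores for every individual in a dataset
#'
#' @param dataset A [genotype_dataset()].
#' @param snps SNP panel (character vector of rsids); defaults to the
#'   dataset's genome-wide-significant SNPs
#'   ([select_genomewide_significant()]).
#' @param gwas_threshold Threshold used when `snps` is NULL.
#' @return A `risk_scores` tibble: `sample`, `pop`, `super_pop`, `score`,
#'   `n_snps_used`, `n_missing`.
#' @export
composite_risk_score <- function(dataset, snps = NULL, gwas_threshold = 5e-8) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(snps)) {
    snps <- select_genomewide_significant(
      dataset$annotations, gwas_threshold
    )$rsid
    if (length(snps) == 0) abort("No genome-wide-significant SNPs in dataset.")
  }
  x <- effect_allele_dosage(dataset, snps)
  scores <- composite_score_from_dosage(x)
  out <- dataset$manifest |>
    dplyr::mutate(
      score = unname(scores[.data$sample]),
      n_snps_used = rowSums(!is.na(x))[.data$sample],
      n_missing = length(snps) - .data$n_snps_used
    )
  structure(out, class = c("risk_scores", class(out)), snps = snps)
}

#' Population (or group) summaries of composite risk scores
#'
#' Mean, median, quartiles (linear-interpolation convention), standard
#' deviation and 1.5 x IQR whisker limits per stratum, sorted by mean
#' score.
#'
#' @param scores A `risk_scores` tibble from [composite_risk_score()].
#' @param by `"population"` or `"group"`.
#' @return A tibble with one row per stratum.
#' @export
population_score_summary <- function(scores, by = c("population", "group")) {
  by <- match.arg(by)
  key <- if (by == "population") "pop" else "super_pop"
  scores |>
    dplyr::group_by(stratum = .data[[key]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$score),
      median = median(.data$score),
      q25 = quantile(.data$score, 0.25, names = FALSE),
      q75 = quantile(.data$score, 0.75, names = FALSE),
      sd = sd(.data$score),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      whisker_low = .data$q25 - 1.5 * (.data$q75 - .data$q25),
      whisker_high = .data$q75 + 1.5 * (.data$q75 - .data$q25)
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean))
}

#' Verify the mean-score = mean-EAF identity
#'
#' On complete data the population-level average of composite scores equals
#' the average of the population's effect-allele frequencies over the SNP
#' panel — both are `sum(k_i) / (2 n I)` read in different orders. This
#' function computes the two sides independently (scores from per-individual
#' dosages; EAFs from pooled allele counts) and reports their absolute
#' difference. With missing genotypes the two denominators decouple and the
#' identity holds only approximately; this is reported in the `exact` flag.
#'
#' @param dataset A [genotype_dataset()].
#' @param snps SNP panel (rsids); defaults to all SNPs in the dataset.
#' @param by `"population"`, `"group"` or `"global"`.
#' @return A tibble per stratum: `stratum`, `mean_score`, `mean_eaf`,
#'   `abs_diff`, `exact` (TRUE when the stratum has no missing calls on the
#'   panel).
#' @export
verify_mean_identity <- function(dataset, snps = NULL,
                                 by = c("global", "population", "group")) {
  by <- match.arg(by)
  if (is.null(snps)) snps <- colnames(dataset$hap1)
  sub <- subset_dataset(dataset, snps = snps)
  scores <- composite_risk_score(sub, snps = snps)
  freqs <- allele_frequencies(count_effect_alleles(sub, by = by))
  key <- switch(by,
    population = scores$pop,
    group = scores$super_pop,
    global = rep("global", nrow(scores))
  )
  miss <- is.na(sub$hap1) | is.na(sub$hap2)
  tibble::as_tibble(scores) |>
    dplyr::mutate(stratum = key) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop") |>
    dplyr::left_join(
      freqs |>
        dplyr::group_by(.data$stratum) |>
        dplyr::summarise(mean_eaf = mean(.data$freq), .groups = "drop"),
      by = "stratum"
    ) |>
    dplyr::mutate(
      abs_diff = abs(.data$mean_score - .data$mean_eaf),
      exact = vapply(.data$stratum, function(s) {
        rows <- which(key == s)
        !any(miss[rows, , drop = FALSE])
      }, logical(1))
    )
}

#' Correlate population mean risk scores with disease prevalence
#'
#' Pools populations into countries (pooling *individuals*, not averaging
#' population means), computes each country's mean composite score, and
#' fits an ordinary least-squares regression of prevalence on mean score.
#'
#' @param scores A `risk_scores` tibble ([composite_risk_score()]).
#' @param prevalence A tibble with columns `country`,
#'   `prevalence_pct` (percent of adults) and `pops` (comma-separated
#'   population codes pooled for that country).
#' @return A `prevalence_fit` object; see [tidy()]/[glance()] methods and
#'   [autoplot.prevalence_fit()]. `glance()` reports `r.squared` and the
#'   two-sided slope p-value (reported as 1 when the fit is degenerate,
#'   e.g. constant prevalence).
#' @export
prevalence_correlation <- function(scores, prevalence) {
  stopifnot(all(c("country", "prevalence_pct", "pops") %in% names(prevalence)))
  if (nrow(prevalence) < 3) abort("Need at least 3 countries.")
  if (any(prevalence$prevalence_pct < 0 | prevalence$prevalence_pct > 100)) {
    abort("Prevalence must lie in [0, 100] percent.")
  }
  pop_lists <- strsplit(prevalence$pops, ",\\s*")
  if (any(vapply(pop_lists, anyDuplicated, 0L) > 0)) {
    abort("A population is listed twice for the same country.")
  }
  country_means <- prevalence |>
    dplyr::mutate(
      mean_score = purrr::map2_dbl(pop_lists, .data$country, function(pl, cn) {
        rows <- scores$pop %in% pl
        if (!any(rows)) abort(paste0("No individuals for country: ", cn))
        mean(scores$score[rows])
      }),
      n_individuals = purrr::map_int(
        pop_lists, function(pl) sum(scores$pop %in% pl)
      )
    ) |>
    dplyr::select(
      "country", "prevalence_pct", "mean_score", "n_individuals"
    )
  fit <- lm(prevalence_pct ~ mean_score, data = country_means)
  structure(
    list(data = country_means, fit = fit),
    class = "prevalence_fit"
  )
}

#' @export
glance.prevalence_fit <- function(x, ...) {
  s <- summary(x$fit)
  r2 <- s$r.squared
  if (is.nan(r2)) r2 <- 0 # constant response: nothing to explain
  p <- if (nrow(s$coefficients) < 2 || is.nan(s$coefficients[2, 4])) {
    1 # degenerate fit (e.g. constant response): no evidence of association
  } else {
    s$coefficients[2, 4]
  }
  tibble::tibble(
    r.squared = r2,
    p.value = p,
    slope = if (nrow(s$coefficients) >= 2) s$coefficients[2, 1] else NA_real_,
    intercept = s$coefficients[1, 1],
    n_countries = nrow(x$data)
  )
}

#' @export
tidy.prevalence_fit <- function(x, ...) {
  broom::tidy(x$fit)
}

#' @export
print.prevalence_fit <- function(x, ...) {
  g <- glance(x)
  cat(
    "<prevalence_fit> ", g$n_countries, " countries; R^2 = ",
    signif(g$r.squared, 3), ", slope p = ", signif(g$p.value, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Correlate effect sizes of independent SNPs with nearby-SNP counts
#'
#' For each independent SNP S (one with a known per-allele effect size),
#' counts how many SNPs of the full panel lie within `window` base pairs of
#' S on the same chromosome — including S itself, so every count is >= 1;
#' the window is closed, so a SNP exactly `window` away is counted. Then
#' computes the Pearson correlation between effect sizes and neighbor
#' counts.
#'
#' @param independent_snps Tibble with `rsid`, `chrom`, `pos`,
#'   `effect_size` (no missing effect sizes).
#' @param all_snps Tibble with `rsid`, `chrom`, `pos` — the full panel used
#'   for the composite score.
#' @param window Half-width of the neighborhood in base pairs (default
#'   1 Mb).
#' @return A `neighbor_fit` object; `glance()` gives `r`, `r.squared` and
#'   the two-sided `p.value`; `$data` holds per-SNP counts.
#' @export
neighbor_effect_correlation <- function(independent_snps, all_snps,
                                        window = 1e6) {
  stopifnot(
    all(c("rsid", "chrom", "pos", "effect_size") %in% names(independent_snps)),
    all(c("rsid", "chrom", "pos") %in% names(all_snps)),
    window > 0
  )
  if (nrow(independent_snps) < 3) abort("Need at least 3 independent SNPs.")
  if (any(is.na(independent_snps$effect_size))) {
    abort("Independent SNPs must all carry effect sizes.")
  }
  counts <- purrr::map_int(seq_len(nrow(independent_snps)), function(i) {
    s <- independent_snps[i, ]
    sum(
      all_snps$chrom == s$chrom &
        abs(all_snps$pos - s$pos) <= window
    )
  })
  ct <- cor.test(independent_snps$effect_size, counts, method = "pearson")
  structure(
    list(
      data = dplyr::mutate(independent_snps, n_neighbors = counts),
      r = unname(ct$estimate),
      p.value = ct$p.value
    ),
    class = "neighbor_fit"
  )
}

#' @export
glance.neighbor_fit <- function(x, ...) {
  tibble::tibble(
    r = x$r, r.squared = x$r^2, p.value = x$p.value,
    n_snps = nrow(x$data)
  )
}

#' Augment a SNP set with a reproducible random draw
#'
#' Draws `n_add` SNPs without replacement from `pool` (excluding those
#' already in `base`) and appends them to `base`. The draw is fixed by
#' `seed`, so the augmented set is reproducible.
#'
#' @param base Character vector of rsids forming the core set.
#' @param pool Character vector of candidate rsids.
#' @param n_add Number of SNPs to add.
#' @param seed Integer seed governing the draw.
#' @return Character vector `c(base, drawn)`.
#' @export
augment_snp_set <- function(base, pool, n_add, seed) {
  candidates <- setdiff(pool, base)
  if (n_add > length(candidates)) {
    abort(paste0(
      "Requested ", n_add, " additional SNPs but only ",
      length(candidates), " candidates available."
    ))
  }
  drawn <- local_seed(as.integer(seed), sample(candidates, n_add))
  c(base, drawn)
}

#' Compare composite scores between two populations across SNP sets
#'
#' Recomputes composite scores per SNP set for the two populations and
#' reports, per set, the population means, their ratio, and a two-sample
#' t-test p-value between the individual score vectors. Welch's unequal-
#' variance t-test is the default; set `var_equal = TRUE` for the classical
#' pooled-variance variant.
#'
#' @param dataset A [genotype_dataset()].
#' @param snp_sets Named list of rsid character vectors.
#' @param pop_a,pop_b Population codes present in the dataset.
#' @param var_equal Use the pooled-variance t-test.
#' @return A tibble per SNP set: `set`, `n_snps`, `mean_a`, `mean_b`,
#'   `ratio`, `p.value`.
#' @export
subset_bias_comparison <- function(dataset, snp_sets, pop_a, pop_b,
                                   var_equal = FALSE) {
  stopifnot(inherits(dataset, "genotype_dataset"), length(snp_sets) >= 2)
  if (is.null(names(snp_sets)) || any(names(snp_sets) == "")) {
    names(snp_sets) <- paste0("set", seq_along(snp_sets))
  }
  for (p in c(pop_a, pop_b)) {
    if (!p %in% dataset$manifest$pop) abort(paste0("Unknown population: ", p))
  }
  purrr::map_dfr(names(snp_sets), function(nm) {
    snps <- snp_sets[[nm]]
    scores <- composite_risk_score(dataset, snps = snps)
    a <- scores$score[scores$pop == pop_a]
    b <- scores$score[scores$pop == pop_b]
    tt <- t.test(a, b, var.equal = var_equal)
    tibble::tibble(
      set = nm,
      n_snps = length(snps),
      mean_a = mean(a),
      mean_b = mean(b),
      ratio = mean(a) / mean(b),
      p.value = tt$p.value
    )
  })
}
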