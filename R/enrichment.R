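#' Exact hypergeometric tail p-value
#'
#' Models the tested stratum's `n` alleles as drawn without replacement from
#' the pooled cohort's `N` alleles, of which `K` are effect alleles. The
#' enrichment p-value is the upper tail `P(X >= k)` and the depletion
#' p-value the lower tail `P(X <= k)` of the hypergeometric distribution —
#' exact tail sums, no normal approximation.
#'
#' @param k Effect alleles observed in the stratum.
#' @param n Total alleles in the stratum.
#' @param K Effect alleles in the pooled cohort.
#' @param N Total alleles in the pooled cohort.
#' @param direction `"enrichment"` (`P(X >= k)`) or `"depletion"`
#'   (`P(X <= k)`).
#' @return Numeric vector of p-values in (0, 1]. Arguments recycle.
#' @examples
#' hypergeom_tail_p(6, 6, 10, 20, "enrichment") # choose(10,6)/choose(20,6)
#' @export
hypergeom_tail_p <- function(k, n, K, N, direction = c("enrichment", "depletion")) {
  direction <- match.arg(direction)
  bad <- k < 0 | n < 0 | K < 0 | N < 0 | k > n | k > K | n > N | K > N |
    (n - k) > (N - K)
  if (any(bad)) {
    abort("Inconsistent hypergeometric counts (need k <= min(K, n), n <= N, K <= N, n - k <= N - K).")
  }
  p <- if (direction == "enrichment") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  # extreme tails can underflow double precision to 0; floor at the smallest
  # representable positive double so p stays in (0, 1] and log10 is finite
  pmax(p, .Machine$double.xmin)
}

#' Raw p-value cutoff controlling the family-wise error rate
#'
#' Bonferroni-style: with two one-sided tests per SNP x stratum the total
#' test count is `n_snps * 2 * n_strata`, and the raw cutoff is
#' `alpha / (n_snps * 2 * n_strata)`. For 225 SNPs and 26 populations at
#' `alpha = 0.01` this is 0.01 / 11700 = 8.55e-7.
#'
#' @param alpha Target family-wise error rate in (0, 1).
#' @param n_snps Number of SNPs tested.
#' @param n_strata Number of strata (populations or groups) tested.
#' @return The raw p-value cutoff.
#' @export
fwer_cutoff <- function(alpha, n_snps, n_strata) {
  stopifnot(alpha > 0, alpha < 1, n_snps >= 1, n_strata >= 1)
  alpha / (n_snps * 2 * n_strata)
}

#' Signed log10 heatmap value from the two one-sided p-values
#'
#' Encodes each SNP x stratum cell on a single signed axis:
#' `-log10(p_enrich)` (positive) when the enrichment p-value is the smaller
#' of the two, `log10(p_deplete)` (negative) when the depletion p-value is
#' smaller, and 0 on an exact tie.
#'
#' @param p_enrich,p_deplete One-sided p-values in (0, 1]; recycled.
#' @return Numeric vector of signed display values.
#' @examples
#' signed_log10_value(1e-3, 0.9) # +3
#' signed_log10_value(0.9, 1e-4) # -4
#' @export
signed_log10_value <- function(p_enrich, p_deplete) {
  stopifnot(
    all(p_enrich > 0 & p_enrich <= 1),
    all(p_deplete > 0 & p_deplete <= 1)
  )
  dplyr::case_when(
    p_enrich < p_deplete ~ -log10(p_enrich),
    p_deplete < p_enrich ~ log10(p_deplete),
    .default = 0
  )
}

#' Enrichment/depletion tests from a count table
#'
#' Core testing engine: takes per-stratum allele counts, pools them into the
#' cohort totals (the pooled cohort *includes* the tested stratum), and runs
#' both one-sided exact hypergeometric tests per SNP x stratum. This entry
#' point lets published frequency tables (via
#' [reconstruct_allele_counts()]) use the identical machinery as
#' genotype-level data.
#'
#' @param counts Count table: tibble `rsid`, `stratum`, `k`, `m`.
#' @param alpha Family-wise error rate used for the significance flags.
#' @return An `enrichment_result` tibble: `rsid`, `stratum`, `k`, `n`, `K`,
#'   `N`, `p_enrich`, `p_deplete`, `signed_log10`, `enriched`, `depleted`,
#'   with the raw cutoff, alpha and test count in attributes.
#' @export
enrichment_test_counts <- function(counts, alpha = 0.01) {
  stopifnot(all(c("rsid", "stratum", "k", "m") %in% names(counts)))
  pooled <- counts |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(K = sum(.data$k), N = sum(.data$m), .groups = "drop")
  n_snps <- nrow(pooled)
  n_strata <- length(unique(counts$stratum))
  cutoff <- fwer_cutoff(alpha, n_snps, n_strata)
  res <- counts |>
    dplyr::rename(n = "m") |>
    dplyr::inner_join(pooled, by = "rsid") |>
    dplyr::mutate(
      p_enrich = hypergeom_tail_p(.data$k, .data$n, .data$K, .data$N, "enrichment"),
      p_deplete = hypergeom_tail_p(.data$k, .data$n, .data$K, .data$N, "depletion"),
      signed_log10 = signed_log10_value(.data$p_enrich, .data$p_deplete),
      enriched = .data$p_enrich < cutoff,
      depleted = .data$p_deplete < cutoff
    )
  structure(
    res,
    class = c("enrichment_result", class(res)),
    alpha = alpha,
    cutoff = cutoff,
    n_tests = n_snps * 2L * n_strata
  )
}

#' Test effect-allele enrichment/depletion of each stratum against the pooled cohort
#'
#' For every SNP and stratum, tests whether the stratum's effect-allele
#' count is significantly enriched (and, separately, depleted) relative to
#' the pooled cohort, using exact hypergeometric tails and a
#' family-wise-error cutoff of `alpha` divided by the total number of tests.
#'
#' @param dataset A [genotype_dataset()].
#' @param alpha Family-wise error rate (default 0.01).
#' @param by `"population"` or `"group"`.
#' @return An `enrichment_result` tibble; see [enrichment_test_counts()].
#' @export
enrichment_test <- function(dataset, alpha = 0.01,
                            by = c("population", "group")) {
  by <- match.arg(by)
  counts <- count_effect_alleles(dataset, by = by)
  enrichment_test_counts(counts, alpha = alpha)
}

#' Signed log10 p-value matrix (SNPs x strata)
#'
#' @param result An `enrichment_result`.
#' @return A numeric matrix with rsids as rows and strata as columns,
#'   carrying class `enrichment_matrix`. Positive cells mark enrichment,
#'   negative cells depletion.
#' @export
enrichment_matrix <- function(result) {
  stopifnot(inherits(result, "enrichment_result"))
  wide <- result |>
    dplyr::select("rsid", "stratum", "signed_log10") |>
    tidyr::pivot_wider(names_from = "stratum", values_from = "signed_log10")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$rsid
  class(m) <- c("enrichment_matrix", class(m))
  m
}

#' Classify SNPs by where their effect allele is significant
#'
#' Partitions the SNPs into four disjoint classes at the result's FWER
#' cutoff: `both` (enriched in at least one stratum and depleted in at
#' least one other), `enriched_only`, `depleted_only`, and `neither`; also
#' reports `any_significant = both + enriched_only + depleted_only`.
#'
#' @param result An `enrichment_result`.
#' @return A one-row tibble with the four class counts, `any_significant`
#'   and `n_snps`.
#' @export
classify_snps <- function(result) {
  stopifnot(inherits(result, "enrichment_result"))
  per_snp <- result |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(
      any_enriched = any(.data$enriched),
      any_depleted = any(.data$depleted),
      .groups = "drop"
    )
  both <- sum(per_snp$any_enriched & per_snp$any_depleted)
  enr <- sum(per_snp$any_enriched & !per_snp$any_depleted)
  dep <- sum(!per_snp$any_enriched & per_snp$any_depleted)
  tibble::tibble(
    both = both,
    enriched_only = enr,
    depleted_only = dep,
    neither = nrow(per_snp) - both - enr - dep,
    any_significant = both + enr + dep,
    n_snps = nrow(per_snp)
  )
}

#' Per-SNP significance classes
#'
#' @param result An `enrichment_result`.
#' @return A tibble `rsid`, `class` with class in
#'   `both`/`enriched_only`/`depleted_only`/`neither`.
#' @export
snp_classes <- function(result) {
  stopifnot(inherits(result, "enrichment_result"))
  result |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(
      any_enriched = any(.data$enriched),
      any_depleted = any(.data$depleted),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      class = dplyr::case_when(
        .data$any_enriched & .data$any_depleted ~ "both",
        .data$any_enriched ~ "enriched_only",
        .data$any_depleted ~ "depleted_only",
        .default = "neither"
      )
    ) |>
    dplyr::select("rsid", "class")
}

#' @export
glance.enrichment_result <- function(x, ...) {
  cls <- classify_snps(x)
  tibble::tibble(
    n_snps = cls$n_snps,
    n_strata = length(unique(x$stratum)),
    n_tests = attr(x, "n_tests"),
    alpha = attr(x, "alpha"),
    cutoff = attr(x, "cutoff"),
    any_significant = cls$any_significant,
    both = cls$both,
    enriched_only = cls$enriched_only,
    depleted_only = cls$depleted_only
  )
}
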