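#' The 26-population reference cohort layout
#'
#' Population codes, continental-group assignment and sample sizes of the 26
#' populations genotyped in the 1000 Genomes Project phase 3 (2504 individuals
#' in five continental groups: AFR, AMR, EAS, EUR, SAS). These sizes are the
#' default cohort layout of [sim_config()], so synthetic cohorts match the
#' real study design.
#'
#' @return A tibble with columns `pop`, `super_pop`, `n`.
#' @examples
#' reference_populations()
#' dplyr::count(reference_populations(), super_pop, wt = n)
#' @export
reference_populations <- function() {
  tibble::tribble(
    ~pop,  ~super_pop, ~n,
    "ACB", "AFR",  96L,
    "ASW", "AFR",  61L,
    "BEB", "SAS",  86L,
    "CDX", "EAS",  93L,
    "CEU", "EUR",  99L,
    "CHB", "EAS", 103L,
    "CHS", "EAS", 105L,
    "CLM", "AMR",  94L,
    "ESN", "AFR",  99L,
    "FIN", "EUR",  99L,
    "GBR", "EUR",  91L,
    "GIH", "SAS", 103L,
    "GWD", "AFR", 113L,
    "IBS", "EUR", 107L,
    "ITU", "SAS", 102L,
    "JPT", "EAS", 104L,
    "KHV", "EAS",  99L,
    "LWK", "AFR",  99L,
    "MSL", "AFR",  85L,
    "MXL", "AMR",  64L,
    "PEL", "AMR",  85L,
    "PJL", "SAS",  96L,
    "PUR", "AMR", 104L,
    "STU", "SAS", 102L,
    "TSI", "EUR", 107L,
    "YRI", "AFR", 108L
  )
}

#' Published continental effect-allele frequencies for 39 obesity risk SNPs
#'
#' A transcription of the published table of effect-allele frequencies (EAF)
#' in the five continental groups plus the pooled global cohort, for the 39
#' obesity risk SNPs whose enrichment or depletion p-value reached at least
#' 1e-100 and whose GWAS association reached genome-wide significance.
#' Coordinates are GRCh37; all alleles are on the forward strand. This table
#' is shipped as a plain-text file under `inst/extdata` and is used to
#' exercise the count-reconstruction path ([reconstruct_allele_counts()]) on
#' real published numbers.
#'
#' @return A tibble with columns `rsid`, `chrom`, `pos`, `func`, `gene`,
#'   `effect_allele`, `other_allele`, `eaf_afr`, `eaf_amr`, `eaf_eas`,
#'   `eaf_eur`, `eaf_sas`, `eaf_global`, `gwas_pvalue`.
#' @examples
#' eaf <- continental_eaf_snps()
#' eaf[eaf$rsid == "rs7708584", c("eaf_eas", "eaf_afr")]
#' @export
continental_eaf_snps <- function() {
  path <- system.file("extdata", "continental_eaf_39snps.tsv",
    package = "popdiffr", mustWork = TRUE
  )
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Continental-group sample sizes of the reference cohort
#'
#' @param populations A population table as returned by
#'   [reference_populations()].
#' @return A tibble with columns `super_pop` and `n` (individuals).
#' @export
continental_sizes <- function(populations = reference_populations()) {
  dplyr::count(populations, .data$super_pop, wt = .data$n, name = "n")
}

#' Reconstruct integer allele counts from published frequencies
#'
#' Published allele-frequency tables report EAFs to limited precision. Given
#' stratum sample sizes, the underlying integer counts can be recovered as
#' `k = round(EAF * 2n)` with denominator `m = 2n` (alleles). The result feeds
#' [enrichment_test_counts()], so published per-stratum frequency tables can
#' be pushed through the same testing machinery as genotype-level data.
#'
#' @param eaf A long tibble with columns `rsid`, `stratum`, `freq`.
#' @param sizes A tibble with columns `stratum`, `n` (individuals per
#'   stratum).
#' @return A count table: tibble with columns `rsid`, `stratum`, `k`, `m`.
#' @examples
#' eaf <- tibble::tibble(
#'   rsid = "rs671", stratum = c("EAS", "EUR"), freq = c(0.83, 1.00)
#' )
#' sizes <- tibble::tibble(stratum = c("EAS", "EUR"), n = c(504, 503))
#' reconstruct_allele_counts(eaf, sizes)
#' @export
reconstruct_allele_counts <- function(eaf, sizes) {
  stopifnot(all(c("rsid", "stratum", "freq") %in% names(eaf)))
  stopifnot(all(c("stratum", "n") %in% names(sizes)))
  if (any(eaf$freq < 0 | eaf$freq > 1, na.rm = TRUE)) {
    abort("Frequencies must lie in [0, 1].")
  }
  missing_strata <- setdiff(unique(eaf$stratum), sizes$stratum)
  if (length(missing_strata) > 0) {
    abort(paste0(
      "No sample size given for stratum: ",
      paste(missing_strata, collapse = ", ")
    ))
  }
  eaf |>
    dplyr::inner_join(sizes, by = "stratum") |>
    dplyr::mutate(
      m = 2L * as.integer(.data$n),
      k = as.integer(round(.data$freq * .data$m))
    ) |>
    dplyr::select("rsid", "stratum", "k", "m")
}
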