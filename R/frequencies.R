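#' Count effect alleles per SNP and stratum
#'
#' Exact integer allele counts: `k` effect alleles out of `m` observed
#' alleles, where `m = 2 x` (samples with a non-missing call on that
#' haplotype) — missing calls are excluded from both numerator and
#' denominator. Continental-group and global rows are obtained by pooling
#' population-level counts (summing both `k` and `m`), never by averaging
#' frequencies, so pooled frequencies are sample-size weighted.
#'
#' @param dataset A [genotype_dataset()].
#' @param by Stratification: `"population"`, `"group"` or `"global"`.
#' @return A count table: tibble `rsid`, `stratum`, `k`, `m`.
#' @export
count_effect_alleles <- function(dataset,
                                 by = c("population", "group", "global")) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  by <- match.arg(by)
  key <- switch(by,
    population = dataset$manifest$pop,
    group = dataset$manifest$super_pop,
    global = rep("global", nrow(dataset$manifest))
  )
  strata <- unique(key)
  out <- lapply(strata, function(s) {
    rows <- which(key == s)
    if (length(rows) == 0) abort(paste0("Empty stratum: ", s))
    h1 <- dataset$hap1[rows, , drop = FALSE]
    h2 <- dataset$hap2[rows, , drop = FALSE]
    tibble::tibble(
      rsid = colnames(h1),
      stratum = s,
      k = as.integer(colSums(h1, na.rm = TRUE) + colSums(h2, na.rm = TRUE)),
      m = as.integer(colSums(!is.na(h1)) + colSums(!is.na(h2)))
    )
  })
  dplyr::bind_rows(out)
}

#' Effect-allele frequencies from a count table
#'
#' Adds `freq = k / m` to a count table; cells with `m = 0` are reported as
#' `NA` (undefined), never as 0. The exact integer counts are kept alongside
#' the decimal so downstream consumers need not re-derive them from rounded
#' frequencies.
#'
#' @param counts A count table from [count_effect_alleles()] (columns
#'   `rsid`, `stratum`, `k`, `m`).
#' @return The count table with a `freq` column.
#' @examples
#' allele_frequencies(tibble::tibble(
#'   rsid = "rs1", stratum = "ACB", k = 3L, m = 8L
#' ))$freq # 0.375
#' @export
allele_frequencies <- function(counts) {
  stopifnot(all(c("rsid", "stratum", "k", "m") %in% names(counts)))
  if (any(counts$k < 0 | counts$k > counts$m)) {
    abort("Counts must satisfy 0 <= k <= m.")
  }
  dplyr::mutate(
    counts,
    freq = ifelse(.data$m > 0, .data$k / .data$m, NA_real_)
  )
}

#' Frequency table in wide (SNP x stratum) layout
#'
#' @param counts A count table ([count_effect_alleles()]).
#' @return A tibble with one row per rsid and one frequency column per
#'   stratum.
#' @export
frequency_table <- function(counts) {
  allele_frequencies(counts) |>
    dplyr::select("rsid", "stratum", "freq") |>
    tidyr::pivot_wider(names_from = "stratum", values_from = "freq")
}
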