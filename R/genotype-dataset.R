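#' Construct a phased genotype dataset
#'
#' The central container of the pipeline: two haplotype matrices (samples in
#' rows, SNPs in columns) holding effect-allele indicators, linked to the
#' sample manifest and the forward-strand-oriented SNP annotations. Cell
#' values are `1L` (effect allele), `0L` (other allele) or `NA` (missing
#' call).
#'
#' @param hap1,hap2 Integer matrices of identical dimension, with sample ids
#'   as row names and rsids as column names; entries in \{0, 1, NA\}.
#' @param manifest Sample manifest tibble with columns `sample`, `pop`,
#'   `super_pop` (one row per sample, matching the matrix rows).
#' @param annotations Oriented SNP annotation tibble with at least `rsid`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`; one row per matrix
#'   column.
#' @param skipped Character vector of annotated rsids that could not be
#'   matched in the genotype source (recorded, not dropped silently).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(hap1, hap2, manifest, annotations,
                             skipped = character()) {
  stopifnot(is.matrix(hap1), is.matrix(hap2))
  if (!identical(dim(hap1), dim(hap2))) {
    abort("hap1 and hap2 must have identical dimensions.")
  }
  if (!identical(rownames(hap1), manifest$sample)) {
    abort("Row names of the haplotype matrices must equal manifest$sample.")
  }
  if (!identical(colnames(hap1), annotations$rsid)) {
    abort("Column names of the haplotype matrices must equal annotations$rsid.")
  }
  bad <- c(hap1, hap2)
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0 && !all(bad %in% c(0L, 1L))) {
    abort("Haplotype calls must be 0, 1 or NA.")
  }
  structure(
    list(
      hap1 = hap1, hap2 = hap2,
      manifest = tibble::as_tibble(manifest),
      annotations = tibble::as_tibble(annotations),
      skipped = skipped
    ),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(
    "<genotype_dataset> ", nrow(x$hap1), " samples x ", ncol(x$hap1),
    " SNPs (phased)\n",
    sep = ""
  )
  cat(
    "  populations: ", length(unique(x$manifest$pop)),
    " in ", length(unique(x$manifest$super_pop)), " continental groups\n",
    sep = ""
  )
  miss <- mean(is.na(x$hap1) | is.na(x$hap2))
  cat("  missing genotype fraction: ", signif(miss, 3), "\n", sep = "")
  if (length(x$skipped) > 0) {
    cat("  skipped annotated SNPs: ", length(x$skipped), "\n", sep = "")
  }
  invisible(x)
}

#' Effect-allele dosage matrix
#'
#' Per-sample, per-SNP count of effect alleles (0, 1 or 2). A genotype with a
#' missing call on either haplotype is treated as missing (`NA`), so the
#' composite score denominator stays well defined.
#'
#' @param dataset A [genotype_dataset()].
#' @param snps Optional character vector of rsids to restrict to.
#' @return Integer matrix, samples x SNPs.
#' @export
effect_allele_dosage <- function(dataset, snps = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  h1 <- dataset$hap1
  h2 <- dataset$hap2
  if (!is.null(snps)) {
    missing <- setdiff(snps, colnames(h1))
    if (length(missing) > 0) {
      abort(paste0(
        "SNP(s) not present in dataset: ",
        paste(head(missing, 5), collapse = ", ")
      ))
    }
    h1 <- h1[, snps, drop = FALSE]
    h2 <- h2[, snps, drop = FALSE]
  }
  x <- h1 + h2
  x[is.na(h1) | is.na(h2)] <- NA_integer_
  x
}

#' Tidy a genotype dataset into a long tibble
#'
#' @param x A [genotype_dataset()].
#' @param ... Unused.
#' @return A tibble with one row per sample x SNP: `sample`, `pop`,
#'   `super_pop`, `rsid`, `dosage`.
#' @export
tidy.genotype_dataset <- function(x, ...) {
  dos <- effect_allele_dosage(x)
  tibble::tibble(
    sample = rep(rownames(dos), times = ncol(dos)),
    rsid = rep(colnames(dos), each = nrow(dos)),
    dosage = as.integer(dos)
  ) |>
    dplyr::left_join(x$manifest, by = "sample") |>
    dplyr::select("sample", "pop", "super_pop", "rsid", "dosage")
}

#' Subset a genotype dataset by samples and/or SNPs
#'
#' @param dataset A [genotype_dataset()].
#' @param samples,snps Optional character vectors of sample ids / rsids.
#' @return A [genotype_dataset()] restricted to the requested entries.
#' @export
subset_dataset <- function(dataset, samples = NULL, snps = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(samples)) samples <- rownames(dataset$hap1)
  if (is.null(snps)) snps <- colnames(dataset$hap1)
  missing_s <- setdiff(samples, rownames(dataset$hap1))
  if (length(missing_s) > 0) {
    abort(paste0("Unknown sample(s): ", paste(head(missing_s, 5), collapse = ", ")))
  }
  missing_v <- setdiff(snps, colnames(dataset$hap1))
  if (length(missing_v) > 0) {
    abort(paste0("Unknown SNP(s): ", paste(head(missing_v, 5), collapse = ", ")))
  }
  genotype_dataset(
    dataset$hap1[samples, snps, drop = FALSE],
    dataset$hap2[samples, snps, drop = FALSE],
    dataset$manifest[match(samples, dataset$manifest$sample), ],
    dataset$annotations[match(snps, dataset$annotations$rsid), ],
    skipped = dataset$skipped
  )
}
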