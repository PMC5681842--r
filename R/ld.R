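#' Pairwise linkage disequilibrium r-squared from phased haplotypes
#'
#' With haplotype frequency `p_AB` and allele frequencies `p_A`, `p_B`
#' computed over haplotypes non-missing at both SNPs,
#' `r^2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))`. A SNP that is
#' monomorphic in the stratum has undefined LD, reported as `NA` (never 0).
#' The statistic is invariant to allele relabelling at either SNP.
#'
#' @param h_i,h_j Binary haplotype vectors (0/1/NA) of equal length, one
#'   entry per haplotype.
#' @return r-squared in \[0, 1\], or `NA` if undefined.
#' @examples
#' # haplotype counts AB=4, Ab=1, aB=1, ab=4: D = 0.15, r^2 = 0.36
#' hi <- rep(c(1, 1, 0, 0), c(4, 1, 1, 4))
#' hj <- rep(c(1, 0, 1, 0), c(4, 1, 1, 4))
#' pairwise_r2(hi, hj)
#' @export
pairwise_r2 <- function(h_i, h_j) {
  stopifnot(length(h_i) == length(h_j))
  keep <- !is.na(h_i) & !is.na(h_j)
  a <- h_i[keep]
  b <- h_j[keep]
  if (length(a) == 0) {
    return(NA_real_)
  }
  # integer-count form of (p_AB - p_A p_B)^2 / (p_A q_A p_B q_B): exact,
  # so perfect LD gives exactly 1 and monomorphic SNPs are caught cleanly
  n <- as.numeric(length(a))
  na_ <- as.numeric(sum(a))
  nb_ <- as.numeric(sum(b))
  if (na_ == 0 || na_ == n || nb_ == 0 || nb_ == n) {
    return(NA_real_)
  }
  nab <- sum(a * b)
  (n * nab - na_ * nb_)^2 / (na_ * (n - na_) * nb_ * (n - nb_))
}

#' Pairwise LD matrix within a stratum
#'
#' Computes r-squared for every SNP pair from the phased haplotypes of the
#' requested stratum. For continental groups, haplotypes of the member
#' populations are pooled. Haplotypes missing at either SNP of a pair are
#' dropped pairwise.
#'
#' @param dataset A [genotype_dataset()].
#' @param snps Character vector of rsids (>= 2).
#' @param stratum Population or group code to restrict to; `NULL` uses all
#'   samples.
#' @param by Whether `stratum` names a `"population"` or a `"group"`.
#' @return A symmetric matrix of r-squared values (class `ld_matrix`);
#'   diagonal is 1 for polymorphic SNPs, `NA` cells mark undefined LD.
#' @export
ld_matrix <- function(dataset, snps, stratum = NULL,
                      by = c("population", "group")) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  by <- match.arg(by)
  if (length(snps) < 2) abort("Need at least 2 SNPs.")
  missing <- setdiff(snps, colnames(dataset$hap1))
  if (length(missing) > 0) {
    abort(paste0("Unknown SNP(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  if (is.null(stratum)) {
    rows <- seq_len(nrow(dataset$manifest))
  } else {
    key <- if (by == "population") dataset$manifest$pop else dataset$manifest$super_pop
    rows <- which(key == stratum)
    if (length(rows) == 0) abort(paste0("Empty stratum: ", stratum))
  }
  # stack the two phased haplotypes of every sample
  h <- rbind(
    dataset$hap1[rows, snps, drop = FALSE],
    dataset$hap2[rows, snps, drop = FALSE]
  )
  p <- length(snps)
  m <- matrix(NA_real_, p, p, dimnames = list(snps, snps))
  for (i in seq_len(p)) {
    for (j in i:p) {
      m[i, j] <- m[j, i] <- pairwise_r2(h[, i], h[, j])
    }
  }
  class(m) <- c("ld_matrix", class(m))
  m
}

#' LD matrices for several strata at once
#'
#' @param dataset A [genotype_dataset()].
#' @param snps Character vector of rsids.
#' @param strata Character vector of stratum codes; defaults to all
#'   continental groups in the dataset.
#' @param by `"population"` or `"group"`.
#' @return A named list of [ld_matrix()] results, one per stratum.
#' @export
ld_by_stratum <- function(dataset, snps, strata = NULL,
                          by = c("group", "population")) {
  by <- match.arg(by)
  if (is.null(strata)) {
    strata <- unique(
      if (by == "group") dataset$manifest$super_pop else dataset$manifest$pop
    )
  }
  setNames(
    lapply(strata, function(s) ld_matrix(dataset, snps, s, by = by)),
    strata
  )
}

#' Tidy an LD matrix into a long tibble
#'
#' @param x An [ld_matrix()].
#' @param ... Unused.
#' @return A tibble `snp_a`, `snp_b`, `r2` (upper triangle, no diagonal).
#' @export
tidy.ld_matrix <- function(x, ...) {
  m <- unclass(x)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    snp_a = rownames(m)[ut[, 1]],
    snp_b = colnames(m)[ut[, 2]],
    r2 = m[ut]
  )
}
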