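# Shared fixture builders and independent oracles.

# Four small populations in two continental groups.
toy_populations <- function(n = 40) {
  tibble::tibble(
    pop = c("P1", "P2", "P3", "P4"),
    super_pop = c("G1", "G1", "G2", "G2"),
    n = rep(n, 4)
  )
}

toy_config <- function(seed = 11, n_snps = 30, n = 40, ...) {
  defaults <- list(
    populations = toy_populations(n),
    n_snps = n_snps,
    n_significant = min(20, n_snps),
    n_effect_sizes = 5,
    ld_blocks = list(c(6, 0.95)),
    seed = seed
  )
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(sim_config, defaults)
}

# Hand-build a dataset from dosage rows: one row per sample, values 0/1/2/NA.
# Dosage 1 is phased as (1|0).
dataset_from_dosage <- function(dosage, pops, super_pops = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  p <- ncol(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("rs%03d", seq_len(p))
  }
  if (is.null(super_pops)) super_pops <- rep("G1", n)
  samples <- sprintf("S%03d", seq_len(n))
  h1 <- matrix(NA_integer_, n, p, dimnames = list(samples, colnames(dosage)))
  h2 <- h1
  h1[!is.na(dosage)] <- as.integer(dosage[!is.na(dosage)] >= 1)
  h2[!is.na(dosage)] <- as.integer(dosage[!is.na(dosage)] == 2)
  ann <- tibble::tibble(
    rsid = colnames(dosage),
    chrom = "1",
    pos = seq_len(p) * 1000L,
    effect_allele = "A",
    other_allele = "G",
    reported_strand = "forward",
    gwas_pvalue = 1e-9,
    effect_size = NA_real_
  )
  manifest <- tibble::tibble(
    sample = samples, pop = pops, super_pop = super_pops
  )
  genotype_dataset(h1, h2, manifest, ann)
}

# Independent hypergeometric tail oracle: explicit choose() ratios.
brute_tail_p <- function(k, n, K, N, direction) {
  xs <- max(0, n - (N - K)):min(n, K)
  mass <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  if (direction == "enrichment") sum(mass[xs >= k]) else sum(mass[xs <= k])
}

# Independent r^2 oracle from the 2x2 haplotype contingency table.
brute_r2 <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  tab <- table(factor(a, 0:1), factor(b, 0:1))
  n <- sum(tab)
  pA <- sum(tab[2, ]) / n
  pB <- sum(tab[, 2]) / n
  pAB <- tab[2, 2] / n
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}
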