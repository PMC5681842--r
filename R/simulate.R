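#' Configure a synthetic cohort simulation
#'
#' Defines the study conditions for a fully synthetic genotype cohort:
#' population layout, Balding-Nichols differentiation, LD-block structure,
#' and the annotation model (GWAS p-values straddling the genome-wide
#' significance threshold, per-allele effect sizes, strand-of-report flags).
#'
#' Population structure follows a two-level Balding-Nichols model: each SNP
#' has an ancestral frequency `p` drawn uniformly from
#' `ancestral_freq_range`; each continental group draws its frequency from
#' `Beta(p(1-Fb)/Fb, (1-p)(1-Fb)/Fb)` with `Fb = fst_between`; each
#' population then draws around its group frequency with `Fw = fst_within`.
#' The Beta parameterisation has mean `p` and variance `F p (1-p)`, so `F`
#' acts as an F_ST-like differentiation parameter. With
#' `fst_between = NULL` the model collapses to the classical single-level
#' Balding-Nichols draw with `fst_within` around the ancestral frequency.
#' The defaults (`fst_between` 0.08, `fst_within` 0.02) reflect the classic
#' apportionment of human diversity: most allele-frequency differentiation
#' lies between continental groups, a smaller part between populations
#' within a group.
#'
#' Within an LD block a haplotype copies its allele state from the previous
#' SNP with the block's copying probability, otherwise it draws fresh from
#' the population frequency; SNPs outside blocks are drawn independently.
#' Blocks occupy consecutive SNPs starting at the first SNP.
#'
#' @param populations Tibble with columns `pop`, `super_pop`, `n` (samples
#'   per population). Default: the 26-population reference cohort layout.
#' @param n_snps Number of simulated SNPs.
#' @param fst_within Population-level differentiation in (0, 1); scalar or
#'   one value per population (named or in `populations` order).
#' @param fst_between Group-level differentiation in (0, 1), or `NULL` for a
#'   single-level model.
#' @param ancestral_freq_range Interval within (0, 1) for ancestral
#'   effect-allele frequencies.
#' @param ld_blocks List of `c(length, copy_prob)` pairs; lengths in SNPs
#'   (>= 1), copying probabilities in \[0, 1\]. Default: one 15-SNP block
#'   with copying probability 0.9, mirroring an FTO-like intronic cluster.
#' @param n_significant Number of SNPs whose simulated GWAS p-value falls
#'   below 5e-8 (the genome-wide significance threshold); the remainder fall
#'   in (5e-8, 9e-6), the catalog search window. Default 155 of 225, the
#'   published split.
#' @param n_effect_sizes Number of genome-wide-significant SNPs assigned a
#'   per-allele effect size (kg/m^2); mirrors the 32 independent BMI SNPs
#'   with published effect sizes.
#' @param effect_size_range Uniform range for simulated effect sizes, kg/m^2
#'   per allele (published BMI effects span roughly 0.06-0.39).
#' @param reverse_strand_fraction Fraction of annotation rows whose alleles
#'   are reported on the reverse strand, to exercise orientation.
#' @param missing_rate Per-haplotype missing-call probability.
#' @param seed Integer seed; fixes every simulated output bit-for-bit.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_snps = 20, seed = 1)
#' cfg$n_snps
#' @export
sim_config <- function(populations = reference_populations(),
                       n_snps = 225,
                       fst_within = 0.02,
                       fst_between = 0.08,
                       ancestral_freq_range = c(0.05, 0.95),
                       ld_blocks = list(c(15, 0.9)),
                       n_significant = 155,
                       n_effect_sizes = 32,
                       effect_size_range = c(0.05, 0.40),
                       reverse_strand_fraction = 0.1,
                       missing_rate = 0,
                       seed = 1L) {
  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("pop", "super_pop", "n") %in% names(populations)))
  if (anyDuplicated(populations$pop) > 0) {
    abort("Duplicated population codes in `populations`.")
  }
  if (any(populations$n < 1)) abort("Each population needs >= 1 sample.")
  if (n_snps < 1) abort("`n_snps` must be >= 1.")
  n_pop <- nrow(populations)
  fw <- rep_len(fst_within, n_pop)
  if (!is.null(names(fst_within))) {
    missing <- setdiff(populations$pop, names(fst_within))
    if (length(missing) > 0) {
      abort("Named `fst_within` must cover every population.")
    }
    fw <- unname(fst_within[populations$pop])
  }
  if (any(fw <= 0 | fw >= 1)) {
    abort("`fst_within` must lie strictly in (0, 1): F = 0 or 1 degenerates the Beta draw.")
  }
  if (!is.null(fst_between) && (fst_between <= 0 || fst_between >= 1)) {
    abort("`fst_between` must lie strictly in (0, 1) (or be NULL).")
  }
  stopifnot(
    length(ancestral_freq_range) == 2,
    ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
    ancestral_freq_range[1] <= ancestral_freq_range[2]
  )
  for (b in ld_blocks) {
    if (length(b) != 2 || b[1] < 1 || b[2] < 0 || b[2] > 1) {
      abort("Each LD block must be c(length >= 1, copy_prob in [0, 1]).")
    }
  }
  if (sum(vapply(ld_blocks, function(b) b[1], 0)) > n_snps) {
    abort("LD blocks cover more SNPs than `n_snps`.")
  }
  if (n_significant < 0 || n_significant > n_snps) {
    abort("`n_significant` must lie in [0, n_snps].")
  }
  if (n_effect_sizes > n_significant) {
    abort("`n_effect_sizes` cannot exceed `n_significant`.")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` in [0, 1).")
  if (reverse_strand_fraction < 0 || reverse_strand_fraction > 1) {
    abort("`reverse_strand_fraction` in [0, 1].")
  }
  structure(
    list(
      populations = populations,
      n_snps = as.integer(n_snps),
      fst_within = fw,
      fst_between = fst_between,
      ancestral_freq_range = ancestral_freq_range,
      ld_blocks = ld_blocks,
      n_significant = as.integer(n_significant),
      n_effect_sizes = as.integer(n_effect_sizes),
      effect_size_range = effect_size_range,
      reverse_strand_fraction = reverse_strand_fraction,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# per-SNP block id (NA outside blocks) and copying probability
block_layout <- function(config) {
  block_id <- rep(NA_integer_, config$n_snps)
  copy_prob <- rep(0, config$n_snps)
  at <- 1L
  for (i in seq_along(config$ld_blocks)) {
    len <- as.integer(config$ld_blocks[[i]][1])
    idx <- seq(at, length.out = len)
    block_id[idx] <- i
    copy_prob[idx] <- config$ld_blocks[[i]][2]
    at <- at + len
  }
  tibble::tibble(
    snp_index = seq_len(config$n_snps),
    block_id = block_id,
    copy_prob = copy_prob
  )
}

#' Draw true population allele frequencies (Balding-Nichols)
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per SNP x population: `rsid`, `pop`,
#'   `super_pop`, `ancestral`, `group_freq`, `freq`. Deterministic under
#'   `config$seed`.
#' @examples
#' truth <- simulate_population_frequencies(sim_config(n_snps = 5, seed = 7))
#' head(truth)
#' @export
simulate_population_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    n_snps <- config$n_snps
    rsid <- sprintf("snp%04d", seq_len(n_snps))
    p <- runif(n_snps, config$ancestral_freq_range[1], config$ancestral_freq_range[2])
    groups <- unique(config$populations$super_pop)
    # group-level frequencies (identity copy when single-level)
    gf <- matrix(rep(p, times = length(groups)),
      nrow = n_snps,
      dimnames = list(rsid, groups)
    )
    if (!is.null(config$fst_between)) {
      fb <- config$fst_between
      for (g in groups) {
        gf[, g] <- rbeta(n_snps, p * (1 - fb) / fb, (1 - p) * (1 - fb) / fb)
      }
    }
    pops <- config$populations
    out <- vector("list", nrow(pops))
    for (i in seq_len(nrow(pops))) {
      fw <- config$fst_within[i]
      base <- gf[, pops$super_pop[i]]
      freq <- rbeta(n_snps, base * (1 - fw) / fw, (1 - base) * (1 - fw) / fw)
      out[[i]] <- tibble::tibble(
        rsid = rsid,
        pop = pops$pop[i],
        super_pop = pops$super_pop[i],
        ancestral = p,
        group_freq = base,
        freq = freq
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Shift a target population's true frequencies at chosen SNPs
#'
#' Plants a known enrichment (or depletion, with negative `shift`) signal:
#' the target population's true frequencies are shifted by `shift` at the
#' target SNPs and clipped to \[0.01, 0.99\]. With `shift = 0` the table is
#' returned unchanged.
#'
#' @param truth A true-frequency table from
#'   [simulate_population_frequencies()].
#' @param target_population Population code present in `truth`.
#' @param target_snps Character vector of rsids present in `truth`.
#' @param shift Additive frequency shift.
#' @return The modified true-frequency table.
#' @export
plant_enrichment <- function(truth, target_population, target_snps, shift) {
  if (!target_population %in% truth$pop) {
    abort(paste0("Unknown population: ", target_population))
  }
  missing <- setdiff(target_snps, unique(truth$rsid))
  if (length(missing) > 0) {
    abort(paste0("Unknown SNP(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  if (shift == 0) {
    return(truth)
  }
  hit <- truth$pop == target_population & truth$rsid %in% target_snps
  truth$freq[hit] <- pmin(pmax(truth$freq[hit] + shift, 0.01), 0.99)
  truth
}

#' Simulate the SNP annotation table
#'
#' Generates rsids, GRCh37-style coordinates (LD-block SNPs sit consecutively
#' a few kb apart on one chromosome; the rest are spread across chromosomes
#' megabases apart), forward-strand effect/other alleles, strand-of-report
#' flags (reported alleles are complemented for rows flagged reverse, as a
#' GWAS catalog would report them), GWAS p-values straddling 5e-8, and
#' per-allele effect sizes for a subset of significant SNPs.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `reported_strand`, `gwas_pvalue`, `effect_size` (NA
#'   where unassigned). Alleles are as *reported*; pass through
#'   [orient_effect_allele()] to recover forward-strand alleles.
#' @export
simulate_snp_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed + 1L, {
    n <- config$n_snps
    layout <- block_layout(config)
    rsid <- sprintf("snp%04d", seq_len(n))
    chrom <- integer(n)
    pos <- integer(n)
    in_block <- !is.na(layout$block_id)
    # block SNPs: consecutive on chromosome 16, ~3 kb spacing
    if (any(in_block)) {
      chrom[in_block] <- 16L
      pos[in_block] <- 53800000L + cumsum(sample(2000:4000, sum(in_block), TRUE))
    }
    # independent SNPs: round-robin over autosomes 1..15, ~2-3 Mb apart
    free <- which(!in_block)
    if (length(free) > 0) {
      chrom[free] <- rep_len(1:15, length(free))
      for (cc in unique(chrom[free])) {
        idx <- free[chrom[free] == cc]
        pos[idx] <- 1000000L + cumsum(sample(2000000:3000000, length(idx), TRUE))
      }
    }
    bases <- c("A", "C", "G", "T")
    effect_fwd <- sample(bases, n, replace = TRUE)
    other_fwd <- vapply(
      effect_fwd,
      function(b) sample(setdiff(bases, b), 1),
      ""
    )
    strand <- ifelse(
      runif(n) < config$reverse_strand_fraction, "reverse", "forward"
    )
    effect_rep <- ifelse(strand == "reverse", COMPLEMENT[effect_fwd], effect_fwd)
    other_rep <- ifelse(strand == "reverse", COMPLEMENT[other_fwd], other_fwd)
    sig <- sample(n, config$n_significant)
    gwas_p <- numeric(n)
    # log-uniform below and above the genome-wide threshold
    gwas_p[sig] <- 10^runif(length(sig), -30, log10(5e-8) - 0.01)
    gwas_p[-sig] <- 10^runif(n - length(sig), log10(5e-8) + 0.001, log10(9e-6))
    if (config$n_significant == n) gwas_p <- 10^runif(n, -30, log10(5e-8) - 0.01)
    effect_size <- rep(NA_real_, n)
    if (config$n_effect_sizes > 0) {
      carriers <- sample(sig, config$n_effect_sizes)
      effect_size[carriers] <- runif(
        config$n_effect_sizes,
        config$effect_size_range[1], config$effect_size_range[2]
      )
    }
    tibble::tibble(
      rsid = rsid,
      chrom = as.character(chrom),
      pos = as.integer(pos),
      effect_allele = unname(effect_rep),
      other_allele = unname(other_rep),
      reported_strand = strand,
      gwas_pvalue = gwas_p,
      effect_size = effect_size
    )
  })
}

#' Simulate phased genotypes from true frequencies
#'
#' Draws two haplotypes per sample. Within an LD block each haplotype copies
#' its previous-SNP allele state with the block's copying probability and
#' otherwise draws fresh from the population frequency, which produces
#' monotone, tunable r-squared decay inside blocks; outside blocks draws are
#' independent Bernoulli(freq).
#'
#' @param truth True-frequency table from
#'   [simulate_population_frequencies()] (possibly after
#'   [plant_enrichment()]).
#' @param config The [sim_config()] that produced `truth`.
#' @param annotations Optional annotation table (as reported) from
#'   [simulate_snp_annotations()]; simulated fresh from `config` when NULL.
#' @return A [genotype_dataset()] whose annotations are oriented to the
#'   forward strand; the true-frequency table is attached as attribute
#'   `"truth"`.
#' @export
simulate_genotypes <- function(truth, config, annotations = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rsids <- unique(truth$rsid)
  if (length(rsids) != config$n_snps) {
    abort("`truth` does not cover the configured SNPs.")
  }
  missing_pop <- setdiff(config$populations$pop, unique(truth$pop))
  if (length(missing_pop) > 0) {
    abort("`truth` does not cover every configured population.")
  }
  if (is.null(annotations)) annotations <- simulate_snp_annotations(config)
  oriented <- orient_effect_allele(annotations, quiet = TRUE)
  layout <- block_layout(config)
  freq_wide <- truth |>
    dplyr::select("rsid", "pop", "freq") |>
    tidyr::pivot_wider(names_from = "pop", values_from = "freq")
  freq_mat <- as.matrix(freq_wide[match(rsids, freq_wide$rsid), -1])
  rownames(freq_mat) <- rsids

  local_seed(config$seed + 2L, {
    pops <- config$populations
    hap_list <- vector("list", nrow(pops))
    sample_ids <- character(0)
    for (i in seq_len(nrow(pops))) {
      n <- pops$n[i]
      nh <- 2L * n
      f <- freq_mat[, pops$pop[i]]
      h <- matrix(0L, nrow = nh, ncol = config$n_snps)
      for (j in seq_len(config$n_snps)) {
        fresh <- rbinom(nh, 1L, f[j])
        if (j > 1 &&
          !is.na(layout$block_id[j]) &&
          identical(layout$block_id[j], layout$block_id[j - 1])) {
          copy <- rbinom(nh, 1L, layout$copy_prob[j]) == 1L
          h[, j] <- ifelse(copy, h[, j - 1], fresh)
        } else {
          h[, j] <- fresh
        }
      }
      hap_list[[i]] <- h
      sample_ids <- c(sample_ids, sprintf("%s_%04d", pops$pop[i], seq_len(n)))
    }
    n_per_pop <- pops$n
    hap1 <- do.call(rbind, lapply(seq_along(hap_list), function(i) {
      hap_list[[i]][seq_len(n_per_pop[i]), , drop = FALSE]
    }))
    hap2 <- do.call(rbind, lapply(seq_along(hap_list), function(i) {
      hap_list[[i]][n_per_pop[i] + seq_len(n_per_pop[i]), , drop = FALSE]
    }))
    if (config$missing_rate > 0) {
      hap1[runif(length(hap1)) < config$missing_rate] <- NA_integer_
      hap2[runif(length(hap2)) < config$missing_rate] <- NA_integer_
    }
    dimnames(hap1) <- dimnames(hap2) <- list(sample_ids, rsids)
    manifest <- tibble::tibble(
      sample = sample_ids,
      pop = rep(pops$pop, times = n_per_pop),
      super_pop = rep(pops$super_pop, times = n_per_pop)
    )
    ds <- genotype_dataset(hap1, hap2, manifest, oriented)
    attr(ds, "truth") <- truth
    ds
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: draws true frequencies, annotations and phased
#' genotypes from one configuration.
#'
#' @param config A [sim_config()].
#' @return A [genotype_dataset()] with the true-frequency table attached as
#'   attribute `"truth"`.
#' @examples
#' ds <- simulate_cohort(sim_config(n_snps = 10, seed = 3,
#'   populations = tibble::tibble(
#'     pop = c("P1", "P2"), super_pop = c("G1", "G1"), n = c(30, 30)
#'   )))
#' ds
#' @export
simulate_cohort <- function(config) {
  truth <- simulate_population_frequencies(config)
  ann <- simulate_snp_annotations(config)
  simulate_genotypes(truth, config, annotations = ann)
}
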