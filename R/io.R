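#' Read a sample panel file
#'
#' Parses a tab-separated panel (one row per sample; columns `sample`,
#' `pop`, `super_pop`, extra columns ignored), validates it, and returns the
#' sample manifest ordered by population code then sample id.
#'
#' @param path Path to the panel TSV.
#' @return A tibble `sample`, `pop`, `super_pop`.
#' @export
read_panel <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0) abort("Panel file is empty.")
  needed <- c("sample", "pop", "super_pop")
  if (!all(needed %in% names(tbl))) {
    abort("Panel must have columns sample, pop, super_pop.")
  }
  validate_manifest(tbl[needed])
}

validate_manifest <- function(manifest) {
  dup <- manifest$sample[duplicated(manifest$sample)]
  if (length(dup) > 0) {
    abort(paste0(
      "Sample(s) listed more than once: ",
      paste(unique(head(dup, 5)), collapse = ", ")
    ))
  }
  split_groups <- manifest |>
    dplyr::distinct(.data$pop, .data$super_pop) |>
    dplyr::count(.data$pop) |>
    dplyr::filter(.data$n > 1)
  if (nrow(split_groups) > 0) {
    abort(paste0(
      "Population(s) mapped to more than one continental group: ",
      paste(split_groups$pop, collapse = ", ")
    ))
  }
  dplyr::arrange(manifest, .data$pop, .data$sample)
}

#' Per-population (or per-group) sample counts of a manifest
#'
#' @param manifest A manifest tibble (`sample`, `pop`, `super_pop`).
#' @param by `"population"` or `"group"`.
#' @return A tibble `stratum`, `n`.
#' @export
manifest_sizes <- function(manifest, by = c("population", "group")) {
  by <- match.arg(by)
  key <- if (by == "population") "pop" else "super_pop"
  manifest |>
    dplyr::count(stratum = .data[[key]], name = "n")
}

#' Orient annotation alleles to the forward strand
#'
#' GWAS catalogs report some effect alleles on the reverse strand while
#' reference genotype panels report all alleles on the forward strand.
#' Rows flagged `reported_strand == "reverse"` have both alleles replaced by
#' their complements (A<->T, C<->G) and the flag set to `"forward"`; other
#' rows pass through unchanged. Strand-ambiguous SNPs (allele pair A/T or
#' C/G, its own reverse complement) cannot have their strand verified from
#' alleles alone; they are processed but flagged in the `strand_ambiguous`
#' column and a warning.
#'
#' @param annotations Tibble with at least `rsid`, `effect_allele`,
#'   `other_allele`, `reported_strand`.
#' @param quiet Suppress the strand-ambiguity warning.
#' @return The annotation tibble with oriented alleles,
#'   `reported_strand = "forward"` throughout, and a logical
#'   `strand_ambiguous` column.
#' @examples
#' ann <- tibble::tibble(
#'   rsid = "rs1", effect_allele = "A", other_allele = "C",
#'   reported_strand = "reverse"
#' )
#' orient_effect_allele(ann)$effect_allele # "T"
#' @export
orient_effect_allele <- function(annotations, quiet = FALSE) {
  needed <- c("rsid", "effect_allele", "other_allele", "reported_strand")
  stopifnot(all(needed %in% names(annotations)))
  ea <- toupper(annotations$effect_allele)
  oa <- toupper(annotations$other_allele)
  bad <- !(ea %in% names(COMPLEMENT)) | !(oa %in% names(COMPLEMENT))
  if (any(bad)) {
    abort(paste0(
      "Non-ACGT allele for: ",
      paste(head(annotations$rsid[bad], 5), collapse = ", ")
    ))
  }
  if (any(ea == oa)) {
    abort("Effect and other allele identical for some SNPs.")
  }
  rev <- annotations$reported_strand == "reverse"
  ea[rev] <- COMPLEMENT[toupper(annotations$effect_allele)[rev]]
  oa[rev] <- COMPLEMENT[toupper(annotations$other_allele)[rev]]
  ambiguous <- COMPLEMENT[ea] == oa # {A,T} or {C,G} pairs
  out <- annotations
  out$effect_allele <- unname(ea)
  out$other_allele <- unname(oa)
  out$reported_strand <- "forward"
  out$strand_ambiguous <- unname(ambiguous)
  if (!quiet && any(ambiguous)) {
    warn(paste0(
      sum(ambiguous), " strand-ambiguous (A/T or C/G) SNP(s) flagged: ",
      paste(head(out$rsid[ambiguous], 5), collapse = ", ")
    ))
  }
  out
}

#' Read an annotation TSV
#'
#' @param path Tab-separated file with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `reported_strand`, `gwas_pvalue` and
#'   optionally `effect_size`.
#' @return A tibble, alleles as reported (not yet oriented).
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(
    path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(chrom = readr::col_character())
  )
  needed <- c(
    "rsid", "chrom", "pos", "effect_allele", "other_allele",
    "reported_strand", "gwas_pvalue"
  )
  if (!all(needed %in% names(tbl))) {
    abort(paste0(
      "Annotation file must have columns: ", paste(needed, collapse = ", ")
    ))
  }
  bad_p <- !is.na(tbl$gwas_pvalue) & (tbl$gwas_pvalue <= 0 | tbl$gwas_pvalue > 1)
  if (any(bad_p)) abort("GWAS p-values must lie in (0, 1].")
  tbl
}

#' Read phased genotypes from a VCF
#'
#' Loads a VCF (plain or bgzipped; 1000 Genomes phase-3 dialect with phased
#' `GT` fields) and classifies each haplotype call at each annotated SNP as
#' effect allele, other allele, or missing. SNPs are matched by
#' (chromosome, position), and the annotation allele pair must equal the VCF
#' \{REF, ALT\} pair in either order — a disjoint pair signals a strand or
#' genome-build mismatch and is an error. Annotated SNPs absent from the VCF
#' go on the skip list; multi-allelic records at annotated sites are skipped
#' with a warning.
#'
#' @param vcf_path Path to the VCF.
#' @param manifest Sample manifest ([read_panel()]); every manifest sample
#'   must be genotyped in the VCF.
#' @param annotations Annotation tibble oriented to the forward strand
#'   ([orient_effect_allele()]).
#' @return A [genotype_dataset()]; skipped rsids are recorded in its
#'   `skipped` field.
#' @export
read_genotypes <- function(vcf_path, manifest, annotations) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Package 'vcfR' is required to read VCF files.")
  }
  if (!all(annotations$reported_strand == "forward")) {
    abort("Annotations must be oriented to the forward strand first.")
  }
  manifest <- validate_manifest(manifest)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf)
  key_vcf <- paste(fix$CHROM, fix$POS, sep = ":")
  key_ann <- paste(annotations$chrom, annotations$pos, sep = ":")
  hit <- match(key_ann, key_vcf)
  skipped <- annotations$rsid[is.na(hit)]

  multi <- !is.na(hit) & grepl(",", fix$ALT[hit])
  if (any(multi)) {
    warn(paste0(
      "Skipping multi-allelic record(s) at annotated site(s): ",
      paste(head(annotations$rsid[multi], 5), collapse = ", ")
    ))
    skipped <- c(skipped, annotations$rsid[multi])
    hit[multi] <- NA
  }
  keep <- !is.na(hit)
  ann <- annotations[keep, , drop = FALSE]
  rows <- hit[keep]

  ref <- toupper(fix$REF[rows])
  alt <- toupper(fix$ALT[rows])
  same <- ann$effect_allele == alt & ann$other_allele == ref
  swap <- ann$effect_allele == ref & ann$other_allele == alt
  disjoint <- !(same | swap)
  if (any(disjoint)) {
    abort(paste0(
      "Annotation alleles disjoint from VCF REF/ALT (strand or build ",
      "mismatch?) for: ",
      paste(head(ann$rsid[disjoint], 5), collapse = ", ")
    ))
  }

  missing_samples <- setdiff(manifest$sample, colnames(gt))
  if (length(missing_samples) > 0) {
    abort(paste0(
      "Manifest sample(s) absent from VCF: ",
      paste(head(missing_samples, 5), collapse = ", ")
    ))
  }
  gt <- gt[rows, manifest$sample, drop = FALSE]

  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  # allele index ("0" = REF, "1" = ALT) -> effect indicator per SNP
  effect_code <- ifelse(same, "1", "0") # which index is the effect allele
  code_mat <- matrix(effect_code, nrow = nrow(gt), ncol = ncol(gt))
  to_indicator <- function(a) {
    a[is.na(a)] <- "."
    out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
    out[a == code_mat] <- 1L
    out[a != code_mat & a %in% c("0", "1")] <- 0L
    out
  }
  hap1 <- t(to_indicator(a1))
  hap2 <- t(to_indicator(a2))
  dimnames(hap1) <- dimnames(hap2) <- list(manifest$sample, ann$rsid)

  if (length(skipped) > 0) {
    warn(paste0(
      length(skipped), " annotated SNP(s) not usable in the VCF ",
      "(see dataset$skipped)."
    ))
  }
  genotype_dataset(hap1, hap2, manifest, ann, skipped = skipped)
}

#' Write a synthetic cohort to disk as VCF + panel + annotation files
#'
#' Emits the three files the reading side consumes: a VCF 4.1 file with
#' phased `GT` genotypes and forward-strand alleles, a tab-separated panel
#' file (`sample`, `pop`, `super_pop`) and a tab-separated annotation table
#' (alleles as reported, with strand flags). Records are sorted by
#' (chromosome, position). To exercise the reader's REF/ALT matching, the
#' effect allele is written as ALT for even SNP indices and as REF for odd
#' ones — a deterministic rule, so identical inputs yield byte-identical
#' files.
#'
#' @param dataset A [genotype_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param annotations Annotation table *as reported* (i.e. before
#'   orientation) to write alongside; defaults to the dataset's oriented
#'   annotations (all-forward).
#' @param prefix File-name prefix.
#' @return Named character vector of the three file paths (`vcf`, `panel`,
#'   `annotations`).
#' @export
write_fixture <- function(dataset, out_dir, annotations = NULL,
                          prefix = "cohort") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (nrow(dataset$manifest) == 0) abort("Dataset has no samples.")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create directory: ", out_dir))
  }
  if (is.null(annotations)) annotations <- dataset$annotations
  paths <- c(
    vcf = file.path(out_dir, paste0(prefix, ".vcf")),
    panel = file.path(out_dir, paste0(prefix, ".panel.tsv")),
    annotations = file.path(out_dir, paste0(prefix, ".annotations.tsv"))
  )
  write_cohort_vcf(dataset, paths["vcf"])
  readr::write_tsv(dataset$manifest, paths["panel"], progress = FALSE)
  ann_cols <- intersect(
    c(
      "rsid", "chrom", "pos", "effect_allele", "other_allele",
      "reported_strand", "gwas_pvalue", "effect_size"
    ),
    names(annotations)
  )
  readr::write_tsv(annotations[ann_cols], paths["annotations"], progress = FALSE)
  paths
}

# Plain-text VCF 4.1 emission; forward-strand alleles, phased GT.
write_cohort_vcf <- function(dataset, path) {
  ann <- dataset$annotations
  ord <- order(suppressWarnings(as.integer(ann$chrom)), ann$chrom, ann$pos)
  ann <- ann[ord, , drop = FALSE]
  h1 <- dataset$hap1[, ann$rsid, drop = FALSE]
  h2 <- dataset$hap2[, ann$rsid, drop = FALSE]
  n_snp <- nrow(ann)
  # deterministic REF/ALT assignment: effect allele is ALT on even rows
  effect_is_alt <- seq_len(n_snp) %% 2L == 0L
  ref <- ifelse(effect_is_alt, ann$other_allele, ann$effect_allele)
  alt <- ifelse(effect_is_alt, ann$effect_allele, ann$other_allele)

  code <- function(h, j) {
    # map effect indicator to allele index given REF/ALT role of SNP j
    x <- h[, j]
    out <- rep(".", length(x))
    if (effect_is_alt[j]) {
      out[!is.na(x)] <- as.character(x[!is.na(x)])
    } else {
      out[!is.na(x)] <- as.character(1L - x[!is.na(x)])
    }
    out
  }
  gt_rows <- vapply(seq_len(n_snp), function(j) {
    paste(code(h1, j), code(h2, j), sep = "|", collapse = "\t")
  }, "")

  header <- c(
    "##fileformat=VCFv4.1",
    "##source=popdiffr_synthetic_cohort",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(
      c(
        "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", dataset$manifest$sample
      ),
      collapse = "\t"
    )
  )
  body <- paste(
    ann$chrom, ann$pos, ann$rsid, ref, alt, ".", "PASS", ".", "GT", gt_rows,
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
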