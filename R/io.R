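# Cohort readers and writers.
#
# On-disk layout: a clinical CSV (one row per participant: id, drug, outcome,
# clinical predictors), a dosage CSV (id + one column per SNP), and a sidecar
# metadata CSV typing every feature. Genotypes can alternatively be written
# and read as a minimal VCF (GT fields only, synthetic CHROM/POS).
# Continuous values are written with 17 significant digits so the round trip
# is bit-exact.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (!is.na(v) && v == round(v) && abs(v) < 1e15) {
      sprintf("%d", as.integer(v))
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
  out
}

#' Write a cohort to plain-text files
#'
#' Writes `clinical.csv` (participant id, drug, outcome, clinical columns),
#' `genotypes.csv` (dosage matrix) or `genotypes.vcf`, and `meta.csv`
#' (feature metadata sidecar: name, kind, type, maf, level_min, level_max).
#' The outcome column is named `remission` or `hrsd_total` according to the
#' cohort's outcome type, and that name is how [read_cohort_csv()] restores
#' the type.
#'
#' @param cohort a `"remit_cohort"`.
#' @param dir output directory (created if needed).
#' @param genotype_format `"csv"` or `"vcf"`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, genotype_format = c("csv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  stopifnot(inherits(cohort, "remit_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$feature_meta
  gen <- meta$name[meta$kind == "genetic"]
  cli <- meta$name[meta$kind == "clinical"]
  n <- nrow(cohort$features)
  id <- sprintf("P%04d", seq_len(n))
  outcome_col <- if (cohort$outcome_type == "binary") "remission" else "hrsd_total"

  clin_df <- data.frame(participant_id = id, drug = as.character(cohort$drug),
                        stringsAsFactors = FALSE)
  clin_df[[outcome_col]] <- cohort$outcome
  for (cn in cli) clin_df[[cn]] <- fmt_num(cohort$features[, cn])
  clinical_path <- file.path(dir, "clinical.csv")
  write.csv(clin_df, clinical_path, row.names = FALSE, quote = FALSE, na = "")

  meta_path <- file.path(dir, "meta.csv")
  write.csv(meta, meta_path, row.names = FALSE, quote = FALSE, na = "")

  if (genotype_format == "csv") {
    gen_df <- data.frame(participant_id = id, stringsAsFactors = FALSE)
    for (cn in gen) gen_df[[cn]] <- cohort$features[, cn]
    genotype_path <- file.path(dir, "genotypes.csv")
    write.csv(gen_df, genotype_path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    genotype_path <- file.path(dir, "genotypes.vcf")
    write_vcf_dosages(cohort$features[, gen, drop = FALSE], genotype_path,
                      sample_ids = id)
  }
  invisible(c(clinical = clinical_path, genotypes = genotype_path,
              meta = meta_path))
}

#' Write a dosage matrix as a minimal VCF
#'
#' One biallelic record per SNP with synthetic positions (CHROM 1, POS in
#' input order) and GT-only sample fields: dosage 0 -> `0/0`, 1 -> `0/1`,
#' 2 -> `1/1`, missing -> `./.`.
#'
#' @param dosages participants x SNPs matrix with entries in `{0, 1, 2}` or
#'   `NA`.
#' @param file output path.
#' @param sample_ids optional participant identifiers.
#' @return Invisibly, `file`.
#' @export
write_vcf_dosages <- function(dosages, file, sample_ids = NULL) {
  n <- nrow(dosages)
  p <- ncol(dosages)
  if (is.null(sample_ids)) sample_ids <- sprintf("P%04d", seq_len(n))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rxremit synthetic cohort writer",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  body <- vapply(seq_len(p), function(j) {
    d <- dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c("1", 1000L * j, colnames(dosages)[j], "A", "G", ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read SNP dosages from a VCF
#'
#' Converts GT fields to additive dosages (count of ALT alleles); missing
#' genotypes become `NA`. Multi-allelic records are skipped with a warning.
#'
#' @param file path to an (uncompressed or bgzipped) VCF.
#' @return A participants x SNPs numeric dosage matrix.
#' @export
read_vcf_dosages <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the `vcfR` package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  dos <- apply(gt, 2, function(g) {
    first <- substr(g, 1, 1)
    second <- substr(g, 3, 3)
    out <- suppressWarnings(as.numeric(first) + as.numeric(second))
    out
  })
  dos <- t(dos)
  colnames(dos) <- ids
  rownames(dos) <- NULL
  dos
}

#' Read a cohort from plain-text files
#'
#' Inverse of [write_cohort()]: restores the feature matrix (genotype columns
#' first, then clinical), metadata, drug labels and outcome. The outcome
#' type is inferred from the outcome column name (`remission` or
#' `hrsd_total`).
#'
#' @param clinical_file clinical CSV path.
#' @param genotype_file dosage CSV or VCF path (extension decides the
#'   parser); may be `NULL` for a genotype-free cohort.
#' @param meta_file feature metadata CSV path.
#' @return A `"remit_cohort"` (with `config = NULL`: the generating truth is
#'   not stored on disk).
#' @export
read_cohort_csv <- function(clinical_file, genotype_file = NULL, meta_file) {
  clin <- read.csv(clinical_file, stringsAsFactors = FALSE)
  meta <- read.csv(meta_file, stringsAsFactors = FALSE)
  outcome_col <- intersect(c("remission", "hrsd_total"), names(clin))
  if (length(outcome_col) != 1L) {
    stop("clinical file must contain exactly one of `remission` or `hrsd_total`",
         call. = FALSE)
  }
  outcome_type <- if (outcome_col == "remission") "binary" else "hrsd_score"
  cli_names <- meta$name[meta$kind == "clinical"]
  gen_names <- meta$name[meta$kind == "genetic"]
  missing_cli <- setdiff(cli_names, names(clin))
  if (length(missing_cli)) {
    stop("clinical file lacks declared column(s): ",
         paste(missing_cli, collapse = ", "), call. = FALSE)
  }
  cli_mat <- as.matrix(clin[, cli_names, drop = FALSE])
  gen_mat <- NULL
  if (!is.null(genotype_file)) {
    if (grepl("\\.vcf(\\.gz)?$", genotype_file)) {
      gen_mat <- read_vcf_dosages(genotype_file)
    } else {
      gdf <- read.csv(genotype_file, stringsAsFactors = FALSE)
      gdf$participant_id <- NULL
      gen_mat <- as.matrix(gdf)
    }
    gen_mat <- gen_mat[, intersect(gen_names, colnames(gen_mat)), drop = FALSE]
  }
  features <- if (is.null(gen_mat)) cli_mat else cbind(gen_mat, cli_mat)
  meta <- meta[meta$name %in% colnames(features), , drop = FALSE]
  meta <- meta[match(colnames(features), meta$name), , drop = FALSE]
  rownames(meta) <- NULL
  structure(
    list(features = features, feature_meta = meta,
         drug = factor(clin$drug),
         outcome = clin[[outcome_col]],
         outcome_type = outcome_type,
         eta = NULL, config = NULL),
    class = "remit_cohort")
}
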