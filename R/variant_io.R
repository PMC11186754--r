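#' Read one patient's paired somatic calls from a multi-sample VCF
#'
#' Parses a VCF 4.x file with VariantAnnotation, splits multi-allelic
#' records into atomic variants, and extracts per-sample depth (`DP`) and
#' alt-supporting reads (second `AD` value) for the named biopsy and
#' resection columns (and the matched normal, when named). The somatic
#' posterior is taken from a configurable INFO tag, by default a
#' phred-scaled somatic-probability tag converted to the linear scale;
#' records lacking the tag get posterior 1.0 with a warning. Records with
#' missing depth or allelic-depth values in either tumor sample are
#' skipped with a logged count; records with depth 0 are retained (their
#' VAF is undefined, flagged `NA`).
#'
#' @param vcf_path path to the VCF.
#' @param sample_names named list or vector with entries `biopsy`,
#'   `resection` and optionally `normal`, giving VCF sample column names.
#' @param priors numeric `c(p1, p2)` pathologist purity estimates.
#' @param regression pathological regression percent, or `NA`.
#' @param patient_id identifier; defaults to the VCF file stem.
#' @param posterior_tag INFO key carrying the somatic posterior.
#' @param posterior_scale `"phred"` (`p = 10^(-tag/10)`) or `"linear"`.
#' @return a [patient_case()].
#' @export
read_paired_case <- function(vcf_path, sample_names,
                             priors = c(NA_real_, NA_real_),
                             regression = NA_real_,
                             patient_id = sub("\\.vcf(\\.gz)?$", "",
                                              basename(vcf_path)),
                             posterior_tag = "PROB_SOMATIC",
                             posterior_scale = c("phred", "linear")) {
  posterior_scale <- match.arg(posterior_scale)
  sample_names <- as.list(sample_names)
  for (role in c("biopsy", "resection"))
    if (is.null(sample_names[[role]]))
      stop("sample_names must name the '", role, "' column")
  vcf <- VariantAnnotation::readVcf(vcf_path)
  have <- colnames(vcf)
  need <- unlist(sample_names[c("biopsy", "resection", "normal")])
  missing_samples <- setdiff(need, have)
  if (length(missing_samples))
    stop("sample column(s) not in ", basename(vcf_path), ": ",
         paste(missing_samples, collapse = ", "))
  vcf <- VariantAnnotation::expand(vcf)  # one row per alt allele

  rr <- SummarizedExperiment::rowRanges(vcf)
  dp <- VariantAnnotation::geno(vcf)$DP
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(dp) || is.null(ad))
    stop("VCF must carry DP and AD FORMAT fields")
  alt_of <- function(smp) {
    if (length(dim(ad)) == 3L) return(as.numeric(ad[, smp, 2]))
    col <- ad[, smp]
    if (is.list(col))
      vapply(col, function(x)
        if (length(x) >= 2L) as.numeric(x[2]) else NA_real_, numeric(1))
    else as.numeric(col)
  }
  sb <- sample_names$biopsy; sr <- sample_names$resection
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    depth_biopsy = as.numeric(dp[, sb]),
    alt_biopsy = alt_of(sb),
    depth_resection = as.numeric(dp[, sr]),
    alt_resection = alt_of(sr),
    stringsAsFactors = FALSE)
  if (!is.null(sample_names$normal)) {
    df$depth_normal <- as.numeric(dp[, sample_names$normal])
    df$alt_normal <- alt_of(sample_names$normal)
  }

  info <- VariantAnnotation::info(vcf)
  if (posterior_tag %in% names(info)) {
    tag <- as.numeric(info[[posterior_tag]])
    post <- if (posterior_scale == "phred") 10^(-tag / 10) else tag
    post[is.na(post)] <- 1
    df$somatic_posterior <- pmin(1, pmax(0, post))
  } else {
    warning("INFO tag '", posterior_tag, "' absent from ",
            basename(vcf_path), "; somatic posterior set to 1.0")
    df$somatic_posterior <- 1
  }

  bad <- is.na(df$depth_biopsy) | is.na(df$alt_biopsy) |
    is.na(df$depth_resection) | is.na(df$alt_resection)
  if (any(bad))
    message(sum(bad), " record(s) skipped in ", basename(vcf_path),
            " (missing depth or allelic depth)")
  df <- df[!bad, , drop = FALSE]
  patient_case(patient_id, df, p1 = priors[1], p2 = priors[2],
               regression_percent = regression)
}

#' Write a patient case as a multi-sample VCF
#'
#' Emits the dialect [read_paired_case()] reads: sample columns `biopsy`
#' and `resection` (plus `normal` when normal counts are present) with
#' `DP`/`AD` FORMAT fields and the somatic posterior as a phred-scaled
#' `PROB_SOMATIC` INFO tag.
#'
#' @param case a [patient_case()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case_vcf <- function(case, path) {
  v <- case$variants
  have_normal <- any(!is.na(v$depth_normal))
  samples <- c("biopsy", "resection", if (have_normal) "normal")
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    paste0("##INFO=<ID=PROB_SOMATIC,Number=1,Type=Float,Description=",
           "\"Phred-scaled posterior probability of being somatic in ",
           "biopsy or resection\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  fmt_sample <- function(depth, alt) {
    depth <- ifelse(is.na(depth), 0, depth)
    alt <- ifelse(is.na(alt), 0, alt)
    sprintf("%d:%d,%d", as.integer(depth),
            as.integer(depth - alt), as.integer(alt))
  }
  cols <- list(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
               sprintf("PROB_SOMATIC=%s",
                       format(.phred(v$somatic_posterior),
                              scientific = FALSE, trim = TRUE)),
               "DP:AD",
               fmt_sample(v$depth_biopsy, v$alt_biopsy),
               fmt_sample(v$depth_resection, v$alt_resection))
  if (have_normal)
    cols <- c(cols, list(fmt_sample(v$depth_normal, v$alt_normal)))
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read the cohort priors CSV
#'
#' @param path CSV with columns `patient_id`, `p1`, `p2`,
#'   `regression_percent`.
#' @return data frame.
#' @export
read_priors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "p1", "p2", "regression_percent")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("priors file lacks columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Attach annotations from a sidecar TSV
#'
#' Joins annotation columns (`pathogenicity_score`, `population_af`,
#' `clinical_significance`, `gene`, `consequence`) onto a case's variants
#' by `(chrom, pos, ref, alt)`.
#'
#' @param case a [patient_case()].
#' @param path TSV with the key columns and any of the annotation columns.
#' @return the case with annotations merged in.
#' @export
annotate_case <- function(case, path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  key <- c("chrom", "pos", "ref", "alt")
  if (!all(key %in% names(ann)))
    stop("annotation table must carry chrom, pos, ref, alt")
  ann_cols <- intersect(names(ann),
                        c("pathogenicity_score", "population_af",
                          "clinical_significance", "gene", "consequence"))
  v <- case$variants
  idx <- match(paste(v$chrom, v$pos, v$ref, v$alt),
               paste(ann$chrom, ann$pos, ann$ref, ann$alt))
  for (col in ann_cols) v[[col]] <- ann[[col]][idx]
  case$variants <- variant_table(v)
  case
}

#' Write the cohort subclone-dynamics table
#'
#' One row per analyzable patient, tab-separated, in the fixed column
#' order: `patient_id`, `regression_percent`, `n_total`, `n_resection`,
#' `n_lost`, `n_gained`, `n_retained`, `fraction_lost`, `fraction_gained`,
#' `purity_biopsy`, `purity_biopsy_status`, `purity_resection`,
#' `purity_resection_status`.
#'
#' @param cohort the list returned by [summarize_cohort()], or its `table`
#'   data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  tab <- if (is.data.frame(cohort)) cohort else cohort$table
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
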