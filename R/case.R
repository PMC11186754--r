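#' Construct a paired-sample patient case
#'
#' A patient case holds the somatic variant calls observed jointly in the
#' pretreatment biopsy and the post-therapy resected tumor of one patient,
#' together with the two pathologist purity estimates for the resection
#' sample and the pathological regression. Purity posteriors and subclone
#' dynamics are attached later by [resolve_resection_purity()] /
#' [estimate_biopsy_purity()] and [classify_subclones()].
#'
#' @param patient_id character scalar.
#' @param variants data frame of variant calls, see [variant_table()].
#' @param p1,p2 pathologist purity estimates in `[0, 1]`, `p1 <= p2`.
#' @param regression_percent pathological regression in `[0, 100]` (percent
#'   reduction of viable tumor cells), or `NA`.
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(patient_id, variants, p1 = NA_real_, p2 = NA_real_,
                         regression_percent = NA_real_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  variants <- variant_table(variants)
  if (!is.na(p1) && !is.na(p2) && p1 > p2)
    stop("pathologist purity estimates must satisfy p1 <= p2 (got ",
         p1, " > ", p2, ")")
  for (p in c(p1, p2))
    if (!is.na(p) && (p < 0 || p > 1)) stop("purity priors must lie in [0, 1]")
  structure(
    list(patient_id = patient_id, variants = variants,
         p1 = p1, p2 = p2, regression_percent = regression_percent,
         purity_biopsy = NULL, purity_resection = NULL, dynamics = NULL),
    class = "patient_case")
}

#' Canonical variant table
#'
#' Coerces a data frame to the internal variant-call layout and checks its
#' invariants: one row per atomic variant (multi-allelic records are split
#' upstream), alt counts never exceed depths, somatic posteriors in
#' `[0, 1]`, `ref != alt`. Optional annotation columns
#' (`pathogenicity_score`, `population_af`, `clinical_significance`,
#' `gene`, `consequence`) and matched-normal counts (`alt_normal`,
#' `depth_normal`) are kept when present, filled with `NA` otherwise.
#'
#' @param df data frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `depth_biopsy`, `alt_biopsy`, `depth_resection`, `alt_resection`,
#'   `somatic_posterior`.
#' @return data frame with the canonical columns and derived `vaf_biopsy`,
#'   `vaf_resection` (`NA` where depth is 0).
#' @export
variant_table <- function(df) {
  required <- c("chrom", "pos", "ref", "alt",
                "depth_biopsy", "alt_biopsy",
                "depth_resection", "alt_resection", "somatic_posterior")
  optional <- c("pathogenicity_score", "population_af",
                "clinical_significance", "gene", "consequence",
                "alt_normal", "depth_normal")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  for (col in optional)
    if (is.null(df[[col]]))
      df[[col]] <- rep(
        if (col %in% c("clinical_significance", "gene", "consequence"))
          NA_character_ else NA_real_,
        nrow(df))
  df <- df[, c(required, optional)]
  if (nrow(df)) {
    stopifnot(all(df$pos >= 1), all(df$ref != df$alt))
    for (s in c("biopsy", "resection")) {
      d <- df[[paste0("depth_", s)]]; a <- df[[paste0("alt_", s)]]
      stopifnot(all(d >= 0), all(a >= 0), all(a <= d))
    }
    stopifnot(all(df$somatic_posterior >= 0 & df$somatic_posterior <= 1))
  }
  df$vaf_biopsy <- ifelse(df$depth_biopsy > 0,
                          df$alt_biopsy / df$depth_biopsy, NA_real_)
  df$vaf_resection <- ifelse(df$depth_resection > 0,
                             df$alt_resection / df$depth_resection, NA_real_)
  df
}

#' Purity estimate record
#'
#' @param value purity in `(0, 1]`, or `NA` when unknown.
#' @param status `"known"` or `"unknown"`; must agree with `value`.
#' @param method one of `"vaf_max_consistent"`, `"scaled_from_resection"`,
#'   `"simulated_truth"`.
#' @param v robust maximal VAF used, if applicable.
#' @param s biopsy-to-resection VAF scaling factor, if applicable.
#' @return object of class `purity_estimate`.
#' @export
purity_estimate <- function(value = NA_real_,
                            status = if (is.na(value)) "unknown" else "known",
                            method = NA_character_,
                            v = NA_real_, s = NA_real_) {
  status <- match.arg(status, c("known", "unknown"))
  if (status == "known") {
    if (is.na(value) || value <= 0 || value > 1)
      stop("known purity must lie in (0, 1]")
  } else if (!is.na(value)) {
    stop("unknown purity must not carry a value")
  }
  if (!is.na(s) && s <= 0) stop("scaling factor s must be positive")
  structure(list(value = value, status = status, method = method,
                 v = v, s = s),
            class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  if (x$status == "known")
    cat(sprintf("purity %.3f (%s)\n", x$value, x$method))
  else cat("purity unknown\n")
  invisible(x)
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("patient %s: %d variants; priors [%.2f, %.2f]\n",
              x$patient_id, nrow(x$variants),
              x$p1, x$p2))
  invisible(x)
}
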