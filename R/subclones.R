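#' Purity-adjusted VAF
#'
#' Divides an observed VAF by the sample purity to approximate the cellular
#' prevalence of the variant among tumor cells, capped at 1.
#'
#' @param f observed VAF in `[0, 1]` (vectorized).
#' @param purity sample purity in `(0, 1]`.
#' @return adjusted VAF in `[0, 1]`.
#' @export
adjust_vaf <- function(f, purity) {
  if (is.na(purity) || purity <= 0) stop("purity must be positive")
  stopifnot(purity <= 1, all(is.na(f) | (f >= 0 & f <= 1)))
  pmin(1, f / purity)
}

#' Would a variant be detectable in the other sample?
#'
#' A variant observed at purity-adjusted (cellular) frequency `f_adj` in
#' one sample is considered detectable in the other sample when, occurring
#' at the same cellular frequency there, it would be expected to be
#' represented by at least `min_reads` reads: the cellular frequency is
#' converted back to the other sample's allele scale via its purity and
#' multiplied by its depth. The bound is inclusive.
#'
#' @param f_adj purity-adjusted VAF in the sample where the variant is
#'   observed (vectorized).
#' @param purity_other purity of the other sample.
#' @param depth_other read depth at the locus in the other sample
#'   (vectorized).
#' @param min_reads expected-read threshold (default 2).
#' @return logical.
#' @export
detectable_in_other <- function(f_adj, purity_other, depth_other,
                                min_reads = 2) {
  stopifnot(purity_other > 0, purity_other <= 1)
  (f_adj * purity_other * depth_other) >= min_reads
}

#' Count and classify subclones lost, gained and retained under therapy
#'
#' Each somatic variant is treated as the representative of the subclone it
#' founded. Qualifying subclones are variants with somatic posterior at
#' least `posterior_min`, purity-adjusted VAF at least `vaf_min` in at
#' least one sample, and passing the expected-read detectability filter
#' toward the respective other sample ([detectable_in_other()]). Among
#' qualifying variants, those with zero alt reads in the resection but
#' adjusted biopsy VAF `>= vaf_min` are lost subclones; symmetrically with
#' zero alt reads in the biopsy, gained; the rest retained. Fractions use
#' the total qualifying count as denominator, so lost, gained and retained
#' partition the total.
#'
#' @param case `patient_case` with both purities known
#'   (see [estimate_purities()]).
#' @param posterior_min somatic-posterior threshold (default 0.95).
#' @param vaf_min adjusted-VAF threshold (default 0.1).
#' @param min_reads detectability threshold in expected reads (default 2).
#' @return list of class `subclone_dynamics`: `n_total`, `n_lost`,
#'   `n_gained`, `n_retained`, `n_resection` (qualifying via the resection
#'   sample alone), `fraction_lost`, `fraction_gained`, `analyzable`, and
#'   `qualifying` (row indices into the variant table).
#' @export
classify_subclones <- function(case, posterior_min = 0.95, vaf_min = 0.1,
                               min_reads = 2) {
  pb <- case$purity_biopsy
  pr <- case$purity_resection
  if (is.null(pb) || is.null(pr) ||
      pb$status != "known" || pr$status != "known")
    stop("both purity estimates must be known; patient should be excluded ",
         "upstream when purity is unknown")
  v <- case$variants
  post_ok <- v$somatic_posterior >= posterior_min

  adj_b <- ifelse(is.na(v$vaf_biopsy), NA_real_,
                  adjust_vaf(v$vaf_biopsy, pb$value))
  adj_r <- ifelse(is.na(v$vaf_resection), NA_real_,
                  adjust_vaf(v$vaf_resection, pr$value))

  obs_b <- !is.na(adj_b) & adj_b >= vaf_min
  obs_r <- !is.na(adj_r) & adj_r >= vaf_min
  # detectability checked from each sample where the variant is observed,
  # toward the other sample
  det_from_b <- obs_b & detectable_in_other(adj_b, pr$value,
                                            v$depth_resection, min_reads)
  det_from_r <- obs_r & detectable_in_other(adj_r, pb$value,
                                            v$depth_biopsy, min_reads)
  qualifying <- post_ok & (det_from_b | det_from_r)

  lost <- qualifying & v$alt_resection == 0 & obs_b
  gained <- qualifying & v$alt_biopsy == 0 & obs_r
  retained <- qualifying & !lost & !gained

  n_total <- sum(qualifying)
  dyn <- list(
    n_total = n_total,
    n_lost = sum(lost),
    n_gained = sum(gained),
    n_retained = sum(retained),
    n_resection = sum(post_ok & det_from_r),
    fraction_lost = if (n_total > 0) sum(lost) / n_total else NA_real_,
    fraction_gained = if (n_total > 0) sum(gained) / n_total else NA_real_,
    analyzable = n_total > 0,
    qualifying = which(qualifying))
  class(dyn) <- "subclone_dynamics"
  dyn
}

#' @export
print.subclone_dynamics <- function(x, ...) {
  if (!x$analyzable) {
    cat("no qualifying subclones (patient not analyzable)\n")
  } else {
    cat(sprintf(
      "%d subclones: %d lost (%.2f), %d gained (%.2f), %d retained\n",
      x$n_total, x$n_lost, x$fraction_lost,
      x$n_gained, x$fraction_gained, x$n_retained))
  }
  invisible(x)
}

#' Summarize subclone dynamics over a cohort
#'
#' Computes purities (unless already present) and subclone dynamics for
#' each case, keeping one row per analyzable patient. Patients with
#' unknown resection purity or an empty qualifying set are excluded and
#' listed with a reason.
#'
#' @param cases list of `patient_case`.
#' @param posterior_min,vaf_min,min_reads passed to [classify_subclones()].
#' @param ... passed to [estimate_purities()] for cases whose purities are
#'   not yet filled.
#' @return list with `table` (cohort data frame, see
#'   [write_cohort_table()] for the column contract), `exclusions` (data
#'   frame `patient_id`, `reason`), and `cases` (cases with purities and
#'   dynamics attached).
#' @export
summarize_cohort <- function(cases, posterior_min = 0.95, vaf_min = 0.1,
                             min_reads = 2, ...) {
  rows <- list(); excl <- list()
  out_cases <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    if (is.null(case$purity_resection))
      case <- estimate_purities(case, ...)
    pr <- case$purity_resection; pb <- case$purity_biopsy
    if (pr$status != "known" || pb$status != "known") {
      excl[[length(excl) + 1L]] <-
        data.frame(patient_id = case$patient_id, reason = "unknown_purity")
      out_cases[[i]] <- case
      next
    }
    dyn <- classify_subclones(case, posterior_min = posterior_min,
                              vaf_min = vaf_min, min_reads = min_reads)
    case$dynamics <- dyn
    out_cases[[i]] <- case
    if (!dyn$analyzable) {
      excl[[length(excl) + 1L]] <-
        data.frame(patient_id = case$patient_id,
                   reason = "empty_qualifying_set")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = case$patient_id,
      regression_percent = case$regression_percent,
      n_total = dyn$n_total,
      n_resection = dyn$n_resection,
      n_lost = dyn$n_lost,
      n_gained = dyn$n_gained,
      n_retained = dyn$n_retained,
      fraction_lost = dyn$fraction_lost,
      fraction_gained = dyn$fraction_gained,
      purity_biopsy = pb$value,
      purity_biopsy_status = pb$status,
      purity_resection = pr$value,
      purity_resection_status = pr$status,
      stringsAsFactors = FALSE)
  }
  empty_tab <- data.frame(
    patient_id = character(), regression_percent = numeric(),
    n_total = integer(), n_resection = integer(), n_lost = integer(),
    n_gained = integer(), n_retained = integer(),
    fraction_lost = numeric(), fraction_gained = numeric(),
    purity_biopsy = numeric(), purity_biopsy_status = character(),
    purity_resection = numeric(), purity_resection_status = character(),
    stringsAsFactors = FALSE)
  list(
    table = if (length(rows)) do.call(rbind, rows) else empty_tab,
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(patient_id = character(), reason = character()),
    cases = out_cases)
}
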