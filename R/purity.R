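#' Robust maximal somatic VAF of one sample
#'
#' Under copy-neutral heterozygosity no somatic variant can exceed a VAF
#' equal to the (allele-scale) tumor purity, so the upper edge of the
#' somatic VAF distribution estimates purity. Isolated read-sampling or
#' copy-number outliers can sit beyond that edge; a high quantile with a
#' depth floor is used instead of the literal maximum.
#'
#' @param variants canonical variant table ([variant_table()]).
#' @param sample `"biopsy"` or `"resection"`.
#' @param quantile upper quantile of the VAF distribution to report.
#' @param min_depth minimum read depth for a variant to enter the
#'   distribution.
#' @param posterior_min minimum somatic posterior for inclusion.
#' @return The quantile of the qualifying VAF distribution, capped at 1, or
#'   `NA_real_` when no variant qualifies (caller marks purity unknown).
#' @export
robust_max_vaf <- function(variants, sample = c("resection", "biopsy"),
                           quantile = 0.98, min_depth = 30L,
                           posterior_min = 0.95) {
  sample <- match.arg(sample)
  variants <- variant_table(variants)
  depth <- variants[[paste0("depth_", sample)]]
  vaf <- variants[[paste0("vaf_", sample)]]
  keep <- !is.na(vaf) & depth >= min_depth &
    variants$somatic_posterior >= posterior_min
  if (!any(keep)) return(NA_real_)
  min(1, stats::quantile(vaf[keep], probs = quantile, names = FALSE))
}

#' Reconcile the VAF-derived purity with pathologist priors
#'
#' The robust maximal VAF `v` is reported as the resection purity only when
#' it is consistent with both pathologist estimates (lies inside
#' `[p1, p2]`) and the pathologists agree sufficiently
#' (`p2 - p1 <= max_disagreement`); otherwise the purity is unknown.
#'
#' @param v robust maximal VAF in `[0, 1]`.
#' @param p1,p2 pathologist purity estimates, `p1 <= p2`.
#' @param max_disagreement maximum tolerated `p2 - p1` (default 0.2).
#' @return [purity_estimate()] with method `"vaf_max_consistent"`.
#' @export
resolve_resection_purity <- function(v, p1, p2, max_disagreement = 0.2) {
  if (is.na(p1) || is.na(p2) || p1 > p2)
    stop("pathologist priors must satisfy p1 <= p2")
  stopifnot(p1 >= 0, p2 <= 1)
  if (is.na(v)) return(purity_estimate(method = "vaf_max_consistent"))
  stopifnot(v >= 0, v <= 1)
  known <- (v >= p1) && (v <= p2) && ((p2 - p1) <= max_disagreement) && v > 0
  if (known)
    purity_estimate(value = v, method = "vaf_max_consistent", v = v)
  else
    purity_estimate(method = "vaf_max_consistent", v = v)
}

#' Empirical 1-Wasserstein distance between two VAF distributions
#'
#' Mean absolute difference of the two empirical quantile functions,
#' evaluated at fixed mid-grid probabilities. Exact up to grid resolution,
#' which is well below the 0.05 step of the scaling-factor search.
#'
#' @param x,y numeric vectors (at least one value each).
#' @param n_grid number of quantile evaluation points.
#' @return non-negative scalar.
#' @keywords internal
wasserstein1 <- function(x, y, n_grid = 512L) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  u <- (seq_len(n_grid) - 0.5) / n_grid
  qx <- stats::quantile(x, probs = u, names = FALSE, type = 1)
  qy <- stats::quantile(y, probs = u, names = FALSE, type = 1)
  mean(abs(qx - qy))
}

#' Transfer the resection purity to the biopsy by VAF-distribution scaling
#'
#' The biopsy VAF distribution is scaled to match the resection
#' distribution; the scaling factor `s` converts the known resection purity
#' into a biopsy purity (`purity_b = purity_r / s`). When at least
#' `min_shared` variants are observed (VAF > 0) in both samples, `s` is the
#' median of per-variant resection/biopsy VAF ratios. Otherwise `s`
#' minimizes the 1-Wasserstein distance between the scaled biopsy VAFs and
#' the resection VAFs over a grid.
#'
#' @param case `patient_case` whose variant table carries both samples.
#' @param resection_purity known [purity_estimate()] of the resection.
#' @param min_shared minimum shared variants for the median-ratio path.
#' @param posterior_min minimum somatic posterior for a variant to enter.
#' @param s_grid scaling-factor search grid for the fallback path.
#' @return [purity_estimate()] with method `"scaled_from_resection"` and
#'   the factor `s` recorded; unknown when fewer than 3 nonzero biopsy VAFs
#'   exist.
#' @export
estimate_biopsy_purity <- function(case, resection_purity,
                                   min_shared = 10L,
                                   posterior_min = 0.95,
                                   s_grid = seq(0.1, 10, by = 0.05)) {
  stopifnot(inherits(resection_purity, "purity_estimate"))
  if (resection_purity$status != "known")
    stop("resection purity must be known before scaling to the biopsy")
  v <- case$variants
  v <- v[v$somatic_posterior >= posterior_min, , drop = FALSE]
  fb <- v$vaf_biopsy
  fr <- v$vaf_resection
  nz_b <- !is.na(fb) & fb > 0
  nz_r <- !is.na(fr) & fr > 0
  if (sum(nz_b) < 3L)
    return(purity_estimate(method = "scaled_from_resection"))
  shared <- nz_b & nz_r
  if (sum(shared) >= min_shared) {
    s <- stats::median(fr[shared] / fb[shared])
  } else {
    dists <- vapply(s_grid, function(s)
      wasserstein1(s * fb[nz_b], fr[nz_r]), numeric(1))
    s <- s_grid[which.min(dists)]
  }
  if (!is.finite(s) || s <= 0)
    return(purity_estimate(method = "scaled_from_resection"))
  value <- min(1, resection_purity$value / s)
  purity_estimate(value = value, method = "scaled_from_resection", s = s)
}

#' Estimate both purities for a patient case
#'
#' Runs [robust_max_vaf()] on the resection, reconciles with the
#' pathologist priors via [resolve_resection_purity()], and, when that
#' yields a known purity, transfers it to the biopsy with
#' [estimate_biopsy_purity()]. A patient whose resection purity is unknown
#' is excluded from subclone dynamics downstream.
#'
#' @param case `patient_case`.
#' @param quantile,min_depth passed to [robust_max_vaf()].
#' @param max_disagreement passed to [resolve_resection_purity()].
#' @param min_shared passed to [estimate_biopsy_purity()].
#' @return the case with `purity_resection` and `purity_biopsy` filled.
#' @export
estimate_purities <- function(case, quantile = 0.98, min_depth = 30L,
                              max_disagreement = 0.2, min_shared = 10L) {
  v <- robust_max_vaf(case$variants, "resection",
                      quantile = quantile, min_depth = min_depth)
  case$purity_resection <- resolve_resection_purity(
    v, case$p1, case$p2, max_disagreement = max_disagreement)
  case$purity_biopsy <- if (case$purity_resection$status == "known")
    estimate_biopsy_purity(case, case$purity_resection,
                           min_shared = min_shared)
  else purity_estimate(method = "scaled_from_resection")
  case
}
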