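#' Filter policy for reportable candidate resistance variants
#'
#' Bundles the annotation-based filter clauses: nonsynonymous consequence,
#' pathogenicity (REVEL-style) score above a threshold when a score is
#' available, population allele frequency below a threshold (absent AF
#' treated as 0), clinical-significance label outside an excluded set, and
#' membership of a cancer-gene list when one is supplied.
#'
#' @param require_nonsynonymous require a nonsynonymous consequence.
#' @param revel_min pathogenicity-score threshold in `[0, 1]` (default 0.5;
#'   a stricter reporting policy uses 0.7).
#' @param gnomad_max population-AF threshold in `[0, 1]` (default 0.2).
#' @param excluded_clinical_labels labels that reject a variant.
#' @param gene_list character vector of gene symbols, or `NULL` to skip the
#'   gene clause.
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(require_nonsynonymous = TRUE,
                          revel_min = 0.5,
                          gnomad_max = 0.2,
                          excluded_clinical_labels = c("benign",
                                                       "likely_benign"),
                          gene_list = NULL) {
  stopifnot(revel_min >= 0, revel_min <= 1, gnomad_max >= 0, gnomad_max <= 1)
  structure(list(require_nonsynonymous = require_nonsynonymous,
                 revel_min = revel_min, gnomad_max = gnomad_max,
                 excluded_clinical_labels = excluded_clinical_labels,
                 gene_list = gene_list),
            class = "filter_policy")
}

NONSYNONYMOUS_CONSEQUENCES <- c(
  "missense_variant", "stop_gained", "stop_lost", "start_lost",
  "frameshift_variant", "inframe_insertion", "inframe_deletion",
  "splice_acceptor_variant", "splice_donor_variant", "nonsynonymous")

#' Filter variants to reportable candidate resistance events
#'
#' Applies the conjunction of the policy clauses; variants lacking a
#' pathogenicity score pass the score clause ("if available" semantics),
#' variants lacking a population AF are treated as AF 0. Rejection reasons
#' are tallied clause-by-clause; the first failing clause (in the order
#' consequence, pathogenicity, population AF, clinical label, gene list)
#' is recorded per rejected variant.
#'
#' @param variants canonical variant table ([variant_table()]).
#' @param policy a [filter_policy()].
#' @return the surviving rows, with attribute `rejection_log` — a data
#'   frame (`reason`, `n`) over reasons `consequence`, `pathogenicity`,
#'   `population_af`, `clinical_significance`, `gene_list`.
#' @export
filter_reportable <- function(variants, policy = filter_policy()) {
  variants <- variant_table(variants)
  n <- nrow(variants)
  pass_cons <- if (policy$require_nonsynonymous)
    !is.na(variants$consequence) &
      variants$consequence %in% NONSYNONYMOUS_CONSEQUENCES
  else rep(TRUE, n)
  score <- variants$pathogenicity_score
  pass_score <- is.na(score) | score > policy$revel_min
  af <- ifelse(is.na(variants$population_af), 0, variants$population_af)
  pass_af <- af < policy$gnomad_max
  lab <- tolower(gsub("[ /]", "_", variants$clinical_significance))
  pass_lab <- is.na(lab) | !(lab %in% policy$excluded_clinical_labels)
  pass_gene <- if (is.null(policy$gene_list)) rep(TRUE, n)
  else !is.na(variants$gene) & variants$gene %in% policy$gene_list

  reason <- rep(NA_character_, n)
  reason[!pass_gene] <- "gene_list"
  reason[!pass_lab] <- "clinical_significance"
  reason[!pass_af] <- "population_af"
  reason[!pass_score] <- "pathogenicity"
  reason[!pass_cons] <- "consequence"
  keep <- is.na(reason)
  out <- variants[keep, , drop = FALSE]
  tab <- table(factor(reason[!keep],
                      levels = c("consequence", "pathogenicity",
                                 "population_af", "clinical_significance",
                                 "gene_list")))
  attr(out, "rejection_log") <- data.frame(reason = names(tab),
                                           n = as.integer(tab))
  out
}

#' Posterior probability that a variant is absent from the matched normal
#'
#' Two-hypothesis binomial model with equal priors: alt reads in the
#' normal arise from sequencing noise (Binomial(depth, `error_rate`)) or
#' from a germline heterozygous variant (Binomial(depth, 0.5)). Returns
#' the posterior weight of the noise hypothesis; 0.5 when depth is 0
#' (uninformative).
#'
#' @param alt_normal alt-supporting reads in the normal (vectorized).
#' @param depth_normal read depth in the normal (vectorized).
#' @param error_rate per-read noise rate (default 0.001).
#' @return probability in `[0, 1]`.
#' @export
prob_absent_in_normal <- function(alt_normal, depth_normal,
                                  error_rate = 0.001) {
  stopifnot(all(alt_normal <= depth_normal), error_rate > 0, error_rate < 1)
  out <- rep(0.5, length(alt_normal))
  pos <- depth_normal > 0
  la <- stats::dbinom(alt_normal[pos], depth_normal[pos], error_rate,
                      log = TRUE)
  lh <- stats::dbinom(alt_normal[pos], depth_normal[pos], 0.5, log = TRUE)
  # posterior of the noise hypothesis, computed stably in log space
  out[pos] <- 1 / (1 + exp(lh - la))
  out
}

#' Posterior probability that the purity-adjusted VAF changed
#'
#' Places independent Jeffreys-prior Beta posteriors on each sample's VAF,
#' divides the draws by the respective purity to move to the cellular
#' scale, and reports the Monte-Carlo probability that the two cellular
#' frequencies differ by more than `delta`.
#'
#' @param alt_b,depth_b biopsy alt reads and depth.
#' @param purity_b biopsy purity in `(0, 1]`.
#' @param alt_r,depth_r resection alt reads and depth.
#' @param purity_r resection purity in `(0, 1]`.
#' @param delta minimal cellular-frequency difference that counts as a
#'   change (default 0.05).
#' @param n_draws Monte-Carlo draws (default 20000).
#' @param seed optional seed applied locally (the caller's RNG state is
#'   restored on exit).
#' @return probability in `[0, 1]`.
#' @export
prob_vaf_changed <- function(alt_b, depth_b, purity_b,
                             alt_r, depth_r, purity_r,
                             delta = 0.05, n_draws = 20000L, seed = NULL) {
  stopifnot(alt_b <= depth_b, alt_r <= depth_r, delta >= 0)
  if (is.na(purity_b) || is.na(purity_r) || purity_b <= 0 || purity_r <= 0)
    stop("both purities must be known and positive")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  fb <- stats::rbeta(n_draws, alt_b + 0.5, depth_b - alt_b + 0.5) / purity_b
  fr <- stats::rbeta(n_draws, alt_r + 0.5, depth_r - alt_r + 0.5) / purity_r
  mean(abs(fb - fr) > delta)
}

#' Prioritization report for one patient
#'
#' Filters the case's variants with [filter_reportable()] and annotates the
#' survivors with [prob_absent_in_normal()] (when normal counts are
#' present) and [prob_vaf_changed()] (when both purities are known). Raw
#' probabilities are reported; any reporting cut is left to the caller.
#'
#' @param case `patient_case` (purities filled for VAF-change scoring).
#' @param policy a [filter_policy()].
#' @param delta,n_draws,seed passed to [prob_vaf_changed()].
#' @return data frame of reportable variants with `prob_absent_normal` and
#'   `prob_vaf_changed` columns; attribute `rejection_log` as in
#'   [filter_reportable()].
#' @export
prioritize_variants <- function(case, policy = filter_policy(),
                                delta = 0.05, n_draws = 20000L,
                                seed = NULL) {
  kept <- filter_reportable(case$variants, policy)
  log <- attr(kept, "rejection_log")
  n <- nrow(kept)
  kept$prob_absent_normal <- if (n)
    ifelse(is.na(kept$depth_normal), NA_real_,
           prob_absent_in_normal(ifelse(is.na(kept$alt_normal), 0,
                                        kept$alt_normal),
                                 ifelse(is.na(kept$depth_normal), 0,
                                        kept$depth_normal)))
  else numeric(0)
  pb <- case$purity_biopsy; pr <- case$purity_resection
  have_purity <- !is.null(pb) && !is.null(pr) &&
    pb$status == "known" && pr$status == "known"
  kept$prob_vaf_changed <- if (n && have_purity)
    vapply(seq_len(n), function(i) prob_vaf_changed(
      kept$alt_biopsy[i], kept$depth_biopsy[i], pb$value,
      kept$alt_resection[i], kept$depth_resection[i], pr$value,
      delta = delta, n_draws = n_draws,
      seed = if (is.null(seed)) NULL else seed + i), numeric(1))
  else rep(NA_real_, n)
  attr(kept, "rejection_log") <- log
  kept
}
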