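ann_variant <- function(consequence = "missense_variant",
                        pathogenicity_score = 0.9,
                        population_af = 0.001,
                        clinical_significance = NA_character_,
                        gene = "TP53", ...) {
  make_variants(vaf_biopsy = 0.2, vaf_resection = 0.2,
                consequence = consequence,
                pathogenicity_score = pathogenicity_score,
                population_af = population_af,
                clinical_significance = clinical_significance,
                gene = gene, ...)
}

test_that("the reportable filter applies each clause of the policy", {
  pol <- filter_policy(gene_list = c("TP53", "KRAS", "STK11"))
  expect_equal(nrow(filter_reportable(ann_variant(), pol)), 1L)

  rejected <- function(v) {
    out <- filter_reportable(v, pol)
    log <- attr(out, "rejection_log")
    list(n = nrow(out), reasons = log$reason[log$n > 0])
  }
  r <- rejected(ann_variant(pathogenicity_score = 0.4))
  expect_equal(r$n, 0L); expect_equal(r$reasons, "pathogenicity")
  r <- rejected(ann_variant(consequence = "synonymous_variant"))
  expect_equal(r$reasons, "consequence")
  r <- rejected(ann_variant(population_af = 0.3))
  expect_equal(r$reasons, "population_af")
  r <- rejected(ann_variant(clinical_significance = "benign"))
  expect_equal(r$reasons, "clinical_significance")
  r <- rejected(ann_variant(gene = "NOTAGENE"))
  expect_equal(r$reasons, "gene_list")

  # a missing pathogenicity score passes the score clause
  expect_equal(nrow(filter_reportable(
    ann_variant(pathogenicity_score = NA_real_), pol)), 1L)
})

test_that("a ten-variant fixture audits clause by clause", {
  pol <- filter_policy(gene_list = c("TP53", "KRAS"))
  v <- rbind(
    ann_variant(), ann_variant(gene = "KRAS"),
    ann_variant(pathogenicity_score = NA_real_),
    ann_variant(population_af = NA_real_),
    ann_variant(clinical_significance = "pathogenic"),
    ann_variant(),
    ann_variant(consequence = "synonymous_variant"),   # fails consequence
    ann_variant(pathogenicity_score = 0.2),            # fails score
    ann_variant(population_af = 0.5),                  # fails AF
    ann_variant(clinical_significance = "likely_benign"))
  v$pos <- seq_len(nrow(v))
  out <- filter_reportable(v, pol)
  expect_equal(nrow(out), 6L)
  log <- attr(out, "rejection_log")
  expect_equal(sum(log$n), 4L)
  expect_setequal(log$reason[log$n > 0],
                  c("consequence", "pathogenicity", "population_af",
                    "clinical_significance"))
})

test_that("tightening any threshold never adds survivors", {
  set.seed(31)
  v <- do.call(rbind, lapply(1:30, function(i) ann_variant(
    pathogenicity_score = runif(1),
    population_af = runif(1, 0, 0.4),
    gene = sample(c("TP53", "KRAS", "OTHER"), 1))))
  v$pos <- seq_len(nrow(v))
  loose <- filter_reportable(v, filter_policy(revel_min = 0.3,
                                              gnomad_max = 0.3))
  tight <- filter_reportable(v, filter_policy(revel_min = 0.7,
                                              gnomad_max = 0.1))
  expect_lte(nrow(tight), nrow(loose))
  key <- function(df) paste(df$pos, df$ref, df$alt)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("absence-in-normal probability follows the two-binomial posterior", {
  # closed-form Bayes posterior of the noise hypothesis
  closed_form <- function(alt, depth, e = 0.001)
    dbinom(alt, depth, e) / (dbinom(alt, depth, e) + dbinom(alt, depth, 0.5))
  expect_gt(prob_absent_in_normal(0, 100), 0.99)
  expect_lt(prob_absent_in_normal(50, 100), 0.01)
  expect_equal(prob_absent_in_normal(0, 0), 0.5)
  for (case in list(c(0, 100), c(2, 200), c(10, 60), c(30, 80)))
    expect_equal(prob_absent_in_normal(case[1], case[2]),
                 closed_form(case[1], case[2]), tolerance = 1e-12)
})

test_that("the VAF-change probability behaves at the extremes", {
  # symmetric null: identical counts and purities; at deep coverage the
  # posteriors concentrate and most difference mass falls inside delta
  p_null <- prob_vaf_changed(100, 500, 0.5, 100, 500, 0.5, seed = 1)
  expect_lt(p_null, 0.5)
  # extreme separation
  p_far <- prob_vaf_changed(0, 200, 0.5, 50, 100, 0.5, seed = 1)
  expect_gt(p_far, 0.99)
  # symmetry under swapping samples (same seed, swapped arguments)
  p_ab <- prob_vaf_changed(10, 100, 0.5, 30, 100, 0.6, seed = 7)
  p_ba <- prob_vaf_changed(30, 100, 0.6, 10, 100, 0.5, seed = 7)
  expect_equal(p_ab, p_ba, tolerance = 0.02)
})

test_that("the VAF-change probability is purity-scale invariant", {
  # multiplying both purities by c rescales both adjusted frequencies by
  # 1/c; with delta rescaled accordingly the probability is unchanged
  p1 <- prob_vaf_changed(10, 100, 0.4, 30, 100, 0.4, delta = 0.05,
                         seed = 3, n_draws = 50000)
  p2 <- prob_vaf_changed(10, 100, 0.8, 30, 100, 0.8, delta = 0.025,
                         seed = 3, n_draws = 50000)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("a moderate case agrees with a high-replicate oracle", {
  p <- prob_vaf_changed(10, 100, 0.5, 30, 100, 0.5, seed = 11)
  set.seed(123)
  p_oracle <- oracle_prob_changed(10, 100, 0.5, 30, 100, 0.5, n = 1e6)
  se <- sqrt(p_oracle * (1 - p_oracle) * (1 / 20000 + 1 / 1e6))
  expect_lt(abs(p - p_oracle), 4 * se)
})

test_that("prioritization annotates survivors with both probabilities", {
  v <- rbind(ann_variant(alt_normal = 0, depth_normal = 120),
             ann_variant(alt_normal = 55, depth_normal = 110))
  v$pos <- 1:2
  case <- make_case(v, purity_biopsy = 0.5, purity_resection = 0.5)
  out <- prioritize_variants(case, filter_policy(), seed = 5)
  expect_equal(nrow(out), 2L)
  expect_gt(out$prob_absent_normal[1], 0.99)
  expect_lt(out$prob_absent_normal[2], 0.01)
  expect_true(all(out$prob_vaf_changed >= 0 & out$prob_vaf_changed <= 1))
})
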