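test_that("robust maximal VAF follows the quantile convention", {
  # constant distribution: any quantile returns the constant
  v <- make_variants(vaf_resection = rep(0.40, 50), depth_resection = 100L)
  expect_equal(robust_max_vaf(v, "resection"), 0.40)

  # CNV-inflated outlier at 0.95 is cut off by a 0.75 quantile; expected
  # value frozen from an independent sorting oracle (sorted VAFs, linear
  # interpolation at h = (n-1)q + 1)
  vafs <- c(0.1, 0.2, 0.3, 0.4, 0.95)
  srt <- sort(vafs)
  h <- (length(srt) - 1) * 0.75 + 1
  oracle <- srt[floor(h)] + (h - floor(h)) * (srt[ceiling(h)] - srt[floor(h)])
  expect_equal(oracle, 0.40)
  v <- make_variants(vaf_resection = vafs, depth_resection = 100L)
  expect_equal(robust_max_vaf(v, "resection", quantile = 0.75), 0.40)

  # no qualifying variants -> unknown signal
  expect_true(is.na(robust_max_vaf(make_variants(n = 0), "resection")))
  low_depth <- make_variants(vaf_resection = 0.4, depth_resection = 10L)
  expect_true(is.na(robust_max_vaf(low_depth, "resection", min_depth = 30)))
  germline <- make_variants(vaf_resection = 0.5, depth_resection = 100L,
                            somatic_posterior = 0.5)
  expect_true(is.na(robust_max_vaf(germline, "resection")))
})

test_that("purity reconciliation matches the literal rule, exhaustively", {
  grid <- seq(0, 1, by = 0.05)
  for (v in grid) for (p1 in grid) for (p2 in grid[grid >= p1]) {
    got <- resolve_resection_purity(v, p1, p2)
    want <- oracle_resolve_purity(v, p1, p2)
    expect_identical(got$status, want$status)
    if (want$status == "known") expect_equal(got$value, want$value)
  }
  expect_error(resolve_resection_purity(0.4, 0.6, 0.3), "p1 <= p2")
})

test_that("spot checks of the reconciliation rule", {
  est <- resolve_resection_purity(0.35, 0.30, 0.45)
  expect_identical(est$status, "known")
  expect_equal(est$value, 0.35)
  expect_identical(resolve_resection_purity(0.35, 0.10, 0.60)$status,
                   "unknown")  # disagreement 0.50 > 0.2
  expect_identical(resolve_resection_purity(0.50, 0.30, 0.45)$status,
                   "unknown")  # v outside [p1, p2]
})

test_that("biopsy purity transfers by the median VAF ratio when shared", {
  # every biopsy VAF exactly half its resection VAF
  v <- make_variants(vaf_biopsy = seq(0.05, 0.20, length.out = 12),
                     vaf_resection = 2 * seq(0.05, 0.20, length.out = 12),
                     depth_biopsy = 200L, depth_resection = 200L)
  case <- make_case(v)
  est <- estimate_biopsy_purity(case, purity_estimate(0.40,
                                                      method = "vaf_max_consistent"))
  expect_equal(est$s, 2.0, tolerance = 0.05)
  expect_equal(est$value, 0.20, tolerance = 0.01)

  # identical distributions: s = 1, purity transfers unchanged
  v <- make_variants(vaf_biopsy = seq(0.1, 0.4, length.out = 15),
                     vaf_resection = seq(0.1, 0.4, length.out = 15))
  est <- estimate_biopsy_purity(make_case(v),
                                purity_estimate(0.40,
                                                method = "vaf_max_consistent"))
  expect_equal(est$s, 1.0)
  expect_equal(est$value, 0.40)

  # fewer than 3 nonzero biopsy VAFs -> unknown
  v <- make_variants(vaf_biopsy = c(0.2, 0.2, 0, 0),
                     vaf_resection = c(0.2, 0.2, 0.3, 0.3))
  est <- estimate_biopsy_purity(make_case(v),
                                purity_estimate(0.40,
                                                method = "vaf_max_consistent"))
  expect_identical(est$status, "unknown")
})

test_that("disjoint variant sets fall back to the Wasserstein grid", {
  set.seed(42)
  fr <- runif(40, 0.1, 0.8)
  fb <- fr * 0.5  # biopsy distribution uniformly shrunk by 0.5
  v <- make_variants(
    vaf_biopsy = c(fb, rep(0, 40)),
    vaf_resection = c(rep(0, 40), fr),
    depth_biopsy = 1000L, depth_resection = 1000L)
  est <- estimate_biopsy_purity(make_case(v),
                                purity_estimate(0.40,
                                                method = "vaf_max_consistent"))
  # brute-force distance over the same grid, independent exact-ECDF W1
  grid <- seq(0.1, 10, by = 0.05)
  fb_obs <- round(fb * 1000) / 1000
  fr_obs <- round(fr * 1000) / 1000
  dists <- vapply(grid, function(s) oracle_w1(s * fb_obs, fr_obs),
                  numeric(1))
  s_oracle <- grid[which.min(dists)]
  expect_equal(est$s, s_oracle, tolerance = 0.051)
  expect_equal(est$s, 2.0, tolerance = 0.11)  # within a grid step or two
})

test_that("the scaling factor is equivariant under rescaled biopsy VAFs", {
  set.seed(7)
  base_b <- runif(20, 0.05, 0.3)
  base_r <- base_b * runif(20, 1.4, 1.6)
  # median-ratio path: exact 1/c scaling (up to read-count rounding)
  v_half <- make_variants(vaf_biopsy = base_b * 0.5, vaf_resection = base_r,
                          depth_biopsy = 10000L, depth_resection = 10000L)
  v_full <- make_variants(vaf_biopsy = base_b, vaf_resection = base_r,
                          depth_biopsy = 10000L, depth_resection = 10000L)
  pr <- purity_estimate(0.40, method = "vaf_max_consistent")
  s_half <- estimate_biopsy_purity(make_case(v_half), pr)$s
  s_full <- estimate_biopsy_purity(make_case(v_full), pr)$s
  expect_equal(s_half, 2 * s_full, tolerance = 1e-2)
})

test_that("purity is recovered on simulated no-CNV data", {
  # light version of the recovery study (full version in the acceptance
  # suite): clonal cluster + subclones, deep coverage
  set.seed(99)
  errs <- vapply(1:25, function(i) {
    true_p <- runif(1, 0.2, 0.5)
    sim <- simulate_case(sim_params(
      n_clones = 6, mutations_per_clone = 50, kill_fraction = 0,
      spatial_miss_prob = 0, purity_biopsy = true_p,
      purity_resection = true_p, mean_depth_biopsy = 600,
      mean_depth_resection = 600, seed = 1000 + i))
    v <- robust_max_vaf(sim$case$variants, "resection")
    abs(v - true_p)
  }, numeric(1))
  expect_gte(mean(errs <= 0.05), 0.9)
})
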