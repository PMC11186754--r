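# Independent brute-force oracles. These deliberately re-derive every rule
# from first principles with plain loops and closed forms, sharing no code
# path with the package implementation.

# literal transcription of the purity reconciliation rule
oracle_resolve_purity <- function(v, p1, p2, max_disagreement = 0.2) {
  if (v >= p1 && v <= p2 && (p2 - p1) <= max_disagreement && v > 0)
    list(status = "known", value = v)
  else
    list(status = "unknown", value = NA_real_)
}

# exact 1-Wasserstein distance between empirical distributions by
# integrating |ECDF difference| over the pooled breakpoints
oracle_w1 <- function(x, y) {
  z <- sort(unique(c(x, y)))
  if (length(z) < 2L) return(0)
  Fx <- ecdf(x); Fy <- ecdf(y)
  mids <- z[-length(z)]
  widths <- diff(z)
  sum(abs(Fx(mids) - Fy(mids)) * widths)
}

# per-variant loop transcription of the subclone counting rules
oracle_classify <- function(variants, purity_b, purity_r,
                            posterior_min = 0.95, vaf_min = 0.1,
                            min_reads = 2) {
  n_lost <- n_gained <- n_retained <- 0L
  for (i in seq_len(nrow(variants))) {
    row <- variants[i, ]
    if (row$somatic_posterior < posterior_min) next
    adj_b <- if (row$depth_biopsy > 0)
      min(1, (row$alt_biopsy / row$depth_biopsy) / purity_b) else NA_real_
    adj_r <- if (row$depth_resection > 0)
      min(1, (row$alt_resection / row$depth_resection) / purity_r)
    else NA_real_
    qual_b <- !is.na(adj_b) && adj_b >= vaf_min &&
      adj_b * purity_r * row$depth_resection >= min_reads
    qual_r <- !is.na(adj_r) && adj_r >= vaf_min &&
      adj_r * purity_b * row$depth_biopsy >= min_reads
    if (!qual_b && !qual_r) next
    if (row$alt_resection == 0 && !is.na(adj_b) && adj_b >= vaf_min)
      n_lost <- n_lost + 1L
    else if (row$alt_biopsy == 0 && !is.na(adj_r) && adj_r >= vaf_min)
      n_gained <- n_gained + 1L
    else
      n_retained <- n_retained + 1L
  }
  n_total <- n_lost + n_gained + n_retained
  list(n_total = n_total, n_lost = n_lost, n_gained = n_gained,
       n_retained = n_retained,
       fraction_lost = if (n_total) n_lost / n_total else NA_real_,
       fraction_gained = if (n_total) n_gained / n_total else NA_real_)
}

# substitution classes from an explicit lookup, not from complementing
.oracle_snv_class <- c(
  "C>A" = "C>A", "G>T" = "C>A",
  "C>G" = "C>G", "G>C" = "C>G",
  "C>T" = "C>T", "G>A" = "C>T",
  "T>A" = "T>A", "A>T" = "T>A",
  "T>C" = "T>C", "A>G" = "T>C",
  "T>G" = "T>G", "A>C" = "T>G")

oracle_substitution <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    unname(.oracle_snv_class[paste0(ref, ">", alt)])
  else if (nchar(ref) == nchar(alt)) "MNV"
  else "complex"
}

# double loop over (threshold, variant)
oracle_spectrum <- function(variants, sample, vaf_grid, region_mb,
                            posterior_min = 0.95) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G", "complex", "MNV")
  out <- expand.grid(class = classes, vaf_threshold = vaf_grid,
                     stringsAsFactors = FALSE)
  out$count <- 0L
  for (k in seq_len(nrow(out))) {
    for (i in seq_len(nrow(variants))) {
      row <- variants[i, ]
      if (row$somatic_posterior < posterior_min) next
      depth <- row[[paste0("depth_", sample)]]
      if (depth == 0) next
      vaf <- row[[paste0("alt_", sample)]] / depth
      if (vaf >= out$vaf_threshold[k] &&
          oracle_substitution(row$ref, row$alt) == out$class[k])
        out$count[k] <- out$count[k] + 1L
    }
  }
  out$per_mb <- out$count / region_mb
  out[order(match(out$class, classes), out$vaf_threshold), ]
}

# high-replicate Monte-Carlo for the VAF-change probability
oracle_prob_changed <- function(alt_b, depth_b, purity_b,
                                alt_r, depth_r, purity_r,
                                delta = 0.05, n = 1e6) {
  fb <- rbeta(n, alt_b + 0.5, depth_b - alt_b + 0.5) / purity_b
  fr <- rbeta(n, alt_r + 0.5, depth_r - alt_r + 0.5) / purity_r
  mean(abs(fb - fr) > delta)
}

# brute-force read-noise simulation under a known clonal truth: how often
# does pure binomial sampling fabricate lost/gained subclones?
oracle_null_noise <- function(truth, mean_depth, n_reps, vaf_min = 0.1,
                              min_reads = 2) {
  prev_b <- truth$prevalence_biopsy[truth$clone_of[seq_len(truth$n_somatic)]]
  prev_r <- truth$prevalence_resection[truth$clone_of[seq_len(truth$n_somatic)]]
  pb <- truth$purity_biopsy; pr <- truth$purity_resection
  lost <- gained <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    db <- rpois(length(prev_b), mean_depth)
    dr <- rpois(length(prev_r), mean_depth)
    ab <- rbinom(length(prev_b), db, prev_b * pb)
    ar <- rbinom(length(prev_r), dr, prev_r * pr)
    n_l <- n_g <- n_ret <- 0L
    for (i in seq_along(ab)) {
      adj_b <- if (db[i] > 0) min(1, (ab[i] / db[i]) / pb) else NA_real_
      adj_r <- if (dr[i] > 0) min(1, (ar[i] / dr[i]) / pr) else NA_real_
      qual_b <- !is.na(adj_b) && adj_b >= vaf_min &&
        adj_b * pr * dr[i] >= min_reads
      qual_r <- !is.na(adj_r) && adj_r >= vaf_min &&
        adj_r * pb * db[i] >= min_reads
      if (!qual_b && !qual_r) next
      if (ar[i] == 0 && !is.na(adj_b) && adj_b >= vaf_min)
        n_l <- n_l + 1L
      else if (ab[i] == 0 && !is.na(adj_r) && adj_r >= vaf_min)
        n_g <- n_g + 1L
      else n_ret <- n_ret + 1L
    }
    tot <- n_l + n_g + n_ret
    lost[r] <- if (tot) n_l / tot else 0
    gained[r] <- if (tot) n_g / tot else 0
  }
  list(mean_lost = mean(lost), mean_gained = mean(gained),
       se_lost = sd(lost) / sqrt(n_reps),
       se_gained = sd(gained) / sqrt(n_reps))
}
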