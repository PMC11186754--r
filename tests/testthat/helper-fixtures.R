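# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

make_variants <- function(n = NULL,
                          vaf_biopsy = NULL, vaf_resection = NULL,
                          depth_biopsy = 100L, depth_resection = 100L,
                          somatic_posterior = 1,
                          ref = "C", alt = "T", ...) {
  if (is.null(n))
    n <- max(length(vaf_biopsy), length(vaf_resection), 1L)
  db <- rep_len(depth_biopsy, n); dr <- rep_len(depth_resection, n)
  fb <- if (is.null(vaf_biopsy)) rep(0, n) else rep_len(vaf_biopsy, n)
  fr <- if (is.null(vaf_resection)) rep(0, n) else rep_len(vaf_resection, n)
  df <- data.frame(
    chrom = rep_len("1", n), pos = seq_len(n) * 100L,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    depth_biopsy = db, alt_biopsy = as.integer(round(fb * db)),
    depth_resection = dr, alt_resection = as.integer(round(fr * dr)),
    somatic_posterior = rep_len(somatic_posterior, n),
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  df
}

make_case <- function(variants, p1 = 0.3, p2 = 0.45,
                      purity_biopsy = NULL, purity_resection = NULL,
                      patient_id = "TEST-001") {
  case <- patient_case(patient_id, variants, p1 = p1, p2 = p2)
  if (!is.null(purity_biopsy))
    case$purity_biopsy <- purity_estimate(purity_biopsy,
                                          method = "simulated_truth")
  if (!is.null(purity_resection))
    case$purity_resection <- purity_estimate(purity_resection,
                                             method = "simulated_truth")
  case
}

# hand-built six-subclone fixture: 2 biopsy-only, 1 resection-only,
# 3 shared; purities 0.5/0.5, depths 100
six_subclone_case <- function() {
  v <- make_variants(
    vaf_biopsy = c(0.20, 0.20, 0.00, 0.25, 0.25, 0.25),
    vaf_resection = c(0.00, 0.00, 0.30, 0.25, 0.25, 0.25))
  make_case(v, purity_biopsy = 0.5, purity_resection = 0.5)
}

# a random variant table with depths, posteriors and annotations
random_variants <- function(n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                character(1))
  db <- rpois(n, 150); dr <- rpois(n, 150)
  data.frame(
    chrom = "1", pos = sort(sample.int(1e6, n)), ref = ref, alt = alt,
    depth_biopsy = db, alt_biopsy = rbinom(n, db, runif(n, 0, 0.4)),
    depth_resection = dr, alt_resection = rbinom(n, dr, runif(n, 0, 0.4)),
    somatic_posterior = sample(c(1, 0.99, 0.5), n, replace = TRUE,
                               prob = c(0.7, 0.2, 0.1)),
    stringsAsFactors = FALSE)
}
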