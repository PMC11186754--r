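#' Simulation parameters for one paired-sample patient
#'
#' The generative model mirrors the assumptions of the inference: every
#' nonlethal somatic mutation founds one new subclone; clone cellular
#' prevalences are tree-consistent (a clone never outnumbers its parent);
#' therapy multiplies clone masses by survival factors; a biopsy can miss a
#' clone for purely spatial reasons; reads are binomial draws at Poisson
#' depths; purity is on the allele scale (the maximal attainable somatic
#' VAF), so expected VAF = clone prevalence x purity.
#'
#' @param n_clones number of clones including the truncal clone.
#' @param mutations_per_clone Poisson mean of mutations per clone; scalar
#'   or length-`n_clones` vector of per-clone means.
#' @param topology `"random"` (uniform random parent), `"star"` (all
#'   clones attach to the truncal clone) or `"chain"`.
#' @param concentration Dirichlet concentration of the recursive
#'   stick-breaking that partitions each clone's mass among its children
#'   and itself; larger values give more even splits.
#' @param prevalence_decay optional geometric decay ratio in `(0, 1)`;
#'   when set (chain topology), clone `i` receives deterministic subtree
#'   prevalence `prevalence_decay^(i-1)` instead of stick-breaking.
#' @param survival per-clone survival multipliers (length `n_clones`), or
#'   `NULL`; a multiplier of 0 kills the clone's whole subtree (descendant
#'   cells carry the ancestor's mutations).
#' @param kill_fraction alternatively, the fraction of non-truncal clones
#'   whose subtrees therapy kills (rounded; ignored when `survival` given).
#' @param spatial_miss_prob probability that a non-truncal clone's subtree
#'   is absent from the biopsy for spatial reasons.
#' @param purity_biopsy,purity_resection allele-scale purities in `(0, 1]`.
#' @param mean_depth_biopsy,mean_depth_resection Poisson depth means.
#' @param p_error half-width of the pathologist-prior noise: priors are
#'   `p1 = purity - U(0, p_error)`, `p2 = purity + U(0, p_error)`.
#' @param n_germline number of germline heterozygous contaminant records
#'   (expected VAF 0.5 in both samples, somatic posterior below 0.95).
#' @param seed integer seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_clones = 8L,
                       mutations_per_clone = 15,
                       topology = c("random", "star", "chain"),
                       concentration = 1,
                       prevalence_decay = NULL,
                       survival = NULL,
                       kill_fraction = 0.25,
                       spatial_miss_prob = 0.05,
                       purity_biopsy = 0.4,
                       purity_resection = 0.4,
                       mean_depth_biopsy = 300,
                       mean_depth_resection = 300,
                       p_error = 0.1,
                       n_germline = 10L,
                       seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_clones >= 1,
            all(mutations_per_clone >= 0),
            length(mutations_per_clone) %in% c(1L, n_clones),
            spatial_miss_prob >= 0, spatial_miss_prob <= 1,
            kill_fraction >= 0, kill_fraction <= 1,
            purity_biopsy > 0, purity_biopsy <= 1,
            purity_resection > 0, purity_resection <= 1,
            mean_depth_biopsy > 0, mean_depth_resection > 0,
            p_error >= 0, n_germline >= 0)
  if (!is.null(survival))
    stopifnot(length(survival) == n_clones, all(survival >= 0))
  if (!is.null(prevalence_decay))
    stopifnot(prevalence_decay > 0, prevalence_decay < 1)
  structure(as.list(environment()), class = "sim_params")
}

# random parent attachment respecting the chosen topology
.sim_tree <- function(n_clones, topology) {
  parent <- integer(n_clones)
  parent[1] <- 0L
  if (n_clones > 1L)
    parent[2:n_clones] <- switch(
      topology,
      random = vapply(2:n_clones, function(j)
        if (j == 2L) 1L else sample.int(j - 1L, 1L), integer(1)),
      star = 1L,
      chain = (2:n_clones) - 1L)
  parent
}

.descendants <- function(parent, j) {
  out <- j
  frontier <- j
  repeat {
    nxt <- which(parent %in% frontier)
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(unique(out))
}

# Exclusive masses (fraction of tumor cells whose most-derived clone is j)
# via recursive stick-breaking; subtree prevalence of j = sum of exclusive
# masses over j's subtree, so child prevalence <= parent prevalence.
.sim_exclusive_masses <- function(parent, concentration) {
  n <- length(parent)
  excl <- numeric(n)
  subtree_mass <- numeric(n)
  subtree_mass[1] <- 1
  for (j in seq_len(n)) {
    kids <- which(parent == j)
    k <- length(kids)
    if (k == 0L) {
      excl[j] <- subtree_mass[j]
    } else {
      w <- stats::rgamma(k + 1L, shape = concentration)
      w <- w / sum(w)
      excl[j] <- subtree_mass[j] * w[k + 1L]
      subtree_mass[kids] <- subtree_mass[j] * w[seq_len(k)]
    }
  }
  excl
}

.subtree_prevalence <- function(parent, excl) {
  vapply(seq_along(parent), function(j)
    sum(excl[.descendants(parent, j)]), numeric(1))
}

.phred <- function(p) {
  p <- pmax(p, 1e-100)
  round(-10 * log10(p), 4)
}

#' Simulate one paired biopsy/resection patient case with ground truth
#'
#' Draws a clone tree, tree-consistent pre-therapy prevalences, applies
#' therapy selection and spatial biopsy sampling, and generates binomial
#' read counts at Poisson depths for every clone mutation in both samples.
#' Identical seeds give bit-identical output.
#'
#' @param params a [sim_params()] object.
#' @param patient_id identifier for the generated case.
#' @return list with `case` (a [patient_case()]) and `truth` — clone tree
#'   (`parent`), per-variant clone assignment, pre/post cellular
#'   prevalences, biopsy-presence flags, true purities, and the true lost
#'   and gained variant sets plus ideal-observation (infinite depth)
#'   qualifying set and `fraction_lost` / `fraction_gained`.
#' @export
simulate_case <- function(params = sim_params(), patient_id = "SIM-001") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  p <- params
  parent <- .sim_tree(p$n_clones, p$topology)

  max_retry <- 20L; retry <- 0L
  repeat {
    if (!is.null(p$prevalence_decay)) {
      prev_pre <- p$prevalence_decay^(seq_len(p$n_clones) - 1)
      # exclusive mass of j = its subtree mass minus its children's
      excl_pre <- prev_pre - vapply(seq_len(p$n_clones), function(j)
        sum(prev_pre[which(parent == j)]), numeric(1))
      stopifnot(all(excl_pre >= -1e-12))
      excl_pre <- pmax(excl_pre, 0)
    } else {
      excl_pre <- .sim_exclusive_masses(parent, p$concentration)
    }

    survival <- p$survival
    if (is.null(survival)) {
      survival <- rep(1, p$n_clones)
      n_kill <- round(p$kill_fraction * (p$n_clones - 1L))
      if (n_kill > 0L) {
        killed <- sample(2:p$n_clones, n_kill)
        survival[killed] <- 0
      }
    }
    # a killed clone takes its whole subtree with it
    for (j in which(survival == 0))
      survival[.descendants(parent, j)] <- 0
    excl_post <- excl_pre * survival
    if (sum(excl_post) > 0) break
    retry <- retry + 1L
    if (retry > max_retry)
      stop("degenerate simulation: all tumor cells killed in ",
           max_retry, " consecutive draws")
    message("all clones killed post-therapy; redrawing prevalences (retry ",
            retry, ")")
  }
  excl_post <- excl_post / sum(excl_post)

  # spatial sampling: the biopsy misses whole non-truncal subtrees
  biopsy_present <- rep(TRUE, p$n_clones)
  if (p$n_clones > 1L && p$spatial_miss_prob > 0) {
    for (j in 2:p$n_clones)
      if (stats::runif(1) < p$spatial_miss_prob)
        biopsy_present[.descendants(parent, j)] <- FALSE
  }
  excl_biopsy <- excl_pre * biopsy_present
  if (sum(excl_biopsy) == 0) {  # biopsy must hit the truncal clone at least
    biopsy_present[1] <- TRUE
    excl_biopsy <- excl_pre * biopsy_present
  }
  excl_biopsy <- excl_biopsy / sum(excl_biopsy)

  prev_biopsy <- .subtree_prevalence(parent, excl_biopsy)
  prev_resection <- .subtree_prevalence(parent, excl_post)
  prev_pre_full <- .subtree_prevalence(parent, excl_pre)

  mu <- if (length(p$mutations_per_clone) == 1L)
    rep(p$mutations_per_clone, p$n_clones) else p$mutations_per_clone
  n_mut <- stats::rpois(p$n_clones, mu)
  if (sum(n_mut) == 0) n_mut[1] <- 1L  # at least one somatic variant
  clone_of <- rep(seq_len(p$n_clones), n_mut)
  n_som <- length(clone_of)

  evaf_b <- prev_biopsy[clone_of] * p$purity_biopsy
  evaf_r <- prev_resection[clone_of] * p$purity_resection
  posterior <- rep(1, n_som)

  n_all <- n_som + p$n_germline
  if (p$n_germline > 0L) {
    evaf_b <- c(evaf_b, rep(0.5, p$n_germline))
    evaf_r <- c(evaf_r, rep(0.5, p$n_germline))
    posterior <- c(posterior, stats::runif(p$n_germline, 0, 0.9))
    clone_of <- c(clone_of, rep(NA_integer_, p$n_germline))
  }

  depth_b <- stats::rpois(n_all, p$mean_depth_biopsy)
  depth_r <- stats::rpois(n_all, p$mean_depth_resection)
  alt_b <- stats::rbinom(n_all, depth_b, evaf_b)
  alt_r <- stats::rbinom(n_all, depth_r, evaf_r)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_all, replace = TRUE)
  alt_allele <- vapply(ref, function(r)
    sample(setdiff(bases, r), 1L), character(1))

  variants <- data.frame(
    chrom = "1",
    pos = sort(sample.int(2.4e8, n_all)),
    ref = ref, alt = alt_allele,
    depth_biopsy = depth_b, alt_biopsy = alt_b,
    depth_resection = depth_r, alt_resection = alt_r,
    somatic_posterior = posterior,
    stringsAsFactors = FALSE)

  e1 <- stats::runif(1, 0, p$p_error); e2 <- stats::runif(1, 0, p$p_error)
  p1 <- max(0, p$purity_resection - e1)
  p2 <- min(1, p$purity_resection + e2)
  regression <- round(100 * stats::runif(1)^0.5, 1)

  case <- patient_case(patient_id, variants, p1 = p1, p2 = p2,
                       regression_percent = regression)

  # ideal (infinite depth, zero read noise) observation truth for the
  # somatic variants, on the cellular-prevalence scale
  som <- seq_len(n_som)
  cell_b <- prev_biopsy[clone_of[som]]
  cell_r <- prev_resection[clone_of[som]]
  ideal_qual <- cell_b >= 0.1 | cell_r >= 0.1
  true_lost <- som[ideal_qual & cell_r == 0 & cell_b >= 0.1]
  true_gained <- som[ideal_qual & cell_b == 0 & cell_r >= 0.1]
  n_q <- sum(ideal_qual)

  truth <- list(
    parent = parent,
    clone_of = clone_of,
    n_somatic = n_som,
    excl_pre = excl_pre,
    prevalence_pre = prev_pre_full,
    prevalence_biopsy = prev_biopsy,
    prevalence_resection = prev_resection,
    biopsy_present = biopsy_present,
    survival = survival,
    purity_biopsy = p$purity_biopsy,
    purity_resection = p$purity_resection,
    ideal_qualifying = som[ideal_qual],
    true_lost = true_lost,
    true_gained = true_gained,
    fraction_lost = if (n_q) length(true_lost) / n_q else NA_real_,
    fraction_gained = if (n_q) length(true_gained) / n_q else NA_real_)
  list(case = case, truth = truth)
}

#' Simulate a cohort of paired-sample patients
#'
#' Derives one deterministic sub-seed per patient from the master seed, so
#' the whole cohort is reproducible and patients are independent streams.
#' Optionally writes each patient's multi-sample VCF plus a cohort priors
#' CSV and a ground-truth JSON to a directory in the dialect
#' [read_paired_case()] reads.
#'
#' @param n_patients cohort size.
#' @param params a [sim_params()] template (its `seed` is replaced by the
#'   per-patient sub-seed), or a list of `n_patients` such templates.
#' @param seed master seed.
#' @param dir output directory, or `NULL` to skip writing.
#' @return list of `list(case, truth)` per patient; when `dir` is given,
#'   attribute `files` names the written VCFs.
#' @export
simulate_cohort <- function(n_patients, params = sim_params(), seed = 1L,
                            dir = NULL) {
  stopifnot(n_patients >= 1)
  per_patient <- if (inherits(params, "sim_params"))
    rep(list(params), n_patients)
  else {
    stopifnot(length(params) == n_patients)
    params
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_patients)
  sims <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pp <- per_patient[[i]]
    pp$seed <- sub_seeds[i]
    sims[[i]] <- simulate_case(pp, patient_id = sprintf("SIM-%03d", i))
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(sims, function(s) {
      f <- file.path(dir, paste0(s$case$patient_id, ".vcf"))
      write_case_vcf(s$case, f)
      f
    }, character(1))
    priors <- data.frame(
      patient_id = vapply(sims, function(s) s$case$patient_id, character(1)),
      p1 = vapply(sims, function(s) s$case$p1, numeric(1)),
      p2 = vapply(sims, function(s) s$case$p2, numeric(1)),
      regression_percent = vapply(sims, function(s)
        s$case$regression_percent, numeric(1)))
    utils::write.csv(priors, file.path(dir, "priors.csv"),
                     row.names = FALSE, quote = FALSE)
    truths <- lapply(sims, function(s) s$truth)
    names(truths) <- priors$patient_id
    jsonlite::write_json(truths, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(sims, "files") <- files
  }
  sims
}
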