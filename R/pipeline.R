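#' Default analysis thresholds
#'
#' The decision constants of the whole analysis in one place: somatic
#' posterior at least 0.95, purity-adjusted VAF at least 0.1, expected
#' detectability of at least two reads in the other sample, pathologist
#' disagreement at most 0.2, VAF quantile 0.98 with a 30x depth floor for
#' the purity edge, 1.94 Mb targeted footprint, REVEL-style score above
#' 0.5, population AF below 0.2, and a 0.05 cellular-frequency difference
#' for the VAF-change probability.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(posterior_min = 0.95, vaf_min = 0.1, min_reads = 2,
       max_disagreement = 0.2, quantile = 0.98, min_depth = 30L,
       region_mb = 1.94, revel_min = 0.5, gnomad_max = 0.2,
       delta = 0.05, n_draws = 20000L)
}

#' Run the full paired-sample subclonal analysis
#'
#' Orchestrates reading, purity estimation, subclone dynamics, spectrum
#' curves and variant prioritization for a cohort, writing a fixed output
#' layout: `purity.tsv`, `cohort_dynamics.tsv`, `exclusions.tsv`,
#' `spectrum.tsv`, `prioritization.tsv` and `manifest.json` (config echo,
#' package version, seed). Per-patient read failures are logged to the
#' exclusion table and the run continues.
#'
#' @param config named list (or path to a YAML file with the same keys):
#'   `vcfs` — named character vector, patient id to VCF path (or a
#'   directory `vcf_dir` holding `<patient_id>.vcf`); `priors` — path to
#'   the priors CSV ([read_priors()]); `sample_names` — VCF column names
#'   (default `biopsy`, `resection`); `annotations` — optional sidecar
#'   TSV; `gene_list` — optional path to a plain-text gene list;
#'   `thresholds` — overrides of [default_thresholds()]; `seed`;
#'   `out_dir`.
#' @return list with the cohort summary, spectra, prioritization table and
#'   output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$priors),
            !is.null(config$out_dir))
  th <- utils::modifyList(default_thresholds(),
                          as.list(config$thresholds))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  sample_names <- if (is.null(config$sample_names))
    list(biopsy = "biopsy", resection = "resection")
  else as.list(config$sample_names)

  priors <- read_priors(config$priors)
  vcfs <- config$vcfs
  if (is.null(vcfs)) {
    if (is.null(config$vcf_dir))
      stop("config must give 'vcfs' or 'vcf_dir'")
    vcfs <- file.path(config$vcf_dir, paste0(priors$patient_id, ".vcf"))
    names(vcfs) <- priors$patient_id
  }
  gene_list <- if (!is.null(config$gene_list))
    readLines(config$gene_list, warn = FALSE)

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cases <- list(); failed <- list()
  for (pid in priors$patient_id) {
    row <- priors[priors$patient_id == pid, ][1, ]
    case <- tryCatch({
      case <- read_paired_case(
        vcfs[[pid]], sample_names,
        priors = c(row$p1, row$p2),
        regression = row$regression_percent, patient_id = pid)
      if (!is.null(config$annotations))
        case <- annotate_case(case, config$annotations)
      case
    }, error = function(e) {
      message("patient ", pid, " skipped: ", conditionMessage(e))
      failed[[length(failed) + 1L]] <<-
        data.frame(patient_id = pid, reason = "unreadable_input")
      NULL
    })
    if (!is.null(case)) {
      case <- estimate_purities(case, quantile = th$quantile,
                                min_depth = th$min_depth,
                                max_disagreement = th$max_disagreement)
      cases[[pid]] <- case
    }
  }

  cohort <- summarize_cohort(cases, posterior_min = th$posterior_min,
                             vaf_min = th$vaf_min,
                             min_reads = th$min_reads)
  exclusions <- rbind(if (length(failed)) do.call(rbind, failed),
                      cohort$exclusions)

  purity_rows <- do.call(rbind, lapply(cases, function(case) {
    fmt <- function(est, sample) data.frame(
      patient_id = case$patient_id, sample = sample,
      value = if (est$status == "known") est$value else NA_real_,
      status = est$status, method = est$method, v = est$v, s = est$s,
      stringsAsFactors = FALSE)
    rbind(fmt(case$purity_biopsy, "biopsy"),
          fmt(case$purity_resection, "resection"))
  }))

  spectra <- do.call(rbind, unlist(lapply(cases, function(case)
    lapply(c("biopsy", "resection"), function(s) {
      sc <- spectrum_curve(case$variants, s, region_mb = th$region_mb,
                           posterior_min = th$posterior_min)
      cbind(patient_id = case$patient_id, as.data.frame(sc))
    })), recursive = FALSE))

  policy <- filter_policy(revel_min = th$revel_min,
                          gnomad_max = th$gnomad_max,
                          gene_list = gene_list)
  prioritized <- do.call(rbind, lapply(seq_along(cases), function(i) {
    p <- prioritize_variants(cases[[i]], policy, delta = th$delta,
                             n_draws = th$n_draws, seed = seed + i)
    if (nrow(p)) cbind(patient_id = cases[[i]]$patient_id, p)
  }))

  paths <- list(
    purity = file.path(out_dir, "purity.tsv"),
    dynamics = file.path(out_dir, "cohort_dynamics.tsv"),
    exclusions = file.path(out_dir, "exclusions.tsv"),
    spectrum = file.path(out_dir, "spectrum.tsv"),
    prioritization = file.path(out_dir, "prioritization.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  wt <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  wt(purity_rows, paths$purity)
  write_cohort_table(cohort, paths$dynamics)
  wt(exclusions, paths$exclusions)
  wt(spectra, paths$spectrum)
  if (is.null(prioritized))
    prioritized <- data.frame(patient_id = character())
  wt(prioritized, paths$prioritization)
  jsonlite::write_json(
    list(config = config[setdiff(names(config), "vcfs")],
         vcfs = as.list(vcfs),
         thresholds = th, seed = seed,
         package_version = as.character(utils::packageVersion("subclonedyn")),
         n_patients_in = nrow(priors),
         n_patients_analyzable = nrow(cohort$table)),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, purity = purity_rows, spectra = spectra,
                 prioritization = prioritized, exclusions = exclusions,
                 paths = paths))
}

#' Simulate a small demo cohort and run the pipeline end to end
#'
#' @param dir workspace directory (created); simulated inputs go to
#'   `dir/input`, pipeline outputs to `dir/output`.
#' @param n_patients cohort size (default 6).
#' @param seed master seed.
#' @param params a [sim_params()] template.
#' @return the [run_pipeline()] result, invisibly.
#' @export
make_demo <- function(dir = tempfile("subclonedyn_demo_"),
                      n_patients = 6L, seed = 1L,
                      params = sim_params()) {
  input <- file.path(dir, "input")
  simulate_cohort(n_patients, params, seed = seed, dir = input)
  run_pipeline(list(
    vcf_dir = input,
    priors = file.path(input, "priors.csv"),
    seed = seed,
    out_dir = file.path(dir, "output")))
}
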