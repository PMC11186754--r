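test_that("a written cohort re-reads with identical counts and VAFs", {
  sims <- simulate_cohort(3, sim_params(seed = 1), seed = 11,
                          dir = tmp <- tempfile("cohort_"))
  for (s in sims) {
    path <- file.path(tmp, paste0(s$case$patient_id, ".vcf"))
    back <- read_paired_case(path,
                             list(biopsy = "biopsy",
                                  resection = "resection"),
                             priors = c(s$case$p1, s$case$p2))
    v0 <- s$case$variants; v1 <- back$variants
    expect_identical(nrow(v1), nrow(v0))
    expect_identical(v1$alt_biopsy, as.numeric(v0$alt_biopsy))
    expect_identical(v1$depth_resection, as.numeric(v0$depth_resection))
    expect_equal(v1$vaf_biopsy, v0$vaf_biopsy, tolerance = 1e-12)
    expect_equal(v1$vaf_resection, v0$vaf_resection, tolerance = 1e-12)
    expect_equal(v1$somatic_posterior, v0$somatic_posterior,
                 tolerance = 1e-4)
    expect_identical(v1$ref, v0$ref)
    expect_identical(v1$alt, v0$alt)
  }
  unlink(tmp, recursive = TRUE)
})

test_that("VAFs are alt over depth and sample columns are validated", {
  case <- make_case(make_variants(vaf_biopsy = 0.10, depth_biopsy = 50L))
  expect_equal(case$variants$vaf_biopsy, 0.10)

  sims <- simulate_cohort(1, sim_params(seed = 2, n_clones = 2,
                                        mutations_per_clone = 3),
                          seed = 5, dir = tmp <- tempfile())
  path <- attr(sims, "files")[1]
  expect_error(
    read_paired_case(path, list(biopsy = "nope", resection = "resection")),
    "sample column")
  expect_error(
    read_paired_case(path, list(biopsy = "biopsy")), "resection")
  unlink(tmp, recursive = TRUE)
})

test_that("a missing somatic-probability tag defaults to 1.0 with a warning", {
  sim <- simulate_case(sim_params(seed = 3, n_clones = 2,
                                  mutations_per_clone = 4, n_germline = 0))
  path <- tempfile(fileext = ".vcf")
  write_case_vcf(sim$case, path)
  lines <- readLines(path)
  lines <- lines[!grepl("^##INFO", lines)]
  lines <- sub("PROB_SOMATIC=[^\t]*", ".", lines)
  writeLines(lines, path)
  expect_warning(
    case <- read_paired_case(path, list(biopsy = "biopsy",
                                        resection = "resection")),
    "somatic posterior set to 1.0")
  expect_true(all(case$variants$somatic_posterior == 1))
  unlink(path)
})

test_that("multi-allelic records are split into atomic variants", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    paste0("##INFO=<ID=PROB_SOMATIC,Number=1,Type=Float,",
           "Description=\"test\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "biopsy", "resection"), collapse = "\t"),
    paste("1", "100", ".", "A", "C,G", ".", "PASS", "PROB_SOMATIC=0",
          "DP:AD", "60:40,12,8", "50:30,15,5", sep = "\t")), path)
  case <- read_paired_case(path, list(biopsy = "biopsy",
                                      resection = "resection"))
  expect_equal(nrow(case$variants), 2L)
  expect_setequal(case$variants$alt, c("C", "G"))
  expect_equal(case$variants$alt_biopsy[case$variants$alt == "C"], 12)
  expect_equal(case$variants$alt_biopsy[case$variants$alt == "G"], 8)
  unlink(path)
})

test_that("depth-0 records are retained with undefined VAF", {
  v <- make_variants(vaf_biopsy = c(0.2, 0),
                     depth_biopsy = c(100L, 0L),
                     vaf_resection = c(0.2, 0),
                     depth_resection = c(100L, 0L))
  tab <- variant_table(v)
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$vaf_biopsy[2]) && is.na(tab$vaf_resection[2]))
})

test_that("cohort table has the documented columns and filter semantics", {
  sims <- simulate_cohort(5, sim_params(seed = 4), seed = 21)
  cases <- lapply(sims, function(s) {
    case <- s$case
    case$purity_biopsy <- purity_estimate(s$truth$purity_biopsy,
                                          method = "simulated_truth")
    case$purity_resection <- purity_estimate(s$truth$purity_resection,
                                             method = "simulated_truth")
    case
  })
  # force one exclusion for unknown purity
  cases[[2]]$purity_resection <- purity_estimate(method = "vaf_max_consistent")
  cohort <- summarize_cohort(cases)
  path <- tempfile(fileext = ".tsv")
  write_cohort_table(cohort, path)
  tab <- read.delim(path)
  expect_named(tab, c("patient_id", "regression_percent", "n_total",
                      "n_resection", "n_lost", "n_gained", "n_retained",
                      "fraction_lost", "fraction_gained",
                      "purity_biopsy", "purity_biopsy_status",
                      "purity_resection", "purity_resection_status"))
  expect_false("SIM-002" %in% tab$patient_id)
  expect_true("SIM-002" %in% cohort$exclusions$patient_id)

  # empty cohort -> header-only file
  write_cohort_table(summarize_cohort(list()), path)
  expect_equal(length(readLines(path)), 1L)
  unlink(path)
})
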