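#!/usr/bin/env Rscript
# Count qualifying subclones per patient and classify them as lost,
# gained or retained between biopsy and resection; write the cohort
# dynamics table (the data behind a per-patient bubble plot) and the
# exclusion log.

library(subclonedyn)

input_dir <- "results/sim/input"
priors <- read_priors(file.path(input_dir, "priors.csv"))
truth <- jsonlite::read_json(file.path(input_dir, "truth.json"))

cases <- lapply(priors$patient_id, function(pid) {
  row <- priors[priors$patient_id == pid, ]
  estimate_purities(read_paired_case(
    file.path(input_dir, paste0(pid, ".vcf")),
    list(biopsy = "biopsy", resection = "resection"),
    priors = c(row$p1, row$p2),
    regression = row$regression_percent, patient_id = pid))
})

cohort <- summarize_cohort(cases)
write_cohort_table(cohort, "results/cohort_dynamics.tsv")
write.table(cohort$exclusions, "results/exclusions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- cohort$table
cat(sprintf("%d of %d patients analyzable (%d excluded: %s)\n",
            nrow(tab), nrow(priors), nrow(cohort$exclusions),
            paste(cohort$exclusions$reason, collapse = ", ")))
cat(sprintf("subclones per patient: median %d; fraction lost: mean %.2f; ",
            as.integer(median(tab$n_total)), mean(tab$fraction_lost)),
    sprintf("fraction gained: mean %.2f\n", mean(tab$fraction_gained)))

ideal <- vapply(tab$patient_id, function(pid)
  truth[[pid]]$fraction_lost, numeric(1))
cat(sprintf(
  "mean |inferred - ideal-observation| fraction lost: %.3f\n",
  mean(abs(tab$fraction_lost - ideal), na.rm = TRUE)))
cat("wrote results/cohort_dynamics.tsv, results/exclusions.tsv\n")
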