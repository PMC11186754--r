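#!/usr/bin/env Rscript
# Filter variants to reportable candidate resistance events and score the
# evidence that their VAF changed under therapy. The simulator emits no
# functional annotations, so synthetic annotations (consequence,
# pathogenicity score, population AF, gene symbol drawn from the toy
# cancer-gene list) are attached here before filtering.

library(subclonedyn)

input_dir <- "results/sim/input"
priors <- read_priors(file.path(input_dir, "priors.csv"))
genes <- readLines(system.file("extdata", "cancer_genes_toy.txt",
                               package = "subclonedyn"))
set.seed(20260924)

reports <- list()
for (pid in priors$patient_id) {
  row <- priors[priors$patient_id == pid, ]
  case <- estimate_purities(read_paired_case(
    file.path(input_dir, paste0(pid, ".vcf")),
    list(biopsy = "biopsy", resection = "resection"),
    priors = c(row$p1, row$p2), patient_id = pid))
  v <- case$variants
  n <- nrow(v)
  v$consequence <- sample(c("missense_variant", "synonymous_variant",
                            "stop_gained", "intron_variant"),
                          n, replace = TRUE, prob = c(0.5, 0.3, 0.1, 0.1))
  v$pathogenicity_score <- ifelse(runif(n) < 0.8, runif(n), NA_real_)
  v$population_af <- rbeta(n, 0.2, 5)
  v$clinical_significance <- sample(
    c(NA_character_, "pathogenic", "benign", "likely_benign"),
    n, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
  v$gene <- sample(c(genes, "OFFPANEL1", "OFFPANEL2"), n, replace = TRUE)
  case$variants <- variant_table(v)
  rep <- prioritize_variants(case, filter_policy(gene_list = genes),
                             seed = 1000 + match(pid, priors$patient_id))
  log <- attr(rep, "rejection_log")
  cat(sprintf("%s: %d of %d variants reportable (rejected: %s)\n",
              pid, nrow(rep), n,
              paste(sprintf("%s=%d", log$reason, log$n), collapse = " ")))
  if (nrow(rep)) reports[[pid]] <- cbind(patient_id = pid, rep)
}

report <- do.call(rbind, reports)
write.table(report, "results/prioritization.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
changed <- report[!is.na(report$prob_vaf_changed) &
                    report$prob_vaf_changed > 0.95, ]
cat(sprintf(
  "%d reportable variants cohort-wide; %d with P(VAF changed) > 0.95\n",
  nrow(report), nrow(changed)))
cat("wrote results/prioritization.tsv\n")
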