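#!/usr/bin/env Rscript
# Mutations-per-megabase curves as a function of minimal VAF, stratified
# by substitution class, for both samples of every patient.

library(subclonedyn)

input_dir <- "results/sim/input"
priors <- read_priors(file.path(input_dir, "priors.csv"))

spectra <- do.call(rbind, unlist(lapply(priors$patient_id, function(pid) {
  row <- priors[priors$patient_id == pid, ]
  case <- read_paired_case(file.path(input_dir, paste0(pid, ".vcf")),
                           list(biopsy = "biopsy",
                                resection = "resection"),
                           priors = c(row$p1, row$p2), patient_id = pid)
  lapply(c("biopsy", "resection"), function(s)
    cbind(patient_id = pid,
          as.data.frame(spectrum_curve(case$variants, s))))
}), recursive = FALSE))

write.table(spectra, "results/spectrum.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

at0 <- spectra[spectra$vaf_threshold == 0, ]
dens <- tapply(at0$per_mb, list(at0$patient_id, at0$sample), sum)
cat("total mutation density (per Mb) at threshold 0:\n")
print(round(dens, 1))
cat("wrote results/spectrum.tsv\n")
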