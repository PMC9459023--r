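#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: 18 patients, ~47 inspected sites with
# replicate Raman acquisitions (FP + HW), co-registered T2/ADC/b2000 volumes,
# per-patient registration transforms and site-level histology. Writes the
# site table, one example acquisition, volumes and transforms under results/.
suppressMessages(library(ramrad))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

config <- synthetic_config(seed = seed)
cohort <- generate_cohort(config)

write_site_table(cohort$sites, file.path(out, "sites.tsv"))
# write one patient's imaging and one acquisition set as format examples;
# the full cohort travels to the next step as the working .rds object
pid <- names(cohort$volumes)[1]
for (mod in c("T2", "ADC", "b2000")) {
  write_volume(cohort$volumes[[pid]][[mod]],
               file.path(out, sprintf("%s_%s.nii", pid, mod)))
}
write_transform(cohort$transforms[[pid]],
                file.path(out, sprintf("%s_transform.json", pid)))
sid <- cohort$sites$site_id[1]
write_spectra_csv(cohort$raman[[sid]]$FP,
                  file.path(out, sprintf("%s_FP.csv", sid)))
saveRDS(cohort, "results/cohort.rds")  # working object for later steps

cat(sprintf("cohort: %d patients, %d sites (%d tumor, %d benign)\n",
            length(cohort$volumes), nrow(cohort$sites),
            sum(cohort$sites$isup_gg > 0), sum(cohort$sites$isup_gg == 0)))
cat(sprintf("class counts (GG0..GG4): %s\n",
            paste(table(factor(cohort$sites$isup_gg, levels = 0:4)),
                  collapse = " ")))
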