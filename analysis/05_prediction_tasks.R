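#!/usr/bin/env Rscript
# Experiment 3: retrain on the consensus feature set only (selection
# bypassed) under three labelings — clinically significant cancer (GG > 1),
# any cancer (GG >= 1) and high-grade (tumor sites under 20% high-grade
# pattern excluded) — and compare operating-point metrics.
suppressMessages(library(ramrad))

cohort <- readRDS("results/cohort.rds")
ft <- readRDS("results/features.rds")
cons <- read.delim("results/consensus_features.tsv")

res <- prediction_task_experiment(ft, cohort$sites,
                                  features = cons$feature)
write.table(res$report, "results/prediction_tasks.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("prediction tasks on the %d consensus features:\n", nrow(cons)))
print(res$report, digits = 3, row.names = FALSE)
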