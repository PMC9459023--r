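#!/usr/bin/env Rscript
# Preprocess every site's replicate spectra (cosmic-ray rejection, averaging,
# baseline removal, SNV) and extract the 48 co-located radiomics features,
# assembling the full 4650-column multimodal feature table.
suppressMessages(library(ramrad))

cohort <- readRDS("results/cohort.rds")
ft <- cohort_feature_table(cohort)
write_feature_table(ft, "results/features.tsv")
saveRDS(ft, "results/features.rds")

cat(sprintf("feature table: %d sites x %d features\n", nrow(ft$X), ncol(ft$X)))
cat(sprintf("  FP %d | HW %d | Rad %d\n", sum(ft$modality == "FP"),
            sum(ft$modality == "HW"), sum(ft$modality == "Rad")))
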