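#!/usr/bin/env Rscript
# Step 2 - raw-signal normalization and calibration with QC acceptance.
#
# Reads the raw ADAT-dialect files written by step 1, runs the five-step
# chain (hybridization controls -> intraplate medians -> plate scaling ->
# calibration -> median normalization to the reference) per cohort, and
# writes normalized ADATs plus QC reports.

suppressMessages(library(somastrat))
dir.create("results/normalized", recursive = TRUE, showWarnings = FALSE)

for (cohort in c("derivation", "validation")) {
  tab <- read_adat(file.path("results/data", cohort, "cohort.adat"))
  res <- normalize_pipeline(tab)
  cat("==", cohort, "==\n")
  print(res$report)
  write_adat(res$table, file.path("results/normalized",
                                  paste0(cohort, ".adat")))
  jsonlite::write_json(
    list(pass = res$report$pass,
         qc_fraction = res$report$qc_fraction,
         factor_checks = res$report$factor_checks,
         plate_scale = res$factors$plate_scale),
    file.path("results/normalized", paste0("qc_", cohort, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(res$factors$hyb,
                     file.path("results/normalized",
                               paste0("factors_hyb_", cohort, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote results/normalized/\n")
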