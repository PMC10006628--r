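#!/usr/bin/env Rscript
# Step 3 - SOMAmer cleanup, protein aggregation, log2, derivation-anchored
# standardization, clinical imputation.
#
# Flagged SOMAmers are dropped, multi-SOMAmer proteins averaged on the RFU
# scale, values log2-transformed, and per-protein (mean, SD) estimated on
# the DERIVATION cohort only; both cohorts are standardized with those
# parameters so a validation patient lives in derivation units. Clinical
# tables are completed by rank-2 iterative low-rank imputation.

suppressMessages(library(somastrat))
dir.create("results/matrices", recursive = TRUE, showWarnings = FALSE)

log2_matrix <- function(cohort) {
  tab <- read_adat(file.path("results/normalized", paste0(cohort, ".adat")))
  out <- read_outcomes(file.path("results/data", cohort, "outcomes.tsv"))
  pm <- aggregate_to_proteins(remove_flagged(tab))
  pm <- pm[match(as.character(out$patient_id), rownames(pm)), ]
  log2_transform(somastrat:::protein_matrix(pm, "rfu"))
}

lg_d <- log2_matrix("derivation")
lg_v <- log2_matrix("validation")
params <- fit_standardization(lg_d)
write_standardization(params, "results/matrices/standardization.tsv")
z_d <- apply_standardization(lg_d, params)
z_v <- apply_standardization(lg_v, params)
cat(sprintf("standardized matrices: %d x %d (derivation), %d x %d (validation)\n",
            nrow(z_d), ncol(z_d), nrow(z_v), ncol(z_v)))
cat(sprintf("derivation column means in [%.2g, %.2g] (exactly 0 by construction)\n",
            min(colMeans(z_d)), max(colMeans(z_d))))

save_matrix <- function(m, path) {
  df <- data.frame(patient_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
save_matrix(z_d, "results/matrices/derivation_std.tsv")
save_matrix(z_v, "results/matrices/validation_std.tsv")

for (cohort in c("derivation", "validation")) {
  clin <- read_clinical(file.path("results/data", cohort, "clinical.tsv"))
  n_miss <- sum(is.na(clin[setdiff(names(clin), "patient_id")]))
  filled <- impute_clinical(clin)
  cat(sprintf("%s clinical: imputed %d missing cells (converged: %s)\n",
              cohort, n_miss, attr(filled, "converged")))
  utils::write.table(filled,
                     file.path("results/matrices",
                               paste0("clinical_", cohort, "_imputed.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote results/matrices/\n")
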