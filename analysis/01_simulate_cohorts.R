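#!/usr/bin/env Rscript
# Step 1 - generate the synthetic derivation and validation cohorts.
#
# The derivation cohort has 254 patients on 3 plates (320 analyte SOMAmers,
# 20 flagged for removal, 20 proteins on multiple SOMAmers); the validation
# cohort has 238 patients and reuses the same protein structure (baseline
# means, informative set, SOMAmer map), so the two cohorts measure the same
# panel. Outputs go to results/data/.

suppressMessages(library(somastrat))

cfg_deriv <- sim_config(seed = 20260101L)
cfg_valid <- cfg_deriv
cfg_valid$n_patients <- 238L
cfg_valid$seed <- 20260102L

deriv <- simulate_cohort(cfg_deriv)
valid <- simulate_cohort(cfg_valid, structure = deriv$structure)

cat("derivation cohort:\n")
print(deriv)
cat("validation cohort:\n")
print(valid)

write_cohort(deriv, "results/data/derivation")
write_cohort(valid, "results/data/validation")

cat("\nEvent counts (cause 0 = censored, 1 = HF hospitalization, 2 = death):\n")
cat("  derivation:", table(deriv$outcomes$cause), "\n")
cat("  validation:", table(valid$outcomes$cause), "\n")
cat("wrote results/data/{derivation,validation}/{cohort.adat,clinical.tsv,outcomes.tsv,truth.json}\n")
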