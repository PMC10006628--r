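#!/usr/bin/env Rscript
# Step 5 - patient stratification on the selected proteins.
#
# k-means (25 restarts) on the derivation cohort for k = 2..6, keeping the
# k with the largest overall average silhouette width; the cluster with the
# higher crude HF incidence is labelled group 2. Validation patients are
# assigned to the frozen centroids by nearest Euclidean distance. Group
# differences in clinical variables are tested with Welch / chi-square.

suppressMessages(library(somastrat))
dir.create("results/groups", recursive = TRUE, showWarnings = FALSE)

load_std <- function(cohort) {
  df <- utils::read.delim(file.path("results/matrices",
                                    paste0(cohort, "_std.tsv")),
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$patient_id
  m
}
sel <- unlist(jsonlite::read_json("results/screen/summary.json")$selected)
z_d <- load_std("derivation")[, sel, drop = FALSE]
z_v <- load_std("validation")[, sel, drop = FALSE]
out_d <- read_outcomes("results/data/derivation/outcomes.tsv")

model <- select_k(z_d, k_range = 2:6, seed = 20260105L, n_restarts = 25L)
model <- order_groups_by_risk(model, out_d)
print(model)
labels_v <- assign_groups(z_v, model$centroids)
cat("validation group sizes:", table(factor(labels_v, levels = 1:2)), "\n")

jsonlite::write_json(
  list(k = model$k, proteins = colnames(model$centroids),
       centroids = model$centroids,
       silhouette_by_k = as.list(model$silhouette_by_k),
       seed = model$seed, n_restarts = model$n_restarts),
  "results/groups/cluster_model.json", auto_unbox = TRUE, digits = NA)
utils::write.table(data.frame(patient_id = rownames(z_d),
                              group = model$labels),
                   "results/groups/groups_derivation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(patient_id = rownames(z_v), group = labels_v),
                   "results/groups/groups_validation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# heatmap export: patients ordered by group, selected proteins as columns
for (cohort in c("derivation", "validation")) {
  z <- if (cohort == "derivation") z_d else z_v
  lab <- if (cohort == "derivation") model$labels else labels_v
  ord <- order(lab)
  utils::write.table(
    data.frame(patient_id = rownames(z)[ord], group = lab[ord],
               z[ord, , drop = FALSE], check.names = FALSE),
    file.path("results/groups", paste0("heatmap_", cohort, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
}

# clinical and proteomic group differences
for (cohort in c("derivation", "validation")) {
  clin <- utils::read.delim(file.path("results/matrices",
                                      paste0("clinical_", cohort,
                                             "_imputed.tsv")))
  lab <- if (cohort == "derivation") model$labels else labels_v
  cmp <- compare_groups(clin, lab)
  n_sig <- sum(cmp$significant, na.rm = TRUE)
  cat(sprintf("%s: %d of %d clinical variables differ between groups (p < 0.05)\n",
              cohort, n_sig, nrow(cmp)))
  utils::write.table(cmp, file.path("results/groups",
                                    paste0("comparisons_", cohort, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote results/groups/\n")
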