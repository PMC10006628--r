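#!/usr/bin/env Rscript
# Step 6 - group-level competing-risk prediction and sensitivity analysis.
#
# Cumulative incidence curves of HF hospitalization per group; Fine-Gray
# models of group 2 vs group 1, unadjusted and adjusted one clinical
# covariate at a time; sensitivity re-clustering after dropping the
# strongest single protein from the panel.

suppressMessages(library(somastrat))
dir.create("results/risk", recursive = TRUE, showWarnings = FALSE)

groups <- list(
  derivation = utils::read.delim("results/groups/groups_derivation.tsv"),
  validation = utils::read.delim("results/groups/groups_validation.tsv"))
outs <- list(
  derivation = read_outcomes("results/data/derivation/outcomes.tsv"),
  validation = read_outcomes("results/data/validation/outcomes.tsv"))

cif_rows <- list()
shr <- list()
adjust_vars <- c("age", "gender", "lvef", "diabetes", "killip2",
                 "creatinine", "bnp", "ntprobnp")
for (cohort in names(groups)) {
  lab <- groups[[cohort]]$group
  out <- outs[[cohort]]
  stopifnot(identical(as.character(groups[[cohort]]$patient_id),
                      as.character(out$patient_id)))
  for (g in 1:2) {
    cc <- cif_aalen_johansen(out[lab == g, ])
    cif_rows[[length(cif_rows) + 1L]] <-
      data.frame(cohort = cohort, group = g, time = cc$time,
                 n_risk = cc$n_risk, cif = cc$cif)
  }
  fit <- group_risk_model(lab, out)
  cat(sprintf("%s: group-2 SHR %.2f [%.2f-%.2f], p = %.2g\n", cohort,
              fit$shr[["group2"]], fit$ci_lower[["group2"]],
              fit$ci_upper[["group2"]], fit$p[["group2"]]))
  clin <- utils::read.delim(file.path("results/matrices",
                                      paste0("clinical_", cohort,
                                             "_imputed.tsv")))
  adj <- lapply(adjust_vars, function(v) {
    f <- group_risk_model(lab, out, adjust = clin[v])
    list(var = v, shr = f$shr[["group2"]],
         ci = c(f$ci_lower[["group2"]], f$ci_upper[["group2"]]),
         p = f$p[["group2"]])
  })
  worst <- adj[[which.min(vapply(adj, function(a) a$shr, numeric(1)))]]
  cat(sprintf("  least favorable adjustment (%s): SHR %.2f [%.2f-%.2f]\n",
              worst$var, worst$shr, worst$ci[1], worst$ci[2]))
  shr[[cohort]] <- list(
    unadjusted = list(shr = fit$shr[["group2"]],
                      ci = c(fit$ci_lower[["group2"]],
                             fit$ci_upper[["group2"]]),
                      p = fit$p[["group2"]]),
    adjusted = adj)
}
utils::write.table(do.call(rbind, cif_rows), "results/risk/cif_curves.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(shr, "results/risk/shr.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

# sensitivity: drop the top-ranked protein (the panel's analog of an
# established biomarker) and re-cluster
screen_d <- utils::read.delim("results/screen/screen_derivation.tsv")
screen_d <- screen_d[order(screen_d$p), ]
drop <- screen_d$protein[1]
cm <- jsonlite::read_json("results/groups/cluster_model.json",
                          simplifyVector = TRUE)
load_std <- function(cohort) {
  df <- utils::read.delim(file.path("results/matrices",
                                    paste0(cohort, "_std.tsv")),
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$patient_id
  m
}
centroids <- cm$centroids
colnames(centroids) <- cm$proteins
baseline <- list(k = cm$k, labels = groups$derivation$group,
                 centroids = centroids, n_restarts = cm$n_restarts)
sens <- sensitivity_drop(load_std("derivation")[, cm$proteins, drop = FALSE],
                         drop, baseline, seed = 20260106L,
                         matrix_valid = load_std("validation")[, cm$proteins,
                                                               drop = FALSE],
                         baseline_valid_labels = groups$validation$group)
cat(sprintf("sensitivity (dropping %s): %d derivation and %d validation patients change groups\n",
            drop, sens$n_changed_deriv, sens$n_changed_valid))
jsonlite::write_json(list(dropped = drop,
                          n_changed_derivation = sens$n_changed_deriv,
                          n_changed_validation = sens$n_changed_valid),
                     "results/risk/sensitivity.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/risk/\n")
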