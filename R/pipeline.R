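# End-to-end orchestration of the three-step strategy: protein selection on
# the derivation cohort, k-means patient grouping transferred to the
# validation cohort, and group-level competing-risk prediction.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] for the derivation cohort.
#' @param sim_valid A [sim_config()] for the validation cohort; by default
#'   the derivation config with 238 patients and a shifted seed. The
#'   validation cohort reuses the derivation cohort's protein structure.
#' @param alpha Familywise error rate of the screen.
#' @param k_range Candidate cluster counts.
#' @param adjust_vars Clinical variables used (one at a time) to adjust the
#'   group risk model.
#' @param drop_proteins Proteins to drop in the sensitivity re-clustering
#'   (intersected with the selected panel); `NULL` skips the analysis.
#' @param terms Optional term sets for [fisher_overrepresentation()].
#' @param seed Seed for clustering restarts.
#' @param out_dir Optional output directory for report and artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            sim_valid = NULL,
                            alpha = 0.05,
                            k_range = 2:6,
                            adjust_vars = c("age", "lvef"),
                            drop_proteins = NULL,
                            terms = NULL,
                            seed = 1L,
                            out_dir = NULL) {
  if (is.null(sim_valid)) {
    sim_valid <- sim
    sim_valid$n_patients <- 238L
    sim_valid$seed <- derive_seed(sim$seed, 9001L)
  }
  structure(list(sim = sim, sim_valid = sim_valid, alpha = alpha,
                 k_range = k_range, adjust_vars = adjust_vars,
                 drop_proteins = drop_proteins, terms = terms,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

preprocess_cohort <- function(cohort) {
  norm <- normalize_pipeline(cohort$somamer_table)
  tab <- remove_flagged(norm$table)
  pm <- aggregate_to_proteins(tab)
  # rows come out in plate order; align them with the outcome/clinical tables
  idx <- match(as.character(cohort$outcomes$patient_id), rownames(pm))
  if (anyNA(idx)) stopf("study samples missing from the protein matrix")
  pm <- protein_matrix(pm[idx, , drop = FALSE], "rfu")
  list(norm = norm, log2 = log2_transform(pm))
}

#' Run the full stratification workflow on synthetic cohorts
#'
#' Executes normalization, preprocessing, derivation-anchored
#' standardization, clinical imputation, the univariate Fine-Gray screen
#' with Bonferroni selection, silhouette-selected k-means on the selected
#' proteins, nearest-centroid transfer to the validation cohort, group
#' comparisons, unadjusted and adjusted group-level risk models, cumulative
#' incidence curves per group, the drop-protein sensitivity analysis and
#' (optionally) term-set overrepresentation. The result is a pure function
#' of the configuration and its seeds.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` (see elements in the source;
#'   the JSON-serializable summary is in `$summary`). When
#'   `config$out_dir` is set, the summary and key tables are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort_d <- simulate_cohort(config$sim)
  cohort_v <- simulate_cohort(config$sim_valid,
                              structure = cohort_d$structure)

  prep_d <- preprocess_cohort(cohort_d)
  prep_v <- preprocess_cohort(cohort_v)

  params <- fit_standardization(prep_d$log2)
  std_d <- apply_standardization(prep_d$log2, params)
  std_v <- apply_standardization(prep_v$log2, params)

  clin_d <- impute_clinical(cohort_d$clinical)
  clin_v <- impute_clinical(cohort_v$clinical)

  screen_d <- univariate_screen(std_d, cohort_d$outcomes,
                                alpha = config$alpha)
  screen_v <- univariate_screen(std_v, cohort_v$outcomes,
                                alpha = config$alpha)
  selected <- screen_d$protein[screen_d$selected]

  report <- list(config = config, cohorts = list(derivation = cohort_d,
                                                 validation = cohort_v),
                 qc = list(derivation = prep_d$norm$report,
                           validation = prep_v$norm$report),
                 standardization = params,
                 screen = list(derivation = screen_d, validation = screen_v),
                 selected = selected)

  summary <- list(
    n_derivation = config$sim$n_patients,
    n_validation = config$sim_valid$n_patients,
    m_tests = attr(screen_d, "m"),
    threshold = attr(screen_d, "threshold"),
    n_selected = length(selected),
    selected = selected,
    qc_pass = c(derivation = prep_d$norm$report$pass,
                validation = prep_v$norm$report$pass),
    seeds = c(derivation = config$sim$seed,
              validation = config$sim_valid$seed,
              clustering = config$seed))

  if (length(selected) < 2L) {
    summary$note <- "no proteins selected; stratification skipped"
    report$summary <- summary
    class(report) <- "pipeline_report"
    if (!is.null(config$out_dir)) write_report(report, config$out_dir)
    return(report)
  }

  conc <- direction_concordance(screen_d, screen_v)
  corr <- correlation_summary(std_d, selected)

  model <- select_k(std_d[, selected, drop = FALSE],
                    k_range = config$k_range, seed = config$seed)
  model <- order_groups_by_risk(model, cohort_d$outcomes)
  labels_v <- assign_groups(std_v[, selected, drop = FALSE],
                            model$centroids)

  cmp_d <- compare_groups(clin_d, model$labels)
  cmp_v <- if (length(unique(labels_v)) == 2L) {
    compare_groups(clin_v, labels_v)
  } else {
    NULL
  }

  fits <- list(
    derivation = group_risk_model(model$labels, cohort_d$outcomes),
    validation = group_risk_model(labels_v, cohort_v$outcomes))
  adjusted <- list()
  for (v in config$adjust_vars) {
    adjusted[[v]] <- list(
      derivation = group_risk_model(model$labels, cohort_d$outcomes,
                                    adjust = clin_d[v]),
      validation = group_risk_model(labels_v, cohort_v$outcomes,
                                    adjust = clin_v[v]))
  }

  cif <- list(
    derivation = lapply(1:2, function(g) {
      cif_aalen_johansen(cohort_d$outcomes[model$labels == g, ])
    }),
    validation = lapply(1:2, function(g) {
      cif_aalen_johansen(cohort_v$outcomes[labels_v == g, ])
    }))

  sens <- NULL
  drop <- intersect(config$drop_proteins, selected)
  if (length(drop) && length(drop) < length(selected)) {
    sens <- sensitivity_drop(std_d[, selected, drop = FALSE], drop,
                             model, seed = config$seed,
                             matrix_valid = std_v[, selected, drop = FALSE],
                             baseline_valid_labels = labels_v)
  }

  enr <- NULL
  if (!is.null(config$terms)) {
    enr <- fisher_overrepresentation(selected, screen_d$protein,
                                     config$terms)
  }

  report <- c(report, list(
    concordance = conc, correlation = corr, model = model,
    labels_validation = labels_v,
    comparisons = list(derivation = cmp_d, validation = cmp_v),
    fits = fits, adjusted = adjusted, cif = cif, sensitivity = sens,
    enrichment = enr))

  summary <- c(summary, list(
    k = model$k,
    silhouette_by_k = as.list(model$silhouette_by_k),
    group_sizes = list(derivation = as.vector(table(model$labels)),
                       validation = as.vector(table(factor(labels_v,
                                                           levels = 1:2)))),
    concordance = conc[c("same_sign", "opposite_sign")],
    max_correlation = corr$max_cor,
    shr = list(
      derivation = list(shr = fits$derivation$shr[["group2"]],
                        ci = c(fits$derivation$ci_lower[[1]],
                               fits$derivation$ci_upper[[1]]),
                        p = fits$derivation$p[[1]]),
      validation = list(shr = fits$validation$shr[["group2"]],
                        ci = c(fits$validation$ci_lower[[1]],
                               fits$validation$ci_upper[[1]]),
                        p = fits$validation$p[[1]])),
    adjusted_shr = lapply(adjusted, function(a) {
      list(derivation = a$derivation$shr[["group2"]],
           validation = a$validation$shr[["group2"]])
    }),
    sensitivity = if (!is.null(sens)) {
      list(dropped = drop, n_changed_derivation = sens$n_changed_deriv,
           n_changed_validation = sens$n_changed_valid)
    }))
  report$summary <- summary
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$screen$derivation,
                     file.path(dir, "screen_derivation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$standardization,
                     file.path(dir, "standardization.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$model)) {
    jsonlite::write_json(
      list(k = report$model$k,
           proteins = colnames(report$model$centroids),
           centroids = report$model$centroids,
           silhouette_by_k = as.list(report$model$silhouette_by_k),
           seed = report$model$seed,
           n_restarts = report$model$n_restarts),
      file.path(dir, "cluster_model.json"), digits = NA, auto_unbox = TRUE)
    cif_rows <- list()
    for (coh in names(report$cif)) {
      for (g in 1:2) {
        cc <- report$cif[[coh]][[g]]
        cif_rows[[length(cif_rows) + 1L]] <-
          data.frame(cohort = coh, group = g, time = cc$time, cif = cc$cif)
      }
    }
    utils::write.table(do.call(rbind, cif_rows),
                       file.path(dir, "cif_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pipeline_report: %d + %d patients, %d proteins tested, %d selected (threshold %.3g)\n",
              s$n_derivation, s$n_validation, s$m_tests, s$n_selected,
              s$threshold))
  if (!is.null(s$k)) {
    cat(sprintf("  k = %d; group sizes %s (derivation), %s (validation)\n",
                s$k, paste(s$group_sizes$derivation, collapse = "/"),
                paste(s$group_sizes$validation, collapse = "/")))
    cat(sprintf("  group-2 SHR: %.2f [%.2f-%.2f] derivation, %.2f [%.2f-%.2f] validation\n",
                s$shr$derivation$shr, s$shr$derivation$ci[1],
                s$shr$derivation$ci[2], s$shr$validation$shr,
                s$shr$validation$ci[1], s$shr$validation$ci[2]))
  } else if (!is.null(s$note)) {
    cat(" ", s$note, "\n")
  }
  invisible(x)
}

#' Score a new patient into the fitted groups
#'
#' Standardizes a single patient's log2 protein values with the derivation
#' cohort's parameters and assigns the nearest centroid. This is the
#' single-patient deployment path of the stratification: the
#' standardization parameters and the cluster model are all that is needed.
#'
#' @param params A `standardization_params` (derivation cohort).
#' @param model A `cluster_model`.
#' @param x Named numeric vector of log2 protein values covering every
#'   protein of the model's centroids.
#' @return The integer group label.
#' @export
score_patient <- function(params, model, x) {
  need <- colnames(model$centroids)
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stopf("patient vector is missing protein(s): %s",
          paste(missing, collapse = ", "))
  }
  mat <- protein_matrix(matrix(x[need], nrow = 1L,
                               dimnames = list("patient", need)), "log2")
  z <- apply_standardization(mat, params)
  as.integer(assign_groups(unclass(z), model$centroids))
}
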