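# Patient stratification: k-means on the selected proteins with
# silhouette-guided choice of k, nearest-centroid transfer to a validation
# cohort, group comparisons, group-level risk models and the drop-protein
# sensitivity analysis.

#' k-means clustering of patients
#'
#' Lloyd's algorithm, best of `n_restarts` random starts by within-cluster
#' sum of squares, deterministic under `seed`.
#'
#' @param matrix Patients x proteins matrix (standardized scale).
#' @param k Number of clusters (>= 2).
#' @param seed RNG seed.
#' @param n_restarts Random restarts (default 25).
#' @return A list with `centroids` (k x p), `labels` (1..k), `wcss`.
#' @export
kmeans_fit <- function(matrix, k, seed = 1L, n_restarts = 25L) {
  matrix <- as.matrix(matrix)
  if (k < 2L) stopf("k must be >= 2")
  if (k > nrow(matrix)) stopf("k = %d exceeds the number of patients (%d)",
                              k, nrow(matrix))
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(matrix, centers = k, nstart = n_restarts, iter.max = 100L,
                  algorithm = "Lloyd")))
  list(centroids = km$centers, labels = as.integer(km$cluster),
       wcss = km$tot.withinss)
}

#' Overall average silhouette width
#'
#' Mean over patients of \eqn{(b_i - a_i)/\max(a_i, b_i)} with \eqn{a_i} the
#' mean Euclidean distance to the patient's own group and \eqn{b_i} the
#' smallest mean distance to another group. Members of singleton groups get
#' silhouette 0 (the usual convention).
#'
#' @param matrix Patients x proteins matrix.
#' @param labels Integer group labels (>= 2 non-empty groups).
#' @return The average silhouette width, in `[-1, 1]`.
#' @export
average_silhouette <- function(matrix, labels) {
  matrix <- as.matrix(matrix)
  labels <- as.integer(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stopf("need at least 2 groups")
  n <- nrow(matrix)
  D <- as.matrix(stats::dist(matrix))
  s <- numeric(n)
  sizes <- table(factor(labels, levels = groups))
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[as.character(own)] == 1L) {
      s[i] <- 0
      next
    }
    a <- sum(D[i, labels == own]) / (sizes[as.character(own)] - 1L)
    b <- min(vapply(groups[groups != own], function(g) {
      mean(D[i, labels == g])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the number of groups by maximizing the average silhouette
#'
#' Fits k-means for each candidate k, computes the overall average
#' silhouette width, and keeps the k with the largest value (ties go to the
#' smaller k).
#'
#' @param matrix Patients x proteins matrix (standardized scale).
#' @param k_range Candidate cluster counts (default 2:6).
#' @param seed RNG seed.
#' @param n_restarts Random restarts per k.
#' @return A list of class `cluster_model`: `k`, `centroids`, `labels`,
#'   `silhouette_by_k` (named vector), `wcss`, `seed`, `n_restarts`.
#' @export
select_k <- function(matrix, k_range = 2:6, seed = 1L, n_restarts = 25L) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) <= max(k_range)) {
    stopf("need more patients (%d) than the largest candidate k (%d)",
          nrow(matrix), max(k_range))
  }
  fits <- list()
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fits[[i]] <- kmeans_fit(matrix, k, seed = derive_seed(seed, k),
                            n_restarts = n_restarts)
    sil[i] <- average_silhouette(matrix, fits[[i]]$labels)
  }
  best <- which.max(sil)   # which.max takes the first (smallest k) on ties
  structure(list(k = k_range[best],
                 centroids = fits[[best]]$centroids,
                 labels = fits[[best]]$labels,
                 silhouette_by_k = sil,
                 wcss = fits[[best]]$wcss,
                 seed = seed, n_restarts = n_restarts),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d over %d proteins\n", x$k,
              ncol(x$centroids)))
  cat("  average silhouette by k:",
      paste(sprintf("k=%s: %.3f", names(x$silhouette_by_k),
                    x$silhouette_by_k), collapse = ", "), "\n")
  cat("  group sizes:", paste(table(x$labels), collapse = " / "), "\n")
  invisible(x)
}

#' Nearest-centroid group assignment
#'
#' Assigns each patient (row) to the group whose centroid is closest in
#' Euclidean distance. The data must be standardized with the derivation
#' cohort's parameters. Works for a single-patient matrix. Exact ties break
#' to the lowest group index.
#'
#' @param matrix Patients x proteins matrix (or a single row).
#' @param centroids k x proteins centroid matrix from the derivation fit.
#' @return Integer labels in 1..k.
#' @export
assign_groups <- function(matrix, centroids) {
  matrix <- as.matrix(matrix)
  if (is.null(dim(matrix)) || ncol(matrix) != ncol(centroids)) {
    stopf("dimension mismatch: data has %d proteins, centroids %d",
          ncol(as.matrix(matrix)), ncol(centroids))
  }
  # squared distances via ||x||^2 - 2 x.c + ||c||^2
  cross <- matrix %*% t(centroids)
  d2 <- sweep(-2 * cross, 2L, rowSums(centroids^2), `+`) + rowSums(matrix^2)
  apply(d2, 1L, which.min)   # which.min returns the first (lowest) index on ties
}

#' Compare clinical or protein variables between groups
#'
#' Welch's t test (Satterthwaite degrees of freedom) for quantitative
#' variables, chi-square (no continuity correction) on the group x level
#' contingency table for categorical variables. Variables with at most
#' `max_levels` distinct values are treated as categorical.
#'
#' @param data Data frame or matrix of per-patient variables (a
#'   `patient_id` column is ignored).
#' @param labels Group labels (two groups).
#' @param max_levels Distinct-value cutoff for treating a numeric variable
#'   as categorical (default 4).
#' @return A data frame of class `group_comparison`: `variable`, `test`,
#'   `statistic`, `p`, `significant` (raw p < 0.05).
#' @export
compare_groups <- function(data, labels, max_levels = 4L) {
  data <- as.data.frame(data)
  data$patient_id <- NULL
  labels <- as.integer(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stopf("group comparison requires exactly 2 groups")
  if (min(table(labels)) < 2L) stopf("each group needs at least 2 members")
  rows <- lapply(names(data), function(v) {
    x <- data[[v]]
    categorical <- is.character(x) || is.factor(x) ||
      length(unique(stats::na.omit(x))) <= max_levels
    if (categorical) {
      tab <- table(labels, x)
      if (ncol(tab) < 2L) {
        return(data.frame(variable = v, test = "chi2", statistic = NA_real_,
                          p = NA_real_, significant = NA,
                          stringsAsFactors = FALSE))
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, test = "chi2",
                 statistic = unname(ct$statistic), p = ct$p.value,
                 significant = ct$p.value < 0.05, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(x[labels == groups[1]], x[labels == groups[2]],
                          var.equal = FALSE)
      data.frame(variable = v, test = "welch",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 significant = tt$p.value < 0.05, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Relabel groups so group 2 carries the higher HF incidence
#'
#' Mirrors the convention that the high-risk cluster is called group 2: the
#' cluster with the larger crude cause-1 event fraction becomes group 2.
#' Returns the model with labels and centroid rows permuted accordingly.
#'
#' @param model A `cluster_model` with k = 2.
#' @param outcomes Outcomes aligned with the model's patients.
#' @return The relabelled model.
#' @export
order_groups_by_risk <- function(model, outcomes) {
  if (model$k != 2L) return(model)
  inc <- vapply(1:2, function(g) {
    mean(outcomes$cause[model$labels == g] == 1L)
  }, numeric(1))
  if (inc[1] > inc[2]) {
    model$labels <- 3L - model$labels
    model$centroids <- model$centroids[2:1, , drop = FALSE]
  }
  model
}

#' Group-level competing-risk model
#'
#' Fits the Fine-Gray model for HF hospitalization on the binary group
#' indicator (group 2 vs group 1), optionally adjusted for clinical
#' covariates (singly or in pairs).
#'
#' @param labels Group labels in 1..2.
#' @param outcomes Data frame with `time` and `cause`.
#' @param adjust Optional data frame of adjustment covariates (complete,
#'   i.e. post-imputation).
#' @return A [fit_fine_gray()] result; the group coefficient is named
#'   `"group2"`.
#' @export
group_risk_model <- function(labels, outcomes, adjust = NULL) {
  g <- as.integer(labels == 2L)
  X <- cbind(group2 = g)
  if (!is.null(adjust)) {
    adjust <- as.data.frame(adjust)
    adjust$patient_id <- NULL
    if (anyNA(adjust)) stopf("adjustment covariates contain missing values; impute first")
    X <- cbind(X, as.matrix(adjust))
  }
  fit_fine_gray(X, outcomes)
}

# Map new cluster labels onto baseline labels by maximal overlap; exhaustive
# over the k! permutations (k <= 6).
match_labels <- function(new_labels, old_labels, k) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  best_overlap <- -1L
  for (p in perms(seq_len(k))) {
    overlap <- sum(p[new_labels] == old_labels)
    if (overlap > best_overlap) {
      best_overlap <- overlap
      best <- p
    }
  }
  best
}

#' Sensitivity analysis: re-cluster after dropping proteins
#'
#' Re-runs the k selection and clustering on the panel minus `drop_proteins`
#' (e.g. the natriuretic peptides), maps the new groups onto the baseline
#' groups by maximal label overlap, and counts how many patients change
#' groups in the derivation cohort and, if supplied, in the validation
#' cohort (assigned by nearest centroid under both panels).
#'
#' @param matrix Derivation patients x selected proteins matrix.
#' @param drop_proteins Protein symbols to drop (a strict subset).
#' @param baseline The `cluster_model` fitted on the full panel.
#' @param seed RNG seed for the re-clustering.
#' @param matrix_valid Optional validation matrix (full panel; columns are
#'   subset internally).
#' @param baseline_valid_labels Optional baseline validation labels; computed
#'   from `baseline` if omitted.
#' @return A list with `model` (relabelled to match the baseline),
#'   `n_changed_deriv`, `n_changed_valid` (NA if no validation matrix).
#' @export
sensitivity_drop <- function(matrix, drop_proteins, baseline, seed = 1L,
                             matrix_valid = NULL,
                             baseline_valid_labels = NULL) {
  matrix <- as.matrix(matrix)
  keep <- setdiff(colnames(matrix), drop_proteins)
  if (!length(keep)) stopf("dropping every protein leaves nothing to cluster")
  missing <- setdiff(drop_proteins, colnames(matrix))
  if (length(missing)) {
    stopf("protein(s) not in the panel: %s", paste(missing, collapse = ", "))
  }
  sub <- matrix[, keep, drop = FALSE]
  model <- select_k(sub, seed = seed, n_restarts = baseline$n_restarts)
  k <- max(model$k, baseline$k)
  map <- match_labels(model$labels, baseline$labels,
                      max(model$k, baseline$k))
  model$labels <- map[model$labels]
  model$centroids <- model$centroids[order(map[seq_len(model$k)]), ,
                                     drop = FALSE]
  n_changed <- sum(model$labels != baseline$labels)
  n_changed_valid <- NA_integer_
  if (!is.null(matrix_valid)) {
    matrix_valid <- as.matrix(matrix_valid)
    if (is.null(baseline_valid_labels)) {
      baseline_valid_labels <- assign_groups(
        matrix_valid[, colnames(baseline$centroids), drop = FALSE],
        baseline$centroids)
    }
    new_valid <- assign_groups(matrix_valid[, keep, drop = FALSE],
                               model$centroids)
    n_changed_valid <- sum(new_valid != baseline_valid_labels)
  }
  list(model = model, n_changed_deriv = n_changed,
       n_changed_valid = n_changed_valid)
}
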