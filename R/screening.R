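# Genome-scale univariate screening of proteins against HF occurrence with
# familywise error control, plus cross-cohort concordance and correlation
# summaries.

#' Bonferroni significance threshold
#'
#' @param alpha Familywise error rate, in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`. With the full-panel values `alpha = 0.05`,
#'   `m = 4668` this is 1.0711e-05.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0, 1)")
  if (m < 1) stopf("number of tests m must be >= 1")
  alpha / m
}

#' Univariate competing-risk screen over all proteins
#'
#' Fits one single-covariate Fine-Gray model per protein of a standardized
#' matrix against the competing-risk outcomes, keeps the raw Wald p-values,
#' and selects proteins at the Bonferroni threshold `alpha / m`. `m` is the
#' number of protein columns, fixed before fitting: proteins whose fit fails
#' are marked untestable (never selected) but still count in `m`.
#'
#' @param matrix A `protein_matrix` on the `"standardized"` scale, rows
#'   aligned with `outcomes`.
#' @param outcomes Data frame with `time` and `cause`.
#' @param alpha Familywise error rate (default 0.05).
#' @return A data frame of class `screen_result` with columns `protein`,
#'   `beta`, `se`, `shr`, `z`, `p`, `converged`, `selected`; attributes
#'   `alpha`, `m`, `threshold`.
#' @export
univariate_screen <- function(matrix, outcomes, alpha = 0.05) {
  if (inherits(matrix, "protein_matrix") && pm_scale(matrix) != "standardized") {
    stopf("screening expects a standardized matrix, got scale '%s'",
          pm_scale(matrix))
  }
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != nrow(outcomes)) {
    stopf("matrix has %d patients but outcomes %d", nrow(matrix),
          nrow(outcomes))
  }
  if (!is.null(rownames(matrix)) && "patient_id" %in% names(outcomes) &&
      !identical(rownames(matrix), as.character(outcomes$patient_id))) {
    stopf("matrix rows and outcome rows are not in the same patient order")
  }
  m <- ncol(matrix)
  thr <- bonferroni_threshold(alpha, m)
  str <- fg_structure(outcomes)
  res <- fg_univariate_batch(matrix, str)
  res$selected <- !is.na(res$p) & res$p < thr
  attr(res, "alpha") <- alpha
  attr(res, "m") <- m
  attr(res, "threshold") <- thr
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Cross-cohort direction concordance of selected proteins
#'
#' Among the proteins selected on the derivation cohort, counts how many
#' have a same-sign and how many an opposite-sign coefficient in the
#' validation screen, naming the discordant proteins.
#'
#' @param res_deriv,res_valid Two [univariate_screen()] results.
#' @param selected Protein symbols to compare; defaults to the derivation
#'   selection.
#' @return A list with `same_sign`, `opposite_sign` and
#'   `opposite_proteins`.
#' @export
direction_concordance <- function(res_deriv, res_valid, selected = NULL) {
  if (is.null(selected)) selected <- res_deriv$protein[res_deriv$selected]
  i1 <- match(selected, res_deriv$protein)
  i2 <- match(selected, res_valid$protein)
  if (anyNA(i1) || anyNA(i2)) {
    stopf("protein(s) missing from a screen result: %s",
          paste(selected[is.na(i1) | is.na(i2)], collapse = ", "))
  }
  s1 <- sign(res_deriv$beta[i1])
  s2 <- sign(res_valid$beta[i2])
  opp <- which(s1 * s2 < 0)
  list(same_sign = sum(s1 * s2 > 0),
       opposite_sign = length(opp),
       opposite_proteins = selected[opp])
}

#' Pairwise correlation among selected proteins
#'
#' Pearson correlation matrix of the selected columns, reporting the pair
#' with the largest off-diagonal correlation.
#'
#' @param matrix Protein matrix restricted to (or indexed by) the selected
#'   proteins.
#' @param proteins Optional column subset.
#' @return A list with `cor` (the matrix), `max_pair` (two symbols) and
#'   `max_cor`.
#' @export
correlation_summary <- function(matrix, proteins = NULL) {
  matrix <- as.matrix(matrix)
  if (!is.null(proteins)) matrix <- matrix[, proteins, drop = FALSE]
  if (ncol(matrix) < 2L) stopf("need at least 2 proteins")
  sds <- apply(matrix, 2L, stats::sd)
  if (any(sds == 0)) {
    stopf("correlation undefined for constant column(s): %s",
          paste(colnames(matrix)[sds == 0], collapse = ", "))
  }
  cm <- stats::cor(matrix)
  off <- cm
  diag(off) <- -Inf
  idx <- which(off == max(off), arr.ind = TRUE)[1L, ]
  list(cor = cm,
       max_pair = c(colnames(cm)[idx[1L]], colnames(cm)[idx[2L]]),
       max_cor = cm[idx[1L], idx[2L]])
}
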