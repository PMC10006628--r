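# SOMAmer-level cleanup, protein aggregation, log2 transform,
# derivation-anchored standardization and clinical imputation.

protein_matrix <- function(values, scale) {
  stopifnot(scale %in% c("rfu", "log2", "standardized"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  attr(values, "scale") <- scale
  class(values) <- c("protein_matrix", class(values))
  values
}

pm_scale <- function(x) attr(x, "scale") %||% "rfu"

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d patients x %d proteins (%s scale)\n",
              nrow(x), ncol(x), pm_scale(x)))
  invisible(x)
}

#' Drop SOMAmers flagged for removal
#'
#' Removes the measurement columns whose metadata carries the manufacturer's
#' removal flag, logging the count.
#'
#' @param table A [somamer_table()].
#' @return The table without flagged columns.
#' @export
remove_flagged <- function(table) {
  table <- validate_somamer_table(table)
  drop <- table$somamer_meta$flagged_removed
  if (all(drop)) stopf("all SOMAmers are flagged for removal; nothing remains")
  if (!any(drop)) return(table)
  message(sprintf("removing %d flagged SOMAmer measurement(s); %d remain",
                  sum(drop), sum(!drop)))
  keep <- which(!drop)
  table$rfu <- table$rfu[, keep, drop = FALSE]
  table$somamer_meta <- table$somamer_meta[keep, , drop = FALSE]
  rownames(table$somamer_meta) <- NULL
  validate_somamer_table(table)
}

#' Aggregate SOMAmers to proteins
#'
#' Builds the patients x proteins matrix from the study samples of a
#' normalized table: proteins measured by several SOMAmers get the
#' per-patient arithmetic mean of their SOMAmer RFUs (computed on the RFU
#' scale, before the log transform), single-SOMAmer proteins are copied.
#' Hybridization control columns and non-study samples are excluded.
#'
#' @param table A `somamer_table` (flagged SOMAmers already removed).
#' @param sample_types Sample types to keep as matrix rows.
#' @return A `protein_matrix` on the `"rfu"` scale, one column per protein
#'   symbol, rows named by sample id.
#' @export
aggregate_to_proteins <- function(table, sample_types = "study") {
  table <- validate_somamer_table(table)
  sm <- table$somamer_meta
  keep_col <- which(!sm$is_hyb_control & !sm$flagged_removed)
  if (!length(keep_col)) stopf("no analyte SOMAmers to aggregate")
  sym <- as.character(sm$protein_symbol[keep_col])
  if (any(!nzchar(sym) | is.na(sym))) {
    stopf("empty protein symbol for SOMAmer(s): %s",
          paste(sm$somamer_id[keep_col][!nzchar(sym) | is.na(sym)],
                collapse = ", "))
  }
  rows <- which(table$sample_meta$sample_type %in% sample_types)
  rfu <- table$rfu[rows, keep_col, drop = FALSE]
  proteins <- unique(sym)
  out <- matrix(0, nrow = length(rows), ncol = length(proteins),
                dimnames = list(table$sample_meta$sample_id[rows], proteins))
  for (j in seq_along(proteins)) {
    cols <- which(sym == proteins[j])
    out[, j] <- if (length(cols) == 1L) {
      rfu[, cols]
    } else {
      rowMeans(rfu[, cols, drop = FALSE])
    }
  }
  protein_matrix(out, "rfu")
}

#' Log2-transform a protein matrix
#'
#' @param matrix A `protein_matrix` on the `"rfu"` scale with strictly
#'   positive values.
#' @return The matrix on the `"log2"` scale.
#' @export
log2_transform <- function(matrix) {
  if (pm_scale(matrix) != "rfu") {
    stopf("log2_transform expects a matrix on the rfu scale, got '%s'",
          pm_scale(matrix))
  }
  if (any(matrix <= 0)) {
    idx <- which(matrix <= 0, arr.ind = TRUE)[1L, ]
    stopf("non-positive value at patient '%s', protein '%s'",
          rownames(matrix)[idx[1L]] %||% idx[1L],
          colnames(matrix)[idx[2L]] %||% idx[2L])
  }
  protein_matrix(log2(unclass(matrix)), "log2")
}

#' Estimate standardization parameters on the derivation cohort
#'
#' Per-protein mean and standard deviation (sample SD, n-1 denominator) of
#' the log2 matrix. These parameters anchor the whole downstream analysis:
#' they are applied unchanged to any other cohort or single patient.
#'
#' @param matrix A `protein_matrix` on the `"log2"` scale with at least two
#'   patients.
#' @return A data frame of class `standardization_params` with columns
#'   `protein`, `mean`, `sd`.
#' @export
fit_standardization <- function(matrix) {
  if (pm_scale(matrix) != "log2") {
    stopf("standardization parameters are estimated on the log2 scale")
  }
  if (nrow(matrix) < 2L) stopf("need at least 2 patients to estimate an SD")
  m <- colMeans(matrix)
  s <- apply(matrix, 2L, stats::sd)
  if (any(s <= 0 | !is.finite(s))) {
    stopf("constant column(s) cannot be standardized: %s",
          paste(colnames(matrix)[s <= 0 | !is.finite(s)], collapse = ", "))
  }
  structure(data.frame(protein = colnames(matrix), mean = m, sd = s,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("standardization_params", "data.frame"))
}

#' Apply derivation-cohort standardization parameters
#'
#' Computes `(x - mean) / sd` per protein using parameters estimated with
#' [fit_standardization()] on the derivation cohort. Works for a full cohort
#' or a single-patient matrix.
#'
#' @param matrix A `protein_matrix` on the `"log2"` scale.
#' @param params A `standardization_params` covering every protein in
#'   `matrix`.
#' @return The matrix on the `"standardized"` scale.
#' @export
apply_standardization <- function(matrix, params) {
  if (pm_scale(matrix) != "log2") {
    stopf("standardization applies to the log2 scale, got '%s'",
          pm_scale(matrix))
  }
  idx <- match(colnames(matrix), params$protein)
  if (anyNA(idx)) {
    stopf("no standardization parameters for protein(s): %s",
          paste(colnames(matrix)[is.na(idx)], collapse = ", "))
  }
  z <- sweep(unclass(matrix), 2L, params$mean[idx], `-`)
  z <- sweep(z, 2L, params$sd[idx], `/`)
  protein_matrix(z, "standardized")
}

#' Serialize / read standardization parameters
#'
#' Written as a TSV (`protein`, `mean`, `sd`) so external cohorts or single
#' patients can be projected into the derivation cohort's standardized space.
#'
#' @param params A `standardization_params`.
#' @param path File path.
#' @return `read_standardization` returns the parameter table;
#'   `write_standardization` returns `path` invisibly.
#' @export
write_standardization <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_standardization
#' @export
read_standardization <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("standardization_params", "data.frame")
  out
}

#' Single imputation of missing clinical values
#'
#' Deterministic low-rank completion in the style of iterative principal-axes
#' imputation: missing cells are initialized at column means, then a
#' truncated rank-`n_components` SVD reconstruction of the column-centered,
#' column-scaled matrix and re-imputation of the missing cells alternate
#' until the largest change in an imputed cell (on the scaled metric) falls
#' below `tol` (or `max_iter` is reached, with a warning). Observed cells
#' are never altered.
#'
#' @param clinical Clinical data frame; a `patient_id` column, if present, is
#'   carried through untouched. All other columns must be numeric-coded.
#' @param n_components Rank of the reconstruction (default 2).
#' @param tol Convergence tolerance on imputed cells.
#' @param max_iter Iteration cap.
#' @return The completed data frame, with attributes `converged` and
#'   `n_imputed`.
#' @export
impute_clinical <- function(clinical, n_components = 2L, tol = 1e-6,
                            max_iter = 200L) {
  id_col <- intersect("patient_id", names(clinical))
  vars <- setdiff(names(clinical), id_col)
  M <- as.matrix(clinical[vars])
  if (!is.numeric(M)) stopf("clinical variables must be numeric-coded")
  miss <- is.na(M)
  if (!any(miss)) {
    attr(clinical, "converged") <- TRUE
    attr(clinical, "n_imputed") <- 0L
    return(clinical)
  }
  frac <- colMeans(miss)
  if (any(frac >= 0.5)) {
    stopf("variable(s) with >= 50%% missingness cannot be imputed: %s",
          paste(vars[frac >= 0.5], collapse = ", "))
  }
  if (any(frac == 1)) stopf("fully missing column(s)")
  # init at column means of observed values
  for (j in seq_along(vars)) {
    M[miss[, j], j] <- mean(M[!miss[, j], j])
  }
  # iterate on column-standardized data so variables on large raw scales
  # (e.g. natriuretic peptides) do not dominate the principal axes, and the
  # tolerance is scale-free
  col_scale <- apply(M, 2L, stats::sd)
  col_scale[col_scale == 0] <- 1
  M <- sweep(M, 2L, col_scale, `/`)
  r <- min(n_components, nrow(M) - 1L, ncol(M))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- colMeans(M)
    C <- sweep(M, 2L, mu, `-`)
    sv <- svd(C, nu = r, nv = r)
    recon <- sv$u %*% (diag(sv$d[seq_len(r)], r, r) %*% t(sv$v))
    recon <- sweep(recon, 2L, mu, `+`)
    delta <- max(abs(recon[miss] - M[miss]))
    M[miss] <- recon[miss]
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warnf("imputation did not converge within %d iterations (last change %.3g)",
          max_iter, delta)
  }
  M <- sweep(M, 2L, col_scale, `*`)
  # observed cells are restored exactly (unscaling introduces float noise)
  orig <- as.matrix(clinical[vars])
  M[!miss] <- orig[!miss]
  out <- clinical
  out[vars] <- as.data.frame(M)
  attr(out, "converged") <- converged
  attr(out, "n_imputed") <- sum(miss)
  out
}
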