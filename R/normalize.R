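# Normalization and calibration of plate-structured SOMAmer RFU data.
#
# Five multiplicative corrections are applied in sequence:
#   1. hybridization control normalization   (per sample)
#   2. intraplate median signal normalization (per calibrator sample and
#      dilution set)
#   3. plate scaling                          (per plate)
#   4. calibration                            (per plate and SOMAmer)
#   5. median normalization to a reference    (per study/QC/buffer sample and
#      dilution set)
# Every step is a median-of-ratios: a reference is divided by the measured
# value, and the median ratio over the relevant unit becomes the scale
# factor, which multiplies the measured values. After each step the defining
# median ratio is exactly 1. Even-count medians are the midpoint of the two
# central order statistics (stats::median).

empty_factors <- function() {
  structure(list(hyb = NULL, intraplate = NULL, plate_scale = NULL,
                 calibration = NULL, ref_median = NULL, qc_ratios = NULL),
            class = "norm_factors")
}

merge_factors <- function(a, b) {
  for (nm in names(b)) {
    if (!is.null(b[[nm]])) a[[nm]] <- rbind(a[[nm]], b[[nm]])
  }
  a
}

check_positive_factors <- function(f, what) {
  if (any(!is.finite(f)) || any(f <= 0)) {
    stopf("%s produced a non-positive or non-finite scale factor", what)
  }
  f
}

#' Hybridization control normalization
#'
#' For each sample, the ratio of the within-plate median of each
#' hybridization control to its measured value is computed; the median of
#' these control ratios is the sample's hybridization scale factor, which
#' multiplies every measurement in that sample (controls included). This
#' removes per-sample readout brightness differences.
#'
#' @param table A [somamer_table()] containing hybridization control columns.
#' @return `list(table, factors)` where `factors$hyb` has one row per sample.
#' @export
hybridization_normalize <- function(table) {
  table <- validate_somamer_table(table)
  hyb <- which(table$somamer_meta$is_hyb_control)
  if (!length(hyb)) stopf("no hybridization control SOMAmers present")
  rfu <- table$rfu
  if (any(rfu[, hyb] <= 0)) {
    stopf("zero or negative hybridization control RFU encountered")
  }
  pm <- table$sample_meta
  factors <- numeric(nrow(rfu))
  for (p in unique(pm$plate_id)) {
    rows <- which(pm$plate_id == p)
    ref <- apply(rfu[rows, hyb, drop = FALSE], 2L, stats::median)
    for (i in rows) {
      factors[i] <- stats::median(ref / rfu[i, hyb])
    }
  }
  check_positive_factors(factors, "hybridization normalization")
  out <- table
  out$rfu <- rfu * factors
  f <- empty_factors()
  f$hyb <- data.frame(sample_id = pm$sample_id, plate_id = pm$plate_id,
                      factor = factors, stringsAsFactors = FALSE)
  list(table = out, factors = f)
}

#' Intraplate median signal normalization
#'
#' Applied to calibrator samples only. Within each plate, the per-SOMAmer
#' local reference is the median over the plate's calibrator samples; for
#' each calibrator sample and each of the three dilution sets, the median of
#' the reference/measured ratios across the SOMAmers of that dilution is the
#' scale factor applied to that dilution's measurements in that sample.
#' Hybridization control columns are excluded (they are controls, not
#' analytes).
#'
#' @param table A `somamer_table`, already hybridization-normalized.
#' @param sample_group Sample type(s) to normalize (default `"calibrator"`).
#' @return `list(table, factors)`; `factors$intraplate` has one row per
#'   (sample, dilution set).
#' @export
intraplate_median_normalize <- function(table, sample_group = "calibrator") {
  table <- validate_somamer_table(table)
  sm <- table$somamer_meta
  pm <- table$sample_meta
  analyte <- which(!sm$is_hyb_control)
  if (!length(analyte)) stopf("no analyte SOMAmers present")
  dil <- sm$dilution_set[analyte]
  dils <- sort(unique(dil))
  if (!length(dils)) stopf("empty dilution sets: no analytes to normalize")
  rfu <- table$rfu
  recs <- list()
  for (p in unique(pm$plate_id)) {
    grp <- which(pm$plate_id == p & pm$sample_type %in% sample_group)
    if (!length(grp)) stopf("plate %s has no %s samples", p,
                            paste(sample_group, collapse = "/"))
    ref <- apply(rfu[grp, analyte, drop = FALSE], 2L, stats::median)
    if (any(ref <= 0)) stopf("zero local reference on plate %s", p)
    for (i in grp) {
      if (any(rfu[i, analyte] <= 0)) {
        stopf("zero or negative RFU in sample '%s'", pm$sample_id[i])
      }
      ratios <- ref / rfu[i, analyte]
      for (d in dils) {
        idx <- analyte[dil == d]
        fct <- stats::median(ratios[dil == d])
        check_positive_factors(fct, "intraplate normalization")
        rfu[i, idx] <- rfu[i, idx] * fct
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = pm$sample_id[i], plate_id = p, dilution_set = d,
          factor = fct, stringsAsFactors = FALSE)
      }
    }
  }
  out <- table
  out$rfu <- rfu
  f <- empty_factors()
  f$intraplate <- do.call(rbind, recs)
  list(table = out, factors = f)
}

#' Build the global reference from calibrator samples
#'
#' The per-SOMAmer median RFU over all calibrator samples across the supplied
#' plates defines the global calibrator reference. The same profile serves as
#' the normalization reference for median normalization of study/QC/buffer
#' samples (this pipeline carries no external healthy-donor reference).
#'
#' @param tables A `somamer_table` (possibly multi-plate) or a list of them.
#' @return A list of class `global_reference` with per-SOMAmer
#'   `calibrator_ref` and `normalization_ref` (named vectors over analyte
#'   SOMAmers).
#' @export
build_global_reference <- function(tables) {
  if (inherits(tables, "somamer_table")) tables <- list(tables)
  pooled <- list()
  ids <- NULL
  for (tab in tables) {
    tab <- validate_somamer_table(tab)
    analyte <- which(!tab$somamer_meta$is_hyb_control)
    this_ids <- tab$somamer_meta$somamer_id[analyte]
    if (is.null(ids)) {
      ids <- this_ids
    } else if (!identical(ids, this_ids)) {
      stopf("plates disagree on analyte SOMAmer ids")
    }
    cal <- which(tab$sample_meta$sample_type == "calibrator")
    if (length(cal)) {
      pooled[[length(pooled) + 1L]] <- tab$rfu[cal, analyte, drop = FALSE]
    }
  }
  if (!length(pooled)) stopf("no calibrator samples found")
  mat <- do.call(rbind, pooled)
  ref <- apply(mat, 2L, stats::median)
  names(ref) <- ids
  if (any(ref <= 0)) stopf("global reference contains non-positive values")
  structure(list(calibrator_ref = ref, normalization_ref = ref),
            class = "global_reference")
}

local_calibrator_medians <- function(rfu, pm, analyte, plate) {
  cal <- which(pm$plate_id == plate & pm$sample_type == "calibrator")
  if (!length(cal)) stopf("plate %s has no calibrator samples", plate)
  med <- apply(rfu[cal, analyte, drop = FALSE], 2L, stats::median)
  if (any(med <= 0)) stopf("zero local calibrator median on plate %s", plate)
  med
}

#' Plate scaling
#'
#' For each plate, per-SOMAmer scale factors (global calibrator reference
#' over local calibrator median) are computed and their median becomes the
#' single plate scale factor, applied to every analyte measurement on the
#' plate.
#'
#' @param table A `somamer_table` with intraplate-normalized calibrators.
#' @param ref A [build_global_reference()] result.
#' @return `list(table, factors)`; `factors$plate_scale` has one row per
#'   plate.
#' @export
plate_scale <- function(table, ref) {
  table <- validate_somamer_table(table)
  sm <- table$somamer_meta
  pm <- table$sample_meta
  analyte <- which(!sm$is_hyb_control)
  gref <- ref$calibrator_ref[sm$somamer_id[analyte]]
  if (anyNA(gref)) stopf("global reference does not cover all analyte SOMAmers")
  rfu <- table$rfu
  recs <- list()
  for (p in unique(pm$plate_id)) {
    med <- local_calibrator_medians(rfu, pm, analyte, p)
    fct <- stats::median(gref / med)
    check_positive_factors(fct, "plate scaling")
    rows <- which(pm$plate_id == p)
    rfu[rows, analyte] <- rfu[rows, analyte] * fct
    recs[[length(recs) + 1L]] <- data.frame(plate_id = p, factor = fct,
                                            stringsAsFactors = FALSE)
  }
  out <- table
  out$rfu <- rfu
  f <- empty_factors()
  f$plate_scale <- do.call(rbind, recs)
  list(table = out, factors = f)
}

#' Plate-to-plate calibration
#'
#' After plate scaling, a unique calibration scale factor (global calibrator
#' reference over local calibrator median) is derived for each SOMAmer on
#' each plate and applied to all measurements of that SOMAmer on the plate.
#' Afterwards the plate's calibrator median equals the global reference for
#' every SOMAmer.
#'
#' @inheritParams plate_scale
#' @return `list(table, factors)`; `factors$calibration` has one row per
#'   (plate, SOMAmer).
#' @export
calibrate <- function(table, ref) {
  table <- validate_somamer_table(table)
  sm <- table$somamer_meta
  pm <- table$sample_meta
  analyte <- which(!sm$is_hyb_control)
  gref <- ref$calibrator_ref[sm$somamer_id[analyte]]
  if (anyNA(gref)) stopf("global reference does not cover all analyte SOMAmers")
  rfu <- table$rfu
  recs <- list()
  for (p in unique(pm$plate_id)) {
    med <- local_calibrator_medians(rfu, pm, analyte, p)
    fct <- gref / med
    check_positive_factors(fct, "calibration")
    rows <- which(pm$plate_id == p)
    rfu[rows, analyte] <- sweep(rfu[rows, analyte, drop = FALSE], 2L, fct, `*`)
    recs[[length(recs) + 1L]] <- data.frame(
      plate_id = p, somamer_id = sm$somamer_id[analyte], factor = fct,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- table
  out$rfu <- rfu
  f <- empty_factors()
  f$calibration <- do.call(rbind, recs)
  list(table = out, factors = f)
}

#' Median normalization to the reference
#'
#' Applied to study, QC and buffer samples. For each such sample, ratios of
#' the normalization reference to the measured value are computed per analyte
#' SOMAmer; the median ratio within each dilution set is the scale factor for
#' that dilution and sample.
#'
#' @inheritParams plate_scale
#' @param sample_group Sample types to normalize.
#' @return `list(table, factors)`; `factors$ref_median` has one row per
#'   (sample, dilution set).
#' @export
median_normalize_to_reference <- function(table, ref,
                                          sample_group = c("study", "qc",
                                                           "buffer")) {
  table <- validate_somamer_table(table)
  sm <- table$somamer_meta
  pm <- table$sample_meta
  analyte <- which(!sm$is_hyb_control)
  gref <- ref$normalization_ref[sm$somamer_id[analyte]]
  if (anyNA(gref)) stopf("reference does not cover all analyte SOMAmers")
  rows <- which(pm$sample_type %in% sample_group)
  if (!length(rows)) {
    warnf("no samples of type %s; median normalization skipped",
          paste(sample_group, collapse = "/"))
    return(list(table = table, factors = empty_factors()))
  }
  dil <- sm$dilution_set[analyte]
  dils <- sort(unique(dil))
  rfu <- table$rfu
  recs <- list()
  for (i in rows) {
    if (any(rfu[i, analyte] <= 0)) {
      stopf("zero or negative RFU in sample '%s'", pm$sample_id[i])
    }
    ratios <- gref / rfu[i, analyte]
    for (d in dils) {
      idx <- analyte[dil == d]
      fct <- stats::median(ratios[dil == d])
      check_positive_factors(fct, "median normalization to reference")
      rfu[i, idx] <- rfu[i, idx] * fct
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = pm$sample_id[i], dilution_set = d, factor = fct,
        stringsAsFactors = FALSE)
    }
  }
  out <- table
  out$rfu <- rfu
  f <- empty_factors()
  f$ref_median <- do.call(rbind, recs)
  list(table = out, factors = f)
}

#' QC acceptance report
#'
#' Checks each scale-factor class against the acceptance band `[0.4, 2.5]`
#' and the distribution of QC-sample ratios to the reference against the band
#' `[0.84, 1.19]`, which must contain at least 85% of the per-SOMAmer ratios.
#'
#' @param factors A `norm_factors` object (typically the merged factors from
#'   [normalize_pipeline()]).
#' @param factor_band Acceptance band for scale factors.
#' @param ratio_band Acceptance band for QC ratios.
#' @param min_ratio_fraction Minimum in-band fraction of QC ratios.
#' @return A list of class `qc_report`: per-class pass/fail, the in-band
#'   QC-ratio fraction, and the overall verdict.
#' @export
qc_report <- function(factors, factor_band = c(0.4, 2.5),
                      ratio_band = c(0.84, 1.19),
                      min_ratio_fraction = 0.85) {
  # The 0.4-2.5 band applies to hybridization, intraplate and plate-scale
  # factors; per-sample median-normalization factors are reported but not
  # banded (buffer samples sit far below the reference by design).
  banded <- c("hyb", "intraplate", "plate_scale")
  checks <- lapply(c(banded, "ref_median"), function(cl) {
    f <- factors[[cl]]
    if (is.null(f) || !nrow(f)) {
      return(data.frame(class = cl, n = 0L, min = NA_real_, max = NA_real_,
                        pass = NA, stringsAsFactors = FALSE))
    }
    data.frame(class = cl, n = nrow(f), min = min(f$factor),
               max = max(f$factor),
               pass = if (cl %in% banded) {
                 all(f$factor >= factor_band[1] & f$factor <= factor_band[2])
               } else {
                 NA
               },
               stringsAsFactors = FALSE)
  })
  checks <- do.call(rbind, checks)
  qc_fraction <- NA_real_
  qc_pass <- NA
  if (!is.null(factors$qc_ratios) && nrow(factors$qc_ratios)) {
    r <- factors$qc_ratios$ratio
    qc_fraction <- mean(r >= ratio_band[1] & r <= ratio_band[2])
    qc_pass <- qc_fraction >= min_ratio_fraction
  }
  verdict <- all(checks$pass[!is.na(checks$pass)]) &&
    (is.na(qc_pass) || qc_pass)
  structure(list(factor_checks = checks, qc_fraction = qc_fraction,
                 qc_pass = qc_pass, factor_band = factor_band,
                 ratio_band = ratio_band,
                 min_ratio_fraction = min_ratio_fraction,
                 pass = verdict), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC acceptance report\n")
  print(x$factor_checks, row.names = FALSE)
  if (!is.na(x$qc_fraction)) {
    cat(sprintf("QC ratios in [%.2f, %.2f]: %.1f%% (needs >= %.0f%%): %s\n",
                x$ratio_band[1], x$ratio_band[2], 100 * x$qc_fraction,
                100 * x$min_ratio_fraction,
                if (isTRUE(x$qc_pass)) "pass" else "FAIL"))
  }
  cat("overall:", if (isTRUE(x$pass)) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Full normalization and calibration chain
#'
#' Runs hybridization normalization, intraplate median normalization of
#' calibrators, plate scaling, calibration and median normalization of
#' study/QC/buffer samples to the reference, in that order; then computes
#' per-SOMAmer QC-sample ratios to the normalization reference and the QC
#' acceptance report.
#'
#' @param table A raw `somamer_table` (one or more plates, each with
#'   calibrator samples).
#' @param ref Optional [build_global_reference()]; by default it is built
#'   from the table's own calibrators after hybridization and intraplate
#'   normalization.
#' @return A list with `table` (normalized), `factors` (all factor classes
#'   merged) and `report` (a [qc_report()]).
#' @export
normalize_pipeline <- function(table, ref = NULL) {
  all_f <- empty_factors()
  s1 <- hybridization_normalize(table)
  all_f <- merge_factors(all_f, s1$factors)
  s2 <- intraplate_median_normalize(s1$table)
  all_f <- merge_factors(all_f, s2$factors)
  if (is.null(ref)) ref <- build_global_reference(s2$table)
  s3 <- plate_scale(s2$table, ref)
  all_f <- merge_factors(all_f, s3$factors)
  s4 <- calibrate(s3$table, ref)
  all_f <- merge_factors(all_f, s4$factors)
  s5 <- median_normalize_to_reference(s4$table, ref)
  all_f <- merge_factors(all_f, s5$factors)
  tab <- s5$table
  qc_rows <- which(tab$sample_meta$sample_type == "qc")
  if (length(qc_rows)) {
    analyte <- which(!tab$somamer_meta$is_hyb_control)
    gref <- ref$normalization_ref[tab$somamer_meta$somamer_id[analyte]]
    recs <- lapply(qc_rows, function(i) {
      data.frame(sample_id = tab$sample_meta$sample_id[i],
                 somamer_id = tab$somamer_meta$somamer_id[analyte],
                 ratio = tab$rfu[i, analyte] / gref,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    all_f$qc_ratios <- do.call(rbind, recs)
  }
  list(table = tab, factors = all_f, reference = ref,
       report = qc_report(all_f))
}
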