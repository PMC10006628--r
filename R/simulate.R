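#' Simulation configuration for a synthetic aptamer-proteomics cohort
#'
#' Bundles every knob of the synthetic cohort generator. Defaults emulate the
#' shape of a derivation cohort of first-MI patients profiled on a
#' plate-structured aptamer array: 254 patients, three plates carrying
#' calibrator/QC/buffer control samples, 320 analyte SOMAmers of which 20 are
#' flagged for removal and 20 proteins are measured by more than one SOMAmer
#' (leaving 275 analysis proteins), a latent high-risk subgroup holding 37%
#' of patients whose 50 informative proteins are shifted by 1.5 on the log2
#' scale, a true group-2 subdistribution hazard ratio of 7 for the HF
#' endpoint (the magnitude observed for proteomic risk groups in post-MI
#' cohorts), all-cause death as the competing event, administrative
#' censoring uniform on 6-16 years of follow-up, and sparse clinical
#' missingness at the per-cell rate 53/6858.
#'
#' @param n_patients Number of study patients.
#' @param n_somamers Number of analyte SOMAmer reagents (hybridization
#'   controls are extra columns, see `n_hyb_controls`).
#' @param removal_count SOMAmers flagged for removal before analysis.
#' @param dup2_count,dup3_count Number of proteins measured by 2 and by 3
#'   SOMAmers respectively.
#' @param n_plates Number of assay plates.
#' @param calibrators_per_plate,qc_per_plate,buffer_per_plate Control samples
#'   added to each plate.
#' @param n_hyb_controls Hybridization control sequences per sample array.
#' @param group2_fraction Proportion of patients in the latent high-risk
#'   group (group 2).
#' @param n_informative Number of proteins whose mean differs between the
#'   two latent groups.
#' @param delta Group-2 mean shift of informative proteins, log2 scale.
#' @param protein_sd Per-protein biological (between-patient) SD on the log2
#'   scale.
#' @param beta1 True subdistribution log-hazard coefficient of group 2 for
#'   the HF endpoint (cause 1).
#' @param p_asym Asymptotic probability of the HF endpoint at baseline, in
#'   (0, 1).
#' @param lambda1,lambda2 Event-time rate parameters (1/years) for the HF
#'   subdistribution and the competing death time.
#' @param censor_lo,censor_hi Administrative censoring window (years);
#'   `Inf, Inf` disables censoring.
#' @param clinical_missing_rate Per-cell missingness probability of the
#'   clinical table.
#' @param sample_bias_range Range of the per-sample multiplicative readout
#'   bias (uniform).
#' @param plate_bias_sd Log-scale SD of the per-plate multiplicative bias.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise.
#' @param seed Master seed; every component derives its own sub-stream from
#'   it so modules can be regenerated independently.
#'
#' @return A validated list of class `sim_config`. `n_proteins` is derived as
#'   `n_somamers - removal_count - dup2_count - 2 * dup3_count`.
#' @export
sim_config <- function(n_patients = 254,
                       n_somamers = 320,
                       removal_count = 20,
                       dup2_count = 15,
                       dup3_count = 5,
                       n_plates = 3,
                       calibrators_per_plate = 5,
                       qc_per_plate = 2,
                       buffer_per_plate = 1,
                       n_hyb_controls = 12,
                       group2_fraction = 0.37,
                       n_informative = 50,
                       delta = 1.5,
                       protein_sd = 0.5,
                       beta1 = log(7),
                       p_asym = 0.10,
                       lambda1 = 0.12,
                       lambda2 = 0.035,
                       censor_lo = 6,
                       censor_hi = 16,
                       clinical_missing_rate = 53 / 6858,
                       sample_bias_range = c(0.7, 1.4),
                       plate_bias_sd = 0.05,
                       noise_cv = 0.05,
                       seed = 1L) {
  cfg <- list(n_patients = n_patients, n_somamers = n_somamers,
              removal_count = removal_count, dup2_count = dup2_count,
              dup3_count = dup3_count, n_plates = n_plates,
              calibrators_per_plate = calibrators_per_plate,
              qc_per_plate = qc_per_plate, buffer_per_plate = buffer_per_plate,
              n_hyb_controls = n_hyb_controls,
              group2_fraction = group2_fraction,
              n_informative = n_informative, delta = delta,
              protein_sd = protein_sd, beta1 = beta1,
              p_asym = p_asym, lambda1 = lambda1, lambda2 = lambda2,
              censor_lo = censor_lo, censor_hi = censor_hi,
              clinical_missing_rate = clinical_missing_rate,
              sample_bias_range = sample_bias_range,
              plate_bias_sd = plate_bias_sd, noise_cv = noise_cv,
              seed = as.integer(seed))
  cfg$n_proteins <- n_somamers - removal_count - dup2_count - 2L * dup3_count
  counts <- c("n_patients", "n_somamers", "removal_count", "dup2_count",
              "dup3_count", "n_plates", "calibrators_per_plate",
              "qc_per_plate", "buffer_per_plate", "n_hyb_controls",
              "n_informative")
  for (nm in counts) {
    if (cfg[[nm]] < 0) stopf("%s must be >= 0", nm)
  }
  if (cfg$n_proteins <= 0) stopf("configuration leaves no analysis proteins")
  if (!(p_asym > 0 && p_asym < 1)) stopf("p_asym must be in (0, 1)")
  if (!(group2_fraction > 0 && group2_fraction < 1)) {
    stopf("group2_fraction must be in (0, 1)")
  }
  if (censor_lo > censor_hi) stopf("censor_lo must be <= censor_hi")
  if (n_informative > cfg$n_proteins) {
    stopf("n_informative (%d) exceeds the number of proteins (%d)",
          n_informative, cfg$n_proteins)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate competing-risk event data from a direct subdistribution model
#'
#' Draws, for each patient, a time and cause under the mixture construction
#' in which the cause-1 (HF hospitalization) cumulative incidence given the
#' linear predictor `x` is
#' \deqn{F_1(t \mid x) = 1 - \{1 - p\,(1 - e^{-\lambda_1 t})\}^{\exp(x)},}
#' so the asymptotic cause-1 probability is \eqn{1 - (1-p)^{\exp(x)}} and the
#' true subdistribution hazard ratio for a unit increase in the covariate
#' behind `x` is exactly the exponentiated coefficient. Cause-1 times come
#' from inverting this CDF; patients escaping cause 1 die from the competing
#' cause at an exponential(`lambda2`) time; independent uniform
#' administrative censoring on `[censor_lo, censor_hi]` is applied.
#'
#' @param linpred Per-patient linear predictor (already including the
#'   coefficient, i.e. \eqn{x^\top\beta}).
#' @param cfg A [sim_config()] supplying `p_asym`, `lambda1`, `lambda2`,
#'   `censor_lo`, `censor_hi`.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#'
#' @return Data frame with columns `time` (years) and `cause`
#'   (0 censored, 1 HF hospitalization, 2 all-cause death).
#' @export
simulate_competing_events <- function(linpred, cfg, seed = NULL) {
  if (any(!is.finite(linpred))) {
    stopf("non-finite linear predictor for patient(s): %s",
          paste(which(!is.finite(linpred)), collapse = ", "))
  }
  draw <- function() {
    n <- length(linpred)
    eta <- exp(linpred)
    p <- cfg$p_asym
    p1_inf <- 1 - (1 - p)^eta
    u <- stats::runif(n)
    is1 <- u <= p1_inf
    t_event <- numeric(n)
    # Inverse of F1 at u (valid for u <= F1(inf|x)):
    # t = -log(1 - (1 - (1-u)^{1/eta}) / p) / lambda1
    if (any(is1)) {
      inner <- (1 - (1 - u[is1])^(1 / eta[is1])) / p
      t_event[is1] <- -log(1 - inner) / cfg$lambda1
    }
    if (any(!is1)) {
      t_event[!is1] <- stats::rexp(sum(!is1), rate = cfg$lambda2)
    }
    cens <- if (is.infinite(cfg$censor_lo)) {
      rep(Inf, n)
    } else {
      stats::runif(n, cfg$censor_lo, cfg$censor_hi)
    }
    time <- pmin(t_event, cens)
    cause <- ifelse(cens < t_event, 0L, ifelse(is1, 1L, 2L))
    data.frame(time = time, cause = as.integer(cause))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Somamer-level structure shared between cohorts generated from one design:
# protein baseline means, informative set, the protein -> SOMAmer map and
# hybridization control levels.
simulate_structure <- function(cfg) {
  n_prot <- cfg$n_proteins
  proteins <- sprintf("PROT%04d", seq_len(n_prot))
  mu <- stats::runif(n_prot, 6, 12)          # baseline log2 RFU per protein
  informative <- sort(sample.int(n_prot, cfg$n_informative))
  # Multiplicity: dup3 proteins first, then dup2, rest single.
  mult <- rep(1L, n_prot)
  if (cfg$dup3_count > 0) mult[seq_len(cfg$dup3_count)] <- 3L
  if (cfg$dup2_count > 0) {
    mult[cfg$dup3_count + seq_len(cfg$dup2_count)] <- 2L
  }
  prot_idx <- rep(seq_len(n_prot), times = mult)
  n_analyte <- length(prot_idx) + cfg$removal_count
  stopifnot(n_analyte == cfg$n_somamers)
  symbol <- c(proteins[prot_idx],
              sprintf("FLG%03d", seq_len(cfg$removal_count)))
  flagged <- c(rep(FALSE, length(prot_idx)), rep(TRUE, cfg$removal_count))
  mu_somamer <- c(mu[prot_idx], stats::runif(cfg$removal_count, 6, 12))
  # Small fixed per-SOMAmer reporter efficiency (log2 offset).
  offset <- stats::rnorm(n_analyte, 0, 0.1)
  hyb_levels <- 2^seq(6, 13, length.out = cfg$n_hyb_controls)
  list(proteins = proteins, mu = mu, informative = informative,
       somamer = data.frame(
         somamer_id = sprintf("SM%05d", seq_len(n_analyte)),
         protein_symbol = symbol,
         dilution_set = rep_len(c(1L, 2L, 3L), n_analyte),
         is_hyb_control = FALSE,
         flagged_removed = flagged,
         stringsAsFactors = FALSE),
       protein_of_somamer = c(prot_idx, rep(NA_integer_, cfg$removal_count)),
       mu_somamer = mu_somamer, offset = offset,
       hyb_levels = hyb_levels,
       sigma_bio = cfg$protein_sd)
}

#' Simulate a full plate-structured cohort with competing-risk outcomes
#'
#' Generates the complete input set of the workflow: a plate-structured
#' SOMAmer RFU table with hybridization controls and calibrator/QC/buffer
#' control samples, a 27-variable clinical table with sparse missingness, a
#' competing-risk follow-up table, and a truth record for recovery testing.
#'
#' Study samples carry a latent two-group structure: group-2 patients
#' (fraction `group2_fraction`) have their `n_informative` proteins shifted
#' upward by `delta` on the log2 scale. Raw RFU values are the true
#' abundances times a per-sample readout bias (uniform on
#' `sample_bias_range`), a per-plate bias (lognormal, sd `plate_bias_sd`) and
#' multiplicative lognormal noise (`noise_cv`). Calibrator and QC samples
#' share the pooled population profile; buffer samples sit at background.
#' Outcomes are drawn from [simulate_competing_events()] with linear
#' predictor `beta1 * I(group 2)`, so the true group subdistribution hazard
#' ratio is `exp(beta1)`.
#'
#' @param cfg A [sim_config()].
#' @param structure Optional structure from a previous cohort (element
#'   `$structure` of the return value); supply it to generate an independent
#'   validation cohort measuring the same proteins with the same informative
#'   set.
#'
#' @return A list of class `synthetic_cohort` with elements `somamer_table`,
#'   `clinical` (missingness already injected at `clinical_missing_rate`),
#'   `outcomes`, `truth` (latent group, informative protein symbols, true
#'   `beta1`, complete clinical table) and `structure`.
#' @export
simulate_cohort <- function(cfg, structure = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(structure)) {
    structure <- with_seed(derive_seed(cfg$seed, 1L), simulate_structure(cfg))
  }
  st <- structure
  n <- cfg$n_patients

  rfu_parts <- with_seed(derive_seed(cfg$seed, 2L), {
    group <- 1L + stats::rbinom(n, 1L, cfg$group2_fraction)
    # True patient-level log2 abundance per protein.
    L <- matrix(rep(st$mu, each = n), nrow = n) +
      matrix(stats::rnorm(n * length(st$mu), 0, st$sigma_bio), nrow = n)
    L[, st$informative] <- L[, st$informative] +
      cfg$delta * (group == 2L)
    list(group = group, L = L)
  })
  group <- rfu_parts$group
  patient_ids <- sprintf("PAT%04d", seq_len(n))

  # Assemble plate layout: controls first, then study samples round-robin.
  plate_of_patient <- rep_len(seq_len(cfg$n_plates), n)
  ctrl_per_plate <- cfg$calibrators_per_plate + cfg$qc_per_plate +
    cfg$buffer_per_plate
  sample_rows <- list()
  for (p in seq_len(cfg$n_plates)) {
    ids <- c(sprintf("CAL-P%d-%d", p, seq_len(cfg$calibrators_per_plate)),
             sprintf("QC-P%d-%d", p, seq_len(cfg$qc_per_plate)),
             sprintf("BUF-P%d-%d", p, seq_len(cfg$buffer_per_plate)))
    types <- c(rep("calibrator", cfg$calibrators_per_plate),
               rep("qc", cfg$qc_per_plate),
               rep("buffer", cfg$buffer_per_plate))
    keep <- nzchar(ids)
    sample_rows[[p]] <- data.frame(
      sample_id = c(ids[keep], patient_ids[plate_of_patient == p]),
      sample_type = c(types[keep],
                      rep("study", sum(plate_of_patient == p))),
      plate_id = sprintf("P%d", p), stringsAsFactors = FALSE)
  }
  sample_meta <- do.call(rbind, sample_rows)
  rownames(sample_meta) <- NULL

  somamer_meta <- rbind(
    st$somamer,
    data.frame(somamer_id = sprintf("HYB%02d", seq_len(cfg$n_hyb_controls)),
               protein_symbol = sprintf("HYBCTRL%02d",
                                        seq_len(cfg$n_hyb_controls)),
               dilution_set = 1L, is_hyb_control = TRUE,
               flagged_removed = FALSE, stringsAsFactors = FALSE))

  rfu <- with_seed(derive_seed(cfg$seed, 3L), {
    ns <- nrow(sample_meta)
    n_col <- nrow(somamer_meta)
    # True expected RFU per sample x SOMAmer.
    true <- matrix(0, ns, n_col)
    is_hyb <- somamer_meta$is_hyb_control
    analyte_mu <- st$mu_somamer + st$offset
    pooled <- 2^analyte_mu                     # pooled population profile
    background <- 2^5
    for (i in seq_len(ns)) {
      stype <- sample_meta$sample_type[i]
      if (stype == "study") {
        pi <- match(sample_meta$sample_id[i], patient_ids)
        lv <- st$protein_of_somamer
        vals <- numeric(sum(!is_hyb))
        ok <- !is.na(lv)
        vals[ok] <- 2^(rfu_parts$L[pi, lv[ok]] + st$offset[ok])
        vals[!ok] <- 2^(st$mu_somamer[!ok] + st$offset[!ok] +
                          stats::rnorm(sum(!ok), 0, st$sigma_bio))
        true[i, !is_hyb] <- vals
      } else if (stype %in% c("calibrator", "qc")) {
        true[i, !is_hyb] <- pooled
      } else {
        true[i, !is_hyb] <- background
      }
      true[i, is_hyb] <- st$hyb_levels
    }
    sample_bias <- stats::runif(ns, cfg$sample_bias_range[1],
                                cfg$sample_bias_range[2])
    plate_bias <- exp(stats::rnorm(cfg$n_plates, 0, cfg$plate_bias_sd))
    names(plate_bias) <- sprintf("P%d", seq_len(cfg$n_plates))
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- matrix(exp(stats::rnorm(ns * n_col, 0, sdlog)), ns, n_col)
    true * sample_bias * plate_bias[sample_meta$plate_id] * noise
  })

  tab <- somamer_table(rfu, somamer_meta, sample_meta)

  linpred <- cfg$beta1 * (group == 2L)
  outcomes <- simulate_competing_events(linpred, cfg,
                                        seed = derive_seed(cfg$seed, 4L))
  outcomes <- cbind(patient_id = patient_ids, outcomes)

  clinical_full <- with_seed(derive_seed(cfg$seed, 5L),
                             simulate_clinical(group))
  clinical_full <- cbind(patient_id = patient_ids, clinical_full)
  clinical <- inject_missing(clinical_full, cfg$clinical_missing_rate,
                             seed = derive_seed(cfg$seed, 6L))

  structure(list(
    somamer_table = tab,
    clinical = clinical,
    outcomes = outcomes,
    truth = list(group = group,
                 informative = st$proteins[st$informative],
                 beta1 = cfg$beta1,
                 clinical_complete = clinical_full,
                 linpred = linpred),
    structure = st,
    config = cfg), class = "synthetic_cohort")
}

# 27 clinical variables: 8 named ones used for adjustment plus 19 noise
# columns. Group-2 patients are older, with lower ejection fraction, more
# diabetes/Killip >= 2 and higher natriuretic peptides.
simulate_clinical <- function(group) {
  n <- length(group)
  g2 <- group == 2L
  out <- data.frame(
    age = round(stats::rnorm(n, 54 + 11 * g2, 13), 1),
    gender = stats::rbinom(n, 1L, ifelse(g2, 0.21, 0.29)),
    lvef = round(stats::rnorm(n, 51 - 6 * g2, 9), 1),
    diabetes = stats::rbinom(n, 1L, ifelse(g2, 0.31, 0.18)),
    killip2 = stats::rbinom(n, 1L, ifelse(g2, 0.45, 0.18)),
    creatinine = round(stats::rnorm(n, 1.0 + 0.15 * g2, 0.25), 3),
    bnp = round(exp(stats::rnorm(n, 4.5 + 0.8 * g2, 0.9)), 1),
    ntprobnp = round(exp(stats::rnorm(n, 6.0 + 0.9 * g2, 1.0)), 1)
  )
  for (j in 9:27) {
    out[[sprintf("clin%02d", j)]] <- round(stats::rnorm(n), 3)
  }
  out
}

#' Mask clinical cells at random
#'
#' Independently masks each data cell (every column except `patient_id`) with
#' probability `rate`. The complete table is retained in the `"complete"`
#' attribute and the mask in `"mask"`, so imputation accuracy can be checked.
#'
#' @param clinical Clinical data frame.
#' @param rate Per-cell masking probability in `[0, 1)`.
#' @param seed Optional seed.
#' @return The masked data frame, with attributes `complete`, `mask` and
#'   `n_masked`.
#' @export
inject_missing <- function(clinical, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) {
    stopf("masking rate must be in [0, 1); a fully missing table is unusable")
  }
  cols <- setdiff(names(clinical), "patient_id")
  if (rate == 0) {
    attr(clinical, "complete") <- clinical
    attr(clinical, "n_masked") <- 0L
    return(clinical)
  }
  run <- function() {
    mask <- matrix(stats::runif(nrow(clinical) * length(cols)) < rate,
                   nrow = nrow(clinical))
    out <- clinical
    for (j in seq_along(cols)) {
      out[[cols[j]]][mask[, j]] <- NA
    }
    attr(out, "complete") <- clinical
    attr(out, "mask") <- mask
    attr(out, "n_masked") <- sum(mask)
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients, %d analyte SOMAmers, %d plates\n",
              x$config$n_patients, x$config$n_somamers, x$config$n_plates))
  cat(sprintf("  latent groups: %d / %d; informative proteins: %d; true beta1 = %.4f\n",
              sum(x$truth$group == 1L), sum(x$truth$group == 2L),
              length(x$truth$informative), x$truth$beta1))
  tab <- table(x$outcomes$cause)
  cat("  outcomes:", paste(sprintf("cause %s: %d", names(tab), tab),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Write all cohort components to a directory
#'
#' Writes the ADAT-dialect file, clinical and outcome TSVs and a JSON truth
#' record (latent group, informative proteins, true coefficient).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    adat = file.path(dir, "cohort.adat"),
    clinical = file.path(dir, "clinical.tsv"),
    outcomes = file.path(dir, "outcomes.tsv"),
    truth = file.path(dir, "truth.json"))
  write_adat(cohort$somamer_table, paths["adat"])
  write_clinical(cohort$clinical, paths["clinical"])
  write_outcomes(cohort$outcomes, paths["outcomes"])
  jsonlite::write_json(
    list(group = cohort$truth$group,
         informative = cohort$truth$informative,
         beta1 = cohort$truth$beta1),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
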