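# Shared fixture builders and independent oracles.

# Minimal somamer_table built by hand: `values` is samples x analytes,
# optionally with extra hybridization-control columns appended.
make_table <- function(values, hyb = NULL, plate_id = "P1",
                       sample_type = NULL, dilution = NULL,
                       protein = NULL, flagged = NULL) {
  values <- as.matrix(values)
  n_s <- nrow(values)
  n_a <- ncol(values)
  if (is.null(sample_type)) sample_type <- rep("study", n_s)
  if (is.null(dilution)) dilution <- rep_len(1:3, n_a)
  if (is.null(protein)) protein <- sprintf("PR%03d", seq_len(n_a))
  if (is.null(flagged)) flagged <- rep(FALSE, n_a)
  plate_id <- rep_len(plate_id, n_s)
  rfu <- values
  som <- data.frame(somamer_id = sprintf("SM%03d", seq_len(n_a)),
                    protein_symbol = protein,
                    dilution_set = dilution,
                    is_hyb_control = FALSE,
                    flagged_removed = flagged,
                    stringsAsFactors = FALSE)
  if (!is.null(hyb)) {
    hyb <- as.matrix(hyb)
    rfu <- cbind(rfu, hyb)
    som <- rbind(som, data.frame(
      somamer_id = sprintf("HYB%02d", seq_len(ncol(hyb))),
      protein_symbol = sprintf("HYBC%02d", seq_len(ncol(hyb))),
      dilution_set = 1L, is_hyb_control = TRUE, flagged_removed = FALSE,
      stringsAsFactors = FALSE))
  }
  somamer_table(rfu, som,
                data.frame(sample_id = sprintf("S%03d", seq_len(n_s)),
                           sample_type = sample_type, plate_id = plate_id,
                           stringsAsFactors = FALSE))
}

# Brute-force Cox partial log-likelihood (Breslow) for a single covariate,
# no ties assumed handled beyond Breslow. Independent of the package's
# Newton path: used as the 1-D optimization oracle.
cox_loglik_brute <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(time[status == 1])) {
    ev <- which(time == t & status == 1)
    risk <- which(time >= t)
    ll <- ll + sum(x[ev] * beta) -
      length(ev) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# Adjusted Rand index from the contingency-table formula (independent of
# any clustering package).
ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- ai * bj / n2
  (nij - exp_idx) / ((ai + bj) / 2 - exp_idx)
}

# Standardized protein matrix with a planted two-group structure, built
# directly (no assay layer): the minimal input for clustering tests.
make_two_group_matrix <- function(n = 250, p = 50, frac2 = 0.38,
                                  delta = 1.5, seed = 1) {
  set.seed(seed)
  g <- 1L + as.integer(runif(n) < frac2)
  X <- matrix(rnorm(n * p), n, p) + delta * (g == 2L)
  X <- scale(X)
  colnames(X) <- sprintf("PR%03d", seq_len(p))
  list(X = X, group = g)
}

# Global-null screening replicate: correlated standardized proteins and
# outcomes drawn independently of them (~30% HF, ~25% death, rest censored).
null_screen_replicate <- function(seed, n = 150, p = 200, block = 10,
                                  rho = 0.5) {
  set.seed(seed)
  nb <- p / block
  Z <- matrix(rnorm(n * nb), n, nb)
  X <- sqrt(rho) * Z[, rep(seq_len(nb), each = block)] +
    sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
  X <- scale(X)
  colnames(X) <- sprintf("P%03d", seq_len(p))
  cfg <- sim_config(p_asym = 0.35, lambda1 = 0.35, lambda2 = 0.07,
                    censor_lo = 2, censor_hi = 12)
  out <- simulate_competing_events(rep(0, n), cfg)
  univariate_screen(X, out)
}

# Small simulation config so whole-cohort tests stay fast; overrides win.
small_cfg <- function(...) {
  defaults <- list(n_patients = 120, n_somamers = 40, removal_count = 4,
                   dup2_count = 3, dup3_count = 1, n_informative = 8,
                   n_plates = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
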