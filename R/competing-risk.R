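# Nonparametric cumulative incidence and Fine-Gray subdistribution-hazard
# regression, implemented from first principles.
#
# The Fine-Gray fit maximizes the IPCW-weighted subdistribution partial
# likelihood: subjects failing from the competing cause remain in the risk
# set after their event with weight w_i(t) = G(t-)/G(T_i-), where G is the
# Kaplan-Meier estimator of the censoring distribution. Ties are handled by
# the Breslow approximation. Newton-Raphson with step-halving guarantees
# monotone likelihood ascent.

#' Aalen-Johansen cumulative incidence function
#'
#' Nonparametric CIF for one cause in the presence of competing risks:
#' \eqn{\hat F_k(t) = \sum_{t_j \le t} \hat S(t_j-) d_{kj} / n_j}, with
#' \eqn{\hat S} the all-cause Kaplan-Meier survivor function.
#'
#' @param outcomes Data frame with `time` and `cause` (0 censored, 1, 2).
#' @param cause Cause of interest (default 1, HF hospitalization).
#' @return A data frame of class `cif_curve` with columns `time`, `n_risk`,
#'   `n_event` (events of the requested cause at that time), `surv`
#'   (all-cause KM just after `time`) and `cif`. Evaluate it with
#'   [cif_at()].
#' @export
cif_aalen_johansen <- function(outcomes, cause = 1L) {
  outcomes <- validate_outcomes(outcomes)
  time <- outcomes$time
  status <- outcomes$cause
  if (!any(status == cause)) {
    warnf("no events of cause %d; cumulative incidence is identically zero",
          cause)
  }
  tj <- sort(unique(time[status > 0]))
  n <- length(time)
  n_risk <- vapply(tj, function(t) sum(time >= t), numeric(1))
  d_all <- vapply(tj, function(t) sum(time == t & status > 0), numeric(1))
  d_k <- vapply(tj, function(t) sum(time == t & status == cause), numeric(1))
  surv_prev <- cumprod(c(1, (1 - d_all / n_risk)))[seq_along(tj)]  # S(t_j-)
  cif <- cumsum(surv_prev * d_k / n_risk)
  structure(data.frame(time = tj, n_risk = n_risk, n_event = d_k,
                       surv = surv_prev * (1 - d_all / n_risk), cif = cif),
            class = c("cif_curve", "data.frame"), cause = cause)
}

#' Evaluate a CIF curve at arbitrary times
#'
#' Right-continuous step-function evaluation; 0 before the first event time.
#'
#' @param curve A [cif_aalen_johansen()] result.
#' @param t Times at which to evaluate.
#' @return Numeric vector of CIF values.
#' @export
cif_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  c(0, curve$cif)[idx + 1L]
}

#' Kaplan-Meier survivor of the censoring distribution
#'
#' Treats censorings as the event of interest and events as censorings; used
#' for the inverse-probability-of-censoring weights of the subdistribution
#' partial likelihood. The returned function evaluates left-continuously,
#' i.e. it gives \eqn{\hat G(t-)}.
#'
#' @param outcomes Data frame with `time` and `cause`.
#' @return A function `G(t)` returning \eqn{\hat G(t-)}; its environment
#'   carries the step times and values.
#' @export
censoring_survivor <- function(outcomes) {
  outcomes <- validate_outcomes(outcomes)
  sf <- survival::survfit(survival::Surv(outcomes$time, outcomes$cause == 0) ~ 1)
  times <- sf$time
  surv <- sf$surv
  # left-continuous: G(t-) jumps strictly after the censoring time
  fn <- stats::stepfun(times, c(1, surv), right = TRUE)
  structure(function(t) fn(t), times = times, surv = surv)
}

# Risk-set structure shared by every fit on the same outcome data:
# unique cause-1 event times, Breslow multiplicities, per-time weight matrix
# and the rows of subjects failing at each time.
fg_structure <- function(outcomes) {
  outcomes <- validate_outcomes(outcomes)
  time <- outcomes$time
  status <- as.integer(outcomes$cause)
  if (!any(status == 1L)) stopf("no cause-1 events; nothing to fit")
  G <- censoring_survivor(outcomes)
  tj <- sort(unique(time[status == 1L]))
  m <- length(tj)
  n <- length(time)
  W <- matrix(0, m, n)
  Gt <- G(tj)
  Gi <- G(time)
  for (j in seq_len(m)) {
    at_risk <- time >= tj[j]
    W[j, at_risk] <- 1
    late <- !at_risk & status == 2L
    if (any(late)) W[j, late] <- Gt[j] / Gi[late]
  }
  d <- vapply(tj, function(t) sum(time == t & status == 1L), numeric(1))
  ev <- lapply(tj, function(t) which(time == t & status == 1L))
  list(times = tj, W = W, d = d, ev = ev, n = n)
}

fg_loglik <- function(beta, X, str) {
  eta <- drop(X %*% beta)
  r <- exp(eta)
  S0 <- drop(str$W %*% r)
  ev_eta <- vapply(str$ev, function(ix) sum(eta[ix]), numeric(1))
  sum(ev_eta - str$d * log(S0))
}

fg_score_info <- function(beta, X, str) {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  r <- exp(eta)
  S0 <- drop(str$W %*% r)
  S1 <- str$W %*% (r * X)                  # m x p
  xbar <- S1 / S0
  ev_x <- t(vapply(str$ev, function(ix) colSums(X[ix, , drop = FALSE]),
                   numeric(p)))
  if (p == 1L) ev_x <- matrix(ev_x, ncol = 1L)
  U <- colSums(ev_x) - colSums(str$d * xbar)
  I <- matrix(0, p, p)
  for (k in seq_len(p)) {
    for (l in k:p) {
      S2 <- drop(str$W %*% (r * X[, k] * X[, l]))
      I[k, l] <- I[l, k] <- sum(str$d * (S2 / S0 - xbar[, k] * xbar[, l]))
    }
  }
  list(U = U, I = I)
}

#' Fit a Fine-Gray subdistribution hazard model
#'
#' Maximizes the IPCW-weighted subdistribution partial likelihood for the
#' cause-1 (HF hospitalization) subdistribution hazard by Newton-Raphson
#' with step-halving. Subjects failing from the competing cause remain in
#' the risk set after their event with weight \eqn{\hat G(t-)/\hat G(T_i-)},
#' \eqn{\hat G} being the Kaplan-Meier censoring survivor. Ties use the
#' Breslow approximation. Standard errors come from the observed
#' information of the weighted partial likelihood.
#'
#' @param X Covariate matrix (patients x covariates) or a single numeric
#'   vector. Columns must be finite and non-constant.
#' @param outcomes Data frame with `time` and `cause`, aligned with the rows
#'   of `X`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return A list of class `fine_gray_fit`: `coef` (log subdistribution
#'   hazard ratios), `se`, `shr`, `ci_lower`/`ci_upper` (95%), `z`, `p`
#'   (two-sided Wald), `loglik`, `iter`, `converged`.
#' @export
fit_fine_gray <- function(X, outcomes, tol = 1e-9, max_iter = 100L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- if (ncol(X) == 1L) "x" else paste0("x", seq_len(ncol(X)))
  }
  if (any(!is.finite(X))) stopf("covariate matrix contains non-finite values")
  const <- apply(X, 2L, function(v) length(unique(v)) < 2L)
  if (any(const)) {
    stopf("constant covariate column(s): %s",
          paste(colnames(X)[const], collapse = ", "))
  }
  str <- fg_structure(outcomes)
  if (nrow(X) != str$n) stopf("X has %d rows but outcomes %d", nrow(X), str$n)
  p <- ncol(X)
  beta <- rep(0, p)
  ll <- fg_loglik(beta, X, str)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    si <- fg_score_info(beta, X, str)
    delta <- solve(si$I, si$U)
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- fg_loglik(cand, X, str)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-8) {
        stopf("Fine-Gray fit failed: step-halving exhausted at iteration %d (loglik %.6f)",
              iter, ll)
      }
    }
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    beta <- cand
    ll <- ll_new
    if (any(abs(beta) > 20)) {
      stopf("separation detected: |beta| > 20 (covariate perfectly orders the subdistribution)")
    }
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stopf("Fine-Gray fit did not converge in %d iterations (last loglik %.6f)",
          max_iter, ll)
  }
  si <- fg_score_info(beta, X, str)
  vcov <- solve(si$I)
  se <- sqrt(diag(vcov))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  nm <- colnames(X)
  structure(list(coef = stats::setNames(beta, nm),
                 se = stats::setNames(se, nm),
                 shr = stats::setNames(exp(beta), nm),
                 ci_lower = stats::setNames(
                   exp(beta - 1.959963984540054 * se), nm),
                 ci_upper = stats::setNames(
                   exp(beta + 1.959963984540054 * se), nm),
                 z = stats::setNames(z, nm),
                 p = stats::setNames(pval, nm),
                 vcov = vcov, loglik = ll, iter = iter,
                 converged = converged, n = str$n,
                 n_events = sum(str$d)),
            class = "fine_gray_fit")
}

#' @export
print.fine_gray_fit <- function(x, ...) {
  cat(sprintf("Fine-Gray subdistribution hazard fit (%d subjects, %d cause-1 events)\n",
              x$n, x$n_events))
  df <- data.frame(coef = x$coef, SHR = x$shr,
                   `2.5%` = x$ci_lower, `97.5%` = x$ci_upper,
                   se = x$se, z = x$z, p = x$p, check.names = FALSE)
  print(df, digits = 4)
  invisible(x)
}

#' Wald test on a Fine-Gray coefficient
#'
#' Two-sided normal-theory p-value \eqn{2(1 - \Phi(|\beta/\mathrm{se}|))}.
#'
#' @param fit A [fit_fine_gray()] result.
#' @return Named vector of p-values, one per covariate.
#' @export
wald_test <- function(fit) {
  if (!isTRUE(fit$converged)) stopf("fit did not converge; Wald test invalid")
  if (any(fit$se <= 0)) stopf("non-positive standard error")
  2 * stats::pnorm(-abs(fit$coef / fit$se))
}

# Vectorized single-covariate Newton across many proteins sharing one
# outcome structure. Used by the genome-scale screen: the risk sets and
# IPCW weights depend only on the outcomes, so they are built once and all
# univariate fits advance in lockstep as matrix products.
fg_univariate_batch <- function(X, str, max_iter = 50L, tol = 1e-10) {
  X <- as.matrix(X)
  p <- ncol(X)
  W <- str$W
  d <- str$d
  ev_rows <- unlist(str$ev)
  sum_x_ev <- colSums(X[ev_rows, , drop = FALSE])
  beta <- rep(0, p)
  active <- rep(TRUE, p)
  info <- rep(NA_real_, p)
  failed <- rep(FALSE, p)
  for (it in seq_len(max_iter)) {
    idx <- which(active)
    if (!length(idx)) break
    Xa <- X[, idx, drop = FALSE]
    R <- exp(sweep(Xa, 2L, beta[idx], `*`))
    S0 <- W %*% R
    S1 <- W %*% (R * Xa)
    S2 <- W %*% (R * Xa * Xa)
    xbar <- S1 / S0
    U <- sum_x_ev[idx] - colSums(d * xbar)
    I <- colSums(d * (S2 / S0 - xbar * xbar))
    step <- U / I
    bad <- !is.finite(step)
    step[!bad] <- pmax(pmin(step[!bad], 1), -1)   # damp early huge steps
    newb <- beta[idx] + ifelse(bad, 0, step)
    diverged <- bad | abs(newb) > 20
    beta[idx] <- newb
    info[idx] <- I
    done <- abs(step) < tol
    failed[idx[diverged]] <- TRUE
    active[idx] <- !(done | diverged)
  }
  failed <- failed | active   # still moving after max_iter => not converged
  se <- ifelse(info > 0, 1 / sqrt(info), NA_real_)
  beta[failed] <- NA_real_
  se[failed] <- NA_real_
  z <- beta / se
  data.frame(protein = colnames(X) %||% paste0("x", seq_len(p)),
             beta = beta, se = se, shr = exp(beta), z = z,
             p = 2 * stats::pnorm(-abs(z)),
             converged = !failed, stringsAsFactors = FALSE)
}
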