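test_that("flag removal drops exactly the flagged columns", {
  tab <- make_table(matrix(1:8, 2, 4), flagged = c(FALSE, TRUE, TRUE, FALSE))
  expect_message(out <- remove_flagged(tab), "removing 2")
  expect_identical(dim(out), c(2L, 2L))
  # no flags -> identity
  tab0 <- make_table(matrix(1:4, 2, 2))
  expect_identical(remove_flagged(tab0), tab0)
  tab_all <- make_table(matrix(1:4, 2, 2), flagged = c(TRUE, TRUE))
  expect_error(remove_flagged(tab_all), "all SOMAmers")
})

test_that("protein aggregation averages multi-SOMAmer proteins on the RFU scale", {
  tab <- make_table(rbind(c(4, 6, 10), c(8, 12, 2)),
                    protein = c("A", "A", "B"))
  pm <- aggregate_to_proteins(tab)
  expect_identical(colnames(pm), c("A", "B"))
  expect_equal(unclass(pm)[, "A"], c(S001 = 5, S002 = 10))
  expect_equal(unclass(pm)[, "B"], c(S001 = 10, S002 = 2))
  # no multi-SOMAmer proteins -> column count unchanged
  tab1 <- make_table(matrix(1:4, 2, 2))
  expect_equal(ncol(aggregate_to_proteins(tab1)), 2L)
})

test_that("the full-panel bookkeeping yields the published protein count", {
  # 5284 SOMAmer measurements, 414 removed, 197 proteins on 2-3 SOMAmers:
  # 5 proteins x 3 SOMAmers + 192 x 2 + 4471 singletons = 4870 kept columns
  # collapsing to 4668 proteins.
  n_kept <- 5284 - 414
  sym <- c(rep(sprintf("T%03d", 1:5), each = 3),
           rep(sprintf("D%03d", 1:192), each = 2),
           sprintf("S%04d", seq_len(n_kept - 15 - 384)))
  protein <- c(sym, sprintf("FLG%03d", seq_len(414)))
  flagged <- c(rep(FALSE, n_kept), rep(TRUE, 414))
  tab <- make_table(matrix(1, 2, 5284), protein = protein, flagged = flagged)
  suppressMessages(kept <- remove_flagged(tab))
  expect_identical(ncol(kept$rfu), 4870L)
  pm <- aggregate_to_proteins(kept)
  expect_identical(ncol(pm), 4668L)
})

test_that("log2 transform checks its domain and inverts cleanly", {
  pm <- protein_matrix(matrix(c(8, 1, 2, 1024), 2, 2,
                              dimnames = list(c("p1", "p2"), c("A", "B"))),
                       "rfu")
  lg <- log2_transform(pm)
  expect_equal(unclass(lg)[1, 1], 3)
  expect_equal(unclass(lg)[2, 1], 0)
  expect_equal(2^unclass(lg), unclass(pm), ignore_attr = TRUE)
  bad <- protein_matrix(matrix(c(1, 0), 1, 2,
                               dimnames = list("p1", c("A", "B"))), "rfu")
  expect_error(log2_transform(bad), "protein 'B'")
})

test_that("standardization parameters follow the sample-SD convention", {
  m <- protein_matrix(matrix(c(1, 3), 2, 1, dimnames = list(NULL, "A")),
                      "log2")
  par <- fit_standardization(m)
  expect_equal(par$mean, 2)
  expect_equal(par$sd, sqrt(2))
  const <- protein_matrix(matrix(1, 3, 1, dimnames = list(NULL, "A")), "log2")
  expect_error(fit_standardization(const), "constant")
})

test_that("standardizing the derivation matrix with its own parameters centers it exactly", {
  set.seed(12)
  m <- protein_matrix(matrix(rnorm(200, 8, 2), 20, 10,
                             dimnames = list(NULL, letters[1:10])), "log2")
  z <- apply_standardization(m, fit_standardization(m))
  expect_equal(unname(colMeans(z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 10), tolerance = 1e-12)
  # simple anchor points
  par <- fit_standardization(m)
  x <- protein_matrix(matrix(par$mean, 1, 10,
                             dimnames = list("p", par$protein)), "log2")
  expect_equal(unname(unclass(apply_standardization(x, par))[1, ]),
               rep(0, 10))
  expect_error(apply_standardization(
    protein_matrix(matrix(1, 1, 1, dimnames = list("p", "ZZZ")), "log2"),
    par), "ZZZ")
})

test_that("derivation-anchored standardization transfers to an independent cohort", {
  set.seed(13)
  mu <- runif(10, 5, 10)
  draw <- function(n) {
    protein_matrix(matrix(rnorm(n * 10, rep(mu, each = n), 1.5), n, 10,
                          dimnames = list(NULL, letters[1:10])), "log2")
  }
  par <- fit_standardization(draw(500))
  z <- apply_standardization(draw(5000), par)
  expect_lt(max(abs(colMeans(z))), 0.1)
})

test_that("aggregation then standardization commutes with column permutation", {
  set.seed(14)
  tab <- make_table(matrix(runif(5 * 6, 100, 1000), 5, 6),
                    protein = c("A", "A", "B", "C", "D", "D"))
  path1 <- fit_standardization(log2_transform(aggregate_to_proteins(tab)))
  perm <- c(6, 3, 1, 5, 2, 4)
  tab2 <- make_table(tab$rfu[, perm],
                     protein = tab$somamer_meta$protein_symbol[perm],
                     dilution = tab$somamer_meta$dilution_set[perm])
  path2 <- fit_standardization(log2_transform(aggregate_to_proteins(tab2)))
  path2 <- path2[match(path1$protein, path2$protein), ]
  expect_equal(path1$mean, path2$mean)
  expect_equal(path1$sd, path2$sd)
})

test_that("imputation recovers a masked cell of an exact rank-1 matrix", {
  u <- 1:10
  v <- c(2, 5, 1, 4, 3) / 2
  M <- outer(u, v)
  df <- as.data.frame(M)
  df_miss <- df
  df_miss[7, 3] <- NA
  # the rank of the completion model matches the rank of the truth; a
  # higher rank can represent the single-cell perturbation exactly and
  # would stall at the mean-initialized value
  out <- impute_clinical(df_miss, n_components = 1)
  expect_true(attr(out, "converged"))
  expect_equal(out[7, 3], M[7, 3], tolerance = 1e-4)
  # observed cells untouched
  obs <- !is.na(as.matrix(df_miss))
  expect_identical(as.matrix(out)[obs], as.matrix(df_miss)[obs])
})

test_that("imputation edge cases behave", {
  df <- data.frame(a = 1:5, b = 6:10)
  expect_identical(impute_clinical(df), df, ignore_attr = TRUE)
  df_bad <- data.frame(a = c(NA, NA, NA, 4, 5), b = 1:5)
  expect_error(impute_clinical(df_bad), "50%")
  # imputed clinical table from the generator completes without NA
  coh <- simulate_cohort(small_cfg(seed = 41L, clinical_missing_rate = 0.02))
  filled <- impute_clinical(coh$clinical)
  expect_false(anyNA(filled[setdiff(names(filled), "patient_id")]))
})
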