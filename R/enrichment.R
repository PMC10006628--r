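# Fisher-exact overrepresentation of the selected protein panel in
# user-supplied term sets (e.g. GO-style annotations). The ontology graph is
# not modeled; terms are flat symbol sets.

#' Fisher exact overrepresentation test
#'
#' For each term, tests whether the selected set is overrepresented among
#' the term's members with the one-sided hypergeometric upper tail:
#' \eqn{P(X \ge \mathrm{overlap})} with
#' \eqn{X \sim \mathrm{Hypergeom}(|U|, |\mathrm{term}|, |\mathrm{selected}|)}.
#' Term sets are intersected with the universe first; terms disjoint from
#' the universe are skipped with a warning. Raw p-values are reported;
#' `adjust = "bonferroni"` adds an adjusted column.
#'
#' @param selected Character vector of selected symbols (must be a subset of
#'   `universe`).
#' @param universe Character vector: all tested symbols.
#' @param terms Named list of character vectors (term id -> member symbols),
#'   or a two-column data frame (term id, symbol).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return A data frame of class `enrichment_result`: `term`, `term_size`
#'   (in the universe), `overlap`, `p` (and `p_adj` if requested).
#' @export
fisher_overrepresentation <- function(selected, universe, terms,
                                      adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (!length(universe)) stopf("empty universe")
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    stopf("selected symbol(s) not in the universe: %s",
          paste(outside, collapse = ", "))
  }
  if (is.data.frame(terms)) {
    terms <- split(as.character(terms[[2L]]), as.character(terms[[1L]]))
  }
  N <- length(universe)
  n_sel <- length(selected)
  rows <- list()
  for (id in names(terms)) {
    members <- intersect(unique(as.character(terms[[id]])), universe)
    if (!length(members)) {
      warnf("term '%s' shares no symbols with the universe; skipped", id)
      next
    }
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- stats::phyper(k - 1L, K, N - K, n_sel, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      term = id, term_size = K, overlap = k, p = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(term = character(), term_size = integer(),
               overlap = integer(), p = numeric())
  if (adjust == "bonferroni" && nrow(out)) {
    out$p_adj <- pmin(1, out$p * nrow(out))
  }
  class(out) <- c("enrichment_result", "data.frame")
  out
}
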