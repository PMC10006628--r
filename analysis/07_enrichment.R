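#!/usr/bin/env Rscript
# Step 7 - term-set overrepresentation of the selected panel.
#
# The generator has no real ontology, so term sets are synthesized: some
# terms are enriched in the selected panel by construction, the rest are
# random draws from the tested universe. The Fisher (hypergeometric
# upper-tail) test should flag the planted terms and leave random terms at
# uniform p-values.

suppressMessages(library(somastrat))
dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)

screen_d <- utils::read.delim("results/screen/screen_derivation.tsv")
universe <- screen_d$protein
selected <- screen_d$protein[screen_d$selected]

set.seed(20260107L)
terms <- list()
# two planted terms biased toward the selected panel
terms[["PLANTED01"]] <- unique(c(sample(selected, min(8, length(selected))),
                                 sample(universe, 4)))
terms[["PLANTED02"]] <- unique(c(sample(selected, min(5, length(selected))),
                                 sample(universe, 10)))
# random background terms
for (i in 1:20) {
  terms[[sprintf("RANDOM%02d", i)]] <- sample(universe,
                                              sample(5:30, 1))
}

res <- fisher_overrepresentation(selected, universe, terms,
                                 adjust = "bonferroni")
res <- res[order(res$p), ]
cat("top terms by overrepresentation p-value:\n")
print(utils::head(res, 5), row.names = FALSE)
cat(sprintf("planted terms rank in the top: %s\n",
            paste(which(grepl("PLANTED", res$term)), collapse = ", ")))
utils::write.table(res, "results/enrichment/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/enrichment/enrichment.tsv\n")
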