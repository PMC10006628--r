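#!/usr/bin/env Rscript
# Step 4 - univariate competing-risk screening with Bonferroni control.
#
# One Fine-Gray model per protein against HF hospitalization (death
# competing), on both cohorts; proteins are selected on the DERIVATION
# cohort at p < alpha/m. Cross-cohort sign concordance and the correlation
# structure of the selected panel are summarized.

suppressMessages(library(somastrat))
dir.create("results/screen", recursive = TRUE, showWarnings = FALSE)

load_std <- function(cohort) {
  df <- utils::read.delim(file.path("results/matrices",
                                    paste0(cohort, "_std.tsv")),
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$patient_id
  somastrat:::protein_matrix(m, "standardized")
}

screen_one <- function(cohort) {
  z <- load_std(cohort)
  out <- read_outcomes(file.path("results/data", cohort, "outcomes.tsv"))
  univariate_screen(z, out, alpha = 0.05)
}

res_d <- screen_one("derivation")
res_v <- screen_one("validation")
sel <- res_d$protein[res_d$selected]
cat(sprintf("tested m = %d proteins; Bonferroni threshold %.3g; selected %d\n",
            attr(res_d, "m"), attr(res_d, "threshold"), length(sel)))

utils::write.table(res_d, "results/screen/screen_derivation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res_v, "results/screen/screen_validation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cc <- direction_concordance(res_d, res_v)
cat(sprintf("direction concordance on the selected panel: %d same-sign, %d opposite (%s)\n",
            cc$same_sign, cc$opposite_sign,
            if (cc$opposite_sign) paste(cc$opposite_proteins, collapse = ", ")
            else "none"))

cs <- correlation_summary(load_std("derivation"), sel)
cat(sprintf("highest correlation among selected proteins: %.3f between %s and %s\n",
            cs$max_cor, cs$max_pair[1], cs$max_pair[2]))
jsonlite::write_json(
  list(selected = sel, threshold = attr(res_d, "threshold"),
       m = attr(res_d, "m"),
       concordance = cc[c("same_sign", "opposite_sign", "opposite_proteins")],
       max_correlation = list(pair = cs$max_pair, r = cs$max_cor)),
  "results/screen/summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote results/screen/\n")
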