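#!/usr/bin/env Rscript
# Reproduce the study's headline tables from the packaged instrument fixture:
# per-dataset and pooled IVW odds ratios, Cochran's Q, and MR-Egger
# pleiotropy intercepts, plus the per-instrument scatter data behind the
# pooled effect plot. Everything is deterministic.
#
# Run from the repository root:  Rscript analysis/01_reproduce_tables.R

suppressPackageStartupMessages(library(gtmr))

rows <- reproduce_study(out_dir = "results")

cat("== IVW estimates (OR per unit exposure) and Egger intercepts ==\n")
tab <- do.call(rbind, lapply(rows, as.data.frame))
print(tab[c("trait", "analysis", "n_snps", "or", "or_ci_low", "or_ci_high",
            "ivw_p", "egger_intercept_or", "egger_p", "Q", "Q_p")],
      row.names = FALSE, digits = 4)

cat("\nFindings: every per-dataset and pooled estimate is compatible with a\n")
cat("null causal effect of the glycemic traits on breast cancer (all IVW\n")
cat("CIs span OR = 1), while Cochran's Q flags strong instrument\n")
cat("heterogeneity in the large OncoArray blocks (Q p < 0.05). Egger\n")
cat("intercepts sit at or near 1.00 per allele in the glucose analyses;\n")
cat("the insulin intercepts are slightly above 1, borderline for the\n")
cat("4-SNP OncoArray set.\n")
cat("\nWrote results/mr_report.{tsv,json} and results/mr_report_scatter.tsv\n")
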