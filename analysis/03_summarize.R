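#!/usr/bin/env Rscript
# Step 3 — cohort-level summaries of the scored sample.
#
# Rating distributions per element and per ECHO outcome, summary shares
# (high on >=1 / >=2 elements, low on all, direct vs indirect high impact),
# overall-score medians and IQRs per route, ATC class, year and
# originator/generic status, with Kruskal-Wallis and Bonferroni-adjusted
# Dunn comparisons, and yearly trends.
#
# Outputs under results/summary/: CSV tables + summary.json + manifest.

suppressPackageStartupMessages(library(shortageimpact))

out_dir <- "results"
scored_path <- file.path(out_dir, "scored_sample.csv")
if (!file.exists(scored_path)) {
  stop("Run analysis/02_score.R first (missing ", scored_path, ")")
}

scored <- readr::read_csv(scored_path, show_col_types = FALSE)
smry <- summarize_cohort(scored)

cat(sprintf("n = %d scored shortages\n", smry$n))
cat(sprintf("Overall impact score: median %g (IQR %g-%g)\n\n",
            smry$overall$median, smry$overall$q1, smry$overall$q3))
cat("Share of records at each rating, per element (%):\n")
print(as.data.frame(tidyr::pivot_wider(smry$distribution$elements,
                                       id_cols = "element",
                                       names_from = "rating",
                                       values_from = "pct",
                                       names_prefix = "pct_rating_")))
cat("\nECHO outcome ratings (%):\n")
print(as.data.frame(tidyr::pivot_wider(smry$distribution$echo,
                                       id_cols = "outcome",
                                       names_from = "rating",
                                       values_from = "pct",
                                       names_prefix = "pct_rating_")))
cat("\nSummary shares (%):\n")
print(as.data.frame(smry$distribution$summary))
cat("\nOverall score per ATC class:\n")
print(as.data.frame(smry$scores_by$atc_class))
kw <- do.call(rbind, lapply(names(smry$tests_by), function(v) {
  t <- smry$tests_by[[v]]
  t[t$test == "kruskal_wallis", c("variable", "statistic", "df", "p_value")]
}))
cat("\nKruskal-Wallis omnibus tests per stratification:\n")
print(as.data.frame(kw))

paths <- write_summary(smry, file.path(out_dir, "summary"))
write_manifest(
  run_manifest("summarize", rater_config(), inputs = scored_path,
               outputs = paths),
  file.path(out_dir, "summary", "manifest_summarize.json"))
cat("\nWrote", length(paths), "summary files to", file.path(out_dir, "summary"), "\n")
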