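#!/usr/bin/env Rscript
# Step 5 -- Planned comparisons and camouflage trends.
#
# Reads the metric records written by step 4 and runs the statistical
# battery: per metric, one between-background test per time point (Wilcoxon
# rank-sum; Welch t for hue) with the four p-values jointly corrected by
# sequential Bonferroni, plus Kruskal-Wallis tests of JND change over time
# per background. The expectation under programmed colour change is no
# difference at time 0 and significant differences afterwards, with
# declining JNDs on backgrounds the fish converge towards.

suppressPackageStartupMessages(library(camochange))
dir.create("results", showWarnings = FALSE)

first_bg <- list(`1` = "black", `2` = "red")
all_trends <- list()
for (ex in 1:2) {
  rec <- read.csv(sprintf("results/metric_records_exp%d.csv", ex))
  cmp <- do.call(rbind, lapply(c("saturation", "hue", "luminance"),
                               function(mm) planned_comparisons(
                                 rec, mm, first_background = first_bg[[as.character(ex)]])))
  cmp$experiment <- ex
  write.csv(cmp, sprintf("results/planned_comparisons_exp%d.csv", ex),
            row.names = FALSE)
  cat(sprintf("-- experiment %d planned comparisons --\n", ex))
  print(cmp[, c("metric", "time_min", "test", "statistic", "df", "p",
                "critical_threshold", "significant")],
        digits = 3, row.names = FALSE)
  for (bg in unique(rec$background))
    for (kind in c("chromatic", "achromatic")) {
      tr <- camouflage_trend(rec, bg, kind)
      tr$experiment <- ex
      all_trends[[length(all_trends) + 1]] <- tr
    }
  cat("\n")
}
trends <- do.call(rbind, all_trends)
write.csv(trends, "results/jnd_trends.csv", row.names = FALSE)
cat("-- Kruskal-Wallis JND trends over time --\n")
print(trends, digits = 3, row.names = FALSE)
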