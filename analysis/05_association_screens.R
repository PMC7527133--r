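#!/usr/bin/env Rscript

# Step 5: the non-network statistical screens.
#
# Environmental parameters are pruned for missingness and collinearity
# (VIF > 10 or |corr| > 0.7), then screened against genus abundances by
# Pearson correlation (alpha 0.001, BH-adjusted, |r| > 0.3). Genus
# abundances are tested across lake-cycle phases with Kruskal-Wallis
# plus post hoc pairwise rank comparison, and OTU detection in cultures
# is compared with the lake time series.

suppressPackageStartupMessages(library(cohortnet))

dir.create("results/screens", showWarnings = FALSE, recursive = TRUE)

ts <- read_otu_table_tsv("results/data/timeseries_otu_table.tsv")
mc <- read_otu_table_tsv("results/data/cultures_otu_table.tsv")
env <- utils::read.table("results/data/environment.tsv", header = TRUE,
                         sep = "\t", row.names = 1)

## collinearity pruning
rep <- prune_collinear(env)
message(sprintf("environmental pruning: %d of %d parameters removed (%s)",
                nrow(rep$removed), ncol(env),
                if (nrow(rep$removed) > 0)
                  paste(rep$removed$parameter, collapse = ", ") else "-"))
utils::write.table(rep$removed, "results/screens/env_pruned.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## genus x environment screen
genus <- collapse_rank(ts, "genus")
scr <- env_screen(genus, env[, rep$retained, drop = FALSE])
hits <- scr[scr$flag_passed, ]
message(sprintf("environment screen: %d of %d tests flagged (|r| > 0.3, p_adj < 0.001)",
                nrow(hits), nrow(scr)))
if (nrow(hits) > 0) print(hits[, c("clade", "parameter", "r", "p_adj")])
utils::write.table(scr, "results/screens/env_screen.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

## seasonal phase differences
kw <- phase_kw(genus, ts$sample_data$phase)
sig <- kw$tests[kw$tests$p_raw < 0.001, ]
message(sprintf("phase screen: %d of %d genera differ across phases (KW p < 0.001)",
                nrow(sig), nrow(kw$tests)))
if (nrow(kw$flagged) > 0) {
  message("phases differing from >= 2 others (first rows):")
  print(utils::head(kw$flagged, 10))
}
utils::write.table(kw$tests, "results/screens/phase_kw.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(kw$posthoc, "results/screens/phase_kw_posthoc.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## lake vs culture detection
cross <- cross_dataset_corr(ts, mc)
message("cross-dataset correlations (all shared OTUs):")
print(cross[cross$subset == "all", c("comparison", "r", "n", "p_adj")])
utils::write.table(cross, "results/screens/cross_dataset.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/screens")
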