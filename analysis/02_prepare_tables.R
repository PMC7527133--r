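#!/usr/bin/env Rscript

# Step 2: normalize and filter the two OTU tables.
#
# The time series is rarefied to 1500 reads and swept over a grid of
# detection-frequency x total-abundance filters, keeping the point that
# retains the most OTUs while achieving sparsity <= 50% and mean
# inverse-Simpson n_eff >= 10. The mixed-culture table is rarefied to
# 500 reads and cleaned of singletons.

suppressPackageStartupMessages(library(cohortnet))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

ts <- read_otu_table_tsv("results/data/timeseries_otu_table.tsv")
mc <- read_otu_table_tsv("results/data/cultures_otu_table.tsv")

ts_rar <- rarefy(ts, 1500, seed = 1L)
sweep_res <- filter_sweep(ts_rar,
                          min_samples_grid = c(2, 5, 10, 20, 29, 40),
                          min_total_ra_grid = c(1, 15, 50, 100, 150) / 1500)
ts_f <- sweep_res$table
message(sprintf(
  "time series filter: >= %d samples, total ra >= %.4f (%s); %d -> %d OTUs",
  sweep_res$best$min_samples, sweep_res$best$min_total_ra,
  if (sweep_res$criteria_met) "criteria met" else "criteria NOT met",
  n_otus(ts_rar), n_otus(ts_f)))
print(summarize_table(ts_f))

mc_rar <- rarefy(mc, 500, seed = 2L)
mc_f <- drop_singletons(mc_rar)
message(sprintf("cultures: %d -> %d OTUs after singleton removal",
                n_otus(mc_rar), n_otus(mc_f)))
print(summarize_table(mc_f))

utils::write.table(sweep_res$grid, "results/tables/filter_sweep_grid.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_otu_table_tsv(ts_f, "results/tables/timeseries_filtered.tsv")
write_otu_table_tsv(mc_f, "results/tables/cultures_filtered.tsv")
message("wrote results/tables")
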