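#!/usr/bin/env Rscript

# Step 1: generate the synthetic study system.
#
# A 100-OTU community with a clade-structured 7-rank taxonomy, 30
# planted signed interactions, five years of weekly lake samples
# (rarefaction-depth 1500 reads), a 98-culture dilution mixed-culture
# experiment founded at ~10 cells per culture (500 reads), and a
# 14-parameter environmental table with two parameters linked to
# abundant OTUs. Everything downstream reads the TSVs written here.

suppressPackageStartupMessages(library(cohortnet))

seed <- 20260101L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

taxa <- make_taxonomy(n_otus = 100, n_phyla = 6, seed = seed)
truth <- make_truth_network(taxa, n_edges = 30, frac_negative = 0.25,
                            strength = 0.8, assortative_bias = 2,
                            seed = seed + 1L)
ts <- simulate_timeseries(taxa, truth, n_samples = 200, depth = 1500,
                          seed = seed + 2L)

# the lake's mean composition founds the dilution cultures
comp <- av_ra(ts)
comp <- comp / sum(comp)
mc <- simulate_cultures(taxa, truth, comp, n_cultures = 98,
                        founder_mean = 10, depth = 500, seed = seed + 3L)

linked <- names(sort(comp, decreasing = TRUE))[1:2]
env <- simulate_env(n_samples(ts), n_params = 14, linked_otus = linked,
                    link_r = 0.7, missing_frac = 0.1, seed = seed + 4L,
                    table = ts)

write_otu_table_tsv(ts, file.path(out, "timeseries_otu_table.tsv"))
write_otu_table_tsv(mc, file.path(out, "cultures_otu_table.tsv"))
write_truth_network_tsv(truth, file.path(out, "truth_edges.tsv"))
write_env_table_tsv(env, file.path(out, "environment.tsv"))
ape::write.tree(taxa$tree, file.path(out, "taxonomy_tree.nwk"))

message(sprintf("time series: %d samples x %d OTUs (%d reads/sample)",
                n_samples(ts), n_otus(ts), 1500))
message(sprintf("cultures: %d of %d flagged detected",
                sum(mc$sample_data$detected), n_samples(mc)))
message(sprintf("truth: %d edges (%d negative), assortative bias 2",
                nrow(truth$edges), sum(truth$edges$sign == "-")))
message("wrote ", out)
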