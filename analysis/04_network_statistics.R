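#!/usr/bin/env Rscript

# Step 4: topology and taxonomy of the consensus networks.
#
# Nominal assortativity at every rank, greedy-modularity partitions,
# 1-degree (primary) cohorts of the three most connected genera, their
# overlap and sign agreement, and phylogenetic distance versus edge
# weight within the leading cohort.

suppressPackageStartupMessages(library(cohortnet))

dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)

ts <- read_otu_table_tsv("results/data/timeseries_otu_table.tsv")
ts_cfg <- pipeline_config("TS", seed = 11L,
                          filter = list(mode = "preset", min_samples = 2,
                                        min_total_ra_pct = 0.001,
                                        strict = FALSE))
net <- run_pipeline(ts, ts_cfg)$network
taxa_tree <- ape::read.tree("results/data/taxonomy_tree.nwk")
pd <- as.matrix(stats::cophenetic(taxa_tree))

## assortativity by rank
ranks <- c("phylum", "class", "order", "family", "genus")
assort <- data.frame(
  rank = ranks,
  assortativity = vapply(ranks, function(r)
    nominal_assortativity(net, r), numeric(1)))
print(assort)
utils::write.table(assort, "results/stats/assortativity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

## modularity
ms <- modularity_stats(net)
message(sprintf("greedy modularity: Q = %.3f over %d communities",
                ms$Q, length(unique(ms$membership))))

## primary cohorts of the three best-connected genera
deg <- table(c(net$edges$otu_i, net$edges$otu_j))
node_genus <- stats::setNames(net$nodes$genus, net$nodes$otu)
genus_deg <- tapply(as.numeric(deg), node_genus[names(deg)], sum)
top_genera <- names(sort(genus_deg, decreasing = TRUE))[1:3]
cohorts <- lapply(top_genera, function(g) {
  target <- net$nodes$otu[net$nodes$genus == g]
  first_neighbors(net, target)
})
names(cohorts) <- top_genera
for (g in top_genera) {
  co <- cohorts[[g]]
  message(sprintf("genus %s: %d target OTUs, %d first neighbors (%d negative)",
                  g, length(co$target), nrow(co$neighbors),
                  sum(co$neighbors$sign == "-")))
  write_network_tsv(co$subnetwork,
                    sprintf("results/stats/cohort_%s_edges.tsv", g))
}

## overlap between cohorts
ov <- cohort_overlap(cohorts)
message("directional shared-neighbor fractions:")
print(round(ov$fractions, 2))
message(sprintf("common to all three cohorts: %s",
                if (length(ov$common_to_all) > 0)
                  paste(ov$common_to_all, collapse = ", ") else "none"))
utils::write.table(as.data.frame(ov$fractions),
                   "results/stats/cohort_overlap.tsv", sep = "\t",
                   quote = FALSE)
utils::write.table(ov$sign_agreement,
                   "results/stats/cohort_sign_agreement.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

## phylogenetic distance vs co-occurrence in the leading cohort
pdres <- pd_vs_correlation(cohorts[[1]], net, pd)
message(sprintf("PD vs edge weight (%s): r = %s, p = %s over %d pairs",
                top_genera[1],
                format(pdres$r, digits = 3), format(pdres$p, digits = 3),
                pdres$n))
utils::write.table(pdres$scatter, "results/stats/pd_vs_weight.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/stats")
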