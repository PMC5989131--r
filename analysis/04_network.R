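#!/usr/bin/env Rscript
## Stage 4: community comparison — depth normalization, square-root
## transform, Bray-Curtis distances, the neighbor-net split network and
## its splits-graph realization, plus prevalence-filtered hierarchical
## clustering of genus profiles.

library(sednet)

out <- "results"
md <- read_metadata("results/data/metadata.tsv")
genus <- read_count_matrix(file.path(out, "profile_genus.tsv"))
genus_main <- genus[-grep("^\\(", rownames(genus)), , drop = FALSE]

norm <- normalize_to_smallest(genus_main)
d <- community_distance(transform_counts(norm, "sqrt"), "braycurtis")
write_distance_matrix(d, file.path(out, "braycurtis_genus.tsv"))
write_distance_phylip(d, file.path(out, "braycurtis_genus.phy"))

css <- neighbor_net(d)
g <- build_splits_graph(css)
write_nexus_splits(css, file.path(out, "network_genus.nex"))
write_edge_list(g, file.path(out, "network_genus_edges.tsv"))
cat(sprintf("neighbor-net: %d splits, splits graph with %d nodes and %d edges\n",
            nrow(css$splits), g$n_nodes, nrow(g$edges)))
cat(sprintf("least-squares fit rss = %.3g\n", css$rss))

## do the sample nodes separate by land use on the network?
sub <- sample_node_distances(g)
dec <- group_distance_decomposition(
  sub, md$land_use[match(rownames(sub), md$sample_id)])
cat(sprintf("network distances: mean within %.3f, mean between %.3f\n",
            dec$mean_within, dec$mean_between))

## hierarchical clustering of prevalent genera (>= 50% of samples)
prev <- prevalence_filter(norm, 0.5)
hc <- hierarchical_cluster(prev)
ord <- data.frame(position = seq_along(hc$order),
                  feature = rownames(prev)[hc$order])
write.table(ord, file.path(out, "cluster_row_order.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("clustering: %d of %d genera pass the 50%% prevalence filter\n",
            nrow(prev), nrow(norm)))
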