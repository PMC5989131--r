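#!/usr/bin/env Rscript
## Stage 6: permutational multivariate statistics on the genus profiles —
## mixed-model PERMANOVA (land use and before/after fixed, rain event
## random, 9,999 permutations under a reduced model, interactions with
## p > 0.25 pooled), PERMDISP, SIMPER, and RELATE between the shotgun
## genus profile and the V6 ribotag OTU profile.

library(sednet)

out <- "results"
md <- read_metadata("results/data/metadata.tsv")
genus <- read_count_matrix(file.path(out, "profile_genus.tsv"))
genus_main <- genus[-grep("^\\(", rownames(genus)), , drop = FALSE]
norm <- normalize_to_smallest(genus_main)
sq <- transform_counts(norm, "sqrt")
d <- community_distance(sq, "braycurtis")
groups <- md$land_use[match(colnames(norm), md$sample_id)]
seed <- 20260927L

pmv <- permanova(d, md, c("land_use", "timing", "rain_event"),
                 random = "rain_event", n_perm = 9999L,
                 pool_threshold = 0.25, seed = substream_seed(seed, 21))
write.table(pmv, file.path(out, "permanova_genus.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("PERMANOVA (genus, Bray-Curtis on sqrt abundances):\n")
print(pmv, digits = 4)

pd <- permdisp(d, groups, n_perm = 9999L, seed = substream_seed(seed, 22))
cat(sprintf("\nPERMDISP by land use: F = %.3f, p = %.4f\n", pd$F, pd$p))
print(round(pd$group_means, 4))

st <- simper(sq, groups)
write.table(st, file.path(out, "simper_genus.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- head(st, 5)
cat(sprintf("\nSIMPER: top 5 genera explain %.1f%% of the %.3f mean between-group dissimilarity\n",
            top$cumulative_pct[5], attr(st, "mean_dissimilarity")))
print(top, digits = 3)

## RELATE: do ribotag OTU profiles tell the same story as shotgun genera?
otu <- read_count_matrix(file.path(out, "otu_v6.tsv"))
d_otu <- community_distance(transform_counts(
  normalize_to_smallest(otu[, colnames(norm)]), "sqrt"), "braycurtis")
rl <- relate(d, d_otu, n_perm = 9999L, seed = substream_seed(seed, 23))
cat(sprintf("\nRELATE genus vs V6-OTU matrices: rho = %.3f, p = %.4f\n",
            rl$rho, rl$p))
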