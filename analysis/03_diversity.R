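#!/usr/bin/env Rscript
## Stage 3: diversity summaries and the univariate test battery —
## rarefaction, Shannon/evenness per sample, Bonferroni-corrected
## permutation t tests per genus, a Mann-Whitney comparison, and Kendall
## tau correlations of environmental variables with rain.

library(sednet)

ind <- "results/data"
out <- "results"
md <- read_metadata(file.path(ind, "metadata.tsv"))
genus <- read_count_matrix(file.path(out, "profile_genus.tsv"))
species <- read_count_matrix(file.path(out, "profile_species.tsv"))
drop_names <- grep("^\\(", rownames(genus))
genus_main <- genus[-drop_names, , drop = FALSE]
species_main <- species[-grep("^\\(", rownames(species)), , drop = FALSE]
seed <- 20260927L

## rarefaction at species level for three samples
depths <- round(seq(50, min(colSums(species_main)), length.out = 12))
rar <- do.call(rbind, lapply(colnames(species_main)[c(1, 17, 33)],
  function(s) {
    rc <- rarefaction_curve(round(species_main[, s]), depths, reps = 20,
                            seed = substream_seed(seed, 11))
    cbind(sample_id = s, rc)
  }))
write.table(rar, file.path(out, "rarefaction.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sat <- tapply(rar$mean_taxa, rar$sample_id, function(v)
  (max(v) - v[length(v) - 1]) / max(v))
cat(sprintf("rarefaction: last-step richness gain %.2f%% (saturation)\n",
            100 * max(sat)))

## diversity indices on depth-normalized genus profiles
norm <- normalize_to_smallest(genus_main)
div <- do.call(rbind, lapply(colnames(norm), function(s) {
  r <- shannon_evenness(norm[, s])
  data.frame(sample_id = s, S = r$S, H = r$H, E = r$E)
}))
div <- merge(div, md, by = "sample_id")
write.table(div, file.path(out, "diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mean Shannon H: industrial %.2f, residential %.2f\n",
            mean(div$H[div$land_use == "industrial"]),
            mean(div$H[div$land_use == "residential"])))

## which genera differ between land uses (999 perms, Bonferroni)
tt <- per_feature_group_test(transform_counts(norm, "sqrt"),
                             md$land_use[match(colnames(norm),
                                               md$sample_id)],
                             n_perm = 999,
                             seed = substream_seed(seed, 12))
write.table(tt, file.path(out, "feature_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d genera differ by land use after Bonferroni\n",
            sum(tt$significant), nrow(tt)))

## Mann-Whitney on Shannon H between land uses
mw <- mann_whitney(div$H[div$land_use == "industrial"],
                   div$H[div$land_use == "residential"])
cat(sprintf("Mann-Whitney on H: U = %.1f, p = %.4f (%s)\n",
            mw$U, mw$p, mw$method))

## rain correlations
rain <- read.table(file.path(ind, "rain.tsv"), header = TRUE, sep = "\t")
env <- read.table(file.path(ind, "env.tsv"), header = TRUE, sep = "\t")
kc <- kendall_rain_correlation(env, rain$rain_mm)
write.table(kc, file.path(out, "env_rain_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(kc)
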