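#!/usr/bin/env Rscript
## Stage 1: generate every pipeline input with known ground truth.
##
## The design mirrors the field campaign: 2 land uses x 2 rain events x
## before/after x 6 replicates = 48 sediment samples.  Desk-scale library
## size is 10,000 reads per sample (the study's per-sample mean, 3.0e7,
## scaled down); half the reads fail protein-database mapping, matching
## the observed ~48% mapping rate.

library(sednet)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260927L

md <- generate_metadata(6L)
cat("design:", nrow(md), "samples across",
    length(unique(md$land_use)) * length(unique(md$rain_event)) *
      length(unique(md$timing)), "factor cells\n")

params <- simulation_params(
  n_taxa = 40L,
  landuse_log_effects = effect_pattern(40, 1.5,
                                       seed = substream_seed(seed, 1)),
  rain_log_effects = effect_pattern(40, 0.8,
                                    seed = substream_seed(seed, 2)),
  dirichlet_concentration = 150,
  library_sizes = 10000L,
  seed = substream_seed(seed, 3))

sim <- generate_profiles_and_hits(md, params)
cat("simulated", nrow(sim$reads), "reads,", nrow(sim$hits),
    "database hits,", length(sim$taxonomy$ids), "taxonomy nodes\n")

write_metadata(md, file.path(out, "metadata.tsv"))
write_taxonomy(sim$taxonomy, file.path(out, "taxonomy.tsv"))
write.table(sim$hits, file.path(out, "hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$reads[, c("read_id", "sample_id", "category", "sequence")],
            file.path(out, "reads.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_count_matrix(sim$truth, file.path(out, "truth_species.tsv"))

## V6 ribotag reads: one small FASTQ per sample, tags drawn from a shared
## catalogue so OTU profiles reflect the same land-use structure
set.seed(substream_seed(seed, 4))
catalogue <- vapply(1:12, function(i)
  paste(sample(c("A", "C", "G", "T"), 33, replace = TRUE), collapse = ""),
  character(1))
truths <- list()
for (s in seq_len(nrow(md))) {
  probs <- rep(1, 12)
  ## industrial samples favour the first six tags, residential the rest
  if (md$land_use[s] == "industrial") probs[1:6] <- 4 else probs[7:12] <- 4
  v6 <- generate_v6_reads(400, catalogue, tag_probs = probs,
                          embed_rate = 0.3, revcomp_rate = 0.3,
                          sample_id = md$sample_id[s],
                          seed = substream_seed(seed, 100 + s))
  write_fastq(v6$reads, file.path(out, paste0("v6_", md$sample_id[s],
                                              ".fq")))
  truths[[s]] <- cbind(sample_id = md$sample_id[s], v6$truth)
}
write.table(do.call(rbind, truths), file.path(out, "v6_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## environment: two years of daily rain plus coupled variables
er <- generate_env_rain(365, seed = substream_seed(seed, 5))
write.table(data.frame(day = seq_along(er$rain), rain_mm = er$rain),
            file.path(out, "rain.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(er$env, file.path(out, "env.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote inputs under", out, "\n")
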