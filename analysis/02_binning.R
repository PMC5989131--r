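#!/usr/bin/env Rscript
## Stage 2: taxonomic binning of the simulated database hits (complexity
## filter, LCA with score floor 35 and top-percent band 10, minimum
## support 25) and V6 ribotag extraction, projected into count matrices.

library(sednet)

ind <- "results/data"
out <- "results"
md <- read_metadata(file.path(ind, "metadata.tsv"))
tree <- read_taxonomy(file.path(ind, "taxonomy.tsv"))
hits <- read.table(file.path(ind, "hits.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
reads <- read.table(file.path(ind, "reads.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)

bp <- binning_params()   # min score 35, top percent 10, min support 25,
                         # complexity 0.44
asn <- assign_reads(hits, tree, bp, reads = reads)
cat(sprintf("binned %d reads: %.1f%% no hits, %.1f%% unassigned\n",
            nrow(asn), 100 * mean(asn$node_id == NO_HITS_ID),
            100 * mean(asn$node_id == UNASSIGNED_ID)))

counts <- aggregate(list(count = rep(1, nrow(asn))),
                    by = list(sample_id = asn$sample_id,
                              node_id = asn$node_id), FUN = sum)
supported <- do.call(rbind, lapply(split(counts, counts$sample_id),
  function(df) {
    v <- setNames(df$count, df$node_id)
    v <- apply_min_support(v, bp$min_support, tree)
    data.frame(sample_id = df$sample_id[1],
               node_id = as.integer(names(v)), count = as.numeric(v))
  }))

for (rk in c("species", "genus", "family")) {
  prof <- profile_at_rank(supported, rk, tree, md)
  write_count_matrix(prof, file.path(out, paste0("profile_", rk, ".tsv")))
  cat(sprintf("%s profile: %d taxa (+%d audit rows)\n", rk,
              nrow(prof) - length(attr(prof, "audit_rows")),
              length(attr(prof, "audit_rows"))))
}

## ribotag OTU table from the per-sample FASTQs
occ <- do.call(rbind, lapply(md$sample_id, function(s)
  extract_v6_tags(file.path(ind, paste0("v6_", s, ".fq")),
                  sample_id = s)))
otu <- tags_to_otu_table(occ, md)
write_count_matrix(otu, file.path(out, "otu_v6.tsv"))
truth <- read.table(file.path(ind, "v6_truth.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
cat(sprintf("v6 ribotags: %d occurrences, %d OTUs (truth: %d full embeds)\n",
            nrow(occ), nrow(otu), sum(truth$full_tag)))
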