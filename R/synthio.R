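## Synthetic-data generators: every input the pipeline consumes, with known
## ground truth.  The defaults emulate the study design this package was
## built around: a 2 (land use) x 2 (rain event) x 2 (before/after) x 6
## (replicate) factorial of 48 sediment metagenomes.

#' Generate the factorial sample metadata table
#'
#' Full crossing of land use (industrial/residential), rain event (RE1/RE2)
#' and timing (before/after), with `n_reps` replicates per cell.  `n_reps =
#' 6` reproduces the 48-sample design.
#'
#' @param n_reps replicates per factor cell (>= 1).
#' @return data.frame with columns `sample_id`, `land_use`, `rain_event`,
#'   `timing`, `replicate`.
#' @export
generate_metadata <- function(n_reps = 6L) {
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1)
    stop("n_reps must be a positive integer")
  n_reps <- as.integer(n_reps)
  md <- expand.grid(replicate = seq_len(n_reps),
                    timing = c("before", "after"),
                    rain_event = c("RE1", "RE2"),
                    land_use = c("industrial", "residential"),
                    stringsAsFactors = FALSE)
  md <- md[, c("land_use", "rain_event", "timing", "replicate")]
  md$sample_id <- sprintf("%s_%s_%s_%d",
                          ifelse(md$land_use == "industrial", "I", "R"),
                          md$rain_event,
                          ifelse(md$timing == "before", "B", "A"),
                          md$replicate)
  md[, c("sample_id", "land_use", "rain_event", "timing", "replicate")]
}

#' Simulation parameters for community profiles and read hits
#'
#' @param n_taxa number of species in the simulated taxonomy.
#' @param base_composition baseline relative abundances (length `n_taxa`,
#'   summing to 1); default a geometric-decay community.
#' @param landuse_log_effects per-taxon log-abundance shifts applied with
#'   opposite half-signs to the two land uses.
#' @param rain_log_effects per-taxon shifts applied before vs after rain.
#' @param dirichlet_concentration concentration of the Dirichlet
#'   perturbation around each sample's expected composition; larger values
#'   mean less biological replicate-to-replicate variation.
#' @param library_sizes reads per sample; a scalar is recycled.  The default
#'   30,000 is the study's per-sample mean depth scaled down three orders of
#'   magnitude to desk scale.
#' @param decoy_rate fraction of reads carrying an extra hit to a random
#'   wrong taxon.
#' @param nohit_rate fraction of reads whose hits all fall below the LCA
#'   score floor; the default matches the roughly half of shotgun reads that
#'   fail protein-database mapping in sediment metagenomes.
#' @param lowcomplexity_rate fraction of reads given a low-entropy
#'   (homopolymer) sequence, to be diverted by the complexity filter.
#' @param seed integer seed.
#' @return a list of class `sim_params`.
#' @export
simulation_params <- function(n_taxa = 60L,
                              base_composition = NULL,
                              landuse_log_effects = 0,
                              rain_log_effects = 0,
                              dirichlet_concentration = 100,
                              library_sizes = 30000L,
                              decoy_rate = 0.05,
                              nohit_rate = 0.5,
                              lowcomplexity_rate = 0.01,
                              seed = 1L) {
  n_taxa <- as.integer(n_taxa)
  if (is.null(base_composition)) {
    base_composition <- 0.9^seq_len(n_taxa)
    base_composition <- base_composition / sum(base_composition)
  }
  if (length(base_composition) != n_taxa)
    stop("base_composition length must equal n_taxa")
  if (abs(sum(base_composition) - 1) > 1e-8)
    stop("base_composition must sum to 1")
  expand <- function(x) if (length(x) == 1L) rep(x, n_taxa) else x
  landuse_log_effects <- expand(landuse_log_effects)
  rain_log_effects <- expand(rain_log_effects)
  if (length(landuse_log_effects) != n_taxa ||
      length(rain_log_effects) != n_taxa)
    stop("effect vectors must have length n_taxa")
  rates <- c(decoy_rate, nohit_rate, lowcomplexity_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(library_sizes <= 0)) stop("library_sizes must be positive")
  if (dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be positive")
  structure(list(n_taxa = n_taxa, base_composition = base_composition,
                 landuse_log_effects = landuse_log_effects,
                 rain_log_effects = rain_log_effects,
                 dirichlet_concentration = dirichlet_concentration,
                 library_sizes = library_sizes,
                 decoy_rate = decoy_rate, nohit_rate = nohit_rate,
                 lowcomplexity_rate = lowcomplexity_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Per-taxon effect pattern helper
#'
#' Gives `frac * n_taxa` taxa a log-effect of alternating sign and magnitude
#' `size`; the rest zero.  Convenient for dialling group separation.
#'
#' @param n_taxa number of taxa; `size` log-effect magnitude; `frac`
#'   affected fraction; `seed` which taxa are picked.
#' @param size log-effect magnitude.
#' @param frac fraction of taxa affected.
#' @param seed integer seed.
#' @export
effect_pattern <- function(n_taxa, size, frac = 0.3, seed = 1L) {
  k <- max(2L, round(frac * n_taxa))
  with_seed(seed, {
    idx <- sample.int(n_taxa, k)
    eff <- numeric(n_taxa)
    eff[idx] <- size * rep_len(c(1, -1), k)
    eff
  })
}

## Dirichlet draw via gammas
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate ground-truth community count profiles
#'
#' For each sample, the baseline log-composition receives half the land-use
#' effect (sign by land use) and half the rain effect (sign by timing), is
#' renormalized, perturbed by a Dirichlet draw with the configured
#' concentration, and sampled multinomially to the library size.
#'
#' @param metadata from [generate_metadata()].
#' @param params a [simulation_params()] object.
#' @param taxonomy optional [tax_tree()]; simulated from the parameter seed
#'   when missing.
#' @return list with `counts` (species x samples matrix of true taxon
#'   counts), `probs` (expected compositions) and `taxonomy`.
#' @export
generate_profiles <- function(metadata, params, taxonomy = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(taxonomy))
    taxonomy <- simulate_taxonomy(params$n_taxa,
                                  substream_seed(params$seed, 0L))
  species <- tax_nodes_at_rank(taxonomy, "species")
  if (length(species) != params$n_taxa)
    stop("taxonomy species count does not match n_taxa")
  n <- nrow(metadata)
  libs <- rep_len(params$library_sizes, n)
  counts <- matrix(0L, params$n_taxa, n,
                   dimnames = list(taxonomy$name[species],
                                   metadata$sample_id))
  probs <- matrix(0, params$n_taxa, n,
                  dimnames = dimnames(counts))
  base_log <- log(params$base_composition)
  for (s in seq_len(n)) {
    x_lu <- if (metadata$land_use[s] == "industrial") 0.5 else -0.5
    x_rain <- if (metadata$timing[s] == "after") 0.5 else -0.5
    eta <- base_log + x_lu * params$landuse_log_effects +
      x_rain * params$rain_log_effects
    p <- exp(eta - max(eta))
    p <- p / sum(p)
    with_seed(substream_seed(params$seed, 100L + s), {
      p_s <- rdirichlet1(params$dirichlet_concentration * p)
      counts[, s] <- rmultinom(1, libs[s], p_s)
    })
    probs[, s] <- p
  }
  list(counts = counts, probs = probs, taxonomy = taxonomy,
       species_ids = species)
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate community profiles plus per-read hit tables
#'
#' Emulates the output of a protein-database search: each read carries its
#' true taxon with a score above the LCA floor, decoy reads get an extra hit
#' to a random wrong taxon (half within the top-score band, half below it),
#' a `nohit_rate` fraction only has a sub-threshold hit, and a
#' `lowcomplexity_rate` fraction receives a homopolymer sequence so the
#' complexity filter diverts it.  Ground truth is returned alongside.
#'
#' @inheritParams generate_profiles
#' @param read_length simulated read length (bases).
#' @return list with `truth` (species x samples count matrix over all
#'   reads), `reads` (read_id, sample_id, true_taxon, category, complexity,
#'   sequence), `hits` (read_id, taxon_id, bit_score) and `taxonomy`.
#' @export
generate_profiles_and_hits <- function(metadata, params, taxonomy = NULL,
                                       read_length = 60L) {
  prof <- generate_profiles(metadata, params, taxonomy)
  taxonomy <- prof$taxonomy
  species <- prof$species_ids
  n <- nrow(metadata)
  reads_list <- vector("list", n)
  hits_list <- vector("list", n)
  for (s in seq_len(n)) {
    cs <- prof$counts[, s]
    n_reads <- sum(cs)
    if (n_reads == 0L) next
    true_taxon <- rep(species, cs)
    read_id <- sprintf("%s_r%06d", metadata$sample_id[s], seq_len(n_reads))
    with_seed(substream_seed(params$seed, 200L + s), {
      true_taxon <- sample(true_taxon)
      u <- runif(n_reads)
      category <- ifelse(u < params$lowcomplexity_rate, "lowcomplexity",
                  ifelse(u < params$lowcomplexity_rate + params$nohit_rate,
                         "nohit", "ok"))
      sequence <- character(n_reads)
      lowc <- category == "lowcomplexity"
      sequence[!lowc] <- random_dna(sum(!lowc), read_length)
      sequence[lowc] <- strrep(sample(c("A", "C", "G", "T"), sum(lowc),
                                      replace = TRUE), read_length)
      ## true hits: scores comfortably above the default floor of 35
      score_true <- runif(n_reads, 50, 100)
      ok_or_low <- category != "nohit"
      h_read <- read_id[ok_or_low]
      h_tax <- true_taxon[ok_or_low]
      h_score <- score_true[ok_or_low]
      ## sub-threshold hit for no-hit reads
      nh <- category == "nohit"
      h_read <- c(h_read, read_id[nh])
      h_tax <- c(h_tax, sample(species, sum(nh), replace = TRUE))
      h_score <- c(h_score, runif(sum(nh), 5, 34))
      ## decoys on a random subset of ok reads
      dec <- which(category == "ok" & runif(n_reads) < params$decoy_rate)
      if (length(dec)) {
        wrong <- vapply(true_taxon[dec], function(t) {
          repeat {
            w <- species[sample.int(length(species), 1L)]
            if (w != t) return(w)
          }
        }, integer(1))
        in_band <- runif(length(dec)) < 0.5
        dscore <- ifelse(in_band,
                         score_true[dec] * runif(length(dec), 0.92, 1.0),
                         score_true[dec] * runif(length(dec), 0.5, 0.85))
        h_read <- c(h_read, read_id[dec])
        h_tax <- c(h_tax, wrong)
        h_score <- c(h_score, dscore)
      }
      reads_list[[s]] <- data.frame(
        read_id = read_id, sample_id = metadata$sample_id[s],
        true_taxon = true_taxon, category = category,
        sequence = sequence, stringsAsFactors = FALSE)
      hits_list[[s]] <- data.frame(
        read_id = h_read, taxon_id = h_tax, bit_score = h_score,
        stringsAsFactors = FALSE)
    })
  }
  reads <- do.call(rbind, reads_list)
  hits <- do.call(rbind, hits_list)
  rownames(reads) <- rownames(hits) <- NULL
  list(truth = prof$counts, probs = prof$probs, reads = reads, hits = hits,
       taxonomy = taxonomy)
}

#' Universal V6 primer used for ribotag extraction
#' @export
V6_PRIMER <- "CGACRRCCATGCANCACCT"

iupac_instantiate <- function(primer) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(primer, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(map[[ch]], "")[[1]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate shotgun reads with embedded V6 ribotags
#'
#' An `embed_rate` fraction of reads contains a concrete instantiation of
#' the degenerate V6 primer followed immediately by a catalogue tag; a
#' `revcomp_rate` fraction of those is placed on the reverse strand.  The
#' remaining reads are i.i.d.-uniform background, which has near-maximal
#' sequence complexity by construction.
#'
#' @param n_reads number of reads.
#' @param tag_catalogue character vector of 33-nt tags over A/C/G/T.
#' @param tag_probs tag sampling probabilities (default uniform).
#' @param embed_rate fraction of reads with an embedded primer+tag.
#' @param revcomp_rate fraction of embedded reads on the reverse strand.
#' @param read_length total read length; `prefix_max` limits the random
#'   offset before the primer so the space left downstream can be made
#'   shorter than 33 nt in tests.
#' @param prefix_max maximum number of random bases before the primer.
#' @param sample_id sample label recorded in the truth table.
#' @param seed integer seed.
#' @param primer degenerate primer (IUPAC).
#' @return list with `reads` (read_id, sequence), `truth` (read_id, tag,
#'   strand, full_tag flag) and `sample_id`.
#' @export
generate_v6_reads <- function(n_reads, tag_catalogue, tag_probs = NULL,
                              embed_rate = 0.1, revcomp_rate = 0.3,
                              read_length = 75L, prefix_max = 10L,
                              sample_id = "S1", seed = 1L,
                              primer = V6_PRIMER) {
  if (!all(nchar(tag_catalogue) == 33L))
    stop("every catalogue tag must be exactly 33 nucleotides")
  if (!all(grepl("^[ACGT]+$", tag_catalogue)))
    stop("tags must be over the alphabet {A,C,G,T}")
  if (is.null(tag_probs)) tag_probs <- rep(1, length(tag_catalogue))
  tag_probs <- tag_probs / sum(tag_probs)
  plen <- nchar(primer)
  with_seed(seed, {
    embedded <- runif(n_reads) < embed_rate
    rc <- embedded & runif(n_reads) < revcomp_rate
    seqs <- random_dna(n_reads, read_length)
    tag_idx <- rep(NA_integer_, n_reads)
    full <- rep(FALSE, n_reads)
    for (i in which(embedded)) {
      tag_idx[i] <- sample.int(length(tag_catalogue), 1L, prob = tag_probs)
      prim <- iupac_instantiate(primer)
      off <- sample.int(prefix_max + 1L, 1L) - 1L   # 0..prefix_max
      insert <- paste0(prim, tag_catalogue[tag_idx[i]])
      avail <- read_length - off
      body <- substr(insert, 1L, avail)
      full[i] <- nchar(body) >= plen + 33L
      s <- paste0(substr(seqs[i], 1L, off), body)
      s <- paste0(s, substr(seqs[i], nchar(s) + 1L, read_length))
      if (rc[i]) s <- revcomp_chr(s)
      seqs[i] <- s
    }
    truth <- data.frame(
      read_id = sprintf("%s_v6_%06d", sample_id, seq_len(n_reads)),
      tag = ifelse(embedded, tag_catalogue[tag_idx], NA_character_),
      strand = ifelse(!embedded, NA_character_, ifelse(rc, "-", "+")),
      full_tag = full, stringsAsFactors = FALSE)
    list(reads = data.frame(read_id = truth$read_id, sequence = seqs,
                            stringsAsFactors = FALSE),
         truth = truth, sample_id = sample_id)
  })
}

#' Write reads as FASTQ (constant qualities)
#' @param reads data.frame with `read_id` and `sequence`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  lines <- rbind(paste0("@", reads$read_id), reads$sequence,
                 "+", strrep("I", nchar(reads$sequence)))
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Generate a rain series and environmental variables with target rank
#' correlation
#'
#' Rain intensities are strictly positive gamma-marginal draws; each
#' environmental variable is coupled to rain through a Gaussian copula with
#' correlation `sin(pi * tau / 2)`, so its Kendall tau-b against the rain
#' series converges to the requested `target_tau`.
#'
#' @param n_time number of time points (>= 3).
#' @param target_tau named numeric vector of per-variable target tau values
#'   in `[-1, 1]`.  The default reproduces the sign pattern reported for the
#'   catchment: dissolved oxygen and temperature positively, sodium and
#'   potassium negatively rain-correlated.
#' @param seed integer seed.
#' @param rain_shape,rain_scale gamma marginal parameters for rain (mm).
#' @return list with `rain` (numeric vector) and `env` (data.frame, one
#'   column per variable).
#' @export
generate_env_rain <- function(n_time,
                              target_tau = c(dissolved_oxygen = 0.4,
                                             temperature = 0.3,
                                             sodium = -0.4,
                                             potassium = -0.3),
                              seed = 1L, rain_shape = 0.9, rain_scale = 18) {
  if (n_time < 3) stop("n_time must be at least 3")
  if (any(abs(target_tau) > 1)) stop("|target_tau| must be <= 1")
  vars <- names(target_tau)
  if (is.null(vars)) vars <- sprintf("var%d", seq_along(target_tau))
  with_seed(seed, {
    z_rain <- rnorm(n_time)
    rain <- qgamma(pnorm(z_rain), shape = rain_shape, scale = rain_scale)
    env <- vapply(seq_along(target_tau), function(v) {
      rho <- sin(pi * target_tau[v] / 2)
      if (abs(rho) == 1) rho * z_rain
      else rho * z_rain + sqrt(1 - rho^2) * rnorm(n_time)
    }, numeric(n_time))
    env <- as.data.frame(env)
    names(env) <- vars
    list(rain = rain, env = env)
  })
}

#' Write / read the sample metadata TSV
#' @param metadata data.frame from [generate_metadata()].
#' @param path file path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
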