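## 16S V6 ribotag extraction: scan shotgun reads for the degenerate V6
## primer and emit the 33-nt tag immediately downstream as an OTU signature.

#' Extract V6 ribotags from reads
#'
#' Each read is scanned for an exact IUPAC match of the degenerate primer,
#' forward strand first and then (optionally) the reverse strand; the first
#' match wins.  On a match the 33 nucleotides immediately downstream are
#' emitted, reverse-complemented into primer orientation for reverse-strand
#' matches.  Reads with fewer than 33 nt downstream of the primer are
#' discarded.
#'
#' @param reads a `Biostrings::DNAStringSet`, a data.frame with `read_id`
#'   and `sequence`, or a path to a FASTQ file.
#' @param primer degenerate primer sequence (IUPAC codes allowed).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param sample_id sample label attached to the occurrences.
#' @return data.frame `read_id`, `sample_id`, `tag`, `strand`.
#' @export
extract_v6_tags <- function(reads, primer = V6_PRIMER, both_strands = TRUE,
                            sample_id = "S1") {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  if (is.data.frame(reads)) {
    seqs <- Biostrings::DNAStringSet(reads$sequence)
    names(seqs) <- reads$read_id
  } else if (methods::is(reads, "DNAStringSet")) {
    seqs <- reads
    if (is.null(names(seqs))) names(seqs) <- sprintf("read%06d",
                                                     seq_along(seqs))
  } else stop("reads must be a DNAStringSet, data.frame or FASTQ path")
  pat <- Biostrings::DNAString(primer)
  plen <- length(pat)

  first_tags <- function(set) {
    mt <- Biostrings::vmatchPattern(pat, set, fixed = FALSE)
    st <- IRanges::start(mt)
    first <- vapply(st, function(v) if (length(v)) min(v) else NA_integer_,
                    integer(1))
    tag <- rep(NA_character_, length(set))
    hit <- which(!is.na(first))
    if (length(hit)) {
      from <- first[hit] + plen
      ok <- from + 32L <= Biostrings::width(set)[hit]
      hit <- hit[ok]
      from <- from[ok]
      if (length(hit))
        tag[hit] <- as.character(Biostrings::subseq(set[hit], start = from,
                                                    width = 33L))
    }
    tag
  }

  fwd <- first_tags(seqs)
  strand <- ifelse(is.na(fwd), NA_character_, "+")
  tag <- fwd
  if (both_strands && any(is.na(tag))) {
    todo <- which(is.na(tag))
    rc <- Biostrings::reverseComplement(seqs[todo])
    rev_tag <- first_tags(rc)
    got <- !is.na(rev_tag)
    tag[todo[got]] <- rev_tag[got]
    strand[todo[got]] <- "-"
  }
  keep <- which(!is.na(tag))
  data.frame(read_id = unname(names(seqs)[keep]),
             sample_id = rep(sample_id, length(keep)),
             tag = tag[keep], strand = strand[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build an OTU count matrix from tag occurrences
#'
#' Rows are distinct 33-mers in lexicographic order, columns the samples of
#' the metadata table; entries are occurrence counts.
#'
#' @param occurrences data.frame with `sample_id` and `tag` (e.g. rbind of
#'   [extract_v6_tags()] outputs across samples).
#' @param metadata sample metadata fixing the column set and order.
#' @return numeric matrix with attribute `level = "v6_otu"`.
#' @export
tags_to_otu_table <- function(occurrences, metadata) {
  unknown <- setdiff(unique(occurrences$sample_id), metadata$sample_id)
  if (length(unknown))
    stop("occurrences reference unknown sample id(s): ",
         paste(unknown, collapse = ", "))
  tags <- sort(unique(occurrences$tag))
  m <- matrix(0, length(tags), nrow(metadata),
              dimnames = list(tags, metadata$sample_id))
  if (nrow(occurrences)) {
    tb <- table(factor(occurrences$tag, levels = tags),
                factor(occurrences$sample_id, levels = metadata$sample_id))
    m[] <- as.numeric(tb)
  }
  attr(m, "level") <- "v6_otu"
  m
}

#' Read a FASTQ file into a data.frame of read ids and sequences
#' @param path FASTQ file (4-line records).
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = unname(sub("\\s.*$", "", names(set))),
             sequence = unname(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}
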