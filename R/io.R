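## Shared I/O: count-matrix TSV dialect (taxa rows, header of sample ids,
## tab-separated, '.' decimal), distance matrices (square TSV and
## PHYLIP-style lower triangle), NEXUS splits blocks, JSON config/manifest.

#' Write a count matrix as TSV
#'
#' First column `feature_id`, remaining columns one per sample.
#'
#' @param m taxa x samples matrix.
#' @param path output file.
#' @export
write_count_matrix <- function(m, path) {
  check_count_matrix(m)
  df <- data.frame(feature_id = rownames(m) %||%
                     sprintf("f%04d", seq_len(nrow(m))),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV
#'
#' Validates shape and content: ragged rows, duplicate feature ids and
#' negative values are reported with their line number.
#'
#' @param path TSV file written by [write_count_matrix()].
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty count matrix file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != ncols[1]))
    stop("ragged row at line ", which(ncols != ncols[1])[1], " of ", path)
  header <- parts[[1]]
  if (length(lines) == 1L) {
    m <- matrix(numeric(0), 0, length(header) - 1L,
                dimnames = list(NULL, header[-1]))
    return(m)
  }
  body <- do.call(rbind, parts[-1])
  ids <- body[, 1]
  if (anyDuplicated(ids))
    stop("duplicate feature id at line ",
         which(duplicated(ids))[1] + 1L, " of ", path)
  vals <- suppressWarnings(matrix(as.numeric(body[, -1, drop = FALSE]),
                                  nrow = nrow(body)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop("non-numeric value at line ", bad + 1L, " of ", path)
  }
  neg <- which(apply(vals < 0, 1, any))
  if (length(neg)) {
    col <- which(vals[neg[1], ] < 0)[1]
    stop("negative value at line ", neg[1] + 1L, " (feature ", ids[neg[1]],
         ", sample ", header[col + 1L], ") of ", path)
  }
  dimnames(vals) <- list(ids, header[-1])
  vals
}

#' Write / read a distance matrix
#'
#' `write_distance_matrix` writes the square TSV form;
#' `write_distance_phylip` writes the lower-triangle PHYLIP dialect.
#'
#' @param d distance matrix (or `dist`).
#' @param path output file.
#' @export
write_distance_matrix <- function(d, path) {
  dm <- as.matrix(d)
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname write_distance_matrix
#' @export
write_distance_phylip <- function(d, path) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    row <- if (i > 1) paste(format(dm[i, seq_len(i - 1)], digits = 10),
                            collapse = " ") else ""
    writeLines(trimws(paste(rownames(dm)[i], row)), con)
  }
  invisible(path)
}

#' Write a circular split system as a NEXUS splits block
#'
#' Emits a taxa block and a weighted splits block (cyclic ordering plus
#' one line per split listing its weight and the taxa indices of the
#' interval side), readable by split-network viewers and by
#' [read_nexus_splits()].
#'
#' @param css a `circular_splits` object.
#' @param path output file.
#' @export
write_nexus_splits <- function(css, path) {
  taxa <- css$ordering
  n <- css$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("", con)
  writeLines("BEGIN Taxa;", con)
  writeLines(sprintf("DIMENSIONS ntax=%d;", n), con)
  writeLines("TAXLABELS", con)
  writeLines(sprintf("[%d] '%s'", seq_len(n), taxa), con)
  writeLines(";", con)
  writeLines("END; [Taxa]", con)
  writeLines("", con)
  writeLines("BEGIN Splits;", con)
  writeLines(sprintf("DIMENSIONS ntax=%d nsplits=%d;", n,
                     nrow(css$splits)), con)
  writeLines("FORMAT labels=no weights=yes confidences=no intervals=no;",
             con)
  writeLines(sprintf("PROPERTIES fit=-1.0 cyclic;"), con)
  writeLines(sprintf("CYCLE %s;", paste(seq_len(n), collapse = " ")), con)
  writeLines("MATRIX", con)
  for (s in seq_len(nrow(css$splits))) {
    members <- seq(css$splits$i[s], css$splits$j[s])
    writeLines(sprintf("[%d] %.10g %s,", s, css$splits$weight[s],
                       paste(members, collapse = " ")), con)
  }
  writeLines(";", con)
  writeLines("END; [Splits]", con)
  invisible(path)
}

#' Read back a NEXUS splits block written by [write_nexus_splits()]
#'
#' @param path NEXUS file.
#' @return a `circular_splits` object (without fitted distances).
#' @export
read_nexus_splits <- function(path) {
  lines <- readLines(path)
  if (!grepl("#NEXUS", lines[1])) stop("not a NEXUS file: ", path)
  tax_lines <- grep("^\\[\\d+\\] '", lines, value = TRUE)
  taxa <- sub("^\\[\\d+\\] '(.*)'$", "\\1", tax_lines)
  n <- length(taxa)
  mstart <- grep("^MATRIX$", lines)
  mend <- grep("^;$", lines)
  mend <- mend[mend > mstart][1]
  splits <- data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  if (mend > mstart + 1) {
    body <- lines[(mstart + 1):(mend - 1)]
    parsed <- lapply(body, function(ln) {
      ln <- sub("^\\[\\d+\\]\\s*", "", ln)
      ln <- sub(",\\s*$", "", ln)
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      w <- as.numeric(toks[1])
      mem <- as.integer(toks[-1])
      data.frame(i = min(mem), j = max(mem), weight = w)
    })
    splits <- do.call(rbind, parsed)
  }
  structure(list(ordering = taxa, ordering_index = seq_len(n),
                 splits = splits, n = n, rss = NA_real_, fitted = NULL),
            class = "circular_splits")
}

#' Write a splits graph as a TSV edge list
#' @param g a `splits_graph`.
#' @param path output file.
#' @export
write_edge_list <- function(g, path) {
  utils::write.table(
    data.frame(node1 = g$edges$from, node2 = g$edges$to,
               weight = g$edges$weight, split_id = g$edges$split),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a pipeline configuration (JSON)
#' @param cfg named list of configuration values.
#' @param path JSON file.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
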