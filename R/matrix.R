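#' Build a k-mer presence/absence matrix
#'
#' Assembles per-taxon k-mer sets into a 0/1 matrix whose rows are the union
#' of all observed k-mers and whose columns are the taxa. `X[i, j] = 1` iff
#' k-mer i occurs in taxon j. By construction no row is all zero, and rows
#' are ordered ascending by the k-mer's 2-bit integer code so the matrix is
#' bit-reproducible across runs.
#'
#' @param kmersets Named list of character vectors, one k-mer set per taxon
#'   (as produced by [enumerate_kmers()]); all sets must share the same k.
#' @param k k-mer length; inferred from the sets when omitted.
#' @param mode Counting mode the sets were built with (stored as metadata).
#' @return Integer 0/1 matrix with `rownames` = k-mers, `colnames` = taxa,
#'   and attributes `k` and `mode`.
#' @examples
#' sets <- list(T1 = c("AT", "CG"), T2 = "AT")
#' build_matrix(sets)
#' @export
build_matrix <- function(kmersets, k = NULL,
                         mode = c("canonical", "non-canonical")) {
  mode <- match.arg(mode)
  if (length(kmersets) < 2) stop("need at least 2 taxa")
  taxa <- names(kmersets)
  if (is.null(taxa) || any(!nzchar(taxa)) || anyDuplicated(taxa))
    stop("kmersets must be uniquely named by taxon_id")
  lens <- unique(nchar(unlist(lapply(kmersets, function(s) s[1]))))
  lens <- lens[!is.na(lens)]
  if (length(lens) > 1)
    stop("k-mer sets have mixed lengths: ", paste(lens, collapse = ", "))
  if (is.null(k)) {
    if (length(lens) == 0) stop("cannot infer k from empty sets")
    k <- lens
  } else if (length(lens) == 1 && lens != k) {
    stop("k-mer sets have length ", lens, ", not k = ", k)
  }
  res <- build_matrix_cpp(lapply(kmersets, as.character), as.integer(k))
  X <- res$X
  rownames(X) <- res$kmers
  colnames(X) <- taxa
  attr(X, "k") <- as.integer(k)
  attr(X, "mode") <- mode
  X
}

#' Build per-k presence/absence matrices straight from sequences
#'
#' Convenience wrapper: enumerates k-mers for each taxon with
#' [enumerate_kmers()] and assembles the matrix with [build_matrix()].
#'
#' @param records Named list of contig character vectors (see [read_fasta()]).
#' @inheritParams enumerate_kmers
#' @return A presence/absence matrix as returned by [build_matrix()].
#' @export
kmer_matrix <- function(records, k, mode = c("canonical", "non-canonical")) {
  mode <- match.arg(mode)
  sets <- lapply(records, enumerate_kmers, k = k, mode = mode)
  build_matrix(sets, k = k, mode = mode)
}

#' Export a presence/absence matrix as relaxed PHYLIP
#'
#' Writes the matrix transposed into a relaxed PHYLIP binary alignment:
#' a header line `m n_rows`, then one line per taxon with the taxon id,
#' whitespace, and its column as a 0/1 character string. This is the format
#' binary-alignment ML tools consume.
#'
#' @param x Presence/absence matrix from [build_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_phylip <- function(x, path) {
  stopifnot(is.matrix(x))
  taxa <- colnames(x)
  if (any(grepl("[[:space:]]", taxa)))
    stop("taxon ids must not contain whitespace: ",
         paste(taxa[grepl("[[:space:]]", taxa)], collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ncol(x), nrow(x)), con)
  for (j in seq_len(ncol(x)))
    writeLines(paste(taxa[j], paste(x[, j], collapse = "")), con)
  invisible(path)
}

#' Read a relaxed PHYLIP 0/1 alignment
#'
#' Inverse of [export_phylip()]: returns the taxon-by-site 0/1 matrix
#' (i.e. the transpose of the presence/absence matrix).
#'
#' @param path File written by [export_phylip()].
#' @return Integer 0/1 matrix, rows = taxa, columns = sites.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  m <- hdr[1]; nsite <- hdr[2]
  body <- strsplit(trimws(lines[1 + seq_len(m)]), "[[:space:]]+")
  taxa <- vapply(body, `[`, "", 1)
  rows <- lapply(body, function(b)
    as.integer(strsplit(b[2], "")[[1]]))
  if (any(lengths(rows) != nsite)) stop("sequence length differs from header")
  out <- do.call(rbind, rows)
  rownames(out) <- taxa
  out
}

#' Dump a presence/absence matrix as TSV
#'
#' @param x Presence/absence matrix.
#' @param path Output file path; rows are k-mer strings, columns taxa.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(kmer = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
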