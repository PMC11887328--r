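#' Read genome sequences from FASTA files
#'
#' Reads one or more FASTA files (plain or gzipped) into a named list of
#' sequence records, one element per taxon. A multi-entry FASTA (e.g. a
#' contig assembly) is merged under a single taxon: the contigs are kept as
#' separate character strings so that k-mer windows never span a contig
#' junction.
#'
#' @param paths Character vector of FASTA file paths, or the path of a
#'   manifest TSV with two columns `taxon_id <tab> path` (no header).
#' @param taxon_ids Optional character vector of taxon identifiers, one per
#'   file. Defaults to the file basename with FASTA extensions stripped.
#' @return A named list; each element is a character vector of uppercased
#'   contig sequences for one taxon.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">T1", "ATAGCGC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(paths, taxon_ids = NULL) {
  stopifnot(length(paths) >= 1)
  if (length(paths) == 1 && !is_fasta_path(paths) && file.exists(paths)) {
    manifest <- utils::read.table(paths, sep = "\t", header = FALSE,
                                  col.names = c("taxon_id", "path"),
                                  colClasses = "character")
    taxon_ids <- manifest$taxon_id
    paths <- manifest$path
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(paths),
                     ignore.case = TRUE)
  }
  if (length(taxon_ids) != length(paths))
    stop("taxon_ids must match paths in length")
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon_id: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  records <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) stop("file not found: ", paths[i])
    seqs <- Biostrings::readDNAStringSet(paths[i])
    if (length(seqs) == 0) stop("empty FASTA file: ", paths[i])
    records[[i]] <- toupper(as.character(seqs, use.names = FALSE))
  }
  names(records) <- taxon_ids
  records
}

is_fasta_path <- function(path) {
  grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences over {A,C,G,T}.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement(c("AAA", "AT"))
#' @export
reverse_complement <- function(x) {
  revcomp_cpp(as.character(x))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller (A<C<G<T)
#' of the k-mer and its reverse complement. Canonical counting treats the
#' two strands of double-stranded DNA as the same molecule.
#'
#' @param x Character vector of k-mers over {A,C,G,T}.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_form("TTT") # "AAA"
#' @export
canonical_form <- function(x) {
  x <- as.character(x)
  rc <- revcomp_cpp(x)
  ifelse(rc < x, rc, x)
}

#' Enumerate the distinct k-mers of one taxon
#'
#' Slides a window of length `k` over every contig and collects the distinct
#' windows as a presence set (multiplicities are discarded). Windows
#' containing any non-ACGT character (IUPAC ambiguity codes, N runs) are
#' skipped entirely, and windows never span contig boundaries. In canonical
#' mode each window is replaced by [canonical_form()] before insertion.
#'
#' @param contigs Character vector of contig sequences for one taxon.
#' @param k k-mer length, an integer between 1 and 31.
#' @param mode `"canonical"` (default; reverse-complement pairs collapsed)
#'   or `"non-canonical"` (strand-specific).
#' @return Character vector of distinct k-mers, sorted ascending in the
#'   A<C<G<T order (equivalently, by 2-bit integer code).
#' @examples
#' enumerate_kmers("ATAGCGC", k = 2, mode = "non-canonical")
#' @export
enumerate_kmers <- function(contigs, k, mode = c("canonical", "non-canonical")) {
  mode <- match.arg(mode)
  enumerate_kmers_cpp(as.character(contigs), as.integer(k),
                      mode == "canonical")
}

#' Encode / decode k-mers as 2-bit integer codes
#'
#' Each base maps to two bits (A=0, C=1, G=2, T=3), so any k-mer with
#' k <= 31 packs into a 64-bit unsigned integer. The code is returned as a
#' decimal string because R has no native 64-bit integer type.
#'
#' @param x Character vector of k-mers (encode) or decimal code strings
#'   (decode).
#' @param k k-mer length, required for decoding.
#' @return Character vector of codes, or of decoded k-mers.
#' @examples
#' kmer_decode(kmer_encode("ACGT"), k = 4)
#' @export
kmer_encode <- function(x) kmer_encode_cpp(as.character(x))

#' @rdname kmer_encode
#' @export
kmer_decode <- function(x, k) kmer_decode_cpp(as.character(x), as.integer(k))
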