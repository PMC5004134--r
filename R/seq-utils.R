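#' @useDynLib hybridolc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors, tolerating
#' `N`. Thin wrapper around Biostrings so the complement table and IUPAC
#' handling are never hand-rolled.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Extract all k-mers of a sequence
#'
#' @param seq a single DNA string.
#' @param k k-mer size in bases.
#' @return character vector of `nchar(seq) - k + 1` k-mers; element `i`
#'   starts at 0-based position `i - 1`.
#' @export
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

#' Canonical form of k-mers
#'
#' The canonical k-mer is the lexicographically smaller of a k-mer and its
#' reverse complement (C-locale order on `A < C < G < T`).
#'
#' @param kmers character vector of k-mers.
#' @return list with `kmer` (canonical strings) and `fwd` (logical, `TRUE`
#'   when the canonical form is the input's forward orientation; palindromes
#'   count as forward).
#' @export
canonical_kmers <- function(kmers) {
  rc <- revcomp(kmers)
  fwd <- kmers <= rc
  list(kmer = ifelse(fwd, kmers, rc), fwd = fwd)
}

#' Read sequences from FASTA or FASTQ
#'
#' Identifiers are truncated at the first whitespace. Qualities, if present,
#' are ignored: the pipeline treats long-read base quality as uninformative.
#'
#' @param path file path; format auto-detected from the first character.
#' @return named character vector of upper-case sequences.
#' @export
read_seqs <- function(path) {
  first <- readChar(path, 1L)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width (default 80 columns).
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write sequences as FASTQ with a flat quality
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param qual single quality character applied to every base.
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep(qual, nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

#' N50 and NG50 contiguity statistics
#'
#' N50 is the length L such that contigs of length >= L hold at least half
#' of the assembly; NG50 uses half of the genome size instead.
#'
#' @param lengths integer vector of sequence lengths.
#' @param genome_size optional genome size for NG50.
#' @return named list `n50`, `ng50` (NA when `genome_size` missing or
#'   unreachable).
#' @export
assembly_n50 <- function(lengths, genome_size = NULL) {
  if (length(lengths) == 0L) return(list(n50 = 0L, ng50 = NA_integer_))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  n50 <- s[which(cum >= sum(s) / 2)[1L]]
  ng50 <- NA_real_
  if (!is.null(genome_size)) {
    i <- which(cum >= genome_size / 2)
    if (length(i)) ng50 <- s[i[1L]]
  }
  list(n50 = as.integer(n50), ng50 = as.integer(ng50))
}
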