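# Ground-truth simulator: genome -> NGS-like contigs + erroneous long reads.
# Every generator is deterministic per seed and returns a truth table
# sufficient to score the downstream stage that consumes its output.

DNA_BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a reference genome with optional planted repeats
#'
#' The background is uniform i.i.d. over ACGT. Each repeat family plants
#' `copies` copies of one random unit at non-overlapping positions; copies
#' are degraded to the requested identity by random substitutions, so
#' near-identical repeats can be used to stress the assembler.
#'
#' @param length genome length in bases.
#' @param repeats optional data.frame with columns `unit_len`, `copies`,
#'   `identity` (one row per family).
#' @param seed integer seed; runs with equal seeds are identical.
#' @return list with `seq` (DNA string), `length`, and `repeats` (truth
#'   data.frame: family, copy, start, end, 1-based inclusive).
#' @export
simulate_genome <- function(length, repeats = NULL, seed = 1L) {
  stopifnot(length >= 1)
  set.seed(seed)
  g <- rand_dna(length)
  truth <- data.frame(family = integer(0), copy = integer(0),
                      start = integer(0), end = integer(0))
  if (!is.null(repeats) && nrow(repeats) > 0) {
    occupied <- integer(0)
    for (f in seq_len(nrow(repeats))) {
      ulen <- repeats$unit_len[f]
      ncop <- repeats$copies[f]
      ident <- repeats$identity[f]
      if (ulen * ncop > length) stop("repeat family ", f, " does not fit the genome")
      unit <- rand_dna(ulen)
      placed <- 0L
      tries <- 0L
      while (placed < ncop) {
        tries <- tries + 1L
        if (tries > 1000L) stop("could not place repeat family ", f)
        s <- sample.int(length - ulen + 1L, 1L)
        span <- s:(s + ulen - 1L)
        if (any(span %in% occupied)) next
        copy <- strsplit(unit, "")[[1]]
        nmut <- rbinom(1L, ulen, 1 - ident)
        if (nmut > 0) {
          at <- sample.int(ulen, nmut)
          copy[at] <- vapply(copy[at], function(b)
            sample(setdiff(DNA_BASES, b), 1L), character(1))
        }
        substr(g, s, s + ulen - 1L) <- paste(copy, collapse = "")
        occupied <- c(occupied, span)
        placed <- placed + 1L
        truth <- rbind(truth, data.frame(family = f, copy = placed,
                                         start = s, end = s + ulen - 1L))
      }
    }
  }
  list(seq = g, length = length, repeats = truth, seed = seed)
}

#' Fragment a genome into NGS-like contigs
#'
#' Emulates the output of an accurate short-read de Bruijn assembly: the
#' genome is cut at random gap positions (gap count ~ Poisson with the
#' requested rate per 10 kb, gap lengths lognormal), and pieces shorter than
#' `min_len` are dropped. Contigs are error-free by default, reflecting the
#' high per-base accuracy of short-read contigs; a small substitution rate
#' can be injected to emulate consensus errors.
#'
#' @param genome result of [simulate_genome()] or a plain DNA string.
#' @param gap_rate expected gaps per 10 kb (default 1).
#' @param gap_meanlog,gap_sdlog lognormal parameters of gap length in bases
#'   (defaults give a median gap of ~200 bp).
#' @param min_len minimum contig length kept (default 300 bp; must be at
#'   least the anchoring k-mer size).
#' @param error_rate per-base substitution rate applied to contigs
#'   (default 0).
#' @param seed integer seed.
#' @return list with `contigs` (named character vector) and `truth`
#'   (data.frame: contig, start, end on the genome, 1-based inclusive).
#' @export
simulate_contigs <- function(genome, gap_rate = 1, gap_meanlog = log(200),
                             gap_sdlog = 0.5, min_len = 300L,
                             error_rate = 0, seed = 1L) {
  g <- if (is.list(genome)) genome$seq else genome
  G <- nchar(g)
  set.seed(seed)
  ngap <- rpois(1L, gap_rate * G / 1e4)
  cuts <- sort(sample.int(G, min(ngap, G)))
  glen <- pmax(1L, round(rlnorm(length(cuts), gap_meanlog, gap_sdlog)))
  # gaps as [start, end] intervals, clipped and non-overlapping
  gs <- cuts
  ge <- pmin(G, cuts + glen - 1L)
  keep <- !logical(length(gs))
  if (length(gs) > 1) for (i in 2:length(gs)) if (gs[i] <= ge[i - 1L] + 1L) keep[i] <- FALSE
  gs <- gs[keep]; ge <- ge[keep]
  starts <- c(1L, ge + 1L)
  ends <- c(gs - 1L, G)
  ok <- ends - starts + 1L >= min_len
  starts <- starts[ok]; ends <- ends[ok]
  if (length(starts) == 0L) stop("no contig survives min_len; lower gap_rate or min_len")
  seqs <- substring(g, starts, ends)
  if (error_rate > 0) {
    seqs <- vapply(seqs, function(s) inject_errors(s, error_rate, 0, 0), character(1))
  }
  ids <- sprintf("ctg%04d", seq_along(seqs))
  names(seqs) <- ids
  list(contigs = seqs,
       truth = data.frame(contig = ids, start = starts, end = ends))
}

# Per-base error channel: substitutions, single-base insertions (after a
# position), deletions. Rates are independent per base.
inject_errors <- function(s, sub, ins, del) {
  n <- nchar(s)
  if (n == 0L) return(s)
  ch <- strsplit(s, "")[[1]]
  u <- runif(n)
  is_sub <- u < sub
  is_del <- u >= sub & u < sub + del
  if (any(is_sub)) {
    ch[is_sub] <- vapply(ch[is_sub], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1), USE.NAMES = FALSE)
  }
  base_part <- ifelse(is_del, "", ch)
  is_ins <- runif(n) < ins
  ins_part <- ifelse(is_ins, sample(DNA_BASES, n, replace = TRUE), "")
  paste(paste0(base_part, ins_part), collapse = "")
}

#' Simulate erroneous long reads with known truth
#'
#' Reads emulate third-generation data: lognormal lengths, random strand,
#' uniform sampling positions, and independent per-base substitution,
#' insertion and deletion errors (the defaults total 15 percent, the
#' PacBio-class regime; Nanopore-class data is emulated by raising them
#' toward 40 percent). A fraction of reads are chimeric: a single-junction
#' fusion of two independently sampled loci, each with its own strand.
#'
#' @param genome result of [simulate_genome()] or a DNA string.
#' @param coverage fold coverage of sampled (pre-error) bases.
#' @param len_meanlog,len_sdlog lognormal read-length parameters; defaults
#'   give a mean of ~8 kb.
#' @param min_len minimum read length (truncation, default 1000).
#' @param sub,ins,del per-base error rates (defaults 0.05 each).
#' @param chimera_rate fraction of chimeric reads (default 0).
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: read, part, start, end, strand, chimeric; one row per
#'   locus, two for chimeras; coordinates 1-based inclusive on the genome).
#' @export
simulate_reads <- function(genome, coverage = 20,
                           len_meanlog = log(8000) - 0.35^2 / 2,
                           len_sdlog = 0.35, min_len = 1000L,
                           sub = 0.05, ins = 0.05, del = 0.05,
                           chimera_rate = 0, seed = 1L) {
  stopifnot(sub >= 0, ins >= 0, del >= 0, sub + ins + del < 1, coverage > 0)
  g <- if (is.list(genome)) genome$seq else genome
  G <- nchar(g)
  set.seed(seed)
  target <- coverage * G
  reads <- character(0)
  truth <- vector("list", 0)
  total <- 0
  i <- 0L
  while (total < target) {
    i <- i + 1L
    L <- max(min_len, round(rlnorm(1L, len_meanlog, len_sdlog)))
    L <- min(L, G)
    id <- sprintf("read%05d", i)
    chim <- runif(1L) < chimera_rate
    if (chim) {
      f <- runif(1L, 0.3, 0.7)
      lens <- c(max(200L, round(L * f)), max(200L, round(L * (1 - f))))
    } else {
      lens <- L
    }
    parts <- character(length(lens))
    for (p in seq_along(lens)) {
      lp <- min(lens[p], G)
      s <- sample.int(G - lp + 1L, 1L)
      strand <- sample(c("+", "-"), 1L)
      sq <- substr(g, s, s + lp - 1L)
      if (strand == "-") sq <- revcomp(sq)
      parts[p] <- inject_errors(sq, sub, ins, del)
      truth[[length(truth) + 1L]] <- data.frame(
        read = id, part = p, start = s, end = s + lp - 1L,
        strand = strand, chimeric = chim)
    }
    reads[[id]] <- paste(parts, collapse = "")
    total <- total + sum(lens)
  }
  list(reads = reads, truth = do.call(rbind, truth))
}
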