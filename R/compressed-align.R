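# Identifier-level overlap detection: an inverted index proposes candidate
# pairs sharing contig identifiers; a Smith-Waterman over the two anchor
# sequences (alphabet = oriented contig ids) scores them and classifies the
# relation (containment / dovetail / none).

#' Scoring scheme for compressed-read alignment
#'
#' A match requires equal contig id and a consistent orientation pair and is
#' scored either by the contig length (`by_contig_length`, the default: long
#' anchors are strong evidence) or by the number of matching k-mers
#' (`by_kmer_support`). Mismatch and gap penalties must be commensurate with
#' the match scores: defaults are minus a quarter of the median contig
#' length, or -5 in support units.
#'
#' @param contig_len named integer vector of contig lengths.
#' @param mode `"by_contig_length"` or `"by_kmer_support"`.
#' @param mismatch,gap non-positive penalties; `NULL` picks the scaled
#'   default.
#' @param min_overlap_score alignments scoring below this are classified
#'   `none` (default 150 length-weighted units).
#' @return object of class `score_scheme`.
#' @export
score_scheme <- function(contig_len, mode = c("by_contig_length", "by_kmer_support"),
                         mismatch = NULL, gap = NULL, min_overlap_score = 150) {
  mode <- match.arg(mode)
  if (is.null(mismatch))
    mismatch <- if (mode == "by_contig_length")
      -stats::median(contig_len) / 4 else -5
  if (is.null(gap)) gap <- mismatch
  stopifnot(mismatch <= 0, gap <= 0)
  structure(list(mode = mode, contig_len = contig_len, mismatch = mismatch,
                 gap = gap, min_overlap_score = min_overlap_score),
            class = "score_scheme")
}

#' Build an inverted index from contig identifiers to compressed reads
#'
#' @param crs named list of `cread` objects.
#' @return object of class `inv_index`: list with `postings` (contig id ->
#'   character vector of read ids).
#' @export
build_inverted_index <- function(crs) {
  tabs <- lapply(crs, function(cr) {
    if (nrow(cr$anchors) == 0L) return(NULL)
    data.table::data.table(contig = unique(cr$anchors$contig), read = cr$id)
  })
  dt <- data.table::rbindlist(tabs)
  postings <- if (nrow(dt)) {
    lapply(split(dt$read, dt$contig), unique)
  } else list()
  structure(list(postings = postings), class = "inv_index")
}

#' Candidate overlapping reads by shared contig identifiers
#'
#' @param cr query `cread`.
#' @param index an `inv_index`.
#' @param min_shared minimum number of distinct shared identifiers
#'   (default 1).
#' @return character vector of read ids (query excluded), sorted.
#' @export
candidates <- function(cr, index, min_shared = 1L) {
  stopifnot(min_shared >= 1L)
  ids <- unique(cr$anchors$contig)
  hits <- unlist(index$postings[ids], use.names = FALSE)
  if (length(hits) == 0L) return(character(0))
  tab <- table(hits)
  out <- names(tab)[tab >= min_shared]
  sort(out[out != cr$id])
}

# Core anchor-sequence Smith-Waterman. `a`, `b` are anchor data.frames in
# the orientation to be aligned. Computes the best local score (with one
# optimal alignment's spans and matched rows; tie-breaking fixed: best cell
# = first maximum in row-major scan, traceback prefers diagonal, then up,
# then left) plus three constrained optima used for tie-break-free relation
# classification: `ca`/`cb` (one read fully consumed, the other's flanks
# free) and `sp`/`ps` (dovetail reaching a's end and b's start, or the
# mirror). A relation holds when its constrained optimum attains the local
# optimum.
sw_anchor_dp <- function(a, b, scheme) {
  n <- nrow(a); m <- nrow(b)
  zero <- list(score = 0, a0 = 0L, a1 = 0L, b0 = 0L, b1 = 0L,
               matched_a = integer(0), matched_b = integer(0), nmatch = 0L,
               ca = -Inf, cb = -Inf, sp = -Inf, ps = -Inf)
  if (n == 0L || m == 0L) return(zero)
  match_score <- if (scheme$mode == "by_contig_length") {
    outer(seq_len(n), seq_len(m), function(i, j)
      as.numeric(scheme$contig_len[a$contig[i]]))
  } else {
    outer(a$support, b$support, pmin)
  }
  ok <- outer(seq_len(n), seq_len(m), function(i, j)
    a$contig[i] == b$contig[j] & a$orient[i] == b$orient[j])
  s <- ifelse(ok, match_score, scheme$mismatch)
  gp <- scheme$gap
  # generic banded-free NW over the scoring matrix: init_a / init_b give the
  # boundary scores (use -Inf to force the alignment through an edge)
  nw_max <- function(init_a, init_b, final) {
    H <- matrix(-Inf, n + 1L, m + 1L)
    H[1L, ] <- c(0, init_b)
    H[, 1L] <- c(0, init_a)
    for (i in seq_len(n)) {
      hi <- H[i + 1L, ]
      hp <- H[i, ]
      for (j in seq_len(m)) {
        hi[j + 1L] <- max(hp[j] + s[i, j], hp[j + 1L] + gp, hi[j] + gp)
      }
      H[i + 1L, ] <- hi
    }
    final(H)
  }
  # local optimum with traceback
  H <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)  # 0 stop, 1 diag, 2 up, 3 left
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag <- H[i, j] + s[i, j]
      up <- H[i, j + 1L] + gp
      left <- H[i + 1L, j] + gp
      v <- 0; p <- 0L
      if (diag >= up && diag >= left && diag > 0) { v <- diag; p <- 1L }
      else if (up >= left && up > 0) { v <- up; p <- 2L }
      else if (left > 0) { v <- left; p <- 3L }
      H[i + 1L, j + 1L] <- v
      P[i + 1L, j + 1L] <- p
      if (v > best) { best <- v; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(zero)
  i <- bi; j <- bj
  ma <- integer(0); mb <- integer(0)
  while (i > 0L && j > 0L && P[i + 1L, j + 1L] != 0L) {
    p <- P[i + 1L, j + 1L]
    if (p == 1L) {
      if (ok[i, j]) { ma <- c(i, ma); mb <- c(j, mb) }
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) i <- i - 1L
    else j <- j - 1L
  }
  ca <- nw_max(gp * seq_len(n), rep(0, m), function(H) max(H[n + 1L, ]))
  cb <- nw_max(rep(0, n), gp * seq_len(m), function(H) max(H[, m + 1L]))
  sp <- nw_max(rep(0, n), gp * seq_len(m), function(H) max(H[n + 1L, ]))
  ps <- nw_max(gp * seq_len(n), rep(0, m), function(H) max(H[, m + 1L]))
  list(score = best, a0 = i, a1 = bi, b0 = j, b1 = bj,
       matched_a = ma, matched_b = mb, nmatch = length(ma),
       ca = ca, cb = cb, sp = sp, ps = ps)
}

#' Align two compressed reads in the identifier domain
#'
#' Runs a local Smith-Waterman over the two anchor sequences, trying `b`
#' both as given and reverse-complemented (the two orientations are never
#' mixed within one alignment), and classifies the relation: containment
#' when an optimal-score alignment consumes one read's anchors completely,
#' `suffix_prefix` / `prefix_suffix` when an optimal-score alignment
#' reaches `a`'s end and `b`'s start (or the mirror; a dovetail), otherwise
#' `none`. Classification compares constrained optima against the local
#' optimum, so it does not depend on traceback tie-breaking. Alignments
#' scoring below `min_overlap_score` are `none`.
#'
#' @param a,b `cread` objects (canonicalized).
#' @param scheme a [score_scheme()].
#' @param min_overlap_score override of the scheme threshold.
#' @return object of class `olc_overlap`: list with `read_a`, `read_b`,
#'   `relation`, `score`, `matched_ids`, `a_span`, `b_span` (0-based
#'   half-open anchor-index intervals, `b_span` in the aligned-b frame),
#'   `orientation` (`same`/`opposite`), `mutual`, and matched anchor row
#'   indices `matched_a` / `matched_b` (aligned-b frame).
#' @export
align_compressed <- function(a, b, scheme,
                             min_overlap_score = scheme$min_overlap_score) {
  n <- nrow(a$anchors); m <- nrow(b$anchors)
  base <- list(read_a = a$id, read_b = b$id, relation = "none", score = 0,
               matched_ids = 0L, a_span = c(0L, 0L), b_span = c(0L, 0L),
               orientation = "same", mutual = FALSE,
               matched_a = integer(0), matched_b = integer(0))
  class(base) <- "olc_overlap"
  if (n == 0L || m == 0L) return(base)
  fwd <- sw_anchor_dp(a$anchors, b$anchors, scheme)
  rev <- sw_anchor_dp(a$anchors, rc_cread(b)$anchors, scheme)
  use_rev <- (rev$score > fwd$score) ||
    (rev$score == fwd$score && rev$nmatch > fwd$nmatch)
  al <- if (use_rev) rev else fwd
  out <- base
  out$score <- al$score
  out$matched_ids <- al$nmatch
  out$a_span <- c(al$a0, al$a1)
  out$b_span <- c(al$b0, al$b1)
  out$orientation <- if (use_rev) "opposite" else "same"
  out$matched_a <- al$matched_a
  out$matched_b <- al$matched_b
  if (al$score < min_overlap_score) return(out)
  eps <- 1e-9
  a_full <- al$ca >= al$score - eps
  b_full <- al$cb >= al$score - eps
  out$relation <-
    if (a_full && b_full) { out$mutual <- TRUE; "contained_a_in_b" }
    else if (a_full) "contained_a_in_b"
    else if (b_full) "contained_b_in_a"
    else if (al$sp >= al$score - eps) "suffix_prefix"
    else if (al$ps >= al$score - eps) "prefix_suffix"
    else "none"
  out
}

#' Dump pairwise overlaps as TSV (debug aid)
#'
#' @param overlaps list of `olc_overlap` objects.
#' @param path output path.
#' @export
write_overlaps <- function(overlaps, path) {
  rows <- vapply(overlaps, function(o) {
    paste(o$read_a, o$read_b, o$relation, format(o$score, trim = TRUE),
          o$matched_ids, o$a_span[1], o$a_span[2], o$b_span[1], o$b_span[2],
          o$orientation, sep = "\t")
  }, character(1))
  writeLines(c("read_a\tread_b\trelation\tscore\tmatched_ids\ta0\ta1\tb0\tb1\torientation",
               rows), path)
  invisible(path)
}
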