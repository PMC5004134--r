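# Anchoring stage: index contigs by unique k-mers, convert each long read
# into a compressed read (ordered, oriented contig identifier list).
#
# Conventions: all k-mer/anchor positions are 0-based k-mer start
# coordinates. A compressed read carries its own frame: `strand` says
# whether its coordinate frame is the raw read's forward strand or its
# reverse complement; anchor coordinates always refer to that frame.

#' Validate and wrap a contig set
#'
#' @param contigs named character vector of contig sequences.
#' @return the validated named character vector (invisibly classed).
#' @export
contig_set <- function(contigs) {
  if (length(contigs) == 0L) stop("empty contig set")
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contig ids must be present and unique")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) stop("contig sequences must be over {A,C,G,T,N}: ",
                     paste(names(contigs)[bad], collapse = ", "))
  structure(contigs, class = c("contig_set", "character"))
}

#' Build a unique k-mer index over contigs
#'
#' Every canonical k-mer occurring exactly once across all contigs (k-mers
#' repeated within a single contig are also positionally ambiguous and are
#' excluded) is stored with its contig, 0-based offset, and the strand on
#' which the canonical form occurs. k-mers containing N are skipped.
#'
#' @param contigs named character vector (see [contig_set()]).
#' @param k k-mer size (`k >= 2`; 17 is the calibrated default for long
#'   erroneous reads, tiny values only make sense in toy examples).
#' @return object of class `ukindex`: list with `k`, `kmer`, `contig`,
#'   `offset`, `fwd` (canonical form on contig forward strand), and
#'   `contig_len`.
#' @export
build_unique_kmer_index <- function(contigs, k) {
  contigs <- contig_set(contigs)
  stopifnot(k >= 2)
  lens <- nchar(contigs)
  if (all(lens < k)) stop("k = ", k, " exceeds every contig length")
  if (any(lens < k)) contigs <- contigs[lens >= k]
  tabs <- lapply(seq_along(contigs), function(i) {
    kms <- seq_kmers(contigs[[i]], k)
    can <- canonical_kmers(kms)
    data.table::data.table(kmer = can$kmer, fwd = can$fwd,
                           contig = names(contigs)[i],
                           offset = seq_along(kms) - 1L)
  })
  dt <- data.table::rbindlist(tabs)
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  cnt <- dt[, .N, by = kmer]
  dt <- dt[cnt[N == 1L], on = "kmer"][, N := NULL]
  data.table::setorder(dt, contig, offset)
  structure(list(k = as.integer(k), kmer = dt$kmer, contig = dt$contig,
                 offset = dt$offset, fwd = dt$fwd,
                 contig_len = stats::setNames(nchar(contigs), names(contigs))),
            class = "ukindex")
}

#' @export
print.ukindex <- function(x, ...) {
  cat("unique k-mer index: k =", x$k, ",", length(x$kmer), "k-mers over",
      length(x$contig_len), "contigs\n")
  invisible(x)
}

# Compressed read constructor. `anchors` is a data.frame with columns
# contig, orient, rp, rp_first, rp_last, cp, cp_first, cp_last, support.
# rp* are 0-based k-mer starts in the cread's frame; cp* are paired contig
# forward offsets of the same supporting hits.
new_cread <- function(id, raw_id, raw_start, raw_end, strand, anchors, k,
                      multiplicity = 1L, members = raw_id) {
  structure(list(id = id, raw_id = raw_id,
                 raw_start = as.integer(raw_start),
                 raw_end = as.integer(raw_end),
                 strand = strand,
                 len = as.integer(raw_end - raw_start + 1L),
                 anchors = anchors, k = as.integer(k),
                 multiplicity = as.integer(multiplicity),
                 members = members),
            class = "cread")
}

empty_anchor_df <- function() {
  data.frame(contig = character(0), orient = character(0),
             rp = integer(0), rp_first = integer(0), rp_last = integer(0),
             cp = integer(0), cp_first = integer(0), cp_last = integer(0),
             support = integer(0), stringsAsFactors = FALSE)
}

#' @export
print.cread <- function(x, ...) {
  a <- x$anchors
  cat(sprintf("compressed read %s (raw %s:%d-%d%s, x%d): %s\n", x$id,
              x$raw_id, x$raw_start, x$raw_end, x$strand, x$multiplicity,
              if (nrow(a)) paste0(a$contig, a$orient, collapse = " ") else "<empty>"))
  invisible(x)
}

#' Number of anchors of a compressed read
#' @param cr a `cread`.
#' @export
n_anchors <- function(cr) nrow(cr$anchors)

#' Oriented sequence of a compressed read
#'
#' Extracts the raw-read interval backing the compressed read and orients it
#' into the cread's own coordinate frame.
#'
#' @param cr a `cread`.
#' @param raws named character vector of raw read sequences.
#' @export
cread_seq <- function(cr, raws) {
  s <- substr(raws[[cr$raw_id]], cr$raw_start, cr$raw_end)
  if (cr$strand == "-") s <- revcomp(s) else s
}

#' Reverse complement of a compressed read
#'
#' Flips the coordinate frame: anchors are reversed, orientations flipped,
#' and positions mirrored (`rp' = len - k - rp`). Contig offsets are
#' forward-strand and unchanged, but first/last hit pairs swap.
#'
#' @param cr a `cread`.
#' @export
rc_cread <- function(cr) {
  a <- cr$anchors
  if (nrow(a)) {
    m <- cr$len - cr$k
    a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
    a <- data.frame(contig = a$contig,
                    orient = ifelse(a$orient == "+", "-", "+"),
                    rp = m - a$rp,
                    rp_first = m - a$rp_last, rp_last = m - a$rp_first,
                    cp = a$cp, cp_first = a$cp_last, cp_last = a$cp_first,
                    support = a$support, stringsAsFactors = FALSE)
    rownames(a) <- NULL
  }
  out <- cr
  out$strand <- if (cr$strand == "+") "-" else "+"
  out$anchors <- a
  out
}

# Lexicographic key on the (contig, orient) anchor sequence; "+" sorts
# before "-" because it is ASCII-smaller ("+" < "-").
cread_key <- function(cr) {
  if (nrow(cr$anchors) == 0L) return("")
  paste(paste0(cr$anchors$contig, cr$anchors$orient), collapse = " ")
}

#' Canonicalize a compressed read under reverse complement
#'
#' A compressed read and its reverse complement are equivalent; the
#' canonical representative is the one whose (contig, orientation) sequence
#' is lexicographically smaller. Idempotent; palindromic reads are kept
#' as given.
#'
#' @param cr a `cread`.
#' @export
canonicalize_cread <- function(cr) {
  r <- rc_cread(cr)
  if (cread_key(r) < cread_key(cr)) r else cr
}

#' Anchor long reads on a unique k-mer index
#'
#' Every k-mer of each read is looked up (both strands via canonical form).
#' Per contig, hits are tallied; an anchor is emitted iff the count reaches
#' `max(min_support, ceiling(adaptive_frac * contig_length))`, the adaptive
#' threshold trading sensitivity against specificity. The anchor orientation
#' is the majority strand relation of the hits; ties drop the anchor, since
#' a wrongly oriented anchor corrupts the overlap graph more than a missing
#' one. Anchor coordinates (median / first / last supporting hit, with the
#' paired contig offsets) are taken over majority-strand hits. Anchors are
#' ordered by median read position. Each read's result is canonicalized.
#'
#' @param reads named character vector of read sequences.
#' @param index a `ukindex`.
#' @param adaptive_frac fraction of contig length required as k-mer support
#'   (paper-calibrated range 0.001-0.02; default 0.008).
#' @param min_support absolute floor on k-mer support (default 2, so tiny
#'   contigs cannot anchor on one spurious hit).
#' @param chunk_bases reads are processed in chunks of about this many bases
#'   to bound memory.
#' @return named list of `cread` objects (possibly with zero anchors).
#' @export
anchor_reads <- function(reads, index, adaptive_frac = 0.008,
                         min_support = 2L, chunk_bases = 2e6) {
  stopifnot(inherits(index, "ukindex"))
  if (adaptive_frac < 0.001 || adaptive_frac > 0.02)
    warning("adaptive_frac outside the calibrated range [0.001, 0.02]")
  k <- index$k
  out <- vector("list", length(reads))
  names(out) <- names(reads)
  lens <- nchar(reads)
  chunks <- split(seq_along(reads), ceiling(cumsum(as.numeric(lens)) / chunk_bases))
  thr <- pmax(as.integer(min_support),
              as.integer(ceiling(adaptive_frac * index$contig_len)))
  names(thr) <- names(index$contig_len)
  for (idx in chunks) {
    hit_tabs <- lapply(idx, function(i) {
      if (lens[i] < k) return(NULL)
      kms <- seq_kmers(reads[[i]], k)
      can <- canonical_kmers(kms)
      m <- match(can$kmer, index$kmer)
      hit <- which(!is.na(m))
      if (length(hit) == 0L) return(NULL)
      j <- m[hit]
      data.table::data.table(
        read = i, rp = hit - 1L, contig = index$contig[j],
        cp = index$offset[j],
        orient = ifelse(can$fwd[hit] == index$fwd[j], "+", "-"))
    })
    dt <- data.table::rbindlist(hit_tabs)
    anchors_by_read <- list()
    if (nrow(dt)) {
      grp <- dt[, .(support = .N, npos = sum(orient == "+")),
                by = .(read, contig)]
      grp <- grp[support >= thr[contig]]
      grp <- grp[npos * 2L != support]  # orientation ties dropped
      grp[, orient := ifelse(npos * 2L > support, "+", "-")]
      if (nrow(grp)) {
        dt2 <- dt[grp[, .(read, contig, orient)], on = c("read", "contig", "orient")]
        data.table::setorder(dt2, read, contig, rp)
        coords <- dt2[, {
          mid <- (length(rp) + 1L) %/% 2L
          .(rp = rp[mid], cp = cp[mid],
            rp_first = rp[1L], cp_first = cp[1L],
            rp_last = rp[.N], cp_last = cp[.N], nmaj = .N)
        }, by = .(read, contig)]
        anc <- grp[coords, on = c("read", "contig")]
        data.table::setorder(anc, read, rp, contig)
        anchors_by_read <- split(anc, by = "read")
        names(anchors_by_read) <- as.character(
          vapply(anchors_by_read, function(x) x$read[1L], integer(1)))
      }
    }
    for (i in idx) {
      a <- anchors_by_read[[as.character(i)]]
      adf <- if (is.null(a)) empty_anchor_df() else
        data.frame(contig = a$contig, orient = a$orient, rp = a$rp,
                   rp_first = a$rp_first, rp_last = a$rp_last,
                   cp = a$cp, cp_first = a$cp_first, cp_last = a$cp_last,
                   support = a$support, stringsAsFactors = FALSE)
      id <- names(reads)[i]
      out[[i]] <- canonicalize_cread(
        new_cread(id, id, 1L, lens[i], "+", adf, k))
    }
  }
  out
}

#' Anchor a single read
#'
#' @inheritParams anchor_reads
#' @param read a single DNA string.
#' @param read_id identifier for the read.
#' @return a `cread`.
#' @export
anchor_read <- function(read, index, adaptive_frac = 0.008, min_support = 2L,
                        read_id = "read") {
  anchor_reads(stats::setNames(read, read_id), index,
               adaptive_frac = adaptive_frac, min_support = min_support)[[1]]
}

#' Collapse identical compressed reads
#'
#' Compressed reads with identical canonical (contig, orientation) anchor
#' sequences are merged into one record: multiplicities are summed, member
#' read ids are kept for the consensus stage, and the member backed by the
#' longest raw interval becomes the representative (its coordinates are the
#' ones used downstream). Reads with no anchors are dropped.
#'
#' @param crs list of canonicalized `cread` objects.
#' @return named list of collapsed `cread` objects.
#' @export
collapse_duplicates <- function(crs) {
  crs <- Filter(function(cr) nrow(cr$anchors) > 0L, crs)
  if (length(crs) == 0L) return(list())
  keys <- vapply(crs, cread_key, character(1))
  out <- lapply(split(seq_along(crs), keys), function(ii) {
    grp <- crs[ii]
    lens <- vapply(grp, function(cr) cr$len, integer(1))
    ids <- vapply(grp, function(cr) cr$id, character(1))
    rep <- grp[[order(-lens, ids)[1L]]]
    rep$multiplicity <- sum(vapply(grp, function(cr) cr$multiplicity, integer(1)))
    rep$members <- unique(unlist(lapply(grp, function(cr) cr$members)))
    rep
  })
  out <- out[order(vapply(out, function(cr) cr$id, character(1)))]
  names(out) <- vapply(out, function(cr) cr$id, character(1))
  out
}

#' Serialize compressed reads to TSV
#'
#' One row per compressed read: id, multiplicity, raw id, raw interval and
#' strand, then the anchor list as space-separated `contig:orient:pos`
#' triples (median 0-based position in the cread frame). The triple format
#' is lossy (supporting-hit detail is dropped); it is the inspection /
#' exchange format, not an internal checkpoint.
#'
#' @param crs list of `cread` objects.
#' @param path output TSV path.
#' @export
write_creads <- function(crs, path) {
  rows <- vapply(crs, function(cr) {
    a <- cr$anchors
    paste(cr$id, cr$multiplicity, cr$raw_id, cr$raw_start, cr$raw_end,
          cr$strand,
          if (nrow(a)) paste(sprintf("%s:%s:%d", a$contig, a$orient, a$rp),
                             collapse = " ") else ".",
          sep = "\t")
  }, character(1))
  writeLines(c("read_id\tmultiplicity\traw_id\traw_start\traw_end\tstrand\tanchors",
               rows), path)
  invisible(path)
}

#' Read compressed reads back from TSV
#'
#' Inverse of [write_creads()] up to the lossy fields (supporting-hit pairs
#' and contig offsets come back as NA, support as NA).
#'
#' @param path TSV path written by [write_creads()].
#' @param k anchoring k-mer size to stamp on the records.
#' @export
read_creads <- function(path, k) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    adf <- empty_anchor_df()
    if (tab$anchors[i] != ".") {
      parts <- strsplit(strsplit(tab$anchors[i], " ", fixed = TRUE)[[1]],
                        ":", fixed = TRUE)
      adf <- data.frame(
        contig = vapply(parts, `[`, character(1), 1L),
        orient = vapply(parts, `[`, character(1), 2L),
        rp = as.integer(vapply(parts, `[`, character(1), 3L)),
        rp_first = NA_integer_, rp_last = NA_integer_, cp = NA_integer_,
        cp_first = NA_integer_, cp_last = NA_integer_,
        support = NA_integer_, stringsAsFactors = FALSE)
    }
    new_cread(tab$read_id[i], tab$raw_id[i], tab$raw_start[i],
              tab$raw_end[i], tab$strand[i], adf, k,
              multiplicity = tab$multiplicity[i])
  })
  names(out) <- tab$read_id
  out
}
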