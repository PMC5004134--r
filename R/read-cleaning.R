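# Multiple-alignment cleaning of compressed reads (pre-collapse): anchors
# unconfirmed by any neighbour are spurious and removed; a junction that no
# neighbour alignment crosses, with the left- and right-supporting neighbour
# sets disjoint, is a chimeric breakpoint and the read is split there.

#' Build a pileup of candidate alignments over one compressed read
#'
#' Aligns the target against every candidate sharing an identifier and keeps
#' all neighbours with positive alignment score (no overlap-score gate: the
#' pileup wants weak but real support too). Tallies, per target anchor, how
#' many neighbours match it. A neighbour's alignment counts toward anchor
#' support only when it matches at least two target anchors (one, for
#' single-anchor targets): a lone shared identifier is co-occurrence of a
#' contig elsewhere in the genome, not a confirming alignment, and exactly
#' such lone matches are what a spurious anchor attracts. The target itself
#' never supports its own anchors.
#'
#' @param target a `cread`.
#' @param crs named list of all `cread`s (must contain the target's
#'   neighbours; may contain the target).
#' @param index an `inv_index` over `crs`.
#' @param scheme a [score_scheme()].
#' @param min_shared candidate gate (default 1 shared identifier).
#' @return object of class `pileup`: list with `target`, `supports` (named
#'   list of `olc_overlap`), and `counts` (per-anchor support).
#' @export
build_pileup <- function(target, crs, index, scheme, min_shared = 1L) {
  cand <- candidates(target, index, min_shared = min_shared)
  supports <- list()
  counts <- integer(nrow(target$anchors))
  need <- min(2L, nrow(target$anchors))
  for (id in cand) {
    o <- align_compressed(target, crs[[id]], scheme, min_overlap_score = 0)
    if (o$score > 0 && o$matched_ids > 0L) {
      supports[[id]] <- o
      if (o$matched_ids >= need)
        counts[o$matched_a] <- counts[o$matched_a] + 1L
    }
  }
  structure(list(target = target, supports = supports, counts = counts),
            class = "pileup")
}

#' Remove spurious anchors from a pileup target
#'
#' Anchors matched by fewer than `min_confirm` neighbours are deleted (the
#' false-positive-anchor case: an anchoring contig appearing only once in
#' the multiple alignment, i.e. only on the target itself). Interior
#' anchors keep their order and coordinates; when an *end* anchor is
#' removed, the read's frame interval is trimmed back to the outermost
#' confirmed supporting hit — sequence beyond the last confirmed anchor
#' with an unconfirmed anchor out there is suspect (it is how a chimeric
#' tail whose far side carries a single anchor presents itself). The
#' result is re-canonicalized. A read losing every anchor comes back with
#' an empty anchor table and is the caller's job to exclude.
#'
#' @param p a `pileup`.
#' @param min_confirm minimum neighbour confirmations (default 1).
#' @return a `cread`.
#' @export
remove_spurious_anchors <- function(p, min_confirm = 1L) {
  stopifnot(min_confirm >= 1L)
  cr <- p$target
  keep <- which(p$counts >= min_confirm)
  if (length(keep) == nrow(cr$anchors)) return(cr)
  if (length(keep) == 0L) {
    cr$anchors <- cr$anchors[0L, , drop = FALSE]
    return(cr)
  }
  fs <- if (min(keep) > 1L) cr$anchors$rp_first[min(keep)] + 1L else 1L
  fe <- if (max(keep) < nrow(cr$anchors))
    cr$anchors$rp_last[max(keep)] + cr$k else cr$len
  a <- cr$anchors[keep, , drop = FALSE]
  shift <- fs - 1L
  a$rp <- a$rp - shift; a$rp_first <- a$rp_first - shift
  a$rp_last <- a$rp_last - shift
  rownames(a) <- NULL
  if (cr$strand == "+") {
    rs <- cr$raw_start + fs - 1L; re <- cr$raw_start + fe - 1L
  } else {
    rs <- cr$raw_end - fe + 1L; re <- cr$raw_end - fs + 1L
  }
  canonicalize_cread(new_cread(cr$id, cr$raw_id, rs, re, cr$strand, a,
                               cr$k, multiplicity = cr$multiplicity,
                               members = cr$members))
}

# Slice a cread to an anchor range [i0, i1] with a frame interval
# [fs, fe] (1-based, cread frame), mapping back to raw coordinates.
slice_cread <- function(cr, i0, i1, fs, fe, new_id) {
  a <- cr$anchors[i0:i1, , drop = FALSE]
  shift <- fs - 1L
  a$rp <- a$rp - shift; a$rp_first <- a$rp_first - shift
  a$rp_last <- a$rp_last - shift
  rownames(a) <- NULL
  if (cr$strand == "+") {
    rs <- cr$raw_start + fs - 1L; re <- cr$raw_start + fe - 1L
  } else {
    rs <- cr$raw_end - fe + 1L; re <- cr$raw_end - fs + 1L
  }
  canonicalize_cread(new_cread(new_id, cr$raw_id, rs, re, cr$strand, a,
                               cr$k, multiplicity = cr$multiplicity,
                               members = cr$members))
}

#' Detect and split a chimeric compressed read
#'
#' For each internal junction between consecutive anchors, neighbours are
#' partitioned by their matched anchor spans into left-supporting (entirely
#' before the junction), right-supporting (entirely after), and crossing. A
#' breakpoint is called where no neighbour crosses the junction and the left
#' and right neighbour id sets are disjoint. The read is cut at every
#' breakpoint; each fragment keeps the bases out to its own outermost
#' supporting k-mer hits (outer fragment ends extend to the read ends), and
#' fragments with fewer than 2 anchors are discarded. Reads with fewer than
#' 2 anchors are trivially clean.
#'
#' @param p a `pileup` built on the (already spurious-cleaned) read.
#' @param min_cross crossing confirmations needed to veto a junction
#'   (default 1; raised to the cleaning `min_confirm` at higher coverage so
#'   that a single coincidentally agreeing chimera cannot shield another).
#' @return object of class `chimera_call`: list with `read`, `breakpoints`
#'   (junction index j = between anchors j and j+1), `verdict` (one of
#'   `clean`, `split`, `discarded`), and `fragments` (list of `cread`s;
#'   the input read itself when clean).
#' @export
detect_chimera <- function(p, min_cross = 1L) {
  cr <- p$target
  n <- nrow(cr$anchors)
  if (n < 2L)
    return(structure(list(read = cr$id, breakpoints = integer(0),
                          verdict = "clean", fragments = list(cr)),
                     class = "chimera_call"))
  spans <- lapply(p$supports, function(o)
    c(min(o$matched_a), max(o$matched_a)))
  # a neighbour crosses junction j only when it confirms the two flanking
  # anchors adjacently (consecutive matched pair on both reads): a match on
  # both sides with extra structure in between is a disagreement, not a
  # confirmation
  crosses <- function(o, j) {
    t <- which(o$matched_a == j)
    length(t) > 0L && t < length(o$matched_a) &&
      o$matched_a[t + 1L] == j + 1L &&
      abs(o$matched_b[t + 1L] - o$matched_b[t]) == 1L
  }
  bps <- integer(0)
  for (j in seq_len(n - 1L)) {
    ncross <- sum(vapply(p$supports, crosses, logical(1), j = j))
    if (ncross >= min_cross) next
    left <- names(spans)[vapply(spans, function(s) s[2] <= j, logical(1))]
    right <- names(spans)[vapply(spans, function(s) s[1] >= j + 1L, logical(1))]
    if (length(intersect(left, right)) == 0L) bps <- c(bps, j)
  }
  if (length(bps) == 0L)
    return(structure(list(read = cr$id, breakpoints = integer(0),
                          verdict = "clean", fragments = list(cr)),
                     class = "chimera_call"))
  # Fragment frame intervals: outer ends extend to the read ends; internal
  # cut ends stop at the fragment's own outermost supporting k-mer hits, so
  # the uncertain chimeric junction region is excluded from both sides.
  starts_i <- c(1L, bps + 1L)
  ends_i <- c(bps, n)
  fs <- cr$anchors$rp_first[starts_i] + 1L
  fe <- cr$anchors$rp_last[ends_i] + cr$k
  fs[1L] <- 1L
  fe[length(fe)] <- cr$len
  frags <- list()
  for (f in seq_along(starts_i)) {
    if (ends_i[f] - starts_i[f] + 1L < 2L) next
    frags[[length(frags) + 1L]] <-
      slice_cread(cr, starts_i[f], ends_i[f], fs[f], fe[f],
                  sprintf("%s/f%d", cr$id, f))
  }
  structure(list(read = cr$id, breakpoints = bps,
                 verdict = if (length(frags)) "split" else "discarded",
                 fragments = frags),
            class = "chimera_call")
}

#' Clean a set of compressed reads
#'
#' Two passes over uncollapsed reads. Pass 1 builds a pileup per read and
#' removes spurious anchors; reads losing all anchors are discarded. Pass 2
#' rebuilds the pileups on the cleaned set and splits chimeric reads at
#' detected breakpoints. Cleaning before collapsing matters: identical twin
#' reads are genuine, independent confirmations of each other.
#'
#' @param crs named list of canonicalized `cread`s (uncollapsed).
#' @param scheme a [score_scheme()].
#' @param min_confirm neighbour confirmations required per anchor
#'   (default 1; use 2 above ~10x long-read coverage).
#' @param remove_chimera run the breakpoint pass (default TRUE).
#' @param min_shared candidate gate for pileups.
#' @return list with `crs` (cleaned named list) and `report` (data.frame:
#'   read, verdict, breakpoints, anchors_removed).
#' @export
clean_reads <- function(crs, scheme, min_confirm = 1L, remove_chimera = TRUE,
                        min_shared = 1L) {
  crs <- Filter(function(cr) nrow(cr$anchors) > 0L, crs)
  if (length(crs) == 0L)
    return(list(crs = list(),
                report = data.frame(read = character(0), verdict = character(0),
                                    breakpoints = character(0),
                                    anchors_removed = integer(0))))
  idx <- build_inverted_index(crs)
  removed <- integer(length(crs)); names(removed) <- names(crs)
  pass1 <- list()
  for (id in names(crs)) {
    p <- build_pileup(crs[[id]], crs, idx, scheme, min_shared = min_shared)
    cl <- remove_spurious_anchors(p, min_confirm = min_confirm)
    removed[[id]] <- nrow(crs[[id]]$anchors) - nrow(cl$anchors)
    if (nrow(cl$anchors) > 0L) pass1[[id]] <- cl
  }
  verdict <- stats::setNames(rep("clean", length(crs)), names(crs))
  verdict[setdiff(names(crs), names(pass1))] <- "discarded"
  bps <- stats::setNames(rep("", length(crs)), names(crs))
  out <- list()
  if (remove_chimera && length(pass1)) {
    idx2 <- build_inverted_index(pass1)
    for (id in names(pass1)) {
      p <- build_pileup(pass1[[id]], pass1, idx2, scheme,
                        min_shared = min_shared)
      call <- detect_chimera(p, min_cross = min_confirm)
      verdict[[id]] <- if (call$verdict == "clean" && removed[[id]] > 0L)
        "spurious_anchors_removed" else call$verdict
      bps[[id]] <- paste(call$breakpoints, collapse = ",")
      for (fr in call$fragments) out[[fr$id]] <- fr
    }
  } else {
    for (id in names(pass1)) {
      if (removed[[id]] > 0L) verdict[[id]] <- "spurious_anchors_removed"
      out[[id]] <- pass1[[id]]
    }
  }
  list(crs = out,
       report = data.frame(read = names(crs), verdict = unname(verdict),
                           breakpoints = unname(bps),
                           anchors_removed = unname(removed)))
}

#' Write a cleaning report as TSV
#'
#' @param report data.frame from [clean_reads()].
#' @param path output path.
#' @export
write_cleaning_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
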