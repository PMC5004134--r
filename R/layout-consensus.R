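# Layout: uncompress a backbone path into a draft nucleotide sequence,
# estimating each junction from the matched anchors' exact k-mer hits and
# patching long-read coverage gaps with the bridging contig. Consensus:
# align the related raw reads back to the draft with a seed-chain-extend
# aligner and polish via a sparse k-mer graph whose reweighted heaviest
# path is the final sequence.

# oriented contig position of a hit pair: for "-" anchors the contig
# appears reverse-complemented in the read frame, so k-mer starts mirror
oc_pos <- function(orient, cp, clen, k) {
  ifelse(orient == "+", cp, clen - k - cp)
}

#' Lay a backbone path out into draft sequence(s)
#'
#' Reads are oriented into the path frame and appended left to right. Each
#' junction offset is the median, over the shared anchors, of the offset
#' implied by the paired (read position, contig offset) supporting k-mer
#' hits; when the two reads share no raw-base overlap, the bridging
#' contig's sequence fills the gap, spliced at the flanking reads' exact
#' hit positions. Backbone ends are extended with the terminal anchors'
#' contig sequence where the contig reaches beyond the outermost reads
#' (the same hybrid principle: contigs cover long-read coverage gaps,
#' including the ones at the ends). An irreconcilable junction (the
#' successor would start before the current read, or no shared anchor)
#' breaks the backbone and a new draft is started.
#'
#' @param bbpath one element of [linear_paths()] output.
#' @param nodes named list of the graph's `cread`s.
#' @param raws named character vector of raw read sequences.
#' @param contigs named character vector of contig sequences.
#' @param path_id id stem for emitted drafts.
#' @param extend_ends extend draft ends with terminal contig sequence
#'   (default TRUE; disable for a strict reads-only layout).
#' @return list of drafts, each of class `draft`: list with `id`, `seq`,
#'   and `segmap` (data.frame: source, type read/contig, src_start,
#'   src_end, bb_start, bb_end, orient; src coordinates are 1-based in the
#'   path-oriented source frame).
#' @export
layout_backbone <- function(bbpath, nodes, raws, contigs,
                            path_id = "backbone_1", extend_ends = TRUE) {
  n <- length(bbpath$nodes)
  ocrs <- lapply(seq_len(n), function(i) {
    cr <- nodes[[bbpath$nodes[i]]]
    if (bbpath$orients[i] == "-") rc_cread(cr) else cr
  })
  k <- ocrs[[1]]$k
  clen <- nchar(contigs)
  drafts <- list()
  pieces <- character(0)
  segmap <- list()
  cur_len <- 0L
  trim_to <- function(len) {
    # cut the draft back to `len` bases, piece by piece from the right
    while (cur_len > len && length(pieces)) {
      excess <- cur_len - len
      last_n <- nchar(pieces[length(pieces)])
      sm <- segmap[[length(segmap)]]
      if (last_n <= excess) {
        pieces <<- pieces[-length(pieces)]
        segmap[[length(segmap)]] <<- NULL
        cur_len <<- cur_len - last_n
      } else {
        pieces[length(pieces)] <<- substr(pieces[length(pieces)], 1L,
                                          last_n - excess)
        sm$src_end <- sm$src_end - excess
        sm$bb_end <- sm$bb_end - excess
        segmap[[length(segmap)]] <<- sm
        cur_len <<- cur_len - excess
      }
    }
  }
  add_piece <- function(s, source, type, src_start, src_end, orient) {
    pieces <<- c(pieces, s)
    segmap[[length(segmap) + 1L]] <<- data.frame(
      source = source, type = type, src_start = src_start,
      src_end = src_end, bb_start = cur_len + 1L,
      bb_end = cur_len + nchar(s), orient = orient,
      stringsAsFactors = FALSE)
    cur_len <<- cur_len + nchar(s)
  }
  flush_draft <- function() {
    if (cur_len > 0L) {
      id <- if (length(drafts) == 0L) path_id else
        sprintf("%s_p%d", path_id, length(drafts) + 1L)
      drafts[[length(drafts) + 1L]] <<- structure(
        list(id = id, seq = paste(pieces, collapse = ""),
             segmap = do.call(rbind, segmap)), class = "draft")
    }
    pieces <<- character(0); segmap <<- list(); cur_len <<- 0L
  }
  eff_orient <- function(i) {
    # net orientation of the raw read in the path frame
    flips <- (ocrs[[i]]$strand == "-") + (bbpath$orients[i] == "-")
    if (flips %% 2L == 0L) "+" else "-"
  }
  oriented_contig <- function(contig, orient) {
    if (orient == "-") revcomp(contigs[[contig]]) else contigs[[contig]]
  }
  start_node <- function(i) {
    s <- cread_seq(ocrs[[i]], raws)
    a <- ocrs[[i]]$anchors[1L, ]
    cf <- oc_pos(a$orient, a$cp_first, clen[[a$contig]], k)
    if (extend_ends && cf > a$rp_first) {
      # terminal contig extension: the first anchor's contig reaches left
      # of the read; splice read prefix out at its first exact hit
      add_piece(substr(oriented_contig(a$contig, a$orient), 1L, cf),
                a$contig, "contig", 1L, cf, a$orient)
      add_piece(substr(s, a$rp_first + 1L, nchar(s)), bbpath$nodes[i],
                "read", a$rp_first + 1L, nchar(s), eff_orient(i))
      pos_prev <<- cur_len - nchar(s)
    } else {
      add_piece(s, bbpath$nodes[i], "read", 1L, nchar(s), eff_orient(i))
      pos_prev <<- cur_len - nchar(s)
    }
    nchar(s)
  }
  end_extend <- function() {
    # mirror extension at the right end of the current draft
    if (!extend_ends || cur_len == 0L) return(invisible())
    a <- ocrs[[prev_i]]$anchors
    a <- a[nrow(a), ]
    cl1 <- clen[[a$contig]]
    ce <- oc_pos(a$orient, a$cp_last, cl1, k)
    node_len <- ocrs[[prev_i]]$len
    if (cl1 - ce > node_len - a$rp_last) {
      trim_to(pos_prev + a$rp_last + k)
      add_piece(substr(oriented_contig(a$contig, a$orient), ce + k + 1L, cl1),
                a$contig, "contig", ce + k + 1L, cl1, a$orient)
    }
    invisible()
  }
  pos_prev <- 0L  # draft offset (0-based) of the previous node's origin
  prev_len <- start_node(1L)
  prev_i <- 1L
  for (i in seq_len(n)[-1L]) {
    a <- ocrs[[prev_i]]$anchors
    b <- ocrs[[i]]$anchors
    sh <- merge(a, b, by = c("contig", "orient"), suffixes = c(".a", ".b"))
    S_b <- cread_seq(ocrs[[i]], raws)
    len_b <- nchar(S_b)
    if (nrow(sh) == 0L) {
      end_extend()
      flush_draft()
      prev_len <- start_node(i); prev_i <- i
      next
    }
    cl <- clen[sh$contig]
    cpa <- oc_pos(sh$orient, sh$cp.a, cl, k)
    cpb <- oc_pos(sh$orient, sh$cp.b, cl, k)
    delta <- round(stats::median(sh$rp.a - cpa - sh$rp.b + cpb))
    len_a <- ocrs[[prev_i]]$len
    if (!is.finite(delta) || delta < 0L) {  # irreconcilable junction
      end_extend()
      flush_draft()
      prev_len <- start_node(i); prev_i <- i
      next
    }
    overlap <- len_a - delta
    if (overlap >= len_b) next  # stray containment: skip the node
    if (overlap >= 0L) {
      pos_b <- cur_len - overlap
      add_piece(substr(S_b, overlap + 1L, len_b), bbpath$nodes[i], "read",
                overlap + 1L, len_b, eff_orient(i))
    } else {
      # long-read coverage gap: splice the bridging contig between the two
      # reads' outermost exact hits
      j <- which.max(sh$support.a + sh$support.b)
      ca <- oc_pos(sh$orient[j], sh$cp_last.a[j], cl[j], k)
      cb <- oc_pos(sh$orient[j], sh$cp_first.b[j], cl[j], k)
      if (cb >= ca + k) {
        trim_to(pos_prev + sh$rp_last.a[j] + k)
        cseq <- contigs[[sh$contig[j]]]
        if (sh$orient[j] == "-") cseq <- revcomp(cseq)
        add_piece(substr(cseq, ca + k + 1L, cb), sh$contig[j], "contig",
                  ca + k + 1L, cb, sh$orient[j])
        pos_b <- cur_len - sh$rp_first.b[j]
        add_piece(substr(S_b, sh$rp_first.b[j] + 1L, len_b),
                  bbpath$nodes[i], "read", sh$rp_first.b[j] + 1L, len_b,
                  eff_orient(i))
      } else {  # contradictory contig coordinates: butt join
        pos_b <- cur_len
        add_piece(S_b, bbpath$nodes[i], "read", 1L, len_b, eff_orient(i))
      }
    }
    pos_prev <- pos_b; prev_len <- len_b; prev_i <- i
  }
  end_extend()
  flush_draft()
  drafts
}

#' @export
print.draft <- function(x, ...) {
  cat(sprintf("draft %s: %d bp over %d segments\n", x$id, nchar(x$seq),
              nrow(x$segmap)))
  invisible(x)
}

#' Collect the read pool related to a backbone path
#'
#' A raw read belongs to the pool when its compressed form shares at least
#' one contig identifier with the path's nodes; members of the path nodes
#' (collapsed twins) and recorded contained reads are added explicitly.
#'
#' @param bbpath one element of [linear_paths()] output.
#' @param nodes named list of graph `cread`s.
#' @param all_crs the full compressed-read collection (pre-cleaning,
#'   uncollapsed) used for identifier lookup.
#' @param contained optional containment data.frame from
#'   [remove_contained()], plus the collapsed set `collapsed` to resolve
#'   member reads.
#' @param collapsed optional named list of collapsed `cread`s.
#' @return sorted character vector of raw read ids.
#' @export
collect_reads <- function(bbpath, nodes, all_crs, contained = NULL,
                          collapsed = NULL) {
  path_contigs <- unique(unlist(lapply(bbpath$nodes, function(id)
    nodes[[id]]$anchors$contig)))
  pool <- unlist(lapply(all_crs, function(cr)
    if (any(cr$anchors$contig %in% path_contigs)) cr$raw_id else NULL))
  pool <- c(pool, unlist(lapply(bbpath$nodes, function(id)
    nodes[[id]]$members)))
  if (!is.null(contained) && nrow(contained) && !is.null(collapsed)) {
    owned <- contained$read[contained$container %in% bbpath$nodes]
    pool <- c(pool, unlist(lapply(collapsed[intersect(owned, names(collapsed))],
                                  function(cr) cr$members)))
  }
  sort(unique(pool))
}

#' Seed index over a draft backbone
#'
#' Positions of the k-mers occurring exactly once in the draft; the seed
#' vocabulary for read-to-backbone alignment.
#'
#' @param seq draft sequence.
#' @param k seed k-mer size (default 11; small enough that 15 percent
#'   error still leaves a seed every few tens of bases).
#' @return list `k`, `kmer`, `pos` (0-based starts).
#' @export
draft_seed_index <- function(seq, k = 11L) {
  kms <- seq_kmers(seq, k)
  dup <- duplicated(kms) | duplicated(kms, fromLast = TRUE)
  list(k = as.integer(k), kmer = kms[!dup], pos = which(!dup) - 1L)
}

# Longest strictly-increasing subsequence (patience sorting) over `v`;
# returns the element indices of one optimal chain (deterministic).
lis_indices <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  tails_v <- numeric(0)   # smallest tail value per chain length
  tails_i <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(v[i] - 0.5, tails_v) + 1L  # first tail >= v[i]
    prev[i] <- if (j > 1L) tails_i[j - 1L] else 0L
    tails_v[j] <- v[i]
    tails_i[j] <- i
  }
  out <- integer(length(tails_i))
  cur <- tails_i[length(tails_i)]
  for (j in rev(seq_along(out))) { out[j] <- cur; cur <- prev[cur] }
  out
}

#' Align a raw read to a draft backbone
#'
#' Seed-chain-extend: unique draft k-mers shared with the read are banded
#' around the dominant diagonal, chained by longest increasing subsequence,
#' split at oversized gaps (keeping the longest chain), and the seed gaps
#' are closed by global alignment. Both strands are tried; the better one
#' is kept. Alignments below the identity floor are discarded.
#'
#' @param read_seq raw read sequence.
#' @param dindex a [draft_seed_index()] over the draft.
#' @param draft_seq the draft sequence.
#' @param read_id identifier carried in the result.
#' @param min_identity identity floor (default 0.5: two 15-percent-error
#'   sequences agree at roughly 0.72).
#' @param max_gap maximum seed gap bridged by alignment (default 2000).
#' @param band diagonal half-band width for seed filtering (default 500).
#' @return alignment object (list with `read`, `strand`, `q`, `t` 0-based
#'   aligned column coordinates, `nmatch`, `ncol`, `identity`, `seq` = the
#'   oriented read sequence) or `NULL`.
#' @export
align_read_to_backbone <- function(read_seq, dindex, draft_seq,
                                   read_id = "read", min_identity = 0.5,
                                   max_gap = 2000L, band = 500L) {
  best <- NULL
  for (strand in c("+", "-")) {
    rs <- if (strand == "-") revcomp(read_seq) else read_seq
    if (nchar(rs) < dindex$k) next
    kms <- seq_kmers(rs, dindex$k)
    m <- match(kms, dindex$kmer)
    hit <- which(!is.na(m))
    if (length(hit) < 3L) next
    rp <- hit - 1L
    dp <- dindex$pos[m[hit]]
    diag <- dp - rp
    bins <- round(diag / band)
    tb <- table(bins)
    mb <- as.numeric(names(tb)[which.max(tb)])
    keep <- abs(diag - mb * band) <= 2L * band
    rp <- rp[keep]; dp <- dp[keep]
    if (length(rp) < 3L) next
    o <- order(rp)
    rp <- rp[o]; dp <- dp[o]
    ch <- lis_indices(dp)
    rp <- rp[ch]; dp <- dp[ch]
    # split chains at oversized gaps, keep the longest run
    if (length(rp) >= 2L) {
      big <- which(diff(rp) > max_gap | diff(dp) > max_gap)
      grp <- cumsum(c(0L, seq_along(rp)[-1L] %in% (big + 1L)))
      runs <- split(seq_along(rp), grp)
      r <- runs[[which.max(lengths(runs))]]
      rp <- rp[r]; dp <- dp[r]
    }
    if (length(rp) < 3L) next
    al <- cpp_chain_fill(rs, draft_seq, rp, dp, dindex$k,
                         max_gap = max_gap + 1000L)
    if (al$ncol == 0) next
    identity <- al$nmatch / al$ncol
    if (is.null(best) || al$nmatch > best$nmatch) {
      best <- list(read = read_id, strand = strand, q = al$q, t = al$t,
                   nmatch = al$nmatch, ncol = al$ncol, identity = identity,
                   seq = rs)
    }
  }
  if (is.null(best) || best$identity < min_identity) return(NULL)
  best
}

#' Sequence identity between two sequences
#'
#' Convenience wrapper: seed-chain alignment of `a` against `b` (both
#' strands) at seed size `k`; identity = matching bases / alignment
#' columns over the aligned region.
#'
#' @param a,b DNA strings.
#' @param k seed size (default 21; raise for near-identical sequences).
#' @param min_identity floor passed through (default 0).
#' @return list with `identity`, `nmatch`, `ncol`, `strand`, `t_range`
#'   (1-based aligned interval on `b`), or `NULL` when no alignment found.
#' @export
align_sequences <- function(a, b, k = 21L, min_identity = 0) {
  di <- draft_seed_index(b, k)
  al <- align_read_to_backbone(a, di, b, read_id = "a",
                               min_identity = min_identity, max_gap = 5000L)
  if (is.null(al)) return(NULL)
  list(identity = al$identity, nmatch = al$nmatch, ncol = al$ncol,
       strand = al$strand, t_range = c(min(al$t) + 1L, max(al$t) + 1L),
       q_range = c(min(al$q) + 1L, max(al$q) + 1L))
}

#' Sparse k-mer graph consensus (heaviest reweighted path)
#'
#' Builds a sparse k-mer graph over the draft: one node every `g` bases
#' (node identity = position plus the local `k_c`-mer), edges carrying the
#' observed inter-node sequence. The draft threads the graph with weight 0
#' (1 on contig-patched segments: contig bases count as coverage-1
#' evidence); every aligned read threads it adding +1 per edge (or its
#' quality weight). Edges are then reweighted `w' = w - t * cov(position)`
#' where `cov` is the number of reads spanning the position, and the
#' consensus is the heaviest source-to-sink path, read out through the
#' edge sequences.
#'
#' @param draft_seq draft sequence.
#' @param alignments list of alignment objects from
#'   [align_read_to_backbone()]; entries may carry a `weight` (default 1).
#' @param k_c consensus k-mer size (default 2).
#' @param g node spacing in bases (default 2; requires `k_c <= g`... equal
#'   by default).
#' @param t reweighting factor in (0,1) (default 0.2).
#' @param contig_mask optional logical vector over draft positions, TRUE
#'   where the base came from a contig patch.
#' @return consensus DNA string.
#' @export
sparc_consensus <- function(draft_seq, alignments, k_c = 2L, g = 2L,
                            t = 0.2, contig_mask = NULL) {
  L <- nchar(draft_seq)
  if (L < k_c + g) return(draft_seq)
  if (length(alignments) == 0L) {
    warning("empty alignment pool; returning the draft unchanged")
    return(draft_seq)
  }
  P <- seq.int(0L, L - k_c, by = g)
  nl <- length(P)
  node_km_draft <- substring(draft_seq, P + 1L, P + k_c)
  draft_w <- if (is.null(contig_mask)) rep(0, nl - 1L) else
    as.numeric(contig_mask[P[-nl] + 1L])
  tabs <- vector("list", length(alignments) + 1L)
  tabs[[1L]] <- data.table::data.table(
    layer = seq_len(nl - 1L), fk = node_km_draft[-nl],
    tk = node_km_draft[-1L],
    seq = substring(draft_seq, P[-nl] + 1L, P[-1L]), w = draft_w)
  cov <- numeric(nl)
  for (ai in seq_along(alignments)) {
    al <- alignments[[ai]]
    qv <- al$q; tv <- al$t
    l0 <- which(P >= tv[1L])[1L]
    l1 <- nl - which(rev(P) + g <= tv[length(tv)])[1L] + 1L
    if (is.na(l0) || is.na(l1) || l1 <= l0) next
    lp <- P[l0:l1]
    r <- qv[findInterval(lp - 0.5, tv) + 1L]
    rl <- nchar(al$seq)
    valid <- r + k_c <= rl
    fk <- substring(al$seq, r + 1L, r + k_c)
    nlp <- length(lp)
    okpair <- valid[-nlp] & valid[-1L]
    if (!any(okpair)) next
    wgt <- if (is.null(al$weight)) 1 else al$weight
    tabs[[ai + 1L]] <- data.table::data.table(
      layer = (l0:(l1 - 1L))[okpair], fk = fk[-nlp][okpair],
      tk = fk[-1L][okpair],
      seq = substring(al$seq, r[-nlp] + 1L, r[-1L])[okpair], w = wgt)
    cov[l0:(l1 - 1L)] <- cov[l0:(l1 - 1L)] + 1
  }
  edt <- data.table::rbindlist(tabs[!vapply(tabs, is.null, logical(1))])
  edges <- edt[, .(w = sum(w)), by = .(layer, fk, tk, seq)]
  edges[, wp := w - t * cov[layer]]
  ndt <- unique(data.table::rbindlist(list(
    edges[, .(layer = layer, km = fk)],
    edges[, .(layer = layer + 1L, km = tk)])))
  data.table::setorder(ndt, layer, km)
  ndt[, id := .I]
  edges[, layer2 := layer + 1L]
  edges[ndt, on = c(layer = "layer", fk = "km"), from := i.id]
  edges[ndt, on = c(layer2 = "layer", tk = "km"), to := i.id]
  data.table::setorder(edges, layer, from, to, seq)
  pe <- cpp_heaviest_path(ndt$layer - 1L, edges$from, edges$to, edges$wp)
  if (length(pe) == 0L) return(draft_seq)
  last_tk <- edges$tk[pe[length(pe)]]
  tail_seq <- if (P[nl] + k_c < L)
    substr(draft_seq, P[nl] + k_c + 1L, L) else ""
  paste0(paste(edges$seq[pe], collapse = ""), last_tk, tail_seq)
}

#' Polish one draft backbone with its read pool
#'
#' @param draft a `draft` object from [layout_backbone()].
#' @param pool named character vector of raw read sequences.
#' @param k_seed aligner seed size (default 11).
#' @param min_identity aligner identity floor (default 0.5).
#' @param k_c,g,t consensus parameters (see [sparc_consensus()]).
#' @param rounds align-and-polish iterations (default 2: the second round
#'   aligns reads against the much more accurate round-1 consensus, which
#'   sharpens the votes; further rounds change little).
#' @return list with `seq` (polished sequence), `n_aligned` (last round),
#'   and `alignments` (last round).
#' @export
polish_backbone <- function(draft, pool, k_seed = 11L, min_identity = 0.5,
                            k_c = 2L, g = 2L, t = 0.2, rounds = 2L) {
  cur <- draft$seq
  mask <- rep(FALSE, nchar(cur))
  sm <- draft$segmap
  for (i in which(sm$type == "contig")) mask[sm$bb_start[i]:sm$bb_end[i]] <- TRUE
  alns <- list()
  for (r in seq_len(max(1L, rounds))) {
    di <- draft_seed_index(cur, k_seed)
    alns <- list()
    for (id in names(pool)) {
      al <- align_read_to_backbone(pool[[id]], di, cur, read_id = id,
                                   min_identity = min_identity)
      if (!is.null(al)) alns[[id]] <- al
    }
    if (length(alns) == 0L) break
    cur <- sparc_consensus(cur, alns, k_c = k_c, g = g, t = t,
                           contig_mask = if (r == 1L) mask else NULL)
    mask <- NULL
  }
  list(seq = cur, n_aligned = length(alns), alignments = alns)
}

#' Import read-to-backbone alignments from a SAM file
#'
#' Minimal SAM parser for plugging an external aligner into the consensus
#' stage: M/=/X CIGAR columns become aligned pairs, I/S consume the read,
#' D/N consume the backbone. Secondary/unmapped records are skipped.
#'
#' @param path SAM file path.
#' @return list of alignment objects compatible with [sparc_consensus()].
#' @export
read_sam_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L || bitwAnd(flag, 256L) > 0L) next
    seq <- f[10]
    tpos <- as.integer(f[4]) - 1L
    ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
    lenv <- as.integer(sub("[A-Z=]$", "", ops))
    opv <- sub("^[0-9]+", "", ops)
    q <- integer(0); tt <- integer(0)
    qpos <- 0L
    for (i in seq_along(opv)) {
      n <- lenv[i]
      if (opv[i] %in% c("M", "=", "X")) {
        q <- c(q, qpos + seq_len(n) - 1L)
        tt <- c(tt, tpos + seq_len(n) - 1L)
        qpos <- qpos + n; tpos <- tpos + n
      } else if (opv[i] %in% c("I", "S")) qpos <- qpos + n
      else if (opv[i] %in% c("D", "N")) tpos <- tpos + n
    }
    if (length(q) == 0L) next
    # SAM SEQ is already in backbone orientation; match count not recoverable
    out[[f[1]]] <- list(read = f[1],
                        strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
                        q = q, t = tt, nmatch = NA_real_, ncol = length(q),
                        identity = NA_real_, seq = seq)
  }
  out
}
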