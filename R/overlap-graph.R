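# Best overlap graph on cleaned, collapsed compressed reads. Round 1 drops
# contained reads; round 2 keeps, per node end, the highest-scoring dovetail
# overlaps. Nodes are bidirected: each read has a B (begin) and E (end) side
# in its canonical frame, and an overlap consumes one side of each read.

#' Round 1: remove contained compressed reads
#'
#' A read whose alignment to another read covers all of its own anchors (in
#' either orientation) is contained and removed; e.g. `{a, b}` is removed
#' when `{a, b, c}` is present. Mutual containments (identical forms that
#' escaped collapsing) keep the lexicographically smaller id. Containment
#' membership is recorded so contained reads can rejoin their container's
#' backbone read pool at consensus.
#'
#' @param crs named list of cleaned, collapsed `cread`s.
#' @param scheme a [score_scheme()].
#' @param min_overlap_score gate below which a containment is not trusted.
#' @param min_shared candidate gate.
#' @return list with `survivors` (named list) and `contained` (data.frame:
#'   read, container).
#' @export
remove_contained <- function(crs, scheme,
                             min_overlap_score = scheme$min_overlap_score,
                             min_shared = 1L) {
  idx <- build_inverted_index(crs)
  ids <- sort(names(crs))
  gone <- character(0)
  container <- character(0)
  for (a in ids) {
    for (b in candidates(crs[[a]], idx, min_shared = min_shared)) {
      if (b <= a) next
      o <- align_compressed(crs[[a]], crs[[b]], scheme,
                            min_overlap_score = min_overlap_score)
      if (o$relation == "contained_a_in_b") {
        if (o$mutual) { gone <- c(gone, b); container <- c(container, a) }
        else { gone <- c(gone, a); container <- c(container, b) }
      } else if (o$relation == "contained_b_in_a") {
        gone <- c(gone, b); container <- c(container, a)
      }
    }
  }
  keep <- !duplicated(gone)
  contained <- data.frame(read = gone[keep], container = container[keep],
                          stringsAsFactors = FALSE)
  list(survivors = crs[setdiff(ids, gone)], contained = contained)
}

# Map a dovetail overlap to the node sides it consumes.
# suffix_prefix/same:      a.E - b.B    prefix_suffix/same:     a.B - b.E
# suffix_prefix/opposite:  a.E - b.E    prefix_suffix/opposite: a.B - b.B
overlap_ends <- function(relation, orientation) {
  if (relation == "suffix_prefix") {
    c("E", if (orientation == "same") "B" else "E")
  } else {
    c("B", if (orientation == "same") "E" else "B")
  }
}

#' Round 2: build the best overlap graph
#'
#' All dovetail (suffix-prefix) overlaps among the survivors scoring at
#' least `min_overlap_score` are computed; per node side the single best is
#' identified (ties broken by matched identifier count, then partner id).
#' An edge is materialized when it is the best for at least one of its two
#' node sides and within `mutual_frac` of the best on the other: pure
#' mutual-best fragments low-coverage data, pure one-sided-best creates
#' branch conflicts.
#'
#' @param survivors named list of `cread`s (round 1 output).
#' @param scheme a [score_scheme()].
#' @param min_overlap_score minimum dovetail score.
#' @param mutual_frac slack on the non-best side (default 0.95).
#' @param min_shared candidate gate.
#' @return object of class `overlap_graph`: list with `nodes` (named list of
#'   `cread`s), `edges` (data.frame: a, a_end, b, b_end, score, matched_ids,
#'   orientation, oid), and `overlaps` (list of `olc_overlap` indexed by
#'   `oid`).
#' @export
best_overlaps <- function(survivors, scheme,
                          min_overlap_score = scheme$min_overlap_score,
                          mutual_frac = 0.95, min_shared = 1L) {
  idx <- build_inverted_index(survivors)
  ids <- sort(names(survivors))
  rows <- list(); ovls <- list()
  for (a in ids) {
    for (b in candidates(survivors[[a]], idx, min_shared = min_shared)) {
      if (b <= a) next
      o <- align_compressed(survivors[[a]], survivors[[b]], scheme,
                            min_overlap_score = min_overlap_score)
      if (!o$relation %in% c("suffix_prefix", "prefix_suffix")) next
      ends <- overlap_ends(o$relation, o$orientation)
      ovls[[length(ovls) + 1L]] <- o
      rows[[length(rows) + 1L]] <- data.frame(
        a = a, a_end = ends[1], b = b, b_end = ends[2], score = o$score,
        matched_ids = o$matched_ids, orientation = o$orientation,
        oid = length(ovls), stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(0), a_end = character(0), b = character(0),
               b_end = character(0), score = numeric(0),
               matched_ids = integer(0), orientation = character(0),
               oid = integer(0), stringsAsFactors = FALSE)
  if (nrow(edges)) {
    # per node side, index of the best incident edge
    long <- rbind(
      data.frame(key = paste0(edges$a, "/", edges$a_end), other = edges$b,
                 e = seq_len(nrow(edges)), score = edges$score,
                 matched = edges$matched_ids),
      data.frame(key = paste0(edges$b, "/", edges$b_end), other = edges$a,
                 e = seq_len(nrow(edges)), score = edges$score,
                 matched = edges$matched_ids))
    long <- long[order(long$key, -long$score, -long$matched, long$other), ]
    best_e <- tapply(long$e, long$key, `[`, 1L)
    best_s <- tapply(long$score, long$key, `[`, 1L)
    ka <- paste0(edges$a, "/", edges$a_end)
    kb <- paste0(edges$b, "/", edges$b_end)
    is_best_a <- best_e[ka] == seq_len(nrow(edges))
    is_best_b <- best_e[kb] == seq_len(nrow(edges))
    keep <- (is_best_a & edges$score >= mutual_frac * best_s[kb]) |
      (is_best_b & edges$score >= mutual_frac * best_s[ka])
    edges <- edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = survivors[ids], edges = edges, overlaps = ovls),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat("overlap graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

# degree of every node side present in the edge table
end_degrees <- function(g) {
  keys <- c(paste0(g$edges$a, "/", g$edges$a_end),
            paste0(g$edges$b, "/", g$edges$b_end))
  table(keys)
}

end_degree <- function(deg, node, end) {
  d <- deg[paste0(node, "/", end)]
  if (is.na(d)) 0L else as.integer(d)
}

# edges incident to a node side, as row indices
edges_at <- function(g, node, end) {
  which((g$edges$a == node & g$edges$a_end == end) |
          (g$edges$b == node & g$edges$b_end == end))
}

# follow edge row e from `node`: returns the partner node and entry end
edge_other <- function(g, e, node) {
  if (g$edges$a[e] == node) c(g$edges$b[e], g$edges$b_end[e])
  else c(g$edges$a[e], g$edges$a_end[e])
}

drop_nodes <- function(g, nodes) {
  g$nodes <- g$nodes[setdiff(names(g$nodes), nodes)]
  g$edges <- g$edges[!(g$edges$a %in% nodes | g$edges$b %in% nodes), ,
                     drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

# Walk a simple chain starting from `node` entered at `entry` end, i.e. the
# walk exits through the opposite side. Stops after at most `max_len` nodes
# or when the next step is ambiguous. Returns the node sequence, the end at
# which the walk stopped, and whether it stopped at a dead end.
walk_chain <- function(g, deg, node, entry, max_len) {
  chain <- node
  ent <- entry
  eids <- integer(0)
  repeat {
    exit <- if (ent == "B") "E" else "B"
    es <- edges_at(g, node, exit)
    if (length(es) == 0L)
      return(list(chain = chain, eids = eids, stopped = "dead"))
    if (length(es) > 1L)
      return(list(chain = chain, eids = eids, stopped = "branch"))
    if (length(chain) >= max_len)
      return(list(chain = chain, eids = eids, stopped = "maxlen"))
    nxt <- edge_other(g, es[1L], node)
    if (nxt[1] %in% chain)
      return(list(chain = chain, eids = eids, stopped = "cycle"))
    eids <- c(eids, es[1L])
    if (end_degree(deg, nxt[1], nxt[2]) > 1L)
      return(list(chain = chain, eids = eids, stopped = "merge", into = nxt))
    node <- nxt[1]; ent <- nxt[2]
    chain <- c(chain, node)
  }
}

#' Simplify the best overlap graph: clip tips, pop bubbles
#'
#' Tips are dead-end chains of at most `tip_len` nodes hanging off a branch;
#' they are removed. Bubbles are pairs of chains of at most `bubble_len`
#' nodes that diverge from one node side and reconverge at another; the side
#' with the lower total overlap score is removed. Applied to fixpoint.
#'
#' @param g an `overlap_graph`.
#' @param tip_len maximum tip length in nodes (default 3).
#' @param bubble_len maximum bubble branch length in nodes (default 5).
#' @return simplified `overlap_graph`.
#' @export
simplify_graph <- function(g, tip_len = 3L, bubble_len = 5L) {
  repeat {
    changed <- FALSE
    deg <- end_degrees(g)
    # --- tips: at every branch side, walk each arm; arms that dead-end
    # within tip_len nodes are tip candidates. Clip all candidates when a
    # longer/through arm exists, otherwise keep the best-scoring candidate
    # (two short dead-end arms meeting head-on must not erase each other).
    for (node in sort(names(g$nodes))) {
      if (!node %in% names(g$nodes)) next
      for (end in c("B", "E")) {
        es <- edges_at(g, node, end)
        if (length(es) < 2L) next
        arms <- lapply(es, function(e) {
          nxt <- edge_other(g, e, node)
          if (end_degree(deg, nxt[1], nxt[2]) > 1L)
            return(list(chain = character(0), stopped = "merge",
                        score = g$edges$score[e]))
          w <- walk_chain(g, deg, nxt[1], nxt[2], tip_len + 1L)
          w$score <- g$edges$score[e] + sum(g$edges$score[w$eids])
          w
        })
        is_tip <- vapply(arms, function(a)
          identical(a$stopped, "dead") && length(a$chain) <= tip_len,
          logical(1))
        if (!any(is_tip)) next
        drop_idx <- which(is_tip)
        if (all(is_tip)) {
          scores <- vapply(arms, `[[`, numeric(1), "score")
          drop_idx <- setdiff(drop_idx, which.max(scores))
        }
        if (!length(drop_idx)) next
        victims <- unique(unlist(lapply(arms[drop_idx], `[[`, "chain")))
        keepers <- unique(unlist(lapply(arms[-drop_idx], `[[`, "chain")))
        victims <- setdiff(victims, c(keepers, node))
        if (!length(victims)) next
        g <- drop_nodes(g, victims)
        deg <- end_degrees(g)
        changed <- TRUE
        break
      }
      if (changed) break
    }
    if (changed) next
    # --- bubbles: two branches from one side reconverging at one side
    deg <- end_degrees(g)
    for (node in sort(names(g$nodes))) {
      for (end in c("B", "E")) {
        es <- edges_at(g, node, end)
        if (length(es) != 2L) next
        arms <- lapply(es, function(e) {
          nxt <- edge_other(g, e, node)
          if (end_degree(deg, nxt[1], nxt[2]) > 1L)
            return(list(chain = character(0), into = nxt,
                        score = g$edges$score[e]))
          w <- walk_chain(g, deg, nxt[1], nxt[2], bubble_len)
          w$score <- g$edges$score[e] + sum(g$edges$score[w$eids])
          w
        })
        ok <- vapply(arms, function(a) !is.null(a$into), logical(1))
        if (!all(ok)) next
        into <- lapply(arms, function(a) a$into)
        if (!identical(into[[1]], into[[2]])) next
        if (into[[1]][1] == node) next
        if (length(intersect(arms[[1]]$chain, arms[[2]]$chain))) next
        loser <- if (arms[[1]]$score < arms[[2]]$score) 1L else 2L
        if (length(arms[[loser]]$chain) == 0L) {
          # parallel edges between the same sides: drop the weaker edge
          g$edges <- g$edges[-es[loser], , drop = FALSE]
          rownames(g$edges) <- NULL
        } else {
          g <- drop_nodes(g, arms[[loser]]$chain)
        }
        deg <- end_degrees(g)
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  g
}

#' Extract maximal linear paths (backbones) from the graph
#'
#' A path extends through a connection only when it is unambiguous on both
#' sides (each involved node side has exactly one incident edge). Branch
#' sides terminate paths and are flagged as junction breakpoints. Every node
#' lands in exactly one path; a fully circular chain is emitted once with a
#' circularity flag. Output order and orientation are deterministic.
#'
#' @param g an `overlap_graph`.
#' @return list of backbone paths: each a list with `nodes`, `orients`
#'   (`+` = the node's canonical frame points along the path), `edges` (oids
#'   of consecutive overlaps), `circular`, and `breaks` (logical left/right
#'   junction flags).
#' @export
linear_paths <- function(g) {
  deg <- end_degrees(g)
  unvisited <- sort(names(g$nodes))
  link_ok <- function(node, exit) {
    es <- edges_at(g, node, exit)
    if (length(es) != 1L) return(NULL)
    nxt <- edge_other(g, es[1L], node)
    if (end_degree(deg, nxt[1], nxt[2]) != 1L) return(NULL)
    list(e = es[1L], node = nxt[1], entry = nxt[2])
  }
  paths <- list()
  emit <- function(nodes, orients, eids, circular, breaks) {
    paths[[length(paths) + 1L]] <<- list(
      nodes = nodes, orients = orients, edges = eids,
      circular = circular, breaks = breaks)
    unvisited <<- setdiff(unvisited, nodes)
  }
  # termini first: a node side that cannot be linked through starts a path
  for (node in sort(names(g$nodes))) {
    if (!node %in% unvisited) next
    start_end <- NULL
    for (end in c("B", "E")) {
      back <- link_ok(node, end)
      if (is.null(back) || !back$node %in% unvisited) {
        start_end <- end; break
      }
    }
    if (is.null(start_end)) next  # interior of a chain or cycle
    orient1 <- if (start_end == "B") "+" else "-"
    left_break <- end_degree(deg, node, start_end) > 0L
    nodes <- node; orients <- orient1; eids <- integer(0)
    cur <- node; entry <- start_end
    repeat {
      exit <- if (entry == "B") "E" else "B"
      nx <- link_ok(cur, exit)
      if (is.null(nx) || !nx$node %in% setdiff(unvisited, nodes)) break
      eids <- c(eids, g$edges$oid[nx$e])
      cur <- nx$node; entry <- nx$entry
      nodes <- c(nodes, cur)
      orients <- c(orients, if (entry == "B") "+" else "-")
    }
    exit <- if (entry == "B") "E" else "B"
    right_break <- end_degree(deg, cur, exit) > 0L
    emit(nodes, orients, eids, FALSE, c(left_break, right_break))
  }
  # leftovers are cycles: start at the smallest id, walk once around
  while (length(unvisited)) {
    node <- unvisited[1L]
    nodes <- node; orients <- "+"; eids <- integer(0)
    cur <- node; entry <- "B"
    repeat {
      exit <- if (entry == "B") "E" else "B"
      nx <- link_ok(cur, exit)
      if (is.null(nx) || nx$node == node) {
        if (!is.null(nx)) eids <- c(eids, g$edges$oid[nx$e])
        break
      }
      eids <- c(eids, g$edges$oid[nx$e])
      cur <- nx$node; entry <- nx$entry
      nodes <- c(nodes, cur)
      orients <- c(orients, if (entry == "B") "+" else "-")
    }
    emit(nodes, orients, eids, TRUE, c(FALSE, FALSE))
  }
  paths
}

#' Export the overlap graph as GFA 1.0
#'
#' Segments are compressed reads (sequence `*`, `LN` = raw interval
#' length); links are the kept best overlaps.
#'
#' @param g an `overlap_graph`.
#' @param path output path.
#' @export
write_gfa <- function(g, path) {
  seg <- vapply(g$nodes, function(cr)
    sprintf("S\t%s\t*\tLN:i:%d", cr$id, cr$len), character(1))
  lnk <- character(0)
  if (nrow(g$edges)) {
    lnk <- vapply(seq_len(nrow(g$edges)), function(i) {
      e <- g$edges[i, ]
      sprintf("L\t%s\t%s\t%s\t%s\t*", e$a,
              if (e$a_end == "E") "+" else "-", e$b,
              if (e$b_end == "B") "+" else "-")
    }, character(1))
  }
  writeLines(c("H\tVN:Z:1.0", seg, lnk), path)
  invisible(path)
}

#' Write backbone paths as TSV
#'
#' @param paths result of [linear_paths()].
#' @param path output path.
#' @export
write_backbones <- function(paths, path) {
  rows <- vapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    paste(sprintf("backbone_%d", i),
          paste(paste0(p$nodes, p$orients), collapse = " "),
          p$circular, sep = "\t")
  }, character(1))
  writeLines(c("path\tnodes\tcircular", rows), path)
  invisible(path)
}
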