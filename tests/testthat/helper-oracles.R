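# Independent oracles. Each re-derives the quantity it checks by a
# different route than the implementation: a textbook full-matrix DP for
# Smith-Waterman scores, exhaustive monotone-matching enumeration for the
# constrained alignment optima, quadratic scans for index structures, and
# recursive path enumeration for the consensus graph.

oracle_match_matrix <- function(a, b, scheme) {
  n <- nrow(a); m <- nrow(b)
  s <- matrix(scheme$mismatch, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (a$contig[i] == b$contig[j] && a$orient[i] == b$orient[j]) {
      s[i, j] <- if (scheme$mode == "by_contig_length")
        scheme$contig_len[[a$contig[i]]] else min(a$support[i], b$support[j])
    }
  }
  s
}

# textbook O(nm) local Smith-Waterman, score only
oracle_sw_score <- function(a, b, scheme) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(0)
  s <- oracle_match_matrix(a, b, scheme)
  H <- matrix(0, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m) {
    H[i + 1, j + 1] <- max(0,
                           H[i, j] + s[i, j],
                           H[i, j + 1] + scheme$gap,
                           H[i + 1, j] + scheme$gap)
  }
  max(H)
}

# anchor-table reverse complement, written out independently
oracle_rc_anchors <- function(a) {
  if (nrow(a) == 0) return(a)
  out <- a[nrow(a):1, , drop = FALSE]
  out$orient <- ifelse(out$orient == "+", "-", "+")
  rownames(out) <- NULL
  out
}

oracle_sw_best2 <- function(a, b, scheme) {
  max(oracle_sw_score(a, b, scheme),
      oracle_sw_score(a, oracle_rc_anchors(b), scheme))
}

# exhaustive enumeration over monotone matchings: the local optimum and the
# four constrained optima (one side fully consumed; dovetails). Feasible
# for anchor counts up to ~7.
oracle_enum_scores <- function(a, b, scheme) {
  n <- nrow(a); m <- nrow(b)
  out <- list(S = 0, ca = -Inf, cb = -Inf, sp = -Inf, ps = -Inf)
  if (n == 0 || m == 0) return(out)
  s <- oracle_match_matrix(a, b, scheme)
  gp <- scheme$gap
  for (k in 1:min(n, m)) {
    rows <- utils::combn(n, k)
    cols <- utils::combn(m, k)
    for (ri in seq_len(ncol(rows))) for (ci in seq_len(ncol(cols))) {
      R <- rows[, ri]; C <- cols[, ci]
      base <- sum(s[cbind(R, C)])
      if (k > 1) base <- base + gp * sum(diff(R) - 1 + diff(C) - 1)
      out$S <- max(out$S, base)
      out$ca <- max(out$ca, base + gp * ((R[1] - 1) + (n - R[k])))
      out$cb <- max(out$cb, base + gp * ((C[1] - 1) + (m - C[k])))
      out$sp <- max(out$sp, base + gp * ((n - R[k]) + (C[1] - 1)))
      out$ps <- max(out$ps, base + gp * ((R[1] - 1) + (m - C[k])))
    }
  }
  out
}

# containment decision replicated from first principles on top of the
# textbook DP scores (orientation picked by score, ties prefer same)
oracle_contained_in <- function(x, y, scheme, min_score) {
  sc_same <- oracle_enum_dp(x$anchors, y$anchors, scheme)
  sc_opp <- oracle_enum_dp(x$anchors, oracle_rc_anchors(y$anchors), scheme)
  sc <- if (sc_opp$S > sc_same$S) sc_opp else sc_same
  sc$S >= min_score && sc$ca >= sc$S - 1e-9
}

# DP version of the constrained optima (same quantities as
# oracle_enum_scores, O(nm); validated against the enumeration in the
# tests, then used for the 300-read containment oracle)
oracle_enum_dp <- function(a, b, scheme) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(list(S = 0, ca = -Inf, cb = -Inf,
                                    sp = -Inf, ps = -Inf))
  s <- oracle_match_matrix(a, b, scheme)
  gp <- scheme$gap
  run <- function(ia, ib, fin) {
    H <- matrix(-Inf, n + 1, m + 1)
    H[1, ] <- c(0, ib); H[, 1] <- c(0, ia)
    for (i in 1:n) for (j in 1:m) {
      H[i + 1, j + 1] <- max(H[i, j] + s[i, j], H[i, j + 1] + gp,
                             H[i + 1, j] + gp)
    }
    fin(H)
  }
  ga <- gp * (1:n); gb <- gp * (1:m); za <- rep(0, n); zb <- rep(0, m)
  list(S = oracle_sw_score(a, b, scheme),
       ca = run(ga, zb, function(H) max(H[n + 1, ])),
       cb = run(za, gb, function(H) max(H[, m + 1])),
       sp = run(za, gb, function(H) max(H[n + 1, ])),
       ps = run(ga, zb, function(H) max(H[, m + 1])))
}

# all source-to-sink paths of a layered DAG by depth-first enumeration;
# returns the best achievable total weight
oracle_best_path_weight <- function(node_layer, efrom, eto, ew) {
  nl <- max(node_layer)
  out_edges <- split(seq_along(efrom), efrom)
  best <- -Inf
  walk <- function(v, acc) {
    if (node_layer[v] == nl) {
      best <<- max(best, acc)
      return(invisible())
    }
    es <- out_edges[[as.character(v)]]
    if (is.null(es)) return(invisible())
    for (e in es) walk(eto[e], acc + ew[e])
  }
  for (v in which(node_layer == 0)) walk(v, 0)
  best
}
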