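make_set <- function(...) {
  crs <- list(...)
  names(crs) <- vapply(crs, function(cr) cr$id, character(1))
  crs
}

test_that("pileup counts per-anchor neighbour support", {
  sch <- toy_scheme(as.character(1:9))
  tgt <- make_cread(c("1", "2", "3"), c("+", "+", "+"), id = "t")
  n1 <- make_cread(c("1", "2"), c("+", "+"), id = "n1")
  n2 <- make_cread(c("2", "3"), c("+", "+"), id = "n2")
  crs <- make_set(tgt, n1, n2)
  idx <- build_inverted_index(crs)
  p <- build_pileup(tgt, crs, idx, sch)
  expect_equal(p$counts, c(1L, 2L, 1L))
  # no candidates -> empty supports, zero counts
  lone <- make_cread(c("9"), "+", id = "lone")
  crs2 <- make_set(lone, n1)
  p2 <- build_pileup(lone, crs2, build_inverted_index(crs2), sch)
  expect_length(p2$supports, 0L)
  expect_equal(p2$counts, 0L)
  # counts recomputable from each support's matched positions
  tally <- integer(3)
  for (o in p$supports) tally[o$matched_a] <- tally[o$matched_a] + 1L
  expect_equal(tally, p$counts)
})

test_that("spurious anchors are removed at the confirmation threshold", {
  sch <- toy_scheme(as.character(1:9))
  # Fig-2-style case: first anchor appears only on the target itself
  tgt <- make_cread(c("7", "2", "3"), c("+", "+", "+"), id = "t")
  n1 <- make_cread(c("2", "3"), c("+", "+"), id = "n1")
  n2 <- make_cread(c("2", "3", "4"), c("+", "+", "+"), id = "n2")
  n3 <- make_cread(c("1", "2", "3"), c("+", "+", "+"), id = "n3")
  crs <- make_set(tgt, n1, n2, n3)
  p <- build_pileup(tgt, crs, build_inverted_index(crs), sch)
  expect_equal(p$counts, c(0L, 3L, 3L))
  cl <- remove_spurious_anchors(p, min_confirm = 1L)
  expect_identical(cl$anchors$contig, c("2", "3"))
  # min_confirm = 1 keeps everything that has any support
  p2 <- build_pileup(n1, crs, build_inverted_index(crs), sch)
  expect_identical(remove_spurious_anchors(p2, 1L)$anchors$contig,
                   n1$anchors$contig)
  # losing every anchor yields the empty read
  lone <- make_cread("9", "+", id = "lone")
  crs2 <- make_set(lone, n1)
  p3 <- build_pileup(lone, crs2, build_inverted_index(crs2), sch)
  expect_equal(n_anchors(remove_spurious_anchors(p3, 1L)), 0L)
})

test_that("chimera detection splits at unsupported junctions only", {
  sch <- toy_scheme(as.character(1:9))
  tgt <- make_cread(c("1", "2", "7", "8"), c("+", "+", "+", "+"), id = "t")
  l <- make_cread(c("1", "2"), c("+", "+"), id = "l")
  r <- make_cread(c("7", "8"), c("+", "+"), id = "r")
  crs <- make_set(tgt, l, r)
  p <- build_pileup(tgt, crs, build_inverted_index(crs), sch)
  call <- detect_chimera(p)
  expect_identical(call$verdict, "split")
  expect_equal(call$breakpoints, 2L)
  expect_length(call$fragments, 2L)
  expect_identical(call$fragments[[1]]$anchors$contig, c("1", "2"))
  expect_identical(call$fragments[[2]]$anchors$contig, c("7", "8"))
  # a neighbour spanning the junction adjacently vetoes the breakpoint
  span <- make_cread(c("2", "7"), c("+", "+"), id = "s")
  crs2 <- make_set(tgt, l, r, span)
  p2 <- build_pileup(tgt, crs2, build_inverted_index(crs2), sch)
  expect_identical(detect_chimera(p2)$verdict, "clean")
  # reads with < 2 anchors are trivially clean
  one <- make_cread("1", "+", id = "one")
  p3 <- build_pileup(one, make_set(one), build_inverted_index(make_set(one)), sch)
  expect_identical(detect_chimera(p3)$verdict, "clean")
})

test_that("fragment slicing keeps raw coordinates consistent", {
  sch <- toy_scheme(as.character(1:9))
  tgt <- make_cread(c("1", "2", "7", "8"), c("+", "+", "+", "+"), id = "t")
  crs <- make_set(tgt, make_cread(c("1", "2"), c("+", "+"), id = "l"),
                  make_cread(c("7", "8"), c("+", "+"), id = "r"))
  p <- build_pileup(tgt, crs, build_inverted_index(crs), sch)
  call <- detect_chimera(p)
  f1 <- call$fragments[[1]]; f2 <- call$fragments[[2]]
  expect_equal(f1$raw_start, 1L)
  expect_lt(f1$raw_end, f2$raw_start + f2$len)  # fragments ordered on raw
  expect_equal(f2$raw_end - f2$raw_start + 1L, f2$len)
  expect_true(all(f2$anchors$rp >= 0))
  expect_true(all(f2$anchors$rp + f2$k <= f2$len))
})

test_that("cleaning removes injected false anchors and keeps true ones", {
  # wide world (many contigs) so that independently injected false anchors
  # cannot coincidentally confirm each other
  gen <- simulate_genome(40000, seed = 301)
  ctg <- simulate_contigs(gen, gap_rate = 10, seed = 302)
  e <- 0.05 / 3
  rd <- simulate_reads(gen, coverage = 20, len_meanlog = log(3000),
                       len_sdlog = 0.3, min_len = 1200, sub = e, ins = e,
                       del = e, seed = 303)
  idx <- build_unique_kmer_index(ctg$contigs, 17)
  crs <- anchor_reads(rd$reads, idx, adaptive_frac = 0.002)
  crs <- Filter(function(cr) n_anchors(cr) > 0, crs)
  sch <- score_scheme(idx$contig_len)
  # inject one random false anchor into ~15% of the multi-anchor reads
  set.seed(304)
  ids <- names(idx$contig_len)
  injected <- character(0)
  for (nm in sample(names(crs))) {
    if (length(injected) >= ceiling(0.15 * length(crs))) break
    cr <- crs[[nm]]
    n <- n_anchors(cr)
    if (n < 2) next
    wrong <- setdiff(ids, cr$anchors$contig)
    fake <- cr$anchors[1, ]
    fake$contig <- sample(wrong, 1)
    fake$orient <- sample(c("+", "-"), 1)
    at <- sample(n + 1L, 1L) - 1L
    cr$anchors <- rbind(cr$anchors[seq_len(at), ], fake,
                        cr$anchors[setdiff(seq_len(n), seq_len(at)), ])
    cr$anchors <- cr$anchors[order(cr$anchors$rp), ]
    rownames(cr$anchors) <- NULL
    crs[[nm]] <- cr
    injected[nm] <- fake$contig
  }
  cl <- clean_reads(crs, sch, min_confirm = 2L, remove_chimera = FALSE)
  removed_ok <- 0; kept_true <- 0; total_true <- 0
  for (nm in names(injected)) {
    out <- cl$crs[[nm]]
    truth <- setdiff(crs[[nm]]$anchors$contig, injected[nm])
    if (is.null(out)) next
    if (!injected[nm] %in% out$anchors$contig) removed_ok <- removed_ok + 1
    kept_true <- kept_true + sum(truth %in% out$anchors$contig)
    total_true <- total_true + length(truth)
  }
  expect_gte(removed_ok / length(injected), 0.95)
  expect_lte(1 - kept_true / total_true, 0.01)
})

test_that("cleaning is idempotent", {
  w <- small_world(seed = 303, genome_len = 12000L, coverage = 15, gap_rate = 6)
  idx <- build_unique_kmer_index(w$ctg$contigs, 17)
  crs <- anchor_reads(w$rd$reads, idx, adaptive_frac = 0.002)
  sch <- score_scheme(idx$contig_len)
  c1 <- clean_reads(crs, sch, min_confirm = 2L)
  c2 <- clean_reads(c1$crs, sch, min_confirm = 2L)
  expect_identical(names(c2$crs), names(c1$crs))
  k1 <- vapply(c1$crs, hybridolc:::cread_key, character(1))
  k2 <- vapply(c2$crs, hybridolc:::cread_key, character(1))
  expect_identical(unname(k2), unname(k1))
  expect_true(all(c2$report$verdict == "clean"))
})

test_that("without mutual coverage cleaning discards everything", {
  # the stated 1x premise: no read is confirmable by another. Enforce it by
  # selecting pairwise-disjoint reads; every multi-anchor read must then
  # lose all of its junctions and be discarded.
  gen <- simulate_genome(30000, seed = 305)
  ctg <- simulate_contigs(gen, gap_rate = 8, seed = 306)
  e <- 0.05 / 3
  rd <- simulate_reads(gen, coverage = 3, len_meanlog = log(3000),
                       len_sdlog = 0.2, min_len = 1500, sub = e, ins = e,
                       del = e, seed = 307)
  tr <- rd$truth[order(rd$truth$start), ]
  sel <- character(0); last_end <- -1e9
  for (i in seq_len(nrow(tr))) {
    if (tr$start[i] > last_end + 100) {
      sel <- c(sel, tr$read[i]); last_end <- tr$end[i]
    }
  }
  idx <- build_unique_kmer_index(ctg$contigs, 17)
  crs <- anchor_reads(rd$reads[sel], idx, adaptive_frac = 0.002)
  multi <- names(Filter(function(cr) n_anchors(cr) >= 2, crs))
  expect_gte(length(multi), 3L)
  sch <- score_scheme(idx$contig_len)
  cl <- clean_reads(crs, sch, min_confirm = 1L)
  expect_length(intersect(names(cl$crs), multi), 0L)
  # single-anchor reads carry no junction and are trivially clean
  expect_true(all(cl$report$verdict[cl$report$read %in% multi] == "discarded"))
})
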