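mkdna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mkpath <- function(ids, orients = rep("+", length(ids))) {
  list(nodes = ids, orients = orients, edges = integer(0),
       circular = FALSE, breaks = c(FALSE, FALSE))
}

test_that("layout reproduces a single-read path verbatim", {
  g <- mkdna(3000, 501)
  contigs <- c(ctg = g)
  idx <- build_unique_kmer_index(contigs, 17)
  raws <- c(r1 = substr(g, 1, 1600))
  crs <- anchor_reads(raws, idx, adaptive_frac = 0.002)
  d <- layout_backbone(mkpath("r1"), crs, raws, contigs,
                       extend_ends = FALSE)
  expect_length(d, 1L)
  expect_identical(d[[1]]$seq, cread_seq(crs[["r1"]], raws))
  expect_identical(d[[1]]$segmap$type, "read")
  # with end extension (the default) the terminal contig completes the draft
  d2 <- layout_backbone(mkpath("r1"), crs, raws, contigs)
  expect_identical(d2[[1]]$seq, g)
})

test_that("layout joins two error-free reads at the exact overlap", {
  g <- mkdna(3000, 502)
  contigs <- c(ctg = g)
  idx <- build_unique_kmer_index(contigs, 17)
  raws <- c(r1 = substr(g, 1, 1600), r2 = substr(g, 1501, 3000))
  crs <- anchor_reads(raws, idx, adaptive_frac = 0.002)
  d <- layout_backbone(mkpath(c("r1", "r2")), crs, raws, contigs)
  expect_length(d, 1L)
  expect_equal(nchar(d[[1]]$seq), 1600 + 1500 - 100)
  expect_identical(d[[1]]$seq, g)
  # segment map tiles the draft without gaps or overlap
  sm <- d[[1]]$segmap
  expect_equal(sm$bb_start, c(1L, 1601L))
  expect_equal(sm$bb_end[nrow(sm)], 3000L)
})

test_that("a long-read coverage gap is patched with contig sequence", {
  g <- mkdna(4000, 503)
  contigs <- c(ctg = g)
  idx <- build_unique_kmer_index(contigs, 17)
  raws <- c(r1 = substr(g, 1, 1200), r2 = substr(g, 2801, 4000))
  crs <- anchor_reads(raws, idx, adaptive_frac = 0.002)
  d <- layout_backbone(mkpath(c("r1", "r2")), crs, raws, contigs)
  expect_length(d, 1L)
  expect_identical(d[[1]]$seq, g)  # exact reconstruction across the gap
  expect_true("contig" %in% d[[1]]$segmap$type)
})

test_that("the read-to-backbone aligner finds exact and reverse matches", {
  draft <- mkdna(5000, 504)
  di <- draft_seed_index(draft, 11)
  read <- substr(draft, 1001, 2500)
  al <- align_read_to_backbone(read, di, draft)
  expect_identical(al$strand, "+")
  expect_equal(al$identity, 1.0)
  expect_equal(min(al$t), 1000)  # 0-based offset of the substring
  expect_equal(length(al$q), 1500)
  rc <- align_read_to_backbone(revcomp(read), di, draft)
  expect_identical(rc$strand, "-")
  expect_equal(rc$identity, 1.0)
  expect_equal(min(rc$t), 1000)
  # garbage does not align
  expect_null(align_read_to_backbone(mkdna(800, 505), di, draft))
})

test_that("simulated reads align within 50 bases of their true position", {
  gen <- simulate_genome(30000, seed = 506)
  e <- 0.15 / 3
  rd <- simulate_reads(gen, coverage = 2, sub = e, ins = e, del = e,
                       len_meanlog = log(3000), min_len = 1500, seed = 507)
  di <- draft_seed_index(gen$seq, 11)
  ok <- 0; tot <- 0
  for (id in names(rd$reads)) {
    tr <- rd$truth[rd$truth$read == id, ]
    al <- align_read_to_backbone(rd$reads[[id]], di, gen$seq, read_id = id)
    tot <- tot + 1
    if (!is.null(al) && abs((min(al$t) - min(al$q)) + 1 - tr$start) <= 50)
      ok <- ok + 1
  }
  expect_gte(ok / tot, 0.95)
})

test_that("consensus of identical reads returns the draft unchanged", {
  draft <- mkdna(600, 508)
  di <- draft_seed_index(draft, 11)
  alns <- lapply(1:5, function(i)
    align_read_to_backbone(draft, di, draft, read_id = paste0("r", i)))
  expect_identical(sparc_consensus(draft, alns), draft)
  expect_warning(out <- sparc_consensus(draft, list()), "empty")
  expect_identical(out, draft)
})

test_that("consensus corrects draft errors from clean reads", {
  truth <- mkdna(800, 509)
  # draft with one substitution and one deletion relative to the truth
  draft <- paste0(substr(truth, 1, 399), "A",
                  substr(truth, 401, 600), substr(truth, 602, 800))
  expect_false(draft == truth)
  di <- draft_seed_index(draft, 11)
  alns <- lapply(1:10, function(i)
    align_read_to_backbone(truth, di, draft, read_id = paste0("r", i)))
  expect_false(any(vapply(alns, is.null, logical(1))))
  out <- sparc_consensus(draft, alns, t = 0.2)
  expect_identical(out, truth)
})

test_that("heaviest path equals exhaustive enumeration on layered graphs", {
  set.seed(510)
  for (rep in 1:40) {
    nl <- sample(4:13, 1)  # up to 12 divergence points
    layers <- lapply(1:nl, function(l) sample(1:2, 1))
    node_layer <- integer(0)
    for (l in seq_len(nl)) node_layer <- c(node_layer, rep(l - 1L, layers[[l]]))
    n <- length(node_layer)
    efrom <- integer(0); eto <- integer(0)
    for (l in seq_len(nl - 1L)) {
      from <- which(node_layer == l - 1L)
      to <- which(node_layer == l)
      for (f in from) for (t in to) {
        if (runif(1) < 0.9) { efrom <- c(efrom, f); eto <- c(eto, t) }
      }
    }
    if (!length(efrom)) next
    ew <- round(runif(length(efrom), -2, 5), 3)
    pe <- hybridolc:::cpp_heaviest_path(node_layer, efrom, eto, ew)
    got <- if (length(pe)) sum(ew[pe]) else -Inf
    want <- oracle_best_path_weight(node_layer, efrom, eto, ew)
    reachable_end <- is.finite(want)
    if (reachable_end) expect_equal(got, want) else expect_true(TRUE)
  }
})

test_that("consensus identity improves monotonically with coverage", {
  gen <- simulate_genome(10000, seed = 511)
  e <- 0.15 / 3
  di_truth <- NULL
  idents <- vapply(c(3, 8, 16), function(cov) {
    rd <- simulate_reads(gen, coverage = cov, sub = e, ins = e, del = e,
                         len_meanlog = log(2500), min_len = 1200,
                         seed = 512)
    # draft = one read-length corrupted copy: use the first read's region
    draft <- list(id = "d", seq = gen$seq, segmap = data.frame(
      source = "g", type = "read", src_start = 1, src_end = 10000,
      bb_start = 1, bb_end = 10000, orient = "+"))
    # corrupt the draft so there is something to fix
    set.seed(513)
    draft$seq <- hybridolc:::inject_errors(gen$seq, 0.03, 0.01, 0.01)
    pol <- polish_backbone(draft, rd$reads, rounds = 1L)
    align_sequences(pol$seq, gen$seq)$identity
  }, numeric(1))
  expect_true(all(diff(idents) > -0.003))  # non-decreasing within noise
  expect_gt(idents[3], idents[1])
})

test_that("SAM alignments import into consensus-compatible objects", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:bb\tLN:50",
    paste("r1", 0, "bb", 3, 60, "4M1I3M2D2M", "*", 0, 0,
          "ACGTAACGTT", "*", sep = "\t"),
    paste("r2", 4, "bb", 1, 0, "4M", "*", 0, 0, "ACGT", "*", sep = "\t")),
    sam)
  alns <- read_sam_alignments(sam)
  expect_length(alns, 1L)  # unmapped r2 skipped
  a <- alns[["r1"]]
  expect_equal(a$q, c(0:3, 5:7, 8:9))
  expect_equal(a$t, c(2:5, 6:8, 11:12))
})
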