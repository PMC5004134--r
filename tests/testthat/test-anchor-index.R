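test_that("unique k-mer index keeps exactly the globally unique k-mers", {
  idx <- build_unique_kmer_index(c(c1 = "ACGTA"), 4)
  expect_setequal(idx$kmer, c("ACGT", "CGTA"))
  expect_true(all(idx$contig == "c1"))
  expect_setequal(idx$offset, c(0L, 1L))
  # a k-mer shared by two contigs (via reverse complement) is excluded
  idx2 <- build_unique_kmer_index(c(c1 = "AAAAC", c2 = "GAAAA"), 4)
  expect_setequal(idx2$kmer, c("AAAC", "GAAA"))
  expect_identical(idx2$contig[match("AAAC", idx2$kmer)], "c1")
  expect_identical(idx2$contig[match("GAAA", idx2$kmer)], "c2")
  expect_error(build_unique_kmer_index(character(0), 5), "empty")
  expect_error(build_unique_kmer_index(c(a = "ACGTT"), 6), "exceeds")
})

test_that("index equals the brute-force unique-k-mer dictionary", {
  set.seed(101)
  contigs <- stats::setNames(vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = ""),
    character(1)), sprintf("c%02d", 1:20))
  k <- 17L
  idx <- build_unique_kmer_index(contigs, k)
  # oracle: count every canonical k-mer across all contigs, keep count == 1
  all_km <- unlist(lapply(names(contigs), function(id) {
    km <- canonical_kmers(seq_kmers(contigs[[id]], k))$kmer
    stats::setNames(km, paste0(id, ":", seq_along(km) - 1L))
  }))
  tab <- table(all_km)
  uniq <- names(tab)[tab == 1]
  expect_setequal(idx$kmer, uniq)
  where <- names(all_km)[match(idx$kmer, all_km)]
  expect_identical(paste0(idx$contig, ":", idx$offset), where)
})

test_that("the adaptive support threshold gates anchors by contig length", {
  set.seed(102)
  ctg <- c(big = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                       collapse = ""))
  idx <- build_unique_kmer_index(ctg, 17)
  # 35 bp substring = 19 k-mers; threshold ceil(0.02 * 1000) = 20
  r19 <- substr(ctg[["big"]], 301, 335)
  r20 <- substr(ctg[["big"]], 301, 336)
  expect_equal(n_anchors(anchor_read(r19, idx, adaptive_frac = 0.02,
                                     min_support = 1L)), 0L)
  cr <- anchor_read(r20, idx, adaptive_frac = 0.02, min_support = 1L)
  expect_equal(n_anchors(cr), 1L)
  expect_equal(cr$anchors$support, 20L)
  # a read with no index hits compresses to the empty read
  off <- paste(rep("ACGTG", 20), collapse = "")
  expect_equal(n_anchors(anchor_read(off, idx)), 0L)
})

test_that("anchoring an error-free two-contig read recovers [A+, B+]", {
  set.seed(103)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  contigs <- c(A = mk(2000), B = mk(2000), C = mk(2000))
  idx <- build_unique_kmer_index(contigs, 17)
  read <- paste0(contigs[["A"]], mk(50), contigs[["B"]])
  cr <- anchor_read(read, idx, adaptive_frac = 0.002)
  expect_identical(cr$anchors$contig, c("A", "B"))
  expect_identical(cr$anchors$orient, c("+", "+"))
  expect_true(all(diff(cr$anchors$rp) > 0))
  # brute-force cross-check of the per-contig hit counts
  km <- canonical_kmers(seq_kmers(read, 17))$kmer
  hits <- table(idx$contig[match(km, idx$kmer)])
  expect_equal(unname(cr$anchors$support),
               as.integer(hits[cr$anchors$contig]))
})

test_that("compressed reads canonicalize consistently under reverse complement", {
  cr <- make_cread(c("5", "9"), c("+", "-"))
  expect_identical(hybridolc:::cread_key(canonicalize_cread(cr)), "5+ 9-")
  rc <- rc_cread(cr)  # (9+, 5-)
  expect_identical(hybridolc:::cread_key(canonicalize_cread(rc)), "5+ 9-")
  pal <- make_cread(c("3", "3"), c("+", "-"))
  expect_identical(hybridolc:::cread_key(canonicalize_cread(pal)),
                   hybridolc:::cread_key(pal))
  set.seed(104)
  for (i in 1:200) {
    cr <- random_cread("r", sprintf("c%d", 1:8))
    expect_identical(hybridolc:::cread_key(canonicalize_cread(cr)),
                     hybridolc:::cread_key(canonicalize_cread(rc_cread(cr))))
    can <- canonicalize_cread(cr)
    expect_identical(canonicalize_cread(can), can)  # idempotent
  }
})

test_that("anchoring is strand-symmetric", {
  w <- small_world(seed = 105, genome_len = 10000L, coverage = 6)
  idx <- build_unique_kmer_index(w$ctg$contigs, 17)
  fwd <- anchor_reads(w$rd$reads, idx, adaptive_frac = 0.002)
  rev <- anchor_reads(vapply(w$rd$reads, revcomp, character(1)), idx,
                      adaptive_frac = 0.002)
  keys_f <- vapply(fwd, hybridolc:::cread_key, character(1))
  keys_r <- vapply(rev, hybridolc:::cread_key, character(1))
  expect_identical(keys_f, keys_r)
})

test_that("raising adaptive_frac never adds anchors", {
  w <- small_world(seed = 106, genome_len = 10000L, coverage = 4)
  idx <- build_unique_kmer_index(w$ctg$contigs, 17)
  for (id in names(w$rd$reads)[1:10]) {
    prev <- NULL
    for (f in c(0.002, 0.008, 0.02)) {
      cr <- anchor_read(w$rd$reads[[id]], idx, adaptive_frac = f)
      ids <- cr$anchors$contig
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
  }
})

test_that("error-free tiling reads recover the genomic contig order", {
  gen <- simulate_genome(20000, seed = 107)
  ctg <- simulate_contigs(gen, gap_rate = 5, seed = 108)
  rd <- simulate_reads(gen, coverage = 4, sub = 0, ins = 0, del = 0,
                       len_meanlog = log(5000), min_len = 3000, seed = 109)
  idx <- build_unique_kmer_index(ctg$contigs, 17)
  crs <- anchor_reads(rd$reads, idx, adaptive_frac = 0.002)
  tr_order <- ctg$truth$contig  # contigs sorted by genomic position
  for (id in names(crs)) {
    a <- crs[[id]]$anchors
    if (nrow(a) < 2) next
    pos <- match(a$contig, tr_order)
    # canonical frame may run against the genome: accept either direction
    expect_true(all(diff(pos) == 1) || all(diff(pos) == -1))
    expect_length(unique(a$orient), 1L)
  }
})

test_that("collapsing merges identical canonical forms and sums multiplicity", {
  a <- canonicalize_cread(make_cread(c("1", "2"), c("+", "+"), id = "a"))
  b <- canonicalize_cread(make_cread(c("1", "2"), c("+", "+"), id = "b"))
  col <- collapse_duplicates(list(a = a, b = b))
  expect_length(col, 1L)
  expect_equal(col[[1]]$multiplicity, 2L)
  expect_setequal(col[[1]]$members, c("a", "b"))
  # a read and its reverse-complement twin collapse after canonicalization
  tw <- canonicalize_cread(rc_cread(make_cread(c("1", "2"), c("+", "+"),
                                               id = "tw")))
  col2 <- collapse_duplicates(list(a = a, tw = tw))
  expect_length(col2, 1L)
  expect_equal(col2[[1]]$multiplicity, 2L)
  # random multiset: multiplicities equal brute-force grouping counts
  set.seed(110)
  crs <- lapply(1:60, function(i)
    canonicalize_cread(random_cread(paste0("r", i), sprintf("c%d", 1:3),
                                    max_len = 3L)))
  names(crs) <- paste0("r", 1:60)
  col3 <- collapse_duplicates(crs)
  keys <- vapply(crs, hybridolc:::cread_key, character(1))
  expect_equal(sort(unname(vapply(col3, function(cr) cr$multiplicity,
                                  integer(1)))),
               sort(unname(as.integer(table(keys)))))
})

test_that("compressed reads survive the TSV round trip", {
  a <- canonicalize_cread(make_cread(c("1", "2"), c("+", "-"), id = "a"))
  b <- canonicalize_cread(make_cread(character(0), character(0), id = "b"))
  path <- tempfile(fileext = ".tsv")
  write_creads(list(a = a, b = b), path)
  back <- read_creads(path, k = 17L)
  expect_identical(names(back), c("a", "b"))
  expect_identical(back$a$anchors$contig, a$anchors$contig)
  expect_identical(back$a$anchors$orient, a$anchors$orient)
  expect_identical(back$a$anchors$rp, a$anchors$rp)
  expect_identical(back$a$strand, a$strand)
  expect_equal(n_anchors(back$b), 0L)
})
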