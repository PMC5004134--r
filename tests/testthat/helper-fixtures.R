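# Shared fixture builders. Everything is generated in code at test time;
# no data files.

# a compressed read built directly from (contig, orient) pairs, with
# plausible coordinates spaced `spacing` bases apart
make_cread <- function(ids, orients, id = "r1", k = 17L, spacing = 1000L,
                       len = NULL, support = NULL) {
  n <- length(ids)
  if (is.null(len)) len <- max(spacing * (n + 1L), 2L * k)
  if (is.null(support)) support <- rep(50L, n)
  rp <- as.integer(seq_len(n) * spacing - spacing %/% 2L)
  adf <- data.frame(contig = as.character(ids), orient = orients,
                    rp = rp, rp_first = pmax(0L, rp - 100L),
                    rp_last = rp + 100L, cp = rp, cp_first = pmax(0L, rp - 100L),
                    cp_last = rp + 100L, support = as.integer(support),
                    stringsAsFactors = FALSE)
  hybridolc:::new_cread(id, id, 1L, len, "+", adf, k)
}

# random compressed read over an id alphabet (used by the oracle tests)
random_cread <- function(id, alphabet, max_len = 6L, k = 17L) {
  n <- sample.int(max_len, 1L)
  make_cread(sample(alphabet, n, replace = TRUE),
             sample(c("+", "-"), n, replace = TRUE), id = id, k = k)
}

# uniform scheme over a synthetic id alphabet with distinct contig lengths
toy_scheme <- function(alphabet, min_overlap_score = 150) {
  lens <- stats::setNames(1000L + 37L * seq_along(alphabet), alphabet)
  score_scheme(lens, min_overlap_score = min_overlap_score)
}

# small simulated world shared by several tests (cheap: ~15 kb)
small_world <- function(seed = 42L, genome_len = 15000L, coverage = 15,
                        gap_rate = 4, err = 0.05, chimera_rate = 0) {
  gen <- simulate_genome(genome_len, seed = seed)
  ctg <- simulate_contigs(gen, gap_rate = gap_rate, seed = seed + 1L)
  e <- err / 3
  rd <- simulate_reads(gen, coverage = coverage,
                       len_meanlog = log(3000), len_sdlog = 0.3,
                       min_len = 1200L, sub = e, ins = e, del = e,
                       chimera_rate = chimera_rate, seed = seed + 2L)
  list(gen = gen, ctg = ctg, rd = rd)
}
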