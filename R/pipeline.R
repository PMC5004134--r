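# Pipeline orchestration: anchor -> clean -> collapse -> graph -> layout ->
# consensus, with stage artifacts on disk so stages can be inspected and
# re-run, and a machine-readable run manifest.

#' Assembly pipeline configuration
#'
#' All tunables in one place. Defaults follow the calibrated ranges where
#' the method states them (k = 17 anchoring k-mers; adaptive k-mer support
#' threshold as a fraction of contig length in 0.001-0.02) and otherwise
#' the package defaults documented per stage.
#'
#' @param k anchoring k-mer size (default 17).
#' @param adaptive_frac anchor support threshold fraction (default 0.008).
#' @param min_support absolute anchor support floor (default 2).
#' @param min_shared candidate gate in shared identifiers (default 1).
#' @param min_overlap_score minimum dovetail score (default 150).
#' @param min_confirm cleaning confirmations per anchor; `NULL` = auto
#'   (2 above ~10x estimated long-read coverage, else 1).
#' @param remove_chimera run chimera splitting (default TRUE).
#' @param score_mode `"by_contig_length"` or `"by_kmer_support"`.
#' @param mutual_frac best-overlap slack (default 0.95).
#' @param tip_len,bubble_len graph simplification limits (3 and 5 nodes).
#' @param k_seed consensus aligner seed size (default 11).
#' @param min_identity consensus aligner identity floor (default 0.5).
#' @param k_c,g,t sparse consensus parameters (2, 2, 0.2).
#' @param consensus_rounds align-and-polish iterations (default 2).
#' @param threads accepted for interface compatibility; the implementation
#'   is single-threaded, so outputs are trivially independent of it.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters for simulation only).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 17L, adaptive_frac = 0.008, min_support = 2L,
                            min_shared = 1L, min_overlap_score = 150,
                            min_confirm = NULL, remove_chimera = TRUE,
                            score_mode = "by_contig_length",
                            mutual_frac = 0.95, tip_len = 3L, bubble_len = 5L,
                            k_seed = 11L, min_identity = 0.5, k_c = 2L,
                            g = 2L, t = 0.2, consensus_rounds = 2L,
                            threads = 1L, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

# cheap, dependency-free content fingerprint for the manifest
content_hash <- function(seqs) {
  n <- sum(nchar(seqs))
  s <- sum(vapply(seqs, function(x)
    sum(utf8ToInt(substr(x, 1L, 1000L))), numeric(1)))
  sprintf("n%d-c%.0f-l%.0f", length(seqs), s, n)
}

#' Run the full hybrid assembly pipeline
#'
#' Executes anchoring, multiple-alignment cleaning, collapsing, contained
#' read removal, best-overlap graph construction and simplification,
#' linear-path layout, and sparse-graph consensus. Identical inputs and
#' configuration give byte-identical outputs.
#'
#' @param contigs named character vector of contig sequences, or a FASTA
#'   path.
#' @param reads named character vector of long reads, or a FASTA/FASTQ
#'   path.
#' @param config a [pipeline_config()].
#' @param outdir optional directory for stage artifacts (compressed reads
#'   TSV, cleaning report, GFA, backbone TSV, draft + final FASTA,
#'   manifest JSON).
#' @param no_consensus stop after layout and emit the draft only.
#' @param genome_size optional genome size for NG50 in the manifest.
#' @return list with `assembly` (named character vector), `drafts`,
#'   `paths`, `graph`, `creads` (pre-clean), `cleaned`, `collapsed`,
#'   `contained`, `report`, and `manifest`.
#' @export
run_pipeline <- function(contigs, reads, config = pipeline_config(),
                         outdir = NULL, no_consensus = FALSE,
                         genome_size = NULL) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- read_seqs(contigs)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_seqs(reads)
  contigs <- contig_set(contigs)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  log_msg <- function(...) message("[hybridolc] ", sprintf(...))

  log_msg("indexing %d contigs (k = %d)", length(contigs), config$k)
  index <- build_unique_kmer_index(contigs, config$k)
  log_msg("anchoring %d reads", length(reads))
  crs0 <- anchor_reads(reads, index, adaptive_frac = config$adaptive_frac,
                       min_support = config$min_support)
  n_anch <- vapply(crs0, n_anchors, integer(1))
  if (all(n_anch == 0L))
    stop("no read produced any anchor; lower adaptive_frac or check inputs")
  scheme <- score_scheme(index$contig_len, mode = config$score_mode,
                         min_overlap_score = config$min_overlap_score)
  est_cov <- sum(nchar(reads)) / sum(index$contig_len)
  min_confirm <- if (is.null(config$min_confirm)) {
    if (est_cov > 10) 2L else 1L
  } else config$min_confirm
  log_msg("cleaning (est. coverage %.1fx, min_confirm %d)", est_cov,
          min_confirm)
  cleaned <- clean_reads(crs0, scheme, min_confirm = min_confirm,
                         remove_chimera = config$remove_chimera,
                         min_shared = config$min_shared)
  collapsed <- collapse_duplicates(cleaned$crs)
  log_msg("%d cleaned reads collapse to %d distinct forms",
          length(cleaned$crs), length(collapsed))
  rc <- remove_contained(collapsed, scheme, min_shared = config$min_shared)
  log_msg("round 1: %d of %d survive containment removal",
          length(rc$survivors), length(collapsed))
  graph <- best_overlaps(rc$survivors, scheme,
                         min_overlap_score = config$min_overlap_score,
                         mutual_frac = config$mutual_frac,
                         min_shared = config$min_shared)
  graph <- simplify_graph(graph, tip_len = config$tip_len,
                          bubble_len = config$bubble_len)
  paths <- linear_paths(graph)
  log_msg("graph: %d nodes, %d edges, %d linear paths",
          length(graph$nodes), nrow(graph$edges), length(paths))
  drafts <- list()
  pools <- list()
  for (pi in seq_along(paths)) {
    dl <- layout_backbone(paths[[pi]], graph$nodes, reads, contigs,
                          path_id = sprintf("backbone_%d", pi))
    for (d in dl) {
      drafts[[d$id]] <- d
      pools[[d$id]] <- collect_reads(paths[[pi]], graph$nodes, crs0,
                                     contained = rc$contained,
                                     collapsed = collapsed)
    }
  }
  assembly <- character(0)
  aligned_counts <- integer(0)
  if (no_consensus) {
    assembly <- vapply(drafts, function(d) d$seq, character(1))
  } else {
    for (id in names(drafts)) {
      pool <- reads[intersect(pools[[id]], names(reads))]
      log_msg("consensus %s: %d bp draft, %d pool reads", id,
              nchar(drafts[[id]]$seq), length(pool))
      pol <- polish_backbone(drafts[[id]], pool, k_seed = config$k_seed,
                             min_identity = config$min_identity,
                             k_c = config$k_c, g = config$g, t = config$t,
                             rounds = config$consensus_rounds)
      assembly[[id]] <- pol$seq
      aligned_counts[[id]] <- pol$n_aligned
    }
  }
  stats <- assembly_n50(nchar(assembly), genome_size)
  manifest <- list(
    config = unclass(config),
    inputs = list(contigs = content_hash(contigs), reads = content_hash(reads)),
    stages = list(
      reads = length(reads),
      mean_raw_read_length = mean(nchar(reads)),
      mean_anchors_per_read = mean(n_anch),
      anchored_reads = sum(n_anch > 0L),
      cleaning = as.list(table(cleaned$report$verdict)),
      min_confirm = min_confirm,
      collapsed_forms = length(collapsed),
      contained_removed = nrow(rc$contained),
      graph_nodes = length(graph$nodes),
      graph_edges = nrow(graph$edges),
      backbones = length(drafts),
      assembly_n50 = stats$n50,
      assembly_ng50 = stats$ng50,
      assembly_bases = sum(nchar(assembly)),
      reads_aligned_in_consensus = sum(aligned_counts)))
  if (!is.null(outdir)) {
    write_creads(crs0, file.path(outdir, "compressed_reads.tsv"))
    write_cleaning_report(cleaned$report, file.path(outdir, "cleaning.tsv"))
    write_gfa(graph, file.path(outdir, "graph.gfa"))
    write_backbones(paths, file.path(outdir, "backbones.tsv"))
    if (length(drafts))
      write_fasta(vapply(drafts, function(d) d$seq, character(1)),
                  file.path(outdir, "draft.fasta"))
    if (length(assembly))
      write_fasta(assembly, file.path(outdir, "assembly.fasta"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(assembly = assembly, drafts = drafts, paths = paths, graph = graph,
       creads = crs0, cleaned = cleaned$crs, collapsed = collapsed,
       contained = rc$contained, report = cleaned$report,
       manifest = manifest)
}
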