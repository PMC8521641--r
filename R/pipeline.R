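# End-to-end pipeline: stream reads -> HPC compress -> winnow -> thread ->
# clean -> condense -> expand -> GFA. Single-threaded and deterministic:
# identical inputs and configuration give byte-identical output files.

#' Build a sparse de Bruijn graph assembly from read files
#'
#' Runs the whole pipeline in order: homopolymer compression, minimizer
#' winnowing, graph threading, optional coverage filtering, transitive-edge
#' cleaning, unitig condensation, run-length-consensus expansion, and GFA
#' output. Per-stage counts are logged to standard error; a machine-readable
#' `key=value` summary goes to standard output.
#'
#' @param input Character vector of FASTA/FASTQ paths (optionally gzipped).
#' @param output_gfa Output GFA path.
#' @param contigs_fasta Optional FASTA path for expanded unitig sequences.
#' @param k K-mer size in HPC bases (>= 2). The defaults (k = 2001,
#'   w = 1000) suit real HiFi read sets; small test genomes want much
#'   smaller values.
#' @param w Window size, `1 <= w <= k - 1`.
#' @param min_node_cov,min_edge_cov Coverage pre-filters (default 1: keep
#'   everything).
#' @param clean Apply transitive-edge cleaning (default TRUE).
#' @param clean_t Relative coverage fraction for cleaning (default 0.25).
#' @param quiet Suppress the stderr log.
#' @return Invisibly, a list with the summary statistics (reads, HPC bases,
#'   minimizer count, nodes, edges, edges removed, unitig count, total
#'   length, N50) plus the unitigs and the cleaned graph.
#' @export
run_build <- function(input, output_gfa, contigs_fasta = NULL,
                      k = 2001L, w = 1000L,
                      min_node_cov = 1L, min_edge_cov = 1L,
                      clean = TRUE, clean_t = 0.25, quiet = FALSE) {
  k <- as.integer(k)
  w <- as.integer(w)
  if (k < 2L) stop("invalid parameters: k must be >= 2")
  if (w < 1L || w > k - 1L) stop("invalid parameters: w must satisfy 1 <= w <= k - 1")
  log_msg <- function(...) if (!quiet) message(sprintf(...))

  b <- dbg_new(k, w)
  n_records <- 0L
  stream_reads(input, function(rec) {
    n_records <<- n_records + 1L
    dbg_add_read(b, rec$sequence, rec$read_id)
  })
  log_msg("[build] %d read records, %.0f HPC bases", n_records, b$hpc_bases)
  if (b$n_reads == 0L)
    stop("no usable input: every read is shorter than k=", k, " in HPC space")
  n_minimizers <- sum(vapply(b$chains, function(ch) length(ch$positions), 0L))
  g <- dbg_finalize(b, min_node_cov, min_edge_cov)
  log_msg("[build] %d selected minimizers -> %d nodes, %d edges",
          n_minimizers, nrow(g$nodes), nrow(g$edges))
  removed <- 0L
  if (clean) {
    cl <- clean_transitive_edges(g, t = clean_t)
    g <- cl$graph
    removed <- cl$removed
    log_msg("[clean] removed %d transitive edges", removed)
  }
  unitigs <- condense_unitigs(g)
  stats <- assembly_stats(unitigs)
  log_msg("[unitig] %d unitigs, total %.0f bp, N50 %.0f bp",
          stats$count, stats$total_length, stats$n50)
  links <- unitig_links(g, unitigs)
  write_gfa(unitigs, links, output_gfa)
  log_msg("[gfa] wrote %s (%d segments, %d links)", output_gfa,
          length(unitigs), nrow(links))
  if (!is.null(contigs_fasta)) write_fasta_contigs(unitigs, contigs_fasta)

  summary <- list(reads = n_records, hpc_bases = b$hpc_bases,
                  minimizers = n_minimizers, nodes = nrow(g$nodes),
                  edges = nrow(g$edges), edges_removed = removed,
                  unitigs = stats$count, total_length = stats$total_length,
                  n50 = stats$n50)
  for (key in names(summary)) cat(sprintf("%s=%s\n", key, summary[[key]]))
  invisible(c(summary, list(unitig_list = unitigs, graph = g, links = links)))
}

#' Simulate a genome and HiFi-like reads to disk
#'
#' @param config A [sim_config()].
#' @param out_prefix Output prefix; writes reads, truth intervals and the
#'   genome (`<prefix>.genome.fasta`).
#' @param format `"fasta"` or `"fastq"`.
#' @param quiet Suppress the stderr log.
#' @return Invisibly, a list with the genome, the simulation result and the
#'   written paths.
#' @export
run_simulate <- function(config, out_prefix, format = "fasta", quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  genome <- random_genome(config$genome_length, seed = config$seed,
                          circular = config$circular)
  sim <- sample_reads(genome, config)
  paths <- write_simulation(sim, out_prefix, format = format)
  gpath <- paste0(out_prefix, ".genome.fasta")
  writeLines(c(">genome", genome), gpath)
  realized <- sim$error_stats$total_bases / nchar(genome)
  if (!quiet) {
    message(sprintf("[simulate] %d reads, realized coverage %.2fx",
                    length(sim$reads), realized))
    message(sprintf("[simulate] perturbed runs %d/%d, substitutions %d",
                    sim$error_stats$perturbed_runs,
                    sim$error_stats$total_runs,
                    sim$error_stats$substitutions))
  }
  cat(sprintf("reads=%d\n", length(sim$reads)))
  cat(sprintf("realized_coverage=%.4f\n", realized))
  invisible(list(genome = genome, sim = sim,
                 paths = c(paths, genome = gpath)))
}
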