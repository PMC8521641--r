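# HiFi-like read simulation with ground truth. The error model mirrors what
# dominates real HiFi reads: most errors perturb homopolymer run lengths
# (+/-1, floor 1), with rare substitutions on top. Genomes are i.i.d. random
# with geometrically extended homopolymer runs so that HPC compression is
# non-trivial.

BASES <- c("A", "C", "G", "T")

#' Generate a random genome with realistic homopolymer structure
#'
#' Bases are drawn uniformly; each new base starts a run whose length is
#' truncated-geometric: the run extends with probability `p_extend` per
#' additional base, capped at `max_homopolymer`. With `max_homopolymer = 1`
#' the genome equals its own HPC form. For circular genomes the first and
#' last characters are forced to differ so no homopolymer run spans the
#' origin.
#'
#' @param length Genome length in bases, >= 1.
#' @param seed Integer seed; the genome is deterministic per seed.
#' @param circular Logical.
#' @param max_homopolymer Maximum run length (default 6).
#' @param p_extend Per-base run extension probability (default 0.25).
#' @return Character scalar.
#' @export
random_genome <- function(length, seed, circular = TRUE, max_homopolymer = 6L,
                          p_extend = 0.25) {
  stopifnot(length >= 1, max_homopolymer >= 1L, p_extend >= 0, p_extend < 1)
  set.seed(seed)
  pieces <- list()
  total <- 0L
  prev <- 0L
  while (total < length) {
    m <- as.integer(ceiling((length - total) / (1 + p_extend))) + 64L
    cand <- sample.int(4L, m, replace = TRUE)
    # collapsing adjacent duplicates of an i.i.d. draw makes each new run's
    # base uniform over the three bases differing from its predecessor
    keep <- c(cand[1L] != prev, diff(cand) != 0L)
    cand <- cand[keep]
    rl <- if (max_homopolymer > 1L) {
      1L + pmin(stats::rgeom(length(cand), prob = 1 - p_extend),
                max_homopolymer - 1L)
    } else rep(1L, length(cand))
    prev <- cand[length(cand)]
    total <- total + sum(rl)
    pieces[[length(pieces) + 1L]] <-
      cpp_hpc_expand(paste(BASES[cand], collapse = ""), rl)
  }
  g <- substr(paste(unlist(pieces), collapse = ""), 1L, length)
  if (circular && length > 1L &&
      substr(g, 1L, 1L) == substr(g, length, length)) {
    last <- substr(g, length, length)
    prev <- substr(g, length - 1L, length - 1L)
    repl <- setdiff(BASES, c(last, prev, substr(g, 1L, 1L)))
    substr(g, length, length) <- sample(repl, 1L)
  }
  g
}

#' Simulation configuration
#'
#' @param genome_length Genome size in bases.
#' @param circular Logical, default TRUE.
#' @param read_length_mean,read_length_sd Read length distribution (normal,
#'   clipped to `[read_length_min, genome_length]`), in bases.
#' @param read_length_min Lower clip for read lengths (default 100).
#' @param coverage Target mean coverage (x).
#' @param run_length_error_rate Probability per homopolymer run that its
#'   observed length is perturbed by +/-1 (floor 1); the dominant HiFi error
#'   mode.
#' @param substitution_rate Probability per base of a substitution.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000L, circular = TRUE,
                       read_length_mean = 20000L, read_length_sd = 2000L,
                       read_length_min = 100L, coverage = 20,
                       run_length_error_rate = 0, substitution_rate = 0,
                       seed = 1L) {
  stopifnot(genome_length >= read_length_min, coverage > 0,
            run_length_error_rate >= 0, run_length_error_rate < 1,
            substitution_rate >= 0, substitution_rate < 1)
  structure(list(genome_length = as.integer(genome_length),
                 circular = circular,
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 read_length_min = as.integer(read_length_min),
                 coverage = coverage,
                 run_length_error_rate = run_length_error_rate,
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

extract_read <- function(genome, start, len, circular) {
  G <- nchar(genome)
  if (start + len - 1L <= G) return(substr(genome, start, start + len - 1L))
  if (!circular) stop("internal error: read beyond linear genome end")
  paste0(substr(genome, start, G), substr(genome, 1L, start + len - 1L - G))
}

perturb_runs <- function(seq, rate) {
  h <- cpp_hpc_compress(seq)
  runs <- h$run_lengths
  hit <- stats::runif(length(runs)) < rate
  nh <- sum(hit)
  if (nh > 0L) {
    delta <- sample(c(-1L, 1L), nh, replace = TRUE)
    runs[hit] <- pmax(1L, runs[hit] + delta)
  }
  list(seq = cpp_hpc_expand(h$chars, runs), n_perturbed = sum(hit),
       n_runs = length(runs))
}

apply_substitutions <- function(seq, rate) {
  n <- nchar(seq)
  pos <- which(stats::runif(n) < rate)
  if (length(pos) == 0L) return(list(seq = seq, n_subs = 0L))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    nb <- c(if (p > 1L) ch[p - 1L], if (p < n) ch[p + 1L])
    cand <- setdiff(BASES, c(ch[p], nb))
    if (length(cand) == 0L) cand <- setdiff(BASES, ch[p])
    ch[p] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  list(seq = paste(ch, collapse = ""), n_subs = length(pos))
}

#' Sample HiFi-like reads from a genome
#'
#' Read starts are uniform (wrapping on circular genomes), strands uniform,
#' lengths normal (clipped). Each homopolymer run of a read is perturbed by
#' +/-1 (floor 1) with probability `run_length_error_rate`; substitutions are
#' then applied per base, choosing a replacement that differs from both
#' neighbors whenever possible. Total read bases approximate
#' `coverage * genome_length`.
#'
#' @param genome Character scalar (A/C/G/T).
#' @param config A `sim_config`.
#' @return List with `reads` (named character vector), `truth` (data.frame:
#'   `read_id`, `start`, `end` 0-based half-open on the genome, `strand`) and
#'   `error_stats` (perturbed-run and substitution tallies).
#' @export
sample_reads <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- nchar(genome)
  n_reads <- max(1L, as.integer(ceiling(config$coverage * G /
                                          config$read_length_mean)))
  lens <- as.integer(round(stats::rnorm(n_reads, config$read_length_mean,
                                        config$read_length_sd)))
  lens <- pmin(pmax(lens, config$read_length_min), G)
  starts <- if (config$circular) {
    sample.int(G, n_reads, replace = TRUE)
  } else {
    vapply(lens, function(l) sample.int(G - l + 1L, 1L), 0L)
  }
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads <- character(n_reads)
  n_pert <- 0L; n_runs <- 0L; n_subs <- 0L
  for (i in seq_len(n_reads)) {
    s <- extract_read(genome, starts[i], lens[i], config$circular)
    if (strands[i] == "-") s <- cpp_revcomp(s)
    if (config$run_length_error_rate > 0) {
      pr <- perturb_runs(s, config$run_length_error_rate)
      s <- pr$seq
      n_pert <- n_pert + pr$n_perturbed
      n_runs <- n_runs + pr$n_runs
    } else {
      n_runs <- n_runs + length(cpp_hpc_compress(s)$run_lengths)
    }
    if (config$substitution_rate > 0) {
      sb <- apply_substitutions(s, config$substitution_rate)
      s <- sb$seq
      n_subs <- n_subs + sb$n_subs
    }
    reads[i] <- s
  }
  ids <- sprintf("read%05d", seq_len(n_reads))
  names(reads) <- ids
  truth <- data.frame(read_id = ids, start = starts - 1L,
                      end = starts - 1L + lens, strand = strands,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth,
       error_stats = list(perturbed_runs = n_pert, total_runs = n_runs,
                          substitutions = n_subs,
                          total_bases = sum(nchar(reads))))
}

#' Write simulated reads and their ground truth to disk
#'
#' @param sim Result of [sample_reads()].
#' @param prefix Output path prefix; writes `<prefix>.fasta` (or `.fastq`
#'   with constant quality) and `<prefix>.truth.tsv` (BED-like: read id,
#'   0-based half-open genome interval, strand).
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, prefix, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  reads_path <- paste0(prefix, ".", format)
  con <- file(reads_path, open = "wb")
  for (id in names(sim$reads)) {
    if (format == "fasta") {
      writeLines(c(paste0(">", id), sim$reads[[id]]), con)
    } else {
      writeLines(c(paste0("@", id), sim$reads[[id]], "+",
                   strrep("I", nchar(sim$reads[[id]]))), con)
    }
  }
  close(con)
  truth_path <- paste0(prefix, ".truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(reads = reads_path, truth = truth_path))
}

#' Are two sequences identical up to rotation and strand?
#'
#' Tests whether `b` equals some rotation of `a` or of its reverse
#' complement: the natural equality for circular contigs versus a circular
#' reference.
#'
#' @param a,b Character scalars (A/C/G/T).
#' @return Logical.
#' @export
rotation_equivalent <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  doubled <- paste0(a, a)
  grepl(b, doubled, fixed = TRUE) || grepl(cpp_revcomp(b), doubled, fixed = TRUE)
}
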