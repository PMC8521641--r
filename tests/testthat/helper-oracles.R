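# Shared fixtures and independent oracles. Brute-force constructions here
# deliberately avoid the package's own code paths: reverse complements come
# from Biostrings, window minima from a quadratic scan, k-mer sets from
# substring enumeration.

BASES4 <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

# random sequence already in HPC space (no two adjacent characters equal)
random_hpc <- function(n) {
  x <- integer(n)
  x[1] <- sample.int(4L, 1L)
  if (n > 1L) {
    step <- sample.int(3L, n - 1L, replace = TRUE)
    for (i in 2:n) x[i] <- (x[i - 1L] + step[i - 1L] - 1L) %% 4L + 1L
  }
  paste(BASES4[x], collapse = "")
}

bio_rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

canonical_oracle <- function(kmers) {
  rc <- bio_rc(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

all_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# quadratic winnowing oracle: leftmost arg-min of every length-w window of
# k-mer start positions, computed from hash ranks
brute_minimizers <- function(chars, k, w) {
  h <- winnow_hashes(chars, k)
  n <- length(h)
  if (n == 0L) return(integer(0))
  r <- match(h, sort(unique(h), method = "radix"))
  if (n <= w) return(which.min(r) - 1L)
  sel <- vapply(seq_len(n - w + 1L), function(i) {
    i - 1L + which.min(r[i:(i + w - 1L)])
  }, 0L)
  sort(unique(sel)) - 1L
}

write_fasta <- function(seqs, path, wrap = 0L) {
  con <- file(path, open = "wt")
  for (i in seq_along(seqs)) {
    nm <- if (is.null(names(seqs))) paste0("r", i) else names(seqs)[i]
    writeLines(paste0(">", nm), con)
    s <- seqs[[i]]
    if (wrap > 0L) {
      starts <- seq(1L, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  close(con)
  path
}

write_fastq <- function(seqs, path) {
  con <- file(path, open = "wt")
  for (i in seq_along(seqs)) {
    nm <- if (is.null(names(seqs))) paste0("r", i) else names(seqs)[i]
    writeLines(c(paste0("@", nm), seqs[[i]], "+",
                 strrep("F", nchar(seqs[[i]]))), con)
  }
  close(con)
  path
}

topo_equal <- function(g1, g2) {
  s1 <- graph_signature(g1, coverage = FALSE)
  s2 <- graph_signature(g2, coverage = FALSE)
  identical(as.data.frame(s1$nodes), as.data.frame(s2$nodes)) &&
    identical(as.data.frame(s1$edges), as.data.frame(s2$edges))
}

sig_equal <- function(g1, g2) {
  s1 <- graph_signature(g1)
  s2 <- graph_signature(g2)
  identical(as.data.frame(s1$nodes), as.data.frame(s2$nodes)) &&
    identical(as.data.frame(s1$edges), as.data.frame(s2$edges))
}

# error-free HiFi-like simulation at desk scale
sim_clean_reads <- function(genome_length = 20000L, coverage = 20,
                            read_mean = 2000L, read_sd = 200L,
                            seed = 101L, circular = TRUE, ...) {
  g <- random_genome(genome_length, seed = seed, circular = circular)
  cfg <- sim_config(genome_length = genome_length, circular = circular,
                    read_length_mean = read_mean, read_length_sd = read_sd,
                    coverage = coverage, seed = seed + 1L, ...)
  sim <- sample_reads(g, cfg)
  list(genome = g, reads = unname(sim$reads), sim = sim)
}

# build a graph, optionally dropping one minimizer occurrence from one read
# (the error mechanism behind transitive edges: a read missing one minimizer)
build_with_drop <- function(reads, k, w, drop_read = NULL, drop_occ = NULL) {
  b <- dbg_new(k, w)
  for (i in seq_along(reads)) {
    h <- hpc_compress(reads[[i]], origin = i)
    ch <- select_minimizers(h, k, w)
    if (!is.null(drop_read) && i == drop_read) {
      stopifnot(drop_occ > 1L, drop_occ < length(ch$positions))
      for (f in c("positions", "hash", "forward", "kmer"))
        ch[[f]] <- ch[[f]][-drop_occ]
    }
    thread_chain(b, ch, h)
  }
  dbg_finalize(b)
}
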