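test_that("the dense graph (w = 1) matches brute-force k-mer enumeration", {
  set.seed(701)
  sc <- sim_clean_reads(genome_length = 5000L, coverage = 8,
                        read_mean = 700L, read_sd = 60L, seed = 711L)
  reads <- sc$reads
  k <- 31L
  g <- dbg_build(reads, k, 1L)

  hpc_reads <- vapply(reads, function(r) hpc_compress(r)$chars, "")
  want_nodes <- sort(unique(canonical_oracle(
    unlist(lapply(hpc_reads, all_kmers, k = k)))))
  got_nodes <- sort(g$nodes$kmer)
  expect_identical(got_nodes, want_nodes)

  # an edge with overlap k-1 is one (k+1)-mer of the reads: compare the
  # canonical junction strings
  want_edges <- sort(unique(canonical_oracle(
    unlist(lapply(hpc_reads, all_kmers, k = k + 1L)))))
  sig <- graph_signature(g)
  junction <- function(i) {
    a <- g$nodes[match(g$edges$from[i], g$nodes$id), kmer]
    if (!g$edges$from_fwd[i]) a <- revcomp(a)
    b <- g$nodes[match(g$edges$to[i], g$nodes$id), kmer]
    if (!g$edges$to_fwd[i]) b <- revcomp(b)
    ov <- g$edges$overlap[i]
    expect_identical(substr(a, k - ov + 1L, k), substr(b, 1L, ov))
    paste0(a, substr(b, ov + 1L, k))
  }
  got_edges <- sort(unique(canonical_oracle(
    vapply(seq_len(nrow(g$edges)), junction, ""))))
  expect_identical(got_edges, want_edges)

  # coverage conservation: node coverages sum to selected occurrences
  total_occ <- sum(vapply(hpc_reads, function(s) nchar(s) - k + 1L, 0L))
  expect_equal(sum(g$nodes$coverage), total_occ)
})

test_that("the graph is invariant under read order and strand, additive in coverage", {
  set.seed(702)
  sc <- sim_clean_reads(genome_length = 8000L, coverage = 10,
                        read_mean = 900L, read_sd = 80L, seed = 721L)
  reads <- sc$reads
  g <- dbg_build(reads, 31, 15)

  expect_true(sig_equal(g, dbg_build(sample(reads), 31, 15)))
  expect_true(sig_equal(g, dbg_build(vapply(reads, revcomp, ""), 31, 15)))

  g2 <- dbg_build(c(reads, reads), 31, 15)
  expect_true(topo_equal(g, g2))
  expect_equal(sort(g2$nodes$coverage), sort(2L * g$nodes$coverage))
  expect_equal(sort(g2$edges$coverage), sort(2L * g$edges$coverage))

  # every edge overlap lies in [k - w, k - 1] and spells consistently
  expect_true(all(g$edges$overlap >= 31 - 15 & g$edges$overlap <= 30))
})

test_that("transitive cleaning removes weak detoured edges and keeps repeats", {
  tri <- function(cov_direct, cov_leg = 10L) {
    nodes <- data.table::data.table(
      id = 1:3, hash = c("aa", "bb", "cc"),
      kmer = c("ACGTA", "CGTAC", "GTACG"), coverage = 10L)
    edges <- data.table::data.table(
      eid = 1:3,
      from = c(1L, 2L, 1L), from_fwd = TRUE,
      to = c(2L, 3L, 3L), to_fwd = TRUE,
      overlap = c(4L, 4L, 3L),
      coverage = c(cov_leg, cov_leg, cov_direct))
    structure(list(k = 5L, w = 2L, nodes = nodes, edges = edges,
                   tallies = data.table::data.table(node = integer(0),
                                                    offset = integer(0),
                                                    runlen = integer(0),
                                                    n = integer(0))),
              class = "sparse_dbg")
  }
  weak <- clean_transitive_edges(tri(1L), t = 0.25)
  expect_equal(weak$removed, 1L)
  expect_equal(nrow(weak$graph$edges), 2L)
  expect_false(3L %in% weak$graph$edges$eid)

  # a genuine repeat triangle (all coverages equal) survives
  strong <- clean_transitive_edges(tri(10L), t = 0.25)
  expect_equal(strong$removed, 0L)

  # threshold arithmetic: floor(0.25 * 10) = 2 keeps coverage 3
  expect_equal(clean_transitive_edges(tri(3L), t = 0.25)$removed, 0L)
  expect_equal(clean_transitive_edges(tri(2L), t = 0.25)$removed, 1L)
})

test_that("a read missing one minimizer creates exactly one cleanable bypass edge", {
  set.seed(703)
  sc <- sim_clean_reads(genome_length = 10000L, coverage = 30,
                        read_mean = 1200L, read_sd = 100L, seed = 731L)
  g0 <- build_with_drop(sc$reads, 31L, 15L)
  g1 <- build_with_drop(sc$reads, 31L, 15L, drop_read = 2L, drop_occ = 8L)
  s0 <- graph_signature(g0, coverage = FALSE)
  s1 <- graph_signature(g1, coverage = FALSE)
  expect_identical(as.data.frame(s1$nodes), as.data.frame(s0$nodes))
  expect_equal(nrow(s1$edges), nrow(s0$edges) + 1L)
  cl <- clean_transitive_edges(g1)
  expect_equal(cl$removed, 1L)
  expect_true(topo_equal(cl$graph, g0))
})

test_that("after cleaning, a real substitution leaves no shortcut between true nodes", {
  set.seed(704)
  sc <- sim_clean_reads(genome_length = 10000L, coverage = 30,
                        read_mean = 1200L, read_sd = 100L, seed = 741L)
  reads <- sc$reads
  g0 <- dbg_build(reads, 31, 15)
  true_hashes <- g0$nodes$hash

  r <- reads[[4]]
  pos <- 600L
  repl <- setdiff(BASES4, c(substr(r, pos - 1L, pos - 1L),
                            substr(r, pos, pos),
                            substr(r, pos + 1L, pos + 1L)))
  substr(r, pos, pos) <- repl[1]
  reads[[4]] <- r
  cl <- clean_transitive_edges(dbg_build(reads, 31, 15))
  s <- graph_signature(cl$graph)
  s0 <- graph_signature(g0)
  ek <- function(e) paste(e$from_hash, e$from_or, e$to_hash, e$to_or, e$overlap)
  between_true <- s$edges[s$edges$from_hash %in% true_hashes &
                            s$edges$to_hash %in% true_hashes, ]
  expect_true(all(ek(between_true) %in% ek(s0$edges)))
})

test_that("coverage filtering removes what a brute-force recount removes", {
  set.seed(705)
  sc <- sim_clean_reads(genome_length = 4000L, coverage = 6,
                        read_mean = 600L, read_sd = 50L, seed = 751L)
  g <- dbg_build(sc$reads, 31, 15)
  expect_true(sig_equal(g, drop_low_coverage(g, 1L, 1L)))

  g2 <- drop_low_coverage(g, 2L, 2L)
  keep <- g$nodes[g$nodes$coverage >= 2L, ]$id
  expect_setequal(g2$nodes$id, keep)
  want_edges <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep &
                          g$edges$coverage >= 2L, ]
  expect_equal(nrow(g2$edges), nrow(want_edges))
  expect_true(all(g2$tallies$node %in% keep))
})
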