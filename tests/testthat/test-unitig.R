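# independent quadratic oracle: partition nodes into maximal non-branching
# paths by repeatedly testing junction linkability on the raw edge table
oracle_partition <- function(g) {
  e <- g$edges
  arcs <- rbind(
    data.frame(u = e$from, uo = e$from_fwd, v = e$to, vo = e$to_fwd),
    data.frame(u = e$to, uo = !e$to_fwd, v = e$from, vo = !e$from_fwd))
  arcs <- unique(cbind(arcs, ov = c(e$overlap, e$overlap),
                       eid = c(e$eid, e$eid)))
  outd <- function(id, o) sum(arcs$u == id & arcs$uo == o)
  linked <- function(a, ao, b, bo) {
    # unique arc a->b and unique arc into b
    sum(arcs$u == a & arcs$uo == ao) == 1L &&
      sum(arcs$u == b & arcs$uo == !bo) == 1L &&
      any(arcs$u == a & arcs$uo == ao & arcs$v == b & arcs$vo == bo)
  }
  ids <- g$nodes$id
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (i in seq_len(nrow(arcs))) {
    a <- arcs$u[i]; ao <- arcs$uo[i]; b <- arcs$v[i]; bo <- arcs$vo[i]
    if (a == b) next
    if (linked(a, ao, b, bo)) {
      parent[[as.character(find(a))]] <- find(b)
    }
  }
  comps <- split(ids, vapply(ids, find, 0))
  unname(lapply(comps, sort))
}

test_that("condensation merges chains, stops at branches, matches the oracle", {
  set.seed(801)
  # a single linear read gives one unitig containing every node
  s <- random_hpc(400)
  g <- dbg_build(c(s, s), 31, 15)
  u <- condense_unitigs(g)
  expect_length(u, 1L)
  expect_equal(nrow(u[[1]]$path), nrow(g$nodes))
  expect_false(u[[1]]$circular)
  expect_identical(sort(u[[1]]$path$id), g$nodes$id)

  # two reads converging on a shared suffix branch into three unitigs
  common <- random_hpc(120)
  mk <- function() {
    repeat {
      x <- random_hpc(100)
      if (substr(x, 100, 100) != substr(common, 1, 1)) return(x)
    }
  }
  x <- mk(); y <- mk()
  gb <- dbg_build(c(paste0(x, common), paste0(y, common)), 31, 1)
  ub <- condense_unitigs(gb)
  expect_length(ub, 3L)

  # node partition equals the brute-force maximal-path partition
  for (seed in c(811L, 812L)) {
    set.seed(seed)
    sc <- sim_clean_reads(genome_length = 3000L, coverage = 6,
                          read_mean = 500L, read_sd = 40L, seed = seed)
    g <- dbg_build(sc$reads, 31, 25)
    u <- condense_unitigs(g)
    got <- lapply(u, function(x) sort(x$path$id))
    want <- oracle_partition(g)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    # every node in exactly one unitig exactly once
    expect_identical(sort(unlist(lapply(u, function(x) x$path$id))),
                     g$nodes$id)
  }
})

test_that("spelled HPC length follows k and the path overlaps", {
  set.seed(802)
  sc <- sim_clean_reads(genome_length = 6000L, coverage = 15,
                        read_mean = 800L, read_sd = 60L, seed = 821L)
  g <- dbg_build(sc$reads, 31, 15)
  u <- condense_unitigs(g)
  for (x in u) {
    m <- nrow(x$path)
    if (x$circular) {
      expect_equal(nchar(x$hpc_seq), sum(31L - x$ov_after))
    } else {
      expect_equal(nchar(x$hpc_seq),
                   31L + if (m > 1L) sum(31L - x$ov_after) else 0L)
    }
    expect_equal(length(x$runs), nchar(x$hpc_seq))
    expect_true(all(x$tallies$n >= 1L))
  }
})

test_that("an error-free circular genome is recovered exactly", {
  sc <- sim_clean_reads(genome_length = 15000L, coverage = 20,
                        read_mean = 1500L, read_sd = 120L, seed = 831L)
  g <- dbg_build(sc$reads, 31, 15)
  u <- condense_unitigs(g)
  expect_length(u, 1L)
  expect_true(u[[1]]$circular)
  # spelled HPC sequence is rotation/RC-equivalent to the genome's HPC form
  ghpc <- hpc_compress(sc$genome)$chars
  expect_true(rotation_equivalent(ghpc, u[[1]]$hpc_seq))
  # expansion restores the genome itself
  expect_true(rotation_equivalent(sc$genome, u[[1]]$seq))
})

test_that("all-ones tallies expand to the HPC sequence itself", {
  # a genome with no homopolymer runs: every observed run length is 1
  g <- random_genome(8000, seed = 841, circular = TRUE, max_homopolymer = 1L)
  cfg <- sim_config(genome_length = 8000L, read_length_mean = 900L,
                    read_length_sd = 80L, coverage = 12, seed = 842L)
  reads <- unname(sample_reads(g, cfg)$reads)
  u <- condense_unitigs(dbg_build(reads, 31, 15))
  expect_length(u, 1L)
  expect_true(all(u[[1]]$runs == 1L))
  expect_identical(u[[1]]$seq, u[[1]]$hpc_seq)
})

test_that("assembly statistics compute N50 on expanded lengths", {
  fake <- function(lens) lapply(lens, function(l) {
    structure(list(seq = strrep("A", l)), class = "sdbg_unitig")
  })
  expect_equal(assembly_stats(fake(100)),
               list(count = 1L, total_length = 100, n50 = 100))
  st <- assembly_stats(fake(c(50, 30, 20)))
  expect_equal(st$total_length, 100)
  expect_equal(st$n50, 50)
  expect_equal(assembly_stats(fake(c(40, 30, 30)))$n50, 30)
  expect_error(assembly_stats(list()), "no unitigs")
})
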