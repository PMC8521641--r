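test_that("genome generation is deterministic with controlled run structure", {
  expect_identical(random_genome(5000, seed = 11), random_genome(5000, seed = 11))
  expect_false(random_genome(5000, seed = 11) == random_genome(5000, seed = 12))
  expect_equal(nchar(random_genome(1234, seed = 3)), 1234L)

  # max_homopolymer = 1: the genome is its own HPC form
  g1 <- random_genome(3000, seed = 13, max_homopolymer = 1L)
  expect_identical(hpc_compress(g1)$chars, g1)

  # run lengths follow the truncated geometric model
  g <- random_genome(2e5, seed = 14)
  rl <- hpc_compress(g)$run_lengths
  expect_lte(max(rl), 6L)
  p <- 0.25
  pr <- c((1 - p) * p^(0:4), p^5)  # P(L = 1..6)
  # P(run >= 2) = p, binomial check over observed runs
  obs <- mean(rl >= 2L)
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / length(rl)))
  # mean run length within 3 SE of the truncated-geometric expectation
  expect_lt(abs(mean(rl) - sum((1:6) * pr)), 3 * stats::sd(rl) / sqrt(length(rl)))

  # circular genomes never wrap a homopolymer run across the origin
  for (seed in 21:25) {
    gc <- random_genome(997, seed = seed, circular = TRUE)
    expect_false(substr(gc, 1, 1) == substr(gc, 997, 997))
  }
})

test_that("error-free reads are exact genomic substrings with valid truth", {
  g <- random_genome(10000, seed = 31, circular = TRUE)
  cfg <- sim_config(genome_length = 10000L, read_length_mean = 1200L,
                    read_length_sd = 100L, coverage = 5, seed = 32L)
  sim <- sample_reads(g, cfg)
  doubled <- paste0(g, g)
  for (i in seq_along(sim$reads)) {
    r <- sim$reads[[i]]
    if (sim$truth$strand[i] == "-") r <- revcomp(r)
    expect_true(grepl(r, doubled, fixed = TRUE))
    expect_equal(nchar(r), sim$truth$end[i] - sim$truth$start[i])
  }
  # same seed, byte-identical read set
  expect_identical(sample_reads(g, cfg)$reads, sim$reads)
  # realized coverage near target
  cfg30 <- sim_config(genome_length = 10000L, read_length_mean = 1200L,
                      read_length_sd = 100L, coverage = 30, seed = 33L)
  tot <- sum(nchar(sample_reads(g, cfg30)$reads))
  expect_lt(abs(tot / 10000 - 30) / 30, 0.1)
})

test_that("the error channel matches its configured rates", {
  g <- random_genome(20000, seed = 41, circular = TRUE)
  cfg <- sim_config(genome_length = 20000L, read_length_mean = 2000L,
                    read_length_sd = 150L, coverage = 10, seed = 42L,
                    run_length_error_rate = 0.1)
  sim <- sample_reads(g, cfg)
  st <- sim$error_stats
  obs <- st$perturbed_runs / st$total_runs
  se <- sqrt(0.1 * 0.9 / st$total_runs)
  expect_lt(abs(obs - 0.1), 3 * se)

  # substitutions stay in-alphabet and avoid neighbor-matching when possible
  cfg2 <- sim_config(genome_length = 20000L, read_length_mean = 2000L,
                     read_length_sd = 150L, coverage = 2, seed = 43L,
                     substitution_rate = 0.002)
  sim2 <- sample_reads(g, cfg2)
  expect_gt(sim2$error_stats$substitutions, 0L)
  expect_true(all(grepl("^[ACGT]+$", sim2$reads)))
})

test_that("simulation files round-trip through the package reader", {
  g <- random_genome(4000, seed = 51)
  cfg <- sim_config(genome_length = 4000L, read_length_mean = 600L,
                    read_length_sd = 50L, coverage = 3, seed = 52L)
  sim <- sample_reads(g, cfg)
  prefix <- tempfile()
  paths <- write_simulation(sim, prefix, format = "fastq")
  back <- read_seqs(paths[["reads"]])
  expect_identical(back$sequence, unname(sim$reads))
  expect_identical(back$read_id, names(sim$reads))
  truth <- utils::read.table(paths[["truth"]], sep = "\t")
  expect_equal(nrow(truth), length(sim$reads))
})
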