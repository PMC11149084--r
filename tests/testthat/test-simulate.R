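test_that("genome generation honours lengths, names and the seed", {
  spec <- community_spec(n_genomes = 5, n_present = 2, genome_length = 1000,
                         read_length = 50, seed = 3)
  g1 <- make_genomes(spec)
  g2 <- make_genomes(spec)
  expect_length(g1, 5)
  expect_identical(vapply(g1, `[[`, numeric(1), "total_length"),
                   rep(1000, 5))
  expect_identical(vapply(g1, `[[`, character(1), "sequences"),
                   vapply(g2, `[[`, character(1), "sequences"))
  g3 <- make_genomes(community_spec(n_genomes = 5, n_present = 2,
                                    genome_length = 1000, read_length = 50,
                                    seed = 4))
  expect_false(identical(g1[[1]]$sequences, g3[[1]]$sequences))
})

test_that("related pairs share k-mers in proportion to divergence", {
  spec <- community_spec(n_genomes = 4, n_present = 2, genome_length = 5000,
                         read_length = 50, related_pairs = 1,
                         related_divergence = 0.01, seed = 8)
  g <- make_genomes(spec)
  src <- all_kmers_str(g[[1]]$sequences, 31)
  cpy <- all_kmers_str(g[[4]]$sequences, 31)
  shared <- length(intersect(src, cpy)) / length(unique(src))
  expect_gt(shared, 0.5)   # ~ (1 - 0.01)^31 = 0.73 of 31-mers survive
  expect_lt(shared, 0.95)
  unrelated <- length(intersect(src, all_kmers_str(g[[2]]$sequences, 31)))
  expect_identical(unrelated, 0L)
})

test_that("read counts follow coverage * genome_length / read_length", {
  spec <- community_spec(n_genomes = 2, n_present = 1, genome_length = 30000,
                         coverage = 2, read_length = 75, error_rate = 0,
                         seed = 5)
  sim <- simulate_community(spec)
  expect_identical(length(sim$reads), 800L)  # 2 * 30000 / 75
  expect_identical(nrow(sim$truth), 800L)
  expect_identical(sort(sim$truth$read_id), sort(sim$reads$read_id))
  expect_identical(anyDuplicated(sim$truth$read_id), 0L)
})

test_that("error-free reads are exact substrings of their source strand", {
  spec <- community_spec(n_genomes = 3, n_present = 3, genome_length = 2000,
                         coverage = 1, read_length = 60, error_rate = 0,
                         seed = 6)
  sim <- simulate_community(spec)
  gseq <- vapply(sim$genomes, `[[`, character(1), "sequences")
  frag <- substring(gseq[sim$truth$genome_id], sim$truth$start,
                    sim$truth$start + sim$truth$read_length - 1)
  minus <- sim$truth$strand == "-"
  frag[minus] <- revcomp_str(frag[minus])
  expect_identical(sim$reads$bases, frag)
})

test_that("injected substitutions match the nominal rate and get low quality", {
  spec <- community_spec(n_genomes = 2, n_present = 2, genome_length = 20000,
                         coverage = 5, read_length = 75, error_rate = 0.02,
                         degraded_fraction = 0, seed = 7)
  sim <- simulate_community(spec)
  gseq <- vapply(sim$genomes, `[[`, character(1), "sequences")
  frag <- substring(gseq[sim$truth$genome_id], sim$truth$start,
                    sim$truth$start + sim$truth$read_length - 1)
  minus <- sim$truth$strand == "-"
  frag[minus] <- revcomp_str(frag[minus])
  read_chars <- strsplit(sim$reads$bases, "", fixed = TRUE)
  frag_chars <- strsplit(frag, "", fixed = TRUE)
  mism <- unlist(Map(`!=`, read_chars, frag_chars), use.names = FALSE)
  n_bases <- length(mism)
  expect_gt(n_bases, 1e5)
  rate <- mean(mism)
  se <- sqrt(0.02 * 0.98 / n_bases)
  expect_lt(abs(rate - 0.02), 3 * se)
  # erroneous bases carry markedly lower Phred scores than correct ones
  q <- unlist(phred_qualities(sim$reads), use.names = FALSE)
  expect_lt(mean(q[mism]), 15)
  expect_gt(mean(q[!mism]), 25)
})

test_that("degraded reads are low-quality throughout and error-enriched", {
  spec <- community_spec(n_genomes = 2, n_present = 2, genome_length = 20000,
                         coverage = 4, read_length = 75, error_rate = 0.002,
                         degraded_fraction = 0.3, degraded_error_rate = 0.05,
                         seed = 13)
  sim <- simulate_community(spec)
  gseq <- vapply(sim$genomes, `[[`, character(1), "sequences")
  frag <- substring(gseq[sim$truth$genome_id], sim$truth$start,
                    sim$truth$start + sim$truth$read_length - 1)
  minus <- sim$truth$strand == "-"
  frag[minus] <- revcomp_str(frag[minus])
  mean_q <- vapply(phred_qualities(sim$reads), mean, numeric(1))
  low_q <- mean_q < 25  # the two populations are well separated (~15 vs ~37)
  expect_equal(mean(low_q), 0.3, tolerance = 0.15)
  mism_rate <- mapply(function(r, f)
    mean(strsplit(r, "")[[1]] != strsplit(f, "")[[1]]),
    sim$reads$bases, frag, USE.NAMES = FALSE)
  expect_gt(mean(mism_rate[low_q]), 10 * mean(mism_rate[!low_q]))
})

test_that("the simulated FASTQ byte stream is deterministic under the seed", {
  spec <- community_spec(n_genomes = 2, n_present = 2, genome_length = 1500,
                         coverage = 1, read_length = 50, seed = 10)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_community(spec, out_dir = d1)
  simulate_community(spec, out_dir = d2)
  f1 <- file.path(d1, "reads.fastq.gz")
  f2 <- file.path(d2, "reads.fastq.gz")
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
})

test_that("simulation output files exist and re-read consistently", {
  spec <- community_spec(n_genomes = 3, n_present = 2, genome_length = 1200,
                         coverage = 1, read_length = 50, seed = 11)
  d <- tempfile()
  sim <- simulate_community(spec, out_dir = d)
  fastas <- list.files(file.path(d, "genomes"), full.names = TRUE)
  expect_length(fastas, 3)
  g <- read_fasta_genomes(sort(fastas))
  expect_identical(vapply(g, `[[`, character(1), "sequences"),
                   vapply(sim$genomes, `[[`, character(1), "sequences"))
  r <- read_fastq(file.path(d, "reads.fastq.gz"))
  expect_identical(r$bases, sim$reads$bases)
  spec_back <- jsonlite::read_json(file.path(d, "spec.json"))
  expect_identical(spec_back$seed, 11L)
})
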