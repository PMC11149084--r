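fake_gt <- function(n, length = 3000) {
  data.frame(genome_id = seq_len(n), name = sprintf("sp%02d", seq_len(n)),
             total_length = rep(length, n), stringsAsFactors = FALSE)
}

fake_assignments <- function(counts, read_length = 75) {
  ids <- rep.int(seq_along(counts), counts)
  data.frame(read_id = sprintf("r%05d", seq_along(ids)), genome_id = ids,
             genome_name = sprintf("sp%02d", ids),
             votes_for = rep(10L, length(ids)),
             votes_total = rep(10L, length(ids)),
             read_length = rep(read_length, length(ids)),
             stringsAsFactors = FALSE)
}

test_that("coverage is identified bases over genome length", {
  cov <- compute_coverages(fake_assignments(c(100)), fake_gt(1))
  expect_equal(cov$coverage, 100 * 75 / 3000)  # 2.5
  expect_equal(cov$n_reads, 100L)
  expect_equal(cov$total_bases, 7500)
})

test_that("empty assignments give an empty coverage table", {
  cov <- compute_coverages(fake_assignments(integer(0)), fake_gt(2))
  expect_identical(nrow(cov), 0L)
  cov2 <- compute_coverages(NULL, fake_gt(2))
  expect_identical(nrow(cov2), 0L)
})

test_that("species with zero reads are absent and unknown ids error", {
  cov <- compute_coverages(fake_assignments(c(5, 0, 3)), fake_gt(3))
  expect_identical(cov$species, c("sp01", "sp03"))
  bad <- fake_assignments(c(2))
  bad$genome_id <- 9L
  expect_error(compute_coverages(bad, fake_gt(3)), "9")
})

test_that("coverage totals agree with an independent recount of the TSV", {
  a <- fake_assignments(c(40, 7, 0, 13))
  f <- tempfile(fileext = ".tsv")
  write_assignments(a, f)
  cov <- compute_coverages(read_assignments(f), fake_gt(4), read_length = 75)
  # brute-force recount straight off the file text
  lines <- utils::read.delim(f, stringsAsFactors = FALSE)
  recount <- table(lines$genome_id)
  expect_identical(cov$n_reads,
                   as.integer(recount[as.character(cov$genome_id)]))
  expect_equal(cov$coverage, cov$n_reads * 75 / 3000)
})

test_that("two well-separated groups split as the WSS oracle says", {
  cov <- data.frame(genome_id = 1:4, species = c("A", "B", "C", "D"),
                    n_reads = 1L, total_bases = 1,
                    genome_length = 1,
                    coverage = c(5.1, 4.9, 0.01, 0.02),
                    stringsAsFactors = FALSE)
  clu <- cluster_coverages(cov, K = 2, seed = 3)
  expect_true(clu$filtered)
  oracle <- best_contiguous_partition(log10(cov$coverage), 2)
  expect_identical(canonical_partition(cov$species, clu$labels),
                   canonical_partition(cov$species, oracle$labels))
  rep <- filter_species(cov, clu)
  expect_setequal(rep$kept$species, c("A", "B"))
  expect_setequal(rep$removed$species, c("C", "D"))
})

test_that("degenerate coverage tables return the no-filtering sentinel", {
  one <- data.frame(genome_id = 1L, species = "A", n_reads = 3L,
                    total_bases = 225, genome_length = 100, coverage = 2.25,
                    stringsAsFactors = FALSE)
  clu <- cluster_coverages(one, K = 2)
  expect_false(clu$filtered)
  expect_identical(nrow(filter_species(one, clu)$removed), 0L)
  flat <- data.frame(genome_id = 1:3, species = c("A", "B", "C"),
                     n_reads = 1L, total_bases = 75, genome_length = 100,
                     coverage = rep(0.75, 3), stringsAsFactors = FALSE)
  clu2 <- cluster_coverages(flat, K = 2)
  expect_false(clu2$filtered)
  expect_identical(filter_species(flat, clu2)$kept$species, flat$species)
  expect_error(cluster_coverages(one, K = 1), "K")
  expect_error(cluster_coverages(one[0, ], K = 2), "empty")
})

test_that("1-D K-means matches the exhaustive contiguous-split oracle", {
  set.seed(99)
  for (rep_i in 1:30) {
    n <- sample(3:20, 1)
    cov <- data.frame(genome_id = seq_len(n),
                      species = sprintf("s%02d", seq_len(n)),
                      n_reads = 1L, total_bases = 1, genome_length = 1,
                      coverage = 10^stats::runif(n, -3, 2),
                      stringsAsFactors = FALSE)
    K <- sample(2:3, 1)
    if (length(unique(cov$coverage)) < K) next
    clu <- cluster_coverages(cov, K = K, seed = rep_i)
    oracle <- best_contiguous_partition(log10(cov$coverage), K)
    expect_identical(canonical_partition(cov$species, clu$labels),
                     canonical_partition(cov$species, oracle$labels),
                     info = sprintf("replicate %d (n=%d, K=%d)", rep_i, n, K))
    # contiguity: sorted by coverage, labels form contiguous blocks
    lab_sorted <- clu$labels[order(cov$coverage)]
    expect_identical(length(rle(as.integer(lab_sorted))$lengths), K)
  }
})

test_that("kept and removed partition the coverage table deterministically", {
  set.seed(5)
  n <- 12
  cov <- data.frame(genome_id = seq_len(n),
                    species = sprintf("s%02d", seq_len(n)),
                    n_reads = 1L, total_bases = 1, genome_length = 1,
                    coverage = 10^stats::runif(n, -2, 1.5),
                    stringsAsFactors = FALSE)
  clu <- cluster_coverages(cov, K = 2, seed = 7)
  rep1 <- filter_species(cov, clu)
  rep2 <- filter_species(cov, cluster_coverages(cov, K = 2, seed = 7))
  expect_setequal(c(rep1$kept$species, rep1$removed$species), cov$species)
  expect_identical(length(intersect(rep1$kept$species,
                                    rep1$removed$species)), 0L)
  expect_identical(rep1$kept, rep2$kept)
  expect_identical(rep1$removed, rep2$removed)
})

test_that("with >= 20-fold separation the filter recovers the true set", {
  set.seed(123)
  for (rep_i in 1:50) {
    n_true <- sample(3:12, 1)
    n_false <- sample(1:10, 1)
    true_cov <- stats::runif(n_true, 2, 40)
    false_cov <- stats::runif(n_false, 1e-4, min(true_cov) / 20)
    cov <- data.frame(
      genome_id = seq_len(n_true + n_false),
      species = c(sprintf("true%02d", seq_len(n_true)),
                  sprintf("false%02d", seq_len(n_false))),
      n_reads = 1L, total_bases = 1, genome_length = 1,
      coverage = c(true_cov, false_cov), stringsAsFactors = FALSE)
    rep <- filter_species(cov, cluster_coverages(cov, K = 2, seed = rep_i))
    expect_setequal(rep$kept$species, sprintf("true%02d", seq_len(n_true)))
  }
})

test_that("external assignment tables feed the same coverage pipeline", {
  af <- write_lines_file(c("read_id\tspecies",
                           paste0("r", 1:6, "\tEscherichia coli"),
                           paste0("r", 7:8, "\tBacillus subtilis")), ".tsv")
  lf <- write_lines_file(c("name\tlength",
                           "Escherichia coli\t1000",
                           "Bacillus subtilis\t2000"), ".tsv")
  cov <- ingest_external_assignments(af, lf, read_length = 150)
  expect_equal(cov$coverage[cov$species == "Escherichia coli"],
               6 * 150 / 1000)
  expect_equal(cov$coverage[cov$species == "Bacillus subtilis"],
               2 * 150 / 2000)
  # missing read length and unresolvable names are errors
  expect_error(ingest_external_assignments(af, lf), "read_length")
  lf2 <- write_lines_file(c("name\tlength", "Escherichia coli\t1000"), ".tsv")
  expect_error(ingest_external_assignments(af, lf2, read_length = 150),
               "bacillus subtilis")
  # empty file -> empty table
  ef <- write_lines_file("read_id\tspecies", ".tsv")
  expect_identical(nrow(ingest_external_assignments(ef, lf,
                                                    read_length = 150)), 0L)
})
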