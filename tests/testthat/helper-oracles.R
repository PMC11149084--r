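# Independent oracles used across the suite. They share no code with the
# implementation paths they check: the k-mer dictionary enumerates strings
# in R, and the clustering oracle searches all contiguous splits.

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

revcomp_str <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

all_kmers_str <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1)
  km <- substring(seq, starts, starts + k - 1)
  km[!grepl("N", km, fixed = TRUE)]
}

# Exact k-mer -> genome-id-set dictionary over forward and reverse strands,
# as a data.frame (kmer, n_genomes, genome_id of the unique owner or NA).
kmer_dictionary <- function(genomes, k) {
  per_genome <- lapply(genomes, function(g) {
    km <- unlist(lapply(g$sequences, function(s)
      c(all_kmers_str(s, k), all_kmers_str(revcomp_str(s), k))),
      use.names = FALSE)
    unique(km)
  })
  ids <- rep.int(vapply(genomes, `[[`, integer(1), "genome_id"),
                 lengths(per_genome))
  km <- unlist(per_genome, use.names = FALSE)
  n_by_kmer <- rowsum(rep(1L, length(km)), km)
  owner <- rowsum(ids, km)  # meaningful only where n == 1
  data.frame(kmer = rownames(n_by_kmer),
             n_genomes = as.integer(n_by_kmer[, 1]),
             owner = ifelse(n_by_kmer[, 1] == 1L, owner[, 1], NA_integer_),
             stringsAsFactors = FALSE)
}

# Exhaustive 1-D K-means oracle: the optimal partition is a contiguous
# split of the sorted values, so minimise within-cluster sum of squares
# over all contiguous K-partitions. Returns cluster membership as a label
# vector (1 = lowest-value block).
best_contiguous_partition <- function(x, K) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  wss_block <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, K - 1)
  best <- NULL
  best_wss <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    wss <- 0
    lab_sorted <- integer(n)
    for (b in seq_len(K)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      wss <- wss + wss_block(xs[idx])
      lab_sorted[idx] <- b
    }
    if (wss < best_wss - 1e-12) {
      best_wss <- wss
      best <- lab_sorted
    }
  }
  labels <- integer(n)
  labels[ord] <- best
  list(labels = labels, wss = best_wss)
}

# Partition of species names by cluster label, as a canonical set-of-sets
# (sorted within and across blocks) for partition equality checks.
canonical_partition <- function(names, labels) {
  blocks <- split(names, labels)
  blocks <- lapply(blocks, sort)
  unname(blocks[order(vapply(blocks, `[`, character(1), 1))])
}

write_lines_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
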