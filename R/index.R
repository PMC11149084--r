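#' Build the genome-id Bloom filter index
#'
#' Indexes every k-mer of every reference genome (both the forward and the
#' reverse-complement strand) in a single integer entry array of size `m`.
#' A family of `n_hash` seeded hash functions maps each k-mer to `n_hash`
#' entries. An entry holds `0` while untouched, a positive genome id once
#' k-mers of exactly one genome have written it, and the "dirty" sentinel
#' `-1` once k-mers of two or more distinct genomes have written it. Dirty
#' entries mark non-unique signatures and never revert.
#'
#' The build is deterministic: identical genomes, `k`, `m`, `n_hash` and
#' `master_seed` give a bit-identical entry array, and the final array does
#' not depend on the order in which genomes are inserted.
#'
#' @param genomes List of `genome_record` objects (see
#'   [read_fasta_genomes()]); ids must be the contiguous range `1..G`.
#' @param k K-mer length (default 31, the usual species-level choice).
#' @param n_hash Number of hash functions (>= 1).
#' @param m Number of entries in the index. Default: `2 * n_hash * D` where
#'   `D = 2 * total_bp` estimates the distinct k-mer count over both
#'   strands, which keeps the expected per-entry write load at 0.5.
#'   Smaller `m` trades memory for more dirty entries; it can silence
#'   unique signatures but can never make a k-mer vote for a genome that
#'   did not contain it.
#' @param master_seed Integer seed from which the per-function hash seeds
#'   are derived.
#' @return A `bloom_index` object: fields `k`, `n_hash`, `m`,
#'   `master_seed`, `entries` (integer vector of length `m`),
#'   `genome_table` and `format_version`.
#' @seealso [query_kmer()], [classify_sample()], [save_index()]
#' @export
build_index <- function(genomes, k = 31, n_hash = 3, m = NULL,
                        master_seed = 1L) {
  stopifnot(length(genomes) >= 1, k >= 1, n_hash >= 1)
  gt <- genome_table(genomes)
  if (!identical(gt$genome_id, seq_len(nrow(gt))))
    stopf("genome ids must be the contiguous range 1..G")
  if (any(gt$total_length < k))
    stopf("genome(s) shorter than k: %s",
          paste(gt$name[gt$total_length < k], collapse = ", "))
  if (is.null(m)) {
    est_kmers <- 2 * sum(gt$total_length)
    m <- ceiling(2 * n_hash * est_kmers)
  }
  m <- as.numeric(m)
  if (m < 1) stopf("m must be >= 1")
  if (m >= 2^31) stopf("m must be < 2^31")
  if (m < nrow(gt))
    warning(sprintf("index has fewer entries (m = %s) than genomes (G = %d); ",
                    format(m, big.mark = ","), nrow(gt)),
            "nearly all entries will be dirty", call. = FALSE)
  entries <- mbx_build_entries(lapply(genomes, `[[`, "sequences"),
                               gt$genome_id, m, as.integer(k),
                               as.integer(n_hash), as.numeric(master_seed))
  new_bloom_index(as.integer(k), as.integer(n_hash), m,
                  as.numeric(master_seed), entries, gt)
}

new_bloom_index <- function(k, n_hash, m, master_seed, entries, genome_table,
                            format_version = 1L) {
  structure(list(k = k, n_hash = n_hash, m = m, master_seed = master_seed,
                 entries = entries, genome_table = genome_table,
                 format_version = format_version),
            class = "bloom_index")
}

#' Insert one genome into an existing index
#'
#' Applies the entry update rule for every k-mer of the genome and of its
#' reverse complement: empty entries take the genome id, entries already
#' holding the same id are unchanged, entries holding a different id become
#' dirty (`-1`), and dirty entries stay dirty. Re-inserting a genome is a
#' no-op.
#'
#' @param index A `bloom_index`.
#' @param genome A `genome_record` whose id is registered in
#'   `index$genome_table`.
#' @return The updated `bloom_index` (value semantics; the input is not
#'   modified).
#' @export
insert_genome <- function(index, genome) {
  stopifnot(inherits(index, "bloom_index"), inherits(genome, "genome_record"))
  if (!genome$genome_id %in% index$genome_table$genome_id)
    stopf("genome id %d is not registered in the index genome table",
          genome$genome_id)
  index$entries <- mbx_insert_genome(index$entries, genome$sequences,
                                     genome$genome_id, index$k, index$n_hash,
                                     index$master_seed)
  index
}

#' Query k-mers for a unanimous genome id
#'
#' Looks up the `n_hash` entries of each k-mer. A k-mer is attributed to
#' genome `g` iff all entries hold the same positive id `g` (a unique
#' signature); any empty entry, dirty entry, disagreement between entries,
#' or `N` base discards the k-mer (`NA`). Queries are forward-only: both
#' strands were already inserted at build time.
#'
#' @param index A `bloom_index`.
#' @param kmers Character vector of k-mers, each of length `index$k`.
#' @return Integer vector of genome ids, `NA` where the k-mer is discarded.
#' @export
query_kmer <- function(index, kmers) {
  stopifnot(inherits(index, "bloom_index"), is.character(kmers))
  mbx_query_kmers(index$entries, kmers, index$k, index$n_hash,
                  index$master_seed)
}

#' Enumerate the k-mer windows of a sequence
#'
#' Returns every length-`k` window of `sequence` together with its 1-based
#' start position, skipping windows that contain `N`. Sequences shorter
#' than `k` yield an empty result.
#'
#' @param sequence A single DNA string.
#' @param k Window length.
#' @return A `data.frame` with columns `kmer` and `position`.
#' @export
enumerate_kmers <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1, k >= 1)
  L <- nchar(sequence)
  if (L < k)
    return(data.frame(kmer = character(0), position = integer(0),
                      stringsAsFactors = FALSE))
  starts <- seq_len(L - k + 1)
  kmers <- substring(sequence, starts, starts + k - 1)
  keep <- !grepl("N", kmers, fixed = TRUE)
  data.frame(kmer = kmers[keep], position = starts[keep],
             stringsAsFactors = FALSE)
}

# ---- serialization ---------------------------------------------------------

INDEX_MAGIC <- "MBIX"
INDEX_FORMAT_VERSION <- 1L

#' Save / load a Bloom filter index
#'
#' The on-disk format is little-endian binary: a header (magic `"MBIX"`,
#' format version, `k`, `n_hash`, `m`, `master_seed`, `G`), the genome
#' table, then the raw 32-bit entry array. `load_index(save_index(x))`
#' reproduces the index exactly.
#'
#' @param index A `bloom_index`.
#' @param path File path.
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   `bloom_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "bloom_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(INDEX_MAGIC), con)
  writeBin(as.integer(index$format_version), con, size = 4, endian = "little")
  writeBin(as.integer(c(index$k, index$n_hash)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(index$m, index$master_seed)), con, size = 8,
           endian = "little")
  gt <- index$genome_table
  writeBin(as.integer(nrow(gt)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(gt))) {
    writeBin(as.integer(gt$genome_id[i]), con, size = 4, endian = "little")
    nm <- charToRaw(gt$name[i])
    writeBin(length(nm), con, size = 4, endian = "little")
    writeBin(nm, con)
    writeBin(as.numeric(gt$total_length[i]), con, size = 8, endian = "little")
  }
  writeBin(index$entries, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, INDEX_MAGIC))
    stopf("'%s' is not an index file (magic '%s', expected '%s')",
          path, magic, INDEX_MAGIC)
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(version, INDEX_FORMAT_VERSION))
    stopf("index format version %s not supported (expected version %d)",
          paste(version, collapse = ""), INDEX_FORMAT_VERSION)
  kn <- readBin(con, "integer", 2, size = 4, endian = "little")
  ms <- readBin(con, "numeric", 2, size = 8, endian = "little")
  if (length(kn) < 2 || length(ms) < 2) stopf("truncated index file: '%s'", path)
  G <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(G) < 1) stopf("truncated index file: '%s'", path)
  ids <- integer(G); nms <- character(G); lens <- numeric(G)
  for (i in seq_len(G)) {
    ids[i] <- readBin(con, "integer", 1, size = 4, endian = "little")
    nl <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(nl) < 1) stopf("truncated index file: '%s'", path)
    nms[i] <- rawToChar(readBin(con, "raw", nl))
    lens[i] <- readBin(con, "numeric", 1, size = 8, endian = "little")
  }
  m <- ms[1]
  entries <- readBin(con, "integer", m, size = 4, endian = "little")
  if (length(entries) != m) stopf("truncated index file: '%s'", path)
  gt <- data.frame(genome_id = ids, name = nms, total_length = lens,
                   stringsAsFactors = FALSE)
  new_bloom_index(kn[1], kn[2], m, ms[2], entries, gt, version)
}

#' @export
print.bloom_index <- function(x, ...) {
  occ <- mean(x$entries != 0L)
  dirty <- mean(x$entries == -1L)
  cat(sprintf(paste0("<bloom_index> k=%d  n_hash=%d  m=%s  G=%d\n",
                     "  occupancy %.1f%%  dirty %.1f%%  master_seed=%s\n"),
              x$k, x$n_hash, format(x$m, big.mark = ","),
              nrow(x$genome_table), 100 * occ, 100 * dirty,
              format(x$master_seed)))
  invisible(x)
}

#' @export
summary.bloom_index <- function(object, ...) {
  pos <- object$entries[object$entries > 0L]
  per_genome <- tabulate(pos, nbins = nrow(object$genome_table))
  out <- list(k = object$k, n_hash = object$n_hash, m = object$m,
              n_genomes = nrow(object$genome_table),
              occupancy = mean(object$entries != 0L),
              dirty_fraction = mean(object$entries == -1L),
              entries_per_genome = stats::setNames(per_genome,
                                                   object$genome_table$name))
  class(out) <- "summary.bloom_index"
  out
}

#' @export
print.summary.bloom_index <- function(x, ...) {
  cat(sprintf("Genome-id Bloom filter: k=%d, %d hash function(s), m=%s\n",
              x$k, x$n_hash, format(x$m, big.mark = ",")))
  cat(sprintf("  %d genomes, occupancy %.2f%%, dirty %.2f%%\n",
              x$n_genomes, 100 * x$occupancy, 100 * x$dirty_fraction))
  cat("  entries holding each genome id:\n")
  print(x$entries_per_genome)
  invisible(x)
}
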