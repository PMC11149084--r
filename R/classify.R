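#' Classify a sample of reads against a Bloom filter index
#'
#' Each read votes with its k-mer windows: windows failing the mean-Phred
#' quality gate are skipped, the remaining windows are looked up with
#' [query_kmer()], and discarded verdicts are excluded from the vote. The
#' read is assigned to the modal genome id iff its share of the kept votes
#' strictly exceeds `majority_threshold`; ties for the modal id, an empty
#' vote set, or reads shorter than `k` leave the read discarded. Mates of a
#' pair are classified independently.
#'
#' @param index A `bloom_index`.
#' @param reads A `fastq_reads` object (see [read_fastq()]).
#' @param majority_threshold Fraction in `[0, 1)`; the winning id must hold
#'   strictly more than this share of kept votes (default 0.5, the "over
#'   50 percent" majority rule).
#' @param min_kmer_quality Minimum mean Phred score of a k-mer's bases for
#'   it to vote; 0 (default) disables the gate. Reference k-mers are never
#'   gated -- the gate applies at query time only.
#' @return A `classification_result` list:
#'   \describe{
#'     \item{assignments}{`data.frame` over identified reads: `read_id`,
#'       `genome_id`, `genome_name`, `votes_for`, `votes_total`,
#'       `kmers_skipped_quality`, `read_length`.}
#'     \item{stats}{list with `total_reads`, `identified_reads`,
#'       `identified_fraction`, `per_genome_reads` (named integer).}
#'     \item{params}{the thresholds used.}
#'   }
#' @export
classify_sample <- function(index, reads, majority_threshold = 0.5,
                            min_kmer_quality = 0) {
  stopifnot(inherits(index, "bloom_index"), inherits(reads, "fastq_reads"))
  if (majority_threshold < 0 || majority_threshold >= 1)
    stopf("majority_threshold must be in [0, 1)")
  if (min_kmer_quality < 0) stopf("min_kmer_quality must be >= 0")
  G <- nrow(index$genome_table)
  n <- length(reads)
  if (n == 0) {
    res <- list(predicted_id = integer(0), votes_for = integer(0),
                votes_total = integer(0), kmers_skipped_quality = integer(0))
  } else {
    res <- mbx_classify(index$entries, reads$bases, reads$qual, index$k,
                        index$n_hash, index$master_seed, G,
                        majority_threshold, min_kmer_quality)
  }
  identified <- which(!is.na(res$predicted_id))
  id <- res$predicted_id[identified]
  assignments <- data.frame(
    read_id = reads$read_id[identified],
    genome_id = id,
    genome_name = index$genome_table$name[id],
    votes_for = res$votes_for[identified],
    votes_total = res$votes_total[identified],
    kmers_skipped_quality = res$kmers_skipped_quality[identified],
    read_length = nchar(reads$bases[identified]),
    stringsAsFactors = FALSE)
  per_genome <- tabulate(id, nbins = G)
  names(per_genome) <- index$genome_table$name
  stats <- list(total_reads = n,
                identified_reads = length(identified),
                identified_fraction = if (n > 0) length(identified) / n else 0,
                per_genome_reads = per_genome)
  structure(list(assignments = assignments, stats = stats,
                 params = list(majority_threshold = majority_threshold,
                               min_kmer_quality = min_kmer_quality)),
            class = "classification_result")
}

#' Classify a single read
#'
#' Convenience wrapper around the voting rule of [classify_sample()] for
#' one read; unlike the sample-level function it also reports discarded
#' reads (as `NA`).
#'
#' @param index A `bloom_index`.
#' @param bases DNA string of the read.
#' @param qualities Optional integer Phred scores (same length as `bases`)
#'   or a Phred+33 quality string.
#' @param read_id Read identifier used in the output row.
#' @inheritParams classify_sample
#' @return A one-row `data.frame`: `read_id`, `predicted_genome_id` (`NA`
#'   if discarded), `votes_for`, `votes_total`, `kmers_skipped_quality`.
#' @export
classify_read <- function(index, bases, qualities = NULL, read_id = "read",
                          majority_threshold = 0.5, min_kmer_quality = 0) {
  stopifnot(is.character(bases), length(bases) == 1)
  qual <- if (is.null(qualities)) {
    ""
  } else if (is.numeric(qualities)) {
    if (length(qualities) != nchar(bases))
      stopf("qualities length %d != read length %d", length(qualities),
            nchar(bases))
    intToUtf8(as.integer(qualities) + 33L)
  } else {
    as.character(qualities)
  }
  reads <- structure(list(read_id = read_id, bases = bases, qual = qual),
                     class = "fastq_reads")
  res <- mbx_classify(index$entries, reads$bases, reads$qual, index$k,
                      index$n_hash, index$master_seed,
                      nrow(index$genome_table),
                      majority_threshold, min_kmer_quality)
  data.frame(read_id = read_id,
             predicted_genome_id = res$predicted_id,
             votes_for = res$votes_for,
             votes_total = res$votes_total,
             kmers_skipped_quality = res$kmers_skipped_quality,
             stringsAsFactors = FALSE)
}

#' Mean-Phred k-mer quality gate
#'
#' A k-mer may vote iff the arithmetic mean of its per-base Phred scores is
#' at least `min_kmer_quality`; a threshold of 0 disables the gate.
#'
#' @param qualities Integer Phred scores of the k-mer's bases.
#' @param min_kmer_quality Threshold on the mean score.
#' @return Logical.
#' @export
kmer_quality_ok <- function(qualities, min_kmer_quality) {
  stopifnot(is.numeric(qualities), length(qualities) >= 1,
            min_kmer_quality >= 0)
  mean(qualities) >= min_kmer_quality
}

#' @export
#' @method predict bloom_index
predict.bloom_index <- function(object, reads, ...) {
  classify_sample(object, reads, ...)
}

#' @export
print.classification_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("<classification_result> %s of %s reads identified",
                     " (%.1f%%)\n"),
              format(s$identified_reads, big.mark = ","),
              format(s$total_reads, big.mark = ","),
              100 * s$identified_fraction))
  hit <- s$per_genome_reads[s$per_genome_reads > 0]
  if (length(hit)) {
    cat(sprintf("  %d genome(s) with >= 1 identified read\n", length(hit)))
  }
  invisible(x)
}
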