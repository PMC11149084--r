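#' Specify a synthetic community
#'
#' Defines the reference universe and sampling conditions for the bundled
#' simulator: `n_genomes` random reference genomes of which
#' `present_ids` are actually sequenced, each present species at its target
#' coverage, with substitution errors at `error_rate` and Phred-informative
#' quality strings (correct bases draw high scores, erroneous bases low
#' scores, so the mean-Phred k-mer gate has signal to work with).
#'
#' Defaults describe a small uneven mock community: a 20-genome universe
#' with 10 species present at coverages log-spaced from 3x to 30x, and
#' 75 bp reads (Illumina short-read scale). The error/quality model has two
#' read populations, mirroring how real short-read runs behave: most reads
#' are high quality (correct-base Phred ~ N(37, 2)) with sporadic
#' substitutions at `error_rate`, while a `degraded_fraction` of reads is
#' uniformly poor (correct-base Phred ~ N(15, 4)) with substitutions at the
#' elevated `degraded_error_rate`. Erroneous bases draw their quality from
#' the low `qual_error` distribution in both populations, and all scores
#' are clipped to the Phred range 2..40. Whole-read degradation gives a
#' mean-Phred k-mer gate its operating point: a single bad base moves a
#' 31-mer's mean by less than one unit, but a degraded read's windows fall
#' below a mid-range threshold wholesale.
#'
#' @param n_genomes Genomes in the reference universe.
#' @param n_present Number of species actually present (ids `1..n_present`
#'   unless `present_ids` is given).
#' @param genome_length Genome length in bp (scalar or per genome); must be
#'   >= 10 * `read_length`.
#' @param coverage Target coverage per present species; default log-spaced
#'   from 3 to 30.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution probability in `[0, 1)` for
#'   reads in the high-quality population.
#' @param qual_correct,qual_error Mean and sd of the Phred score
#'   distribution for correct / erroneous bases, as `c(mean=, sd=)`.
#' @param degraded_fraction Fraction of reads drawn from the degraded
#'   population (0 disables it).
#' @param degraded_error_rate Per-base substitution probability within
#'   degraded reads; defaults to `10 * error_rate` (so `error_rate = 0`
#'   yields fully error-free reads).
#' @param qual_degraded Phred distribution of correct bases in degraded
#'   reads, as `c(mean=, sd=)`.
#' @param related_pairs Number of "related pair" genomes: for pair `p`, the
#'   `p`-th genome from the end is a mutated copy of genome `p`, creating
#'   shared k-mers between close relatives.
#' @param related_divergence Per-base substitution rate applied to the copy
#'   in a related pair.
#' @param present_ids Optional explicit ids of the present species.
#' @param seed Master seed; the full simulation is deterministic given the
#'   spec.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_genomes = 20, n_present = 10,
                           genome_length = 25000, coverage = NULL,
                           read_length = 75, error_rate = 0.005,
                           qual_correct = c(mean = 37, sd = 2),
                           qual_error = c(mean = 8, sd = 3),
                           degraded_fraction = 0.1,
                           degraded_error_rate = NULL,
                           qual_degraded = c(mean = 15, sd = 4),
                           related_pairs = 0, related_divergence = 0.02,
                           present_ids = NULL, seed = 1L) {
  present_ids <- present_ids %||% seq_len(n_present)
  if (!all(present_ids >= 1 & present_ids <= n_genomes))
    stopf("present_ids must lie in 1..n_genomes")
  coverage <- coverage %||% 10^seq(log10(3), log10(30),
                                   length.out = length(present_ids))
  coverage <- rep_len(coverage, length(present_ids))
  if (any(coverage <= 0)) stopf("coverages must be > 0")
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0, 1)")
  if (degraded_fraction < 0 || degraded_fraction > 1)
    stopf("degraded_fraction must be in [0, 1]")
  degraded_error_rate <- degraded_error_rate %||% min(10 * error_rate, 0.5)
  if (degraded_error_rate < 0 || degraded_error_rate >= 1)
    stopf("degraded_error_rate must be in [0, 1)")
  genome_length <- rep_len(genome_length, n_genomes)
  if (any(genome_length < 10 * read_length))
    stopf("genome_length must be >= 10 * read_length")
  if (related_pairs > floor(n_genomes / 2))
    stopf("too many related pairs for the universe size")
  qual_correct <- stats::setNames(as.numeric(qual_correct[1:2]),
                                  c("mean", "sd"))
  qual_error <- stats::setNames(as.numeric(qual_error[1:2]), c("mean", "sd"))
  qual_degraded <- stats::setNames(as.numeric(qual_degraded[1:2]),
                                   c("mean", "sd"))
  structure(list(n_genomes = as.integer(n_genomes),
                 present_ids = as.integer(present_ids),
                 genome_length = as.numeric(genome_length),
                 coverage = as.numeric(coverage),
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 qual_correct = qual_correct, qual_error = qual_error,
                 degraded_fraction = degraded_fraction,
                 degraded_error_rate = degraded_error_rate,
                 qual_degraded = qual_degraded,
                 related_pairs = as.integer(related_pairs),
                 related_divergence = related_divergence,
                 seed = as.integer(seed)),
            class = "community_spec")
}

DNA_BASES <- c("A", "C", "G", "T")

#' Generate the reference genomes of a community spec
#'
#' Genomes are i.i.d. uniform ACGT strings, deterministic under the spec
#' seed. With `related_pairs > 0`, the last `related_pairs` genomes are
#' mutated copies of the first ones, which plants shared k-mers between
#' close relatives (the dirty-entry mechanism's natural substrate).
#'
#' @param spec A `community_spec`.
#' @return A list of `genome_record` objects with names
#'   `species_01..species_G`.
#' @export
make_genomes <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(derive_seed(spec$seed, 101L), {
    seqs <- vapply(seq_len(spec$n_genomes), function(i)
      paste(sample(DNA_BASES, spec$genome_length[i], replace = TRUE),
            collapse = ""),
      character(1))
    if (spec$related_pairs > 0) {
      for (p in seq_len(spec$related_pairs)) {
        dst <- spec$n_genomes - spec$related_pairs + p
        seqs[dst] <- mutate_sequence(seqs[p], spec$related_divergence)
      }
    }
    lapply(seq_len(spec$n_genomes), function(i)
      new_genome_record(i, sprintf("species_%02d", i), seqs[i]))
  })
}

mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    cur <- match(chars[hit], DNA_BASES)
    shift <- sample.int(3, length(hit), replace = TRUE)
    chars[hit] <- DNA_BASES[((cur - 1 + shift) %% 4) + 1]
  }
  paste(chars, collapse = "")
}

#' Simulate reads from the present species of a community
#'
#' For each present species, `round(coverage * genome_length /
#' read_length)` reads are drawn uniformly over positions and strands.
#' Substitution errors are injected independently per base at
#' `spec$error_rate` (no indels); each base receives a Phred score drawn
#' from the correct-base distribution, overridden by the erroneous-base
#' distribution where an error was injected. The emitted read order is a
#' seeded permutation, and every read appears exactly once in the returned
#' truth table.
#'
#' @param genomes Genome list from [make_genomes()] (or compatible
#'   `genome_record`s).
#' @param spec The `community_spec`.
#' @return A list with `reads` (a `fastq_reads` object) and `truth`
#'   (`data.frame`: `read_id`, `genome_id`, `species`, `start`, `strand`,
#'   `read_length`), where `start` is the 1-based position of the fragment
#'   on the forward strand of its source genome.
#' @export
make_reads <- function(genomes, spec) {
  stopifnot(inherits(spec, "community_spec"))
  gt <- genome_table(genomes)
  rl <- spec$read_length
  with_seed(derive_seed(spec$seed, 202L), {
    frags <- vector("list", length(spec$present_ids))
    src <- vector("list", length(spec$present_ids))
    pos <- vector("list", length(spec$present_ids))
    str <- vector("list", length(spec$present_ids))
    for (j in seq_along(spec$present_ids)) {
      g <- spec$present_ids[j]
      L <- gt$total_length[g]
      n_reads <- round(spec$coverage[j] * L / rl)
      # reads are drawn from the genome's first sequence (simulated genomes
      # have exactly one)
      seq1 <- genomes[[g]]$sequences[1]
      starts <- sample.int(nchar(seq1) - rl + 1, n_reads, replace = TRUE)
      f <- substring(seq1, starts, starts + rl - 1)
      minus <- stats::runif(n_reads) < 0.5
      if (any(minus)) f[minus] <- reverse_complement(f[minus])
      frags[[j]] <- f
      src[[j]] <- rep.int(g, n_reads)
      pos[[j]] <- starts
      str[[j]] <- ifelse(minus, "-", "+")
    }
    f <- unlist(frags, use.names = FALSE)
    source_id <- unlist(src, use.names = FALSE)
    source_pos <- unlist(pos, use.names = FALSE)
    source_strand <- unlist(str, use.names = FALSE)
    n <- length(f)
    if (n == 0) {
      empty <- list(reads = new_fastq_reads(character(0), character(0),
                                            character(0)),
                    truth = data.frame(read_id = character(0),
                                       genome_id = integer(0),
                                       species = character(0),
                                       start = integer(0),
                                       strand = character(0),
                                       read_length = integer(0),
                                       stringsAsFactors = FALSE))
      return_value <- empty
    } else {
    N <- n * rl
    chars <- unlist(strsplit(f, "", fixed = TRUE), use.names = FALSE)
    degraded <- stats::runif(n) < spec$degraded_fraction
    base_rate <- ifelse(rep(degraded, each = rl), spec$degraded_error_rate,
                        spec$error_rate)
    err <- which(stats::runif(N) < base_rate)
    if (length(err)) {
      cur <- match(chars[err], DNA_BASES)
      shift <- sample.int(3, length(err), replace = TRUE)
      chars[err] <- DNA_BASES[((cur - 1 + shift) %% 4) + 1]
    }
    qm <- ifelse(rep(degraded, each = rl), spec$qual_degraded[["mean"]],
                 spec$qual_correct[["mean"]])
    qs <- ifelse(rep(degraded, each = rl), spec$qual_degraded[["sd"]],
                 spec$qual_correct[["sd"]])
    q <- round(stats::rnorm(N, qm, qs))
    if (length(err))
      q[err] <- round(stats::rnorm(length(err), spec$qual_error[["mean"]],
                                   spec$qual_error[["sd"]]))
    q <- pmin(40L, pmax(2L, as.integer(q)))
    big_bases <- paste(chars, collapse = "")
    big_qual <- rawToChar(as.raw(q + 33L))
    first <- seq.int(1L, by = rl, length.out = n)
    bases <- substring(big_bases, first, first + rl - 1L)
    qual <- substring(big_qual, first, first + rl - 1L)
    perm <- sample.int(n)
    read_id <- sprintf("read_%07d", seq_len(n))
    reads <- new_fastq_reads(read_id, bases[perm], qual[perm])
    truth <- data.frame(read_id = read_id,
                        genome_id = source_id[perm],
                        species = gt$name[source_id[perm]],
                        start = source_pos[perm],
                        strand = source_strand[perm],
                        read_length = rl,
                        stringsAsFactors = FALSE)
    return_value <- list(reads = reads, truth = truth)
    }
    return_value
  })
}

#' Simulate a full community and optionally write it to disk
#'
#' Convenience wrapper: generates genomes and reads and, when `out_dir` is
#' given, writes `genomes/species_XX.fasta`, `reads.fastq.gz`, `truth.tsv`
#' and the locked spec as `spec.json`.
#'
#' @param spec A `community_spec`.
#' @param out_dir Optional output directory.
#' @return A list with `genomes`, `reads`, `truth` and `spec`.
#' @export
simulate_community <- function(spec, out_dir = NULL) {
  genomes <- make_genomes(spec)
  sim <- make_reads(genomes, spec)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "genomes"), recursive = TRUE,
               showWarnings = FALSE)
    for (g in genomes)
      write_genome_fasta(g, file.path(out_dir, "genomes",
                                      paste0(g$name, ".fasta")))
    write_fastq(sim$reads, file.path(out_dir, "reads.fastq.gz"))
    utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(spec), file.path(out_dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(genomes = genomes, reads = sim$reads, truth = sim$truth, spec = spec)
}
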