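#' Run the full identification pipeline
#'
#' Wires the stages end to end: build (or reuse) the index, classify the
#' reads, compute approximate coverages, cluster them and drop the
#' lowest-mean cluster, and -- when a truth set is given -- score the kept
#' species. When `out_dir` is given, all artifacts are written there
#' (`config.json` with the fully resolved parameters, `assignments.tsv`,
#' `report.tsv`, `stats.json` and, with truth, `metrics.json`).
#'
#' @param genomes List of `genome_record`s, a character vector of FASTA
#'   paths, or a prebuilt `bloom_index`.
#' @param reads A `fastq_reads` object or a FASTQ path.
#' @param k,n_hash,m,master_seed Index parameters (see [build_index()]);
#'   ignored when `genomes` is already a `bloom_index`.
#' @param majority_threshold,min_kmer_quality Classifier parameters (see
#'   [classify_sample()]).
#' @param K,scale,cluster_seed Coverage-clustering parameters (see
#'   [cluster_coverages()]).
#' @param truth_species Optional character vector of species truly present.
#' @param out_dir Optional output directory.
#' @return A list: `index`, `classification`, `coverage`, `clusters`,
#'   `report`, and `evaluation` (NULL without truth).
#' @export
run_all <- function(genomes, reads, k = 31, n_hash = 3, m = NULL,
                    master_seed = 1L, majority_threshold = 0.5,
                    min_kmer_quality = 0, K = 2, scale = "log10",
                    cluster_seed = 1L, truth_species = NULL,
                    out_dir = NULL) {
  if (is.character(genomes)) genomes <- read_fasta_genomes(genomes)
  index <- if (inherits(genomes, "bloom_index")) genomes
           else build_index(genomes, k = k, n_hash = n_hash, m = m,
                            master_seed = master_seed)
  if (is.character(reads)) reads <- read_fastq(reads)

  cls <- classify_sample(index, reads,
                         majority_threshold = majority_threshold,
                         min_kmer_quality = min_kmer_quality)
  cov <- compute_coverages(cls$assignments, index$genome_table)
  if (nrow(cov) > 0) {
    clu <- cluster_coverages(cov, K = K, scale = scale, seed = cluster_seed)
    report <- filter_species(cov, clu)
  } else {
    clu <- NULL
    report <- structure(list(kept = cov, removed = cov,
                             params = list(K = K, scale = scale,
                                           seed = cluster_seed,
                                           filtered = FALSE)),
                        class = "prediction_report")
  }
  evaluation <- if (!is.null(truth_species))
    score_species_sets(report$kept$species, truth_species) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    config <- list(k = index$k, n_hash = index$n_hash, m = index$m,
                   master_seed = index$master_seed,
                   majority_threshold = majority_threshold,
                   min_kmer_quality = min_kmer_quality, K = K, scale = scale,
                   cluster_seed = cluster_seed)
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    write_assignments(cls$assignments, file.path(out_dir, "assignments.tsv"))
    write_prediction_report(report, file.path(out_dir, "report.tsv"))
    jsonlite::write_json(cls$stats[c("total_reads", "identified_reads",
                                     "identified_fraction")],
                         file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(evaluation))
      jsonlite::write_json(unclass(evaluation),
                           file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  list(index = index, classification = cls, coverage = cov, clusters = clu,
       report = report, evaluation = evaluation)
}
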