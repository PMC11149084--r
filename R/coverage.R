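#' Approximate per-species genomic coverage from identified reads
#'
#' Coverage is the total length of the reads assigned to a species divided
#' by its genome length, i.e. the usual sequencing-depth estimator
#' restricted to identified reads. Species with zero identified reads do
#' not appear in the table.
#'
#' @param assignments Assignment `data.frame` (the `assignments` element of
#'   [classify_sample()], or [read_assignments()] output). If it carries no
#'   `read_length` column, a uniform `read_length` must be supplied.
#' @param genome_table Genome table (see [genome_table()]) covering every
#'   assigned id.
#' @param read_length Uniform read length in bp, used only when
#'   `assignments` has no `read_length` column.
#' @return A `data.frame` with one row per species holding >= 1 identified
#'   read: `genome_id`, `species`, `n_reads`, `total_bases`,
#'   `genome_length`, `coverage`.
#' @export
compute_coverages <- function(assignments, genome_table, read_length = NULL) {
  empty <- data.frame(genome_id = integer(0), species = character(0),
                      n_reads = integer(0), total_bases = numeric(0),
                      genome_length = numeric(0), coverage = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(assignments) || nrow(assignments) == 0) return(empty)
  ids <- assignments$genome_id
  bad <- setdiff(unique(ids), genome_table$genome_id)
  if (length(bad))
    stopf("assigned genome id(s) missing from genome table: %s",
          paste(sort(bad), collapse = ", "))
  if (!"read_length" %in% names(assignments)) {
    if (is.null(read_length))
      stopf(paste("assignments carry no read_length column;",
                  "supply a uniform read_length"))
    assignments$read_length <- read_length
  }
  n_reads <- tapply(assignments$read_length, ids, length)
  bases <- tapply(as.numeric(assignments$read_length), ids, sum)
  gid <- as.integer(names(n_reads))
  ord <- order(gid)
  gid <- gid[ord]
  row <- match(gid, genome_table$genome_id)
  data.frame(genome_id = gid,
             species = genome_table$name[row],
             n_reads = as.integer(n_reads[ord]),
             total_bases = as.numeric(bases[ord]),
             genome_length = genome_table$total_length[row],
             coverage = as.numeric(bases[ord]) / genome_table$total_length[row],
             stringsAsFactors = FALSE)
}

#' Cluster species by approximate coverage
#'
#' One-dimensional K-means over the (scaled) coverage values, used to
#' separate species that are genuinely present (nontrivial coverage) from
#' false-positive calls whose coverage is exceptionally low. Clustering is
#' done on `log10(coverage)` by default because coverages span orders of
#' magnitude; the linear scale is available. With fewer species than `K`,
#' or when all (scaled) coverages are equal, clustering is skipped and a
#' "no filtering" sentinel is returned so that [filter_species()] keeps
#' everything.
#'
#' @param coverage_table Output of [compute_coverages()] or
#'   [ingest_external_assignments()].
#' @param K Number of clusters (>= 2, default 2: present vs artifact).
#' @param scale `"log10"` (default) or `"linear"`.
#' @param seed Seed for the K-means restarts; recorded in the result.
#' @return A `coverage_clusters` object: `K`, `scale`, `seed`, `filtered`
#'   (FALSE for the sentinel), `labels` (integer per species, named),
#'   `cluster_means` (on the clustering scale) and `lowest_mean_cluster`
#'   (ties broken towards the smallest label).
#' @export
cluster_coverages <- function(coverage_table, K = 2, scale = c("log10", "linear"),
                              seed = 1L) {
  scale <- match.arg(scale)
  if (K < 2) stopf("K must be >= 2")
  if (is.null(coverage_table) || nrow(coverage_table) == 0)
    stopf("coverage table is empty; nothing to cluster")
  x <- if (scale == "log10") log10(coverage_table$coverage)
       else coverage_table$coverage
  sentinel <- function(reason) {
    structure(list(K = as.integer(K), scale = scale, seed = as.integer(seed),
                   filtered = FALSE, reason = reason,
                   labels = stats::setNames(rep(1L, nrow(coverage_table)),
                                            coverage_table$species),
                   cluster_means = NULL, lowest_mean_cluster = NA_integer_),
              class = "coverage_clusters")
  }
  if (nrow(coverage_table) < K)
    return(sentinel(sprintf("fewer species (%d) than clusters (K = %d)",
                            nrow(coverage_table), K)))
  if (length(unique(x)) < K)
    return(sentinel("fewer distinct coverage values than clusters"))
  if (nrow(coverage_table) == K) {
    # exactly K species: the optimal partition is one species per cluster
    labels <- seq_len(K)
    means <- x
  } else {
    km <- with_seed(seed,
                    stats::kmeans(x, centers = K, nstart = 50,
                                  iter.max = 100))
    labels <- as.integer(km$cluster)
    means <- as.numeric(km$centers)
  }
  structure(list(K = as.integer(K), scale = scale, seed = as.integer(seed),
                 filtered = TRUE, reason = NULL,
                 labels = stats::setNames(as.integer(labels),
                                          coverage_table$species),
                 cluster_means = means,
                 lowest_mean_cluster = which.min(means)),
            class = "coverage_clusters")
}

#' @export
print.coverage_clusters <- function(x, ...) {
  if (!x$filtered) {
    cat(sprintf("<coverage_clusters> no filtering (%s)\n", x$reason))
  } else {
    cat(sprintf("<coverage_clusters> K=%d on %s scale, seed=%d\n",
                x$K, x$scale, x$seed))
    for (j in seq_len(x$K))
      cat(sprintf("  cluster %d: %d species, mean %.3f%s\n", j,
                  sum(x$labels == j), x$cluster_means[j],
                  if (j == x$lowest_mean_cluster) "  <- lowest (removed)" else ""))
  }
  invisible(x)
}

#' Remove the lowest-coverage cluster as false positives
#'
#' Species in the cluster with the lowest mean coverage are reported as
#' removed (false positives); all others are kept as the predicted
#' community. Exactly one cluster is removed regardless of `K`. On a
#' "no filtering" sentinel every species is kept.
#'
#' @param coverage_table Output of [compute_coverages()].
#' @param clusters Output of [cluster_coverages()] on the same table.
#' @return A `prediction_report`: `kept` and `removed` coverage tables
#'   (augmented with `cluster` and `cluster_mean` columns) and `params`.
#' @export
filter_species <- function(coverage_table, clusters) {
  stopifnot(inherits(clusters, "coverage_clusters"))
  if (nrow(coverage_table) != length(clusters$labels) ||
      !identical(unname(names(clusters$labels)), coverage_table$species))
    stopf("cluster labels do not cover the coverage table")
  tab <- coverage_table
  tab$cluster <- unname(clusters$labels)
  tab$cluster_mean <- if (clusters$filtered)
    clusters$cluster_means[tab$cluster] else NA_real_
  drop <- clusters$filtered & tab$cluster == clusters$lowest_mean_cluster
  structure(list(kept = tab[!drop, , drop = FALSE],
                 removed = tab[drop, , drop = FALSE],
                 params = list(K = clusters$K, scale = clusters$scale,
                               seed = clusters$seed,
                               filtered = clusters$filtered)),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %d species kept, %d removed%s\n",
              nrow(x$kept), nrow(x$removed),
              if (!x$params$filtered) " (no filtering applied)" else ""))
  if (nrow(x$kept)) {
    cat("  kept:\n")
    print(x$kept[, c("species", "n_reads", "coverage")], row.names = FALSE)
  }
  if (nrow(x$removed)) {
    cat(sprintf("  removed (lowest-mean cluster): %s\n",
                paste(x$removed$species, collapse = ", ")))
  }
  invisible(x)
}

#' Write a prediction report to TSV
#'
#' Columns: `species`, `n_reads`, `coverage`, `cluster`, `cluster_mean`,
#' `kept`.
#'
#' @param report A `prediction_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(report, path) {
  stopifnot(inherits(report, "prediction_report"))
  tab <- rbind(cbind(report$kept, kept = TRUE),
               cbind(report$removed, kept = FALSE))
  tab <- tab[order(-tab$coverage),
             c("species", "n_reads", "coverage", "cluster", "cluster_mean",
               "kept")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a coverage table from an external classifier's assignments
#'
#' Applies the coverage computation to any tool's per-read species calls so
#' that the clustering filter can be used downstream of other classifiers.
#' The assignment TSV needs columns `read_id` and `species` (a
#' `genome_name` column is accepted as an alias) and optionally
#' `read_length`; without that column a uniform `read_length` must be
#' given.
#'
#' @param path TSV of per-read species assignments.
#' @param genome_lengths Genome lengths: a TSV path with columns
#'   `name`/`species` and `length` (bp), a two-column `data.frame`, or a
#'   named numeric vector.
#' @param read_length Uniform read length in bp (used when the file has no
#'   `read_length` column).
#' @return A coverage `data.frame` as from [compute_coverages()].
#' @export
ingest_external_assignments <- function(path, genome_lengths,
                                        read_length = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lens <- resolve_genome_lengths(genome_lengths)
  if (nrow(df) == 0)
    return(compute_coverages(NULL, NULL))
  if (!"species" %in% names(df) && "genome_name" %in% names(df))
    names(df)[names(df) == "genome_name"] <- "species"
  missing <- setdiff(c("read_id", "species"), names(df))
  if (length(missing))
    stopf("'%s' lacks column(s): %s", path, paste(missing, collapse = ", "))
  key <- normalize_species(df$species)
  lens_key <- normalize_species(names(lens))
  unresolved <- setdiff(unique(key), lens_key)
  if (length(unresolved))
    stopf("species name(s) not resolvable against genome lengths: %s",
          paste(sort(unresolved), collapse = ", "))
  gid <- match(key, lens_key)
  if (!"read_length" %in% names(df)) {
    if (is.null(read_length))
      stopf(paste("'%s' has no read_length column;",
                  "supply a uniform read_length"), path)
    df$read_length <- read_length
  }
  gt <- data.frame(genome_id = seq_along(lens), name = names(lens),
                   total_length = as.numeric(lens), stringsAsFactors = FALSE)
  compute_coverages(data.frame(read_id = df$read_id, genome_id = gid,
                               read_length = df$read_length,
                               stringsAsFactors = FALSE),
                    gt)
}

resolve_genome_lengths <- function(genome_lengths) {
  if (is.character(genome_lengths) && length(genome_lengths) == 1) {
    df <- utils::read.delim(genome_lengths, stringsAsFactors = FALSE)
    genome_lengths <- df
  }
  if (is.data.frame(genome_lengths)) {
    name_col <- intersect(c("name", "species", "genome_name"),
                          names(genome_lengths))[1]
    len_col <- intersect(c("length", "total_length", "genome_length", "bp"),
                         names(genome_lengths))[1]
    if (is.na(name_col) || is.na(len_col))
      stopf("genome length table needs a name column and a length column")
    out <- stats::setNames(as.numeric(genome_lengths[[len_col]]),
                           as.character(genome_lengths[[name_col]]))
  } else if (is.numeric(genome_lengths) && !is.null(names(genome_lengths))) {
    out <- genome_lengths
  } else {
    stopf("genome_lengths must be a TSV path, a data.frame or a named vector")
  }
  if (any(out <= 0)) stopf("genome lengths must be positive")
  out
}
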