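#' Read reference genomes from FASTA files
#'
#' Each FASTA file is treated as one genome: all of its records (chromosome,
#' plasmids, contigs) share a single genome id. Ids are assigned 1..G in
#' input order; id 0 and -1 are reserved index sentinels. Bases are
#' uppercased and any character outside `A,C,G,T,N` (including IUPAC
#' ambiguity codes) is mapped to `N`; k-mers containing `N` are skipped by
#' all downstream operations.
#'
#' @param paths Character vector of FASTA file paths (optionally gzipped),
#'   one file per genome.
#' @param names Optional character vector of genome names, recycled against
#'   `paths`. Defaults to the file stem.
#' @return A list of `genome_record` objects, each with fields `genome_id`,
#'   `name`, `sequences` (character vector of uppercase DNA strings) and
#'   `total_length` (sum of sequence lengths, bp).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1", "ACGTACGT", ">plasmid", "GGGTTT"), fa)
#' g <- read_fasta_genomes(fa)
#' g[[1]]$total_length  # 14
#' @export
read_fasta_genomes <- function(paths, names = NULL) {
  stopifnot(is.character(paths), length(paths) >= 1)
  if (is.null(names)) {
    names <- vapply(paths, function(p) {
      b <- basename(p)
      b <- sub("\\.gz$", "", b)
      tools::file_path_sans_ext(b)
    }, character(1), USE.NAMES = FALSE)
  }
  names <- rep_len(as.character(names), length(paths))
  if (anyDuplicated(names))
    stopf("duplicate genome name(s): %s",
          paste(unique(names[duplicated(names)]), collapse = ", "))
  genomes <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    recs <- tryCatch(Biostrings::readBStringSet(paths[i]),
                     error = function(e)
                       stopf("cannot read FASTA file '%s': %s",
                             paths[i], conditionMessage(e)))
    if (length(recs) == 0)
      stopf("empty FASTA file: '%s'", paths[i])
    seqs <- toupper(as.character(recs))
    seqs <- gsub("[^ACGTN]", "N", seqs)
    genomes[[i]] <- new_genome_record(i, names[i], unname(seqs))
  }
  genomes
}

new_genome_record <- function(genome_id, name, sequences) {
  stopifnot(genome_id >= 1)
  structure(list(genome_id = as.integer(genome_id),
                 name = as.character(name),
                 sequences = as.character(sequences),
                 total_length = sum(as.numeric(nchar(sequences)))),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> id=%d  name=%s  %d sequence(s), %s bp\n",
              x$genome_id, x$name, length(x$sequences),
              format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Genome id/name/length table
#'
#' Summarises a list of genome records into the table used by the index and
#' the coverage computation (id, name, total length in bp).
#'
#' @param genomes A list of `genome_record` objects.
#' @return A `data.frame` with columns `genome_id`, `name`, `total_length`.
#' @export
genome_table <- function(genomes) {
  stopifnot(length(genomes) >= 1)
  data.frame(genome_id = vapply(genomes, `[[`, integer(1), "genome_id"),
             name = vapply(genomes, `[[`, character(1), "name"),
             total_length = vapply(genomes, `[[`, numeric(1), "total_length"),
             stringsAsFactors = FALSE)
}

#' Write one genome to a FASTA file
#'
#' @param genome A `genome_record`.
#' @param path Output path; `.gz` suffix enables compression.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequences)
  names(x) <- sprintf("%s_seq%d", genome$name, seq_along(genome$sequences))
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads a Phred+33 FASTQ file (optionally gzipped) into an in-memory read
#' set. Qualities are kept as Phred+33 strings for compactness; use
#' [phred_qualities()] to decode them to integer scores.
#'
#' @param path FASTQ file path.
#' @return A `fastq_reads` object with fields `read_id`, `bases` and `qual`
#'   (Phred+33 quality strings, same lengths as `bases`).
#' @export
read_fastq <- function(path) {
  tryCatch({
    # Biostrings warns about dropped metadata columns on plain FASTQ; benign
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    new_fastq_reads(read_id = names(x) %||% character(0),
                    bases = as.character(x),
                    qual = suppressWarnings(
                      as.character(Biostrings::quality(x))))
  }, error = function(e)
    stopf("cannot read FASTQ file '%s': %s", path, conditionMessage(e)))
}

new_fastq_reads <- function(read_id, bases, qual) {
  read_id <- as.character(read_id)
  bases <- unname(as.character(bases))
  qual <- unname(as.character(qual))
  if (length(bases) != length(qual) || length(bases) != length(read_id))
    stopf("read_id, bases and qual must have equal lengths")
  bad <- which(nchar(bases) != nchar(qual))
  if (length(bad))
    stopf("base/quality length mismatch for read(s): %s",
          paste(utils::head(read_id[bad], 5), collapse = ", "))
  structure(list(read_id = read_id, bases = bases, qual = qual),
            class = "fastq_reads")
}

#' @export
length.fastq_reads <- function(x) length(x$bases)

#' @export
print.fastq_reads <- function(x, ...) {
  cat(sprintf("<fastq_reads> %d read(s)", length(x)))
  if (length(x) > 0)
    cat(sprintf(", lengths %d..%d bp", min(nchar(x$bases)), max(nchar(x$bases))))
  cat("\n")
  invisible(x)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param reads A `fastq_reads` object.
#' @return A list of integer vectors, one per read.
#' @export
phred_qualities <- function(reads) {
  lapply(reads$qual, function(s)
    if (nchar(s) == 0) integer(0) else utf8ToInt(s) - 33L)
}

#' Write reads to a FASTQ file
#'
#' @param reads A `fastq_reads` object.
#' @param path Output path; `.gz` suffix enables compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$bases),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write identified-read assignments to TSV
#'
#' Writes one row per identified read with columns `read_id`, `genome_id`,
#' `genome_name`, `votes_for`, `votes_total`. Discarded reads are omitted.
#'
#' @param assignments Assignment `data.frame` (e.g. the `assignments`
#'   element of [classify_sample()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  cols <- c("read_id", "genome_id", "genome_name", "votes_for", "votes_total")
  missing <- setdiff(cols, names(assignments))
  if (length(missing))
    stopf("assignments lack column(s): %s", paste(missing, collapse = ", "))
  out <- assignments[!is.na(assignments$genome_id), cols, drop = FALSE]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e)
    stopf("cannot write assignments to '%s': %s", path, conditionMessage(e)))
  invisible(path)
}

#' Read an assignment TSV written by [write_assignments()]
#'
#' @param path TSV path.
#' @return A `data.frame` with the five assignment columns.
#' @export
read_assignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c("read_id", "genome_id", "genome_name", "votes_for", "votes_total")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("'%s' lacks assignment column(s): %s", path,
          paste(missing, collapse = ", "))
  df$read_id <- as.character(df$read_id)
  df$genome_id <- as.integer(df$genome_id)
  df$genome_name <- as.character(df$genome_name)
  df$votes_for <- as.integer(df$votes_for)
  df$votes_total <- as.integer(df$votes_total)
  df[cols]
}
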