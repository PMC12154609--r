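# File interfaces: FASTA (via Biostrings, 60-column wrap), BED6 annotations,
# and the TSV tables the pipeline exchanges (mate pairs, identity profiles,
# dot matches, read verdicts).

#' Read FASTA sequences
#' @param path FASTA file.
#' @return Named uppercase character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write FASTA sequences (60-column wrap)
#' @param seqs Named character vector (or `simulated_genome`).
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequences(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60)
  invisible(path)
}

#' Write BED6 annotations
#'
#' `name` carries the class label; score 0, strand `+`.
#' @param regions data.frame with `start`, `end`, a label column
#'   (`label`), and optionally `seq_name`.
#' @param path Output file.
#' @param seq_name Fallback sequence name when `regions` has none.
#' @export
write_bed <- function(regions, path, seq_name = "chrY") {
  chrom <- if ("seq_name" %in% names(regions)) regions$seq_name else seq_name
  df <- data.frame(chrom = chrom, start = regions$start, end = regions$end,
                   name = regions$label, score = 0L, strand = "+")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file of labeled regions
#' @param path BED file (>= 4 columns).
#' @return data.frame: `seq_name`, `start`, `end`, `label`.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("expected BED with at least 4 columns")
  data.frame(seq_name = df[[1]], start = df[[2]], end = df[[3]],
             label = df[[4]], stringsAsFactors = FALSE)
}

#' Write / read a mate-pair TSV (`contig_a pos_a contig_b pos_b`)
#' @param pairs `mate_pairs` data.frame.
#' @param path File path.
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs[, c("contig_a", "pos_a", "contig_b", "pos_b")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig_a", "pos_a", "contig_b", "pos_b") %in% names(df)))
  structure(df, class = c("mate_pairs", "data.frame"))
}

#' Write an identity profile TSV (`start window identity n_compared`)
#' @param profile [sliding_identity()] result.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(start = profile$window_start, window = profile$window_len,
                   identity = profile$identity, n_compared = profile$n_compared)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write reads as FASTA
#' @param reads `read_set` data.frame.
#' @param path Output file.
#' @export
write_reads_fasta <- function(reads, path) {
  write_fasta(setNames(reads$seq, reads$read_id), path)
}

#' Write a simulated genome (FASTA + truth BED)
#' @param g `simulated_genome`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_genome <- function(g, dir) {
  stopifnot(inherits(g, "simulated_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(g$sequences, file.path(dir, "genome.fa"))
  write_bed(g$truth, file.path(dir, "truth.bed"))
  invisible(dir)
}
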