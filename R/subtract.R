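# Electronic subtraction: classify male reads as Y-candidates by the absence
# of their k-mers from a female k-mer set. K-mers are canonical (lexicographic
# minimum of k-mer and reverse complement), so strand is irrelevant.

reads_as_character <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot("seq" %in% names(reads))
    setNames(toupper(reads$seq),
             if ("read_id" %in% names(reads)) reads$read_id else
               sprintf("read%d", seq_len(nrow(reads))))
  } else {
    s <- as_sequences(reads)
    if (is.null(names(s))) names(s) <- sprintf("read%d", seq_along(s))
    s
  }
}

#' Build a canonical k-mer set from reads
#'
#' Canonical k-mers observed at least `min_count` times across all reads.
#' The default `k = 31` (odd, so no k-mer is its own reverse complement) and
#' `min_count = 2` (suppresses singleton sequencing-error k-mers) are the
#' package's declared conventions.
#'
#' @param reads A `read_set` data.frame, character vector, or `DNAStringSet`.
#' @param k K-mer size, 1-32.
#' @param min_count Minimum multiplicity.
#' @return `kmer_set` list: `k`, `min_count`, `codes` (opaque encoded
#'   k-mers), `n` (set size).
#' @export
build_kmer_set <- function(reads, k = 31, min_count = 2) {
  rs <- reads_as_character(reads)
  if (!length(rs)) stop("no reads")
  if (k > max(nchar(rs))) stop("k larger than every read")
  codes <- cpp_kmer_set(unname(rs), as.integer(k), as.integer(min_count))
  structure(list(k = as.integer(k), min_count = as.integer(min_count),
                 codes = codes, n = length(codes)),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> k=%d, min_count=%d, %d canonical k-mers\n",
              x$k, x$min_count, x$n))
  invisible(x)
}

#' Decode a k-mer set
#'
#' The canonical k-mers as strings (mainly for inspection and testing).
#' @param ks A `kmer_set`.
#' @return Character vector of canonical k-mers.
#' @export
kmers <- function(ks) {
  stopifnot(inherits(ks, "kmer_set"))
  cpp_decode_codes(ks$codes, ks$k)
}

#' Classify male reads against a female k-mer set
#'
#' Per read, the fraction of its canonical k-mers absent from the female set;
#' reads at or above `threshold` are Y-candidates. Reads shorter than k (or
#' without a single ACGT-only k-mer) get a missing fraction and verdict
#' `not-Y`. Reads from Y regions shared with the X (PAR, X-transposed) carry
#' female k-mers and are deliberately classified `not-Y`: the target is
#' male-specific sequence.
#'
#' @param male_reads Reads (as in [build_kmer_set()]).
#' @param female A [build_kmer_set()] result from female reads.
#' @param threshold Absent-fraction decision threshold in `[0, 1]`.
#' @return `read_verdicts` data.frame: `read_id`, `absent_fraction`,
#'   `label` (`Y-candidate` / `not-Y`).
#' @export
classify_reads <- function(male_reads, female, threshold = 0.5) {
  stopifnot(inherits(female, "kmer_set"))
  rs <- reads_as_character(male_reads)
  af <- cpp_absent_fraction(unname(rs), female$k, female$codes)
  structure(data.frame(read_id = names(rs), absent_fraction = af,
                       label = ifelse(!is.na(af) & af >= threshold,
                                      "Y-candidate", "not-Y"),
                       stringsAsFactors = FALSE),
            threshold = threshold,
            class = c("read_verdicts", "data.frame"))
}
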