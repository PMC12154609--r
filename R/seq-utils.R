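# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars; coordinates are 0-based half-open throughout.

BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' I.i.d. bases at a target GC fraction (A and T each get `(1-gc)/2`,
#' C and G each `gc/2`). Uses the current RNG state; seed control belongs to
#' the caller (or to [simulate_pair()] via the blueprint seed).
#'
#' @param n Length in bases.
#' @param gc Target GC fraction in (0, 1).
#' @return A single uppercase character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.4) {
  stopifnot(n > 0, gc > 0, gc < 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(BASES[sample.int(4L, n, replace = TRUE, prob = p)], collapse = "")
}

#' Reverse complement
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Substitute each site independently with probability `rate`; substituted
# sites always change to one of the three other bases (uniformly), so the
# pairwise mismatch probability against the input equals `rate` exactly.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    cur <- match(v[hit], BASES)
    # uniform over the 3 non-current bases
    off <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- BASES[((cur - 1L + off) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

# Run `expr` under seed `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Raw-byte view of a sequence, plus an ACGT mask (uppercase only; simulator
# output is always uppercase, file input is uppercased on read).
seq_raw <- function(seq) charToRaw(seq)

ACGT_RAW <- charToRaw("ACGT")

is_acgt <- function(r) r %in% ACGT_RAW

# Accept a simulated_genome, DNAStringSet, or named character vector and
# return named uppercase character sequences.
as_sequences <- function(x) {
  if (inherits(x, "simulated_genome")) return(x$sequences)
  if (inherits(x, "DNAStringSet")) {
    out <- toupper(as.character(x))
    names(out) <- names(x)
    return(out)
  }
  if (is.character(x)) {
    out <- toupper(x)
    if (is.null(names(out)) && length(out) == 1) names(out) <- "seq1"
    return(out)
  }
  stop("cannot interpret input as DNA sequences")
}

one_seq <- function(x) {
  s <- as_sequences(x)
  if (length(s) != 1) stop("expected exactly one sequence")
  unname(s)
}
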