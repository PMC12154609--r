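# Shared helpers: brute-force oracles and small constructors used across
# test files. Oracles deliberately avoid the package's own fast paths.

rc_oracle <- function(x) {
  vapply(x, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    "", USE.NAMES = FALSE)
}

# O(n*m) all-pairs window comparison, both strands; the reference for the
# hash-based dot plots.
oracle_dotplot <- function(a, b = NULL, w, step = w) {
  self <- is.null(b)
  if (self) b <- a
  sa <- seq(0, nchar(a) - w, by = step)
  sb <- seq(0, nchar(b) - w, by = step)
  wa <- substring(a, sa + 1, sa + w)
  wb <- substring(b, sb + 1, sb + w)
  oka <- !grepl("[^ACGT]", wa)
  okb <- !grepl("[^ACGT]", wb)
  rows <- list()
  for (ii in seq_along(sa)) {
    if (!oka[ii]) next
    rcw <- rc_oracle(wa[ii])
    for (jj in seq_along(sb)) {
      if (!okb[jj]) next
      if (self && sb[jj] <= sa[ii]) next   # upper triangle, diagonal excluded
      if (wa[ii] == wb[jj])
        rows[[length(rows) + 1]] <- data.frame(i = sa[ii], j = sb[jj], strand = "+")
      if (rcw == wb[jj])
        rows[[length(rows) + 1]] <- data.frame(i = sa[ii], j = sb[jj], strand = "-")
    }
  }
  if (!length(rows))
    return(data.frame(i = integer(0), j = integer(0), strand = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$i, out$j, out$strand), ]
}

match_key <- function(m) {
  d <- as.data.frame(m)[, c("i", "j", "strand")]
  d$i <- as.integer(d$i); d$j <- as.integer(d$j); d$strand <- as.character(d$strand)
  d <- d[order(d$i, d$j, d$strand), ]
  rownames(d) <- NULL
  d
}

# exact tandem repeat of a given unit
tandem <- function(unit, copies) paste(rep(unit, copies), collapse = "")

# per-base label vector from a region table (for accuracy computations)
label_vector <- function(regions, L) {
  v <- character(L)
  for (k in seq_len(nrow(regions)))
    if (regions$end[k] > regions$start[k])
      v[(regions$start[k] + 1):regions$end[k]] <- regions$label[k]
  v
}

# fragment a random scaffold, simulate + filter pairs, recover the order
recover_scaffold <- function(seed, n_contigs = 5, contig_bp = 100000,
                             n_pairs = 10000) {
  set.seed(seed)
  L <- n_contigs * contig_bp
  scaf <- c(scaffold = random_dna(L))
  brk <- list(scaffold = contig_bp * seq_len(n_contigs - 1))
  contigs <- fragment_genome(scaf, brk)
  pairs <- simulate_hic_pairs(scaf, n_pairs, 1.0, seed = seed, breaks = brk)
  kept <- filter_pairs(pairs, unique_kmers(contigs))
  so <- order_and_orient(flank_link_matrix(kept, contigs))
  want <- names(contigs)
  fwd <- identical(so$contig, want) && all(so$orientation == "+")
  bwd <- identical(so$contig, rev(want)) && all(so$orientation == "-")
  fwd || bwd
}
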