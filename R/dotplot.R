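# Exact-match windowed dot plots. A dot is 100% identity of a w-bp window
# between two positions (forward or reverse complement), the same definition
# as classic assembly-paper self/pairwise dot plots. The tested artifact is
# the match table; rendering is a thin layer on top.

win_starts0 <- function(len, w, step) {
  if (w < 1 || w > len) stop("window must satisfy 1 <= w <= sequence length")
  if (step < 1) stop("step must be >= 1")
  as.integer(seq.int(0L, len - w, by = step))
}

extract_windows <- function(seq, starts0, w) {
  substring(seq, starts0 + 1L, starts0 + w)
}

#' Index sequence windows by content
#'
#' Maps each w-bp window (at starts 0, step, 2*step, ...) to its canonical
#' key, the lexicographic minimum of the window and its reverse complement.
#' Windows containing non-ACGT characters are skipped.
#'
#' @param seq DNA string.
#' @param w Window length in bp.
#' @param step Step between window starts (default `w`: non-overlapping).
#' @return A `window_index`: data.frame with `key` (canonical content),
#'   `pos` (0-based start), `content_is_rc` (whether the canonical key is the
#'   reverse complement of the actual window content); attributes `w`,
#'   `step`, `seq_len`.
#' @export
window_index <- function(seq, w, step = w) {
  seq <- one_seq(seq)
  if (nchar(seq) == 0) stop("empty sequence")
  starts0 <- win_starts0(nchar(seq), w, step)
  win <- extract_windows(seq, starts0, w)
  ok <- !grepl("[^ACGT]", win)
  win <- win[ok]; starts0 <- starts0[ok]
  rcw <- revcomp(win)
  key <- pmin(win, rcw)
  structure(data.frame(key = key, pos = starts0, content_is_rc = key != win,
                       stringsAsFactors = FALSE),
            w = w, step = step, seq_len = nchar(seq),
            class = c("window_index", "data.frame"))
}

new_dot_matches <- function(i, j, strand, w, mode) {
  o <- order(i, j, strand)
  structure(data.frame(i = as.integer(i)[o], j = as.integer(j)[o],
                       strand = strand[o],
                       w = rep_len(as.integer(w), length(i)),
                       stringsAsFactors = FALSE),
            mode = mode, class = c("dot_matches", "data.frame"))
}

#' @export
print.dot_matches <- function(x, ...) {
  cat(sprintf("<dot_matches> %s, w=%d: %d matches (%d forward, %d reverse)\n",
              attr(x, "mode") %||% "?", if (nrow(x)) x$w[1] else NA_integer_,
              nrow(x), sum(x$strand == "+"), sum(x$strand == "-")))
  if (nrow(x)) print(head(as.data.frame(x), 10))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

group_pairs <- function(pos_list) {
  # all unordered pairs within each group of positions
  keep <- pos_list[lengths(pos_list) >= 2L]
  if (!length(keep)) return(list(i = integer(0), j = integer(0)))
  res <- lapply(keep, function(p) utils::combn(sort(p), 2L))
  m <- do.call(cbind, res)
  list(i = m[1, ], j = m[2, ])
}

#' Triangular self dot plot
#'
#' Exact-match windowed comparison of a sequence against itself. Forward
#' matches are reported with `j > i` (upper triangle, diagonal excluded);
#' reverse-complement matches with `i < j` by convention. Equals the
#' brute-force all-pairs window comparison.
#'
#' @inheritParams window_index
#' @return `dot_matches` data.frame: `i`, `j` (0-based window starts),
#'   `strand` (`+` forward, `-` reverse complement), `w`.
#' @export
self_dotplot <- function(seq, w, step = w) {
  seq <- one_seq(seq)
  starts0 <- win_starts0(nchar(seq), w, step)
  win <- extract_windows(seq, starts0, w)
  ok <- !grepl("[^ACGT]", win)
  win <- win[ok]; starts0 <- starts0[ok]
  if (!length(win)) return(new_dot_matches(integer(0), integer(0), character(0), w, "self"))
  fmap <- split(starts0, win)
  fp <- group_pairs(fmap)
  # reverse-complement matches: content of one window equals RC of the other
  rcw <- revcomp(win)
  mi <- match(rcw, names(fmap))
  hit <- which(!is.na(mi) & rcw != win)  # palindromes handled separately
  ri <- rj <- integer(0)
  if (length(hit)) {
    partner <- fmap[mi[hit]]
    a <- rep(starts0[hit], lengths(partner))
    b <- unlist(partner, use.names = FALSE) %||% integer(0)
    sel <- a < b
    pr <- unique(data.frame(i = a[sel], j = b[sel]))
    ri <- pr$i; rj <- pr$j
  }
  # palindromic windows (content == its own RC): every distinct pair matches
  # on both strands; forward pairs already come from fmap
  pal <- which(rcw == win)
  if (length(pal)) {
    pp <- group_pairs(split(starts0[pal], win[pal]))
    ri <- c(ri, pp$i); rj <- c(rj, pp$j)
  }
  new_dot_matches(c(fp$i, ri), c(fp$j, rj),
                  c(rep("+", length(fp$i)), rep("-", length(ri))), w, "self")
}

#' Square pairwise dot plot
#'
#' Exact-match windowed comparison of two sequences; both strands, no
#' triangle restriction. `i` indexes windows of `a`, `j` windows of `b`.
#'
#' @param a,b DNA strings.
#' @inheritParams window_index
#' @return `dot_matches` data.frame (see [self_dotplot()]).
#' @export
pair_dotplot <- function(a, b, w, step = w) {
  a <- one_seq(a); b <- one_seq(b)
  sa <- win_starts0(nchar(a), w, step)
  sb <- win_starts0(nchar(b), w, step)
  wa <- extract_windows(a, sa, w); wb <- extract_windows(b, sb, w)
  oka <- !grepl("[^ACGT]", wa); okb <- !grepl("[^ACGT]", wb)
  wa <- wa[oka]; sa <- sa[oka]; wb <- wb[okb]; sb <- sb[okb]
  if (!length(wa) || !length(wb))
    return(new_dot_matches(integer(0), integer(0), character(0), w, "pair"))
  bmap <- split(sb, wb)
  link <- function(keys) {
    mi <- match(keys, names(bmap))
    hit <- which(!is.na(mi))
    partner <- bmap[mi[hit]]
    list(i = rep(sa[hit], lengths(partner)),
         j = unlist(partner, use.names = FALSE) %||% integer(0))
  }
  fwd <- link(wa)
  rev <- link(revcomp(wa))
  new_dot_matches(c(fwd$i, rev$i), c(fwd$j, rev$j),
                  c(rep("+", length(fwd$i)), rep("-", length(rev$i))), w, "pair")
}

#' Write dot-plot matches as TSV
#'
#' Columns `seq_a i seq_b j strand w`.
#' @param matches `dot_matches`.
#' @param path Output file.
#' @param seq_a,seq_b Sequence names for the output.
#' @export
write_dot_matches <- function(matches, path, seq_a = "seqA", seq_b = seq_a) {
  df <- data.frame(seq_a = seq_a, i = matches$i, seq_b = seq_b, j = matches$j,
                   strand = matches$strand, w = matches$w)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a dot-plot match table
#'
#' Thin base-graphics rendering of the match coordinates (forward matches
#' black, reverse-complement matches red).
#' @param x `dot_matches`.
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dot_matches <- function(x, y, ...) {
  graphics::plot(x$i, x$j, pch = ".", col = ifelse(x$strand == "+", "black", "red"),
                 xlab = "position in A (bp)", ylab = "position in B (bp)", ...)
  invisible(x)
}
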