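# Ampliconic-region calling and tandem-array geometry from self dot-plot
# matches: diagonal chaining, base-level identity recomputation against the
# ">99% identity over >10 kb" amplicon definition, modal-offset periodicity
# estimation, and array span measurement.

#' Chain dot-plot matches into diagonal runs
#'
#' Forward matches whose diagonal offsets (`j - i`) differ by at most
#' `offset_tolerance` and whose along-diagonal gaps (distance between the end
#' of one window and the start of the next) are at most `max_gap` are merged
#' into maximal runs. Reverse-complement matches (inverted repeats) are not
#' chained.
#'
#' @param matches `dot_matches` from one [self_dotplot()] call.
#' @param max_gap Maximum along-diagonal gap in bp.
#' @param offset_tolerance Maximum offset spread within one run, in bp.
#' @return `diagonal_runs` data.frame: `a_start`, `a_end`, `b_start`,
#'   `b_end` (0-based half-open), `offset` (mean `j - i`), `n_matches`,
#'   `span` (`a_end - a_start`).
#' @export
diagonal_runs <- function(matches, max_gap = 2000, offset_tolerance = 500) {
  w <- if (nrow(matches)) matches$w[1] else NA_integer_
  fwd <- matches[matches$strand == "+", , drop = FALSE]
  if (!nrow(fwd)) {
    return(structure(data.frame(a_start = numeric(0), a_end = numeric(0),
                                b_start = numeric(0), b_end = numeric(0),
                                offset = numeric(0), n_matches = integer(0),
                                span = numeric(0)),
                     w = w, class = c("diagonal_runs", "data.frame")))
  }
  off <- fwd$j - fwd$i
  o <- order(off, fwd$i)
  fwd <- fwd[o, ]; off <- off[o]
  # cluster offsets: break where consecutive sorted offsets differ more than
  # the tolerance
  obreak <- c(TRUE, diff(off) > offset_tolerance)
  ogrp <- cumsum(obreak)
  runs <- lapply(split(seq_len(nrow(fwd)), ogrp), function(idx) {
    sub <- fwd[idx[order(fwd$i[idx])], , drop = FALSE]
    gap_break <- c(TRUE, diff(sub$i) - sub$w[1] > max_gap)
    rgrp <- cumsum(gap_break)
    lapply(split(seq_len(nrow(sub)), rgrp), function(ii) {
      s <- sub[ii, , drop = FALSE]
      data.frame(a_start = min(s$i), a_end = max(s$i) + s$w[1],
                 b_start = min(s$j), b_end = max(s$j) + s$w[1],
                 offset = mean(s$j - s$i), n_matches = nrow(s))
    })
  })
  out <- do.call(rbind, unlist(runs, recursive = FALSE))
  out$span <- out$a_end - out$a_start
  out <- out[order(out$a_start, out$offset), ]
  rownames(out) <- NULL
  structure(out, w = w, class = c("diagonal_runs", "data.frame"))
}

# interval union length / merged intervals, input data.frame(start, end)
merge_intervals <- function(df) {
  if (!nrow(df)) return(df[, c("start", "end")])
  df <- df[order(df$start, df$end), , drop = FALSE]
  start <- df$start; end <- df$end
  keep_s <- numeric(0); keep_e <- numeric(0)
  cs <- start[1]; ce <- end[1]
  for (k in seq_len(nrow(df))[-1]) {
    if (start[k] <= ce) ce <- max(ce, end[k])
    else { keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce); cs <- start[k]; ce <- end[k] }
  }
  data.frame(start = c(keep_s, cs), end = c(keep_e, ce))
}

overlaps_any <- function(start, end, regions) {
  if (is.null(regions) || !nrow(regions)) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(k)
    any(regions$start < end[k] & regions$end > start[k]), TRUE)
}

#' Call ampliconic pairs from chained diagonal runs
#'
#' For each run the base-level ungapped identity of the two spanned intervals
#' is recomputed from the sequence; pairs with span above `min_len` and
#' identity above `min_identity` are amplicons (defaults encode the
#' ">99% identity over >10 kb" euchromatic-repeat definition). Runs touching
#' `exclude` regions (typically heterochromatin, which is repetitive but not
#' ampliconic by definition) are dropped before identity is computed.
#'
#' @param seq The DNA string the runs were derived from.
#' @param runs A [diagonal_runs()] result.
#' @param min_len Minimum interval span in bp (exclusive).
#' @param min_identity Minimum percent identity (exclusive).
#' @param exclude Optional data.frame of `start`,`end` regions to mask.
#' @return `amplicon_pairs` data.frame: `a_start`, `a_end`, `b_start`,
#'   `b_end`, `offset`, `identity`, `span`.
#' @export
call_amplicons <- function(seq, runs, min_len = 10000, min_identity = 99,
                           exclude = NULL) {
  seq <- one_seq(seq)
  L <- nchar(seq)
  if (nrow(runs) && max(runs$a_end, runs$b_end) > L)
    stop("run coordinates outside the sequence")
  cand <- runs[runs$span > min_len, , drop = FALSE]
  if (nrow(cand)) {
    drop <- overlaps_any(cand$a_start, cand$a_end, exclude) |
      overlaps_any(cand$b_start, cand$b_end, exclude)
    cand <- cand[!drop, , drop = FALSE]
  }
  if (nrow(cand)) {
    cand$identity <- vapply(seq_len(nrow(cand)), function(k) {
      global_identity(substr(seq, cand$a_start[k] + 1L, cand$a_end[k]),
                      substr(seq, cand$b_start[k] + 1L, cand$b_start[k] +
                               (cand$a_end[k] - cand$a_start[k])))
    }, 0)
    cand <- cand[cand$identity > min_identity, , drop = FALSE]
  } else cand$identity <- numeric(0)
  out <- cand[, c("a_start", "a_end", "b_start", "b_end", "offset", "identity", "span")]
  rownames(out) <- NULL
  structure(out, class = c("amplicon_pairs", "data.frame"))
}

#' Ampliconic footprint
#'
#' Interval union of both intervals of all amplicon pairs; the order of the
#' pairs is irrelevant.
#' @param pairs `amplicon_pairs`.
#' @return data.frame of merged `start`,`end` intervals.
#' @export
amplicon_footprint <- function(pairs) {
  merge_intervals(data.frame(start = c(pairs$a_start, pairs$b_start),
                             end = c(pairs$a_end, pairs$b_end)))
}

#' Tandem-array unit periodicity
#'
#' Bins forward-match diagonal offsets at `bin_width` and returns the modal
#' offset: in a head-to-tail array of c copies the unit offset carries c-1
#' pair diagonals, any multiple fewer, so the most populated bin is the unit.
#' Ties break toward the smallest offset. The reported value is the most
#' frequent exact offset within the winning bin.
#'
#' @param matches `dot_matches` from [self_dotplot()].
#' @param min_offset Offsets below this are ignored (suppresses the
#'   near-diagonal clutter of low-order self-similarity).
#' @param bin_width Offset bin width in bp.
#' @return Modal unit offset in bp.
#' @export
tandem_periodicity <- function(matches, min_offset = 1000, bin_width = 1000) {
  off <- matches$j[matches$strand == "+"] - matches$i[matches$strand == "+"]
  off <- off[off >= min_offset]
  if (!length(off)) stop("no periodic matches at or above min_offset")
  bin <- floor(off / bin_width)
  tab <- table(bin)
  best <- as.integer(names(tab)[tab == max(tab)])
  bsel <- min(best)  # smallest offset among maximal bins
  inbin <- off[bin == bsel]
  itab <- table(inbin)
  as.numeric(names(itab)[which.max(itab)])
}

#' Measure a tandem-array span
#'
#' The merged anchor-side interval of matches whose offset lies within
#' `unit +/- tolerance`, extended by one unit at the trailing edge (the last
#' copy only pairs leftward), with `n_units = round(span / unit)`.
#'
#' @param matches `dot_matches` from [self_dotplot()].
#' @param unit Repeat-unit length in bp (from [tandem_periodicity()] or the
#'   user).
#' @param tolerance Offset tolerance in bp.
#' @return A `tandem_array` list: `start`, `end`, `span`, `unit`, `n_units`.
#' @export
array_span <- function(matches, unit, tolerance = 500) {
  sel <- matches$strand == "+" &
    abs((matches$j - matches$i) - unit) <= tolerance
  if (!any(sel)) stop("no matches at the given unit offset")
  i <- matches$i[sel]; w <- matches$w[sel][1]
  start <- min(i)
  end <- max(i) + w + unit
  structure(list(start = start, end = end, span = end - start, unit = unit,
                 n_units = round((end - start) / unit)),
            class = "tandem_array")
}

#' @export
print.tandem_array <- function(x, ...) {
  cat(sprintf("<tandem_array> [%s, %s) span %.3f Mb, unit %.1f kb, ~%d units\n",
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$span / 1e6, x$unit / 1e3, x$n_units))
  invisible(x)
}
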