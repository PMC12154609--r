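# Collinear X-Y identity analysis: base-difference counting, sliding-window
# identity profiles, pseudoautosomal-boundary (PAB) detection, homology-arc
# extraction, and the PAR recombination-rate calculation.

# Logical vectors (match, comparable) for two equal-length sequences.
pairwise_match <- function(a, b) {
  ra <- seq_raw(a); rb <- seq_raw(b)
  if (length(ra) != length(rb)) stop("sequences must have equal length (collinear, gap-free)")
  comp <- is_acgt(ra) & is_acgt(rb)
  list(match = comp & (ra == rb), comp = comp)
}

#' Count nucleotide differences between collinear sequences
#'
#' Positions where both bases are ACGT and unequal; positions involving any
#' other character (e.g. N) are not counted.
#'
#' @param a,b Equal-length DNA strings.
#' @return Integer difference count.
#' @export
count_differences <- function(a, b) {
  pm <- pairwise_match(one_seq(a), one_seq(b))
  sum(pm$comp & !pm$match)
}

#' Sliding-window percent identity profile
#'
#' One record per full window start (0, step, 2*step, ...). Identity is
#' `100 * matching / compared` over bases where both sequences are ACGT;
#' windows with nothing comparable get `identity = NA` (missing, not zero).
#' With `step == window` the compared-base-weighted mean of the windows
#' equals the global identity.
#'
#' @param a,b Equal-length DNA strings.
#' @param window Window length in bp (default 1000).
#' @param step Step in bp (default `window`).
#' @return `identity_profile` data.frame: `window_start`, `window_len`,
#'   `identity` (percent), `n_compared`.
#' @export
sliding_identity <- function(a, b, window = 1000, step = window) {
  a <- one_seq(a); b <- one_seq(b)
  pm <- pairwise_match(a, b)
  L <- length(pm$match)
  if (window < 1) stop("window must be >= 1")
  starts0 <- win_starts0(L, window, step)
  cm <- c(0, cumsum(pm$match))
  cc <- c(0, cumsum(pm$comp))
  nm <- cm[starts0 + window + 1L] - cm[starts0 + 1L]
  nc <- cc[starts0 + window + 1L] - cc[starts0 + 1L]
  idy <- ifelse(nc > 0, 100 * nm / nc, NA_real_)
  structure(data.frame(window_start = starts0, window_len = as.integer(window),
                       identity = idy, n_compared = as.integer(nc)),
            step = as.integer(step),
            class = c("identity_profile", "data.frame"))
}

#' Global percent identity
#'
#' `100 * matching / compared` over all comparable (both-ACGT) positions.
#' @param a,b Equal-length DNA strings.
#' @return Percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b) {
  pm <- pairwise_match(one_seq(a), one_seq(b))
  100 * sum(pm$match) / sum(pm$comp)
}

#' Detect the pseudoautosomal boundary
#'
#' Scans the profile from its telomeric end (ascending `window_start`; the
#' PAR is assumed to start the profile) and returns the start of the first
#' window of the first run of at least `k_consecutive` windows whose identity
#' falls below `threshold`. Windows with missing identity count as divergent.
#' Returns `NA` for a fully pseudoautosomal profile.
#'
#' The defaults (99.9% over 5 windows) separate a PAR-like stratum
#' (~99.99% or higher) from the ~99.5% X-transposed stratum at 1-kb windows.
#'
#' @param profile An [sliding_identity()] result, sorted by `window_start`.
#' @param threshold Percent identity below which a window is divergent.
#' @param k_consecutive Run length required to call the boundary.
#' @return 0-based bp position of the boundary window start, or `NA`.
#' @export
detect_pab <- function(profile, threshold = 99.9, k_consecutive = 5) {
  if (!nrow(profile)) stop("empty profile")
  if (is.unsorted(profile$window_start)) stop("profile must be sorted by window_start")
  below <- is.na(profile$identity) | profile$identity < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= k_consecutive)
  if (!length(hit)) return(NA_real_)
  first <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  profile$window_start[first]
}

#' Extract homology arcs from an identity profile
#'
#' Maximal runs of consecutive windows with identity strictly above
#' `threshold`, merged and reported with their compared-base-weighted mean
#' identity; runs shorter than `min_len` bp are dropped. The default 95%
#' threshold reproduces ">95% X-Y sequence identity" arcs.
#'
#' @inheritParams detect_pab
#' @param threshold Arc identity threshold (percent, exclusive).
#' @param min_len Minimum arc length in bp.
#' @return `homology_arcs` data.frame: `start`, `end` (0-based half-open),
#'   `mean_identity`, `n_windows`.
#' @export
homology_arcs <- function(profile, threshold = 95, min_len = 0) {
  if (!nrow(profile)) {
    return(structure(data.frame(start = numeric(0), end = numeric(0),
                                mean_identity = numeric(0), n_windows = integer(0)),
                     class = c("homology_arcs", "data.frame")))
  }
  if (is.unsorted(profile$window_start)) stop("profile must be sorted by window_start")
  above <- !is.na(profile$identity) & profile$identity > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    wts <- profile$n_compared[idx]
    data.frame(start = profile$window_start[starts[k]],
               end = profile$window_start[ends[k]] + profile$window_len[ends[k]],
               mean_identity = sum(profile$identity[idx] * wts) / sum(wts),
               n_windows = length(idx))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = numeric(0), end = numeric(0),
               mean_identity = numeric(0), n_windows = integer(0))
  out <- out[out$end - out$start >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("homology_arcs", "data.frame"))
}

#' PAR recombination rate
#'
#' One obligatory crossover (50 cM) per male meiosis across the PAR:
#' `50 / (par_length_bp / 1e6)` cM/Mb. A 300-kb PAR gives ~166.7, printed in
#' the field as "approximately 166 cM/Mb".
#'
#' @param par_length_bp PAR length in bp (> 0).
#' @return Recombination rate in centimorgans per megabase.
#' @export
par_recombination_rate <- function(par_length_bp) {
  if (!is.numeric(par_length_bp) || par_length_bp <= 0)
    stop("par_length_bp must be > 0")
  50 / (par_length_bp / 1e6)
}
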