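# GC-content profiling by sequence class and a label-permutation test for GC
# elevation between classes (X-transposed regions carry visibly elevated GC,
# consistent with GC-biased gene conversion in a formerly recombining
# region).

#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; characters outside ACGT are excluded from the
#' denominator.
#' @param seq DNA string.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  r <- seq_raw(one_seq(seq))
  acgt <- sum(is_acgt(r))
  if (acgt == 0) stop("sequence has no ACGT bases")
  sum(r %in% charToRaw("GC")) / acgt
}

#' Per-class windowed GC values
#'
#' Windows fully inside each annotated region contribute one GC value to
#' that region's class; windows straddling region boundaries are dropped.
#'
#' @param seq DNA string.
#' @param regions `region_annotation`-style data.frame (`start`, `end`,
#'   `label`).
#' @param window Window size in bp (default 1000).
#' @return data.frame: `label`, `window_start`, `gc`.
#' @export
windowed_gc <- function(seq, regions, window = 1000) {
  seq <- one_seq(seq)
  L <- nchar(seq)
  if (nrow(regions) && (min(regions$start) < 0 || max(regions$end) > L))
    stop("regions outside the sequence")
  r <- seq_raw(seq)
  cg <- cumsum(r %in% charToRaw("GC"))
  ac <- cumsum(is_acgt(r))
  cg <- c(0L, cg); ac <- c(0L, ac)
  out <- lapply(seq_len(nrow(regions)), function(k) {
    lo <- regions$start[k]; hi <- regions$end[k]
    if (hi - lo < window) return(NULL)
    starts0 <- seq.int(lo, hi - window, by = window)
    n_acgt <- ac[starts0 + window + 1L] - ac[starts0 + 1L]
    n_gc <- cg[starts0 + window + 1L] - cg[starts0 + 1L]
    data.frame(label = regions$label[k], window_start = starts0,
               gc = ifelse(n_acgt > 0, n_gc / n_acgt, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(label = character(0), window_start = numeric(0),
                      gc = numeric(0))
  rownames(out) <- NULL
  out
}

#' Per-class GC summary with bootstrap interval
#'
#' Mean window GC per class with a percentile bootstrap confidence interval
#' (the numbers behind a per-class GC bar graph).
#'
#' @param wgc A [windowed_gc()] result.
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Optional seed for the resampling.
#' @return `gc_summary` data.frame: `label`, `n_windows`, `mean_gc`,
#'   `ci_low`, `ci_high`.
#' @export
gc_summary <- function(wgc, n_boot = 1000, conf = 0.95, seed = NULL) {
  run <- function() {
    rows <- lapply(split(wgc$gc, wgc$label), function(v) {
      v <- v[!is.na(v)]
      bm <- vapply(seq_len(n_boot),
                   function(i) mean(v[sample.int(length(v), replace = TRUE)]), 0)
      qs <- quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
      data.frame(n_windows = length(v), mean_gc = mean(v),
                 ci_low = qs[1], ci_high = qs[2])
    })
    out <- cbind(label = names(rows), do.call(rbind, rows))
    rownames(out) <- NULL
    structure(out, class = c("gc_summary", "data.frame"))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Permutation test for GC elevation between two classes
#'
#' Statistic `mean(a) - mean(b)`; two-sided p-value by label permutation with
#' add-one correction, `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`, so p is
#' never zero. Degenerate all-equal input gives p = 1.
#'
#' @param class_a_gc,class_b_gc Numeric vectors of window GC values.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional seed.
#' @return `gc_perm_test` list: `statistic` (observed difference),
#'   `p_value`, `n_perm`, `n_a`, `n_b`.
#' @export
gc_elevation_test <- function(class_a_gc, class_b_gc, n_perm = 10000,
                              seed = NULL) {
  a <- class_a_gc[!is.na(class_a_gc)]
  b <- class_b_gc[!is.na(class_b_gc)]
  if (!length(a) || !length(b)) stop("both classes need at least one value")
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- mean(a) - mean(b)
  # canonical permutation scheme: sorted pool, smaller group resampled, so
  # the p-value is exactly invariant to relabeling a <-> b (statistic sign
  # aside) under the same seed
  pooled <- sort(c(a, b))
  na <- length(a); n <- length(pooled)
  m <- min(na, n - na)
  run <- function() {
    perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, m)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, 0)
    p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
    structure(list(statistic = obs, p_value = p, n_perm = n_perm,
                   n_a = na, n_b = length(b)),
              class = "gc_perm_test")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.gc_perm_test <- function(x, ...) {
  cat(sprintf("<gc_perm_test> mean difference %.5f, p = %.4g (%d permutations, n = %d vs %d)\n",
              x$statistic, x$p_value, x$n_perm, x$n_a, x$n_b))
  invisible(x)
}
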