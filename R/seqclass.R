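# Five-class sequence segmentation: PAR, X-transposed, ancestral, ampliconic
# and heterochromatic (plus "other") labels per base, from X-Y identity arcs,
# amplicon footprints and satellite content, under a fixed label precedence.

#' Satellite content profile
#'
#' A base is satellite-covered when any k-mer overlapping it (either strand;
#' monomers treated circularly) occurs in the monomer k-mer set; the covered
#' fraction is reported per window. Stands in for satellite-repeat masking on
#' synthetic data.
#'
#' @param seq DNA string.
#' @param monomers Character vector of monomer sequences (default: the
#'   packaged [satellite_monomer()]).
#' @param k K-mer size (<= shortest monomer; default 21).
#' @param window Window size in bp (default 10000). Only full windows are
#'   reported.
#' @return `satellite_profile` data.frame: `window_start`,
#'   `satellite_fraction`; attribute `window`.
#' @export
satellite_profile <- function(seq, monomers = satellite_monomer(), k = 21,
                              window = 10000) {
  seq <- one_seq(seq)
  if (!length(monomers)) stop("empty monomer set")
  if (k > min(nchar(monomers))) stop("k must not exceed the monomer length")
  if (window < k) stop("window must be >= k")
  # circularise each monomer so wrap-around k-mers count too
  circ <- paste0(monomers, substr(monomers, 1L, k - 1L))
  codes <- cpp_kmer_set(circ, k, 1L)
  hits <- cpp_match_positions(seq, k, codes)
  L <- nchar(seq)
  cov <- logical(L)
  if (length(hits)) {
    # delta-encode the union of [hit, hit + k) intervals
    tab_start <- tabulate(hits + 1L, nbins = L + 1L)
    tab_end <- tabulate(pmin(hits + k, L) + 1L, nbins = L + 1L)
    cov <- cumsum(tab_start - tab_end)[seq_len(L)] > 0L
  }
  starts0 <- seq.int(0L, L - window, by = window)
  cs <- c(0L, cumsum(cov))
  frac <- (cs[starts0 + window + 1L] - cs[starts0 + 1L]) / window
  structure(data.frame(window_start = starts0, satellite_fraction = frac),
            window = as.integer(window),
            class = c("satellite_profile", "data.frame"))
}

#' Call heterochromatic regions from a satellite profile
#'
#' Maximal merged runs of consecutive windows with satellite fraction at or
#' above `min_fraction`.
#'
#' @param profile A [satellite_profile()] result, sorted by `window_start`.
#' @param min_fraction Minimum satellite fraction (inclusive).
#' @return data.frame of `start`, `end`, `label = "heterochromatic"`.
#' @export
call_heterochromatin <- function(profile, min_fraction = 0.5) {
  empty <- data.frame(start = numeric(0), end = numeric(0), label = character(0))
  if (!nrow(profile)) return(empty)
  if (is.unsorted(profile$window_start)) stop("profile must be sorted")
  window <- attr(profile, "window") %||%
    (if (nrow(profile) > 1) diff(profile$window_start[1:2]) else
       stop("profile window size unknown"))
  above <- profile$satellite_fraction >= min_fraction
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty)
  data.frame(start = profile$window_start[starts[keep]],
             end = profile$window_start[ends[keep]] + window,
             label = "heterochromatic", stringsAsFactors = FALSE)
}

#' Classification thresholds
#'
#' Identity strata separating the observed sequence classes on 1-kb profile
#' windows: PAR-like arcs are essentially identical (>= 99.9%), X-transposed
#' arcs sit near 99.5% (in `[95, 99.9)`), ancestral gametologs are deeply
#' diverged (`[70, 95)`). Only the 95% arc threshold is field-standard; the
#' flanking strata are this package's conventions. `telomere_tol` is how
#' close (bp) an arc must come to a sequence end to count as
#' telomere-anchored, which PAR status requires.
#'
#' @param par_min_identity,xtr_min_identity,ancestral_min_identity Stratum
#'   floors in percent.
#' @param telomere_tol Telomere-anchoring tolerance in bp.
#' @return Named list of thresholds.
#' @export
classify_config <- function(par_min_identity = 99.9, xtr_min_identity = 95,
                            ancestral_min_identity = 70, telomere_tol = 1000) {
  list(par_min_identity = par_min_identity, xtr_min_identity = xtr_min_identity,
       ancestral_min_identity = ancestral_min_identity,
       telomere_tol = telomere_tol)
}

#' Segment a chromosome into the five-class mosaic
#'
#' Labels every base of `y_seq` by precedence heterochromatic > PAR > XTR >
#' ancestral > ampliconic > other. Identity arcs (computed against the
#' homologous chromosome at the ancestral floor) are assigned a stratum by
#' their mean identity; an essentially-identical arc (>= `par_min_identity`)
#' is PAR only when telomere-anchored, otherwise it falls back to XTR.
#' Adjacent same-label intervals are merged; the output tiles the sequence
#' exactly.
#'
#' @param y_seq The chromosome being classified.
#' @param arcs [homology_arcs()] result (threshold at the ancestral floor).
#' @param footprint Ampliconic footprint intervals ([amplicon_footprint()]).
#' @param het_regions Heterochromatic intervals ([call_heterochromatin()]).
#' @param config A [classify_config()] list.
#' @param seq_name Name for the output annotation.
#' @return `region_annotation` data.frame: `seq_name`, `start`, `end`,
#'   `label`.
#' @export
classify <- function(y_seq, arcs = NULL, footprint = NULL, het_regions = NULL,
                     config = classify_config(), seq_name = "chrY") {
  y_seq <- one_seq(y_seq)
  L <- nchar(y_seq)
  lab <- rep.int(6L, L)  # other
  paint <- function(lab, regions, value) {
    if (is.null(regions) || !nrow(regions)) return(lab)
    if (any(regions$start < 0 | regions$end > L))
      stop("input region outside the sequence")
    for (k in seq_len(nrow(regions)))
      if (regions$end[k] > regions$start[k])
        lab[(regions$start[k] + 1L):regions$end[k]] <- value
    lab
  }
  # ascending precedence: ampliconic < ancestral < XTR < PAR < heterochromatic
  lab <- paint(lab, footprint, 4L)
  if (!is.null(arcs) && nrow(arcs)) {
    anchored <- arcs$start <= config$telomere_tol |
      arcs$end >= L - config$telomere_tol
    stratum <- ifelse(arcs$mean_identity >= config$par_min_identity,
                      ifelse(anchored, 1L, 2L),
               ifelse(arcs$mean_identity >= config$xtr_min_identity, 2L,
               ifelse(arcs$mean_identity >= config$ancestral_min_identity, 3L, 6L)))
    for (v in c(3L, 2L, 1L))
      lab <- paint(lab, arcs[stratum == v, , drop = FALSE], v)
  }
  lab <- paint(lab, het_regions, 5L)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  labels <- c("PAR", "XTR", "ancestral", "ampliconic", "heterochromatic", "other")
  structure(data.frame(seq_name = seq_name, start = ends - r$lengths,
                       end = ends, label = labels[r$values],
                       stringsAsFactors = FALSE),
            class = c("region_annotation", "data.frame"))
}

#' @export
print.region_annotation <- function(x, ...) {
  cat("<region_annotation>", nrow(x), "regions\n")
  print(as.data.frame(x))
  invisible(x)
}
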