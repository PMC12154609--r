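# End-to-end classification pipeline: from a collinear X/Y pair to the
# five-class mosaic, wiring together identity profiling, arc extraction,
# self dot-plot amplicon calling and satellite masking.

#' Classify a Y chromosome from its X counterpart
#'
#' Runs the full segmentation pipeline on a collinear X/Y pair: 1-kb sliding
#' identity profile, homology arcs at the ancestral identity floor, self
#' dot plot and diagonal chaining for the ampliconic footprint (with
#' heterochromatin masked), satellite profiling for heterochromatin calls,
#' then per-base classification by precedence.
#'
#' @param y_seq,x_seq Equal-length chromosome sequences.
#' @param monomers Satellite monomer set for heterochromatin detection.
#' @param window Identity window in bp (default 1000).
#' @param dot_w Dot-plot window in bp (default 250).
#' @param het_window Satellite window in bp (default 10000).
#' @param config [classify_config()] thresholds.
#' @param seq_name Name for the output annotation.
#' @return List: `annotation` (`region_annotation`), plus the intermediate
#'   `profile`, `arcs`, `amplicons`, `footprint`, `het_regions`.
#' @export
classify_pipeline <- function(y_seq, x_seq, monomers = satellite_monomer(),
                              window = 1000, dot_w = 250, het_window = 10000,
                              config = classify_config(), seq_name = "chrY") {
  y_seq <- one_seq(y_seq); x_seq <- one_seq(x_seq)
  profile <- sliding_identity(y_seq, x_seq, window = window)
  arcs <- homology_arcs(profile, threshold = config$ancestral_min_identity,
                        min_len = 2 * window)
  sat <- satellite_profile(y_seq, monomers = monomers, window = het_window)
  het <- call_heterochromatin(sat)
  dots <- self_dotplot(y_seq, w = dot_w)
  runs <- diagonal_runs(dots)
  amp <- call_amplicons(y_seq, runs, exclude = het)
  fp <- amplicon_footprint(amp)
  ann <- classify(y_seq, arcs = arcs, footprint = fp, het_regions = het,
                  config = config, seq_name = seq_name)
  list(annotation = ann, profile = profile, arcs = arcs, amplicons = amp,
       footprint = fp, het_regions = het)
}
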