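# Blueprints: declarative plans for synthetic X/Y sequence pairs.
# A blueprint is an ordered list of segment specs per chromosome (telomere to
# telomere) plus homology links between X and Y segments that share a common
# ancestor copy.

SEQ_CLASSES <- c("PAR", "XTR", "ancestral", "ampliconic", "heterochromatic", "other")

#' Segment specification
#'
#' One building block of a synthetic chromosome: a sequence class label, a
#' length, and (depending on kind) a pairwise divergence against its
#' homologous copy, tandem-array geometry, or a satellite monomer.
#'
#' @param label Sequence class, one of `PAR`, `XTR`, `ancestral`,
#'   `ampliconic`, `heterochromatic`, `other`.
#' @param length_bp Segment length in bases (> 0).
#' @param divergence Per-site substitution probability in `[0, 1]` between
#'   homologous copies (linked X-Y blocks or tandem-array copies).
#' @param unit_length_bp Tandem arrays only: repeat-unit length; must satisfy
#'   `unit_length_bp * copies == length_bp`.
#' @param copies Tandem arrays only: number of repeat units.
#' @param satellite_monomer Identifier of a satellite monomer (currently
#'   `"sat234"`, the packaged 234-bp synthetic monomer) or `NA`.
#' @param gc Target GC fraction in (0, 1); default 0.40 genome background.
#' @return A `segment_spec` list.
#' @export
segment_spec <- function(label, length_bp, divergence = 0,
                         unit_length_bp = NA_integer_, copies = NA_integer_,
                         satellite_monomer = NA_character_, gc = 0.40) {
  s <- structure(list(label = label, length_bp = as.integer(length_bp),
                      divergence = divergence,
                      unit_length_bp = as.integer(unit_length_bp),
                      copies = as.integer(copies),
                      satellite_monomer = satellite_monomer, gc = gc),
                 class = "segment_spec")
  validate_segment_spec(s)
  s
}

validate_segment_spec <- function(s) {
  if (!s$label %in% SEQ_CLASSES)
    stop("unknown sequence class: ", s$label)
  if (is.na(s$length_bp) || s$length_bp <= 0)
    stop("length_bp must be > 0")
  if (is.na(s$divergence) || s$divergence < 0 || s$divergence > 1)
    stop("divergence must lie in [0, 1]")
  if (is.na(s$gc) || s$gc <= 0 || s$gc >= 1)
    stop("gc must lie in (0, 1)")
  if (!is.na(s$unit_length_bp) || !is.na(s$copies)) {
    if (is.na(s$unit_length_bp) || is.na(s$copies))
      stop("tandem arrays need both unit_length_bp and copies")
    if (s$unit_length_bp * s$copies != s$length_bp)
      stop("unit_length_bp * copies must equal length_bp")
  }
  invisible(s)
}

is_array_seg <- function(s) !is.na(s$unit_length_bp)
is_satellite_seg <- function(s) !is.na(s$satellite_monomer)

new_blueprint <- function(name, y_segments, x_segments, homology_links, seed) {
  bp <- structure(list(name = name, y_segments = y_segments,
                       x_segments = x_segments,
                       homology_links = homology_links, seed = as.integer(seed)),
                  class = "blueprint")
  validate_blueprint(bp)
  bp
}

validate_blueprint <- function(bp) {
  for (s in bp$y_segments) validate_segment_spec(s)
  for (s in bp$x_segments) validate_segment_spec(s)
  for (ln in bp$homology_links) {
    yi <- ln[[1]]; xi <- ln[[2]]
    if (yi < 1 || yi > length(bp$y_segments) || xi < 1 || xi > length(bp$x_segments))
      stop("homology link indexes a missing segment")
    if (bp$y_segments[[yi]]$length_bp != bp$x_segments[[xi]]$length_bp)
      stop("linked segments must have equal length_bp (collinear, gap-free homology)")
  }
  invisible(bp)
}

# ---- presets ----------------------------------------------------------------
# Architecture parameters model a rat-like sex-chromosome pair:
# a terminal PAR block of 282 kb differing by ~5 nucleotides (functional PAR
# 300 kb, Xp scaffold 400 kb), an X-transposed region 99.5% identical over
# 207 kb (Xq scaffold 515 kb), a Med14 retrogene 93% identical over 5 kb, an
# Ssty tandem array of 24 x 85-kb units, the largest amplicon spanning 3.5 Mb
# at 99.5% identity, and ~4-fold more satellite heterochromatin on Xq than on
# its Y counterpart.

PAR_DIVERGENCE <- 5 / 282000

preset_definitions <- function() {
  seg <- segment_spec
  sat <- function(len) segment_spec("heterochromatic", len, satellite_monomer = "sat234")
  list(
    PAR = list(
      y = list(seg("PAR", 18000, PAR_DIVERGENCE),
               seg("PAR", 282000, PAR_DIVERGENCE),
               seg("other", 100000, 0.02)),
      x = list(seg("PAR", 18000, PAR_DIVERGENCE),
               seg("PAR", 282000, PAR_DIVERGENCE),
               seg("other", 100000, 0.02)),
      links = list(c(1L, 1L), c(2L, 2L), c(3L, 3L))),
    XTR = list(
      y = list(seg("XTR", 207000, 0.005, gc = 0.46),
               sat(50000),
               seg("other", 258000)),
      x = list(seg("XTR", 207000, 0.005, gc = 0.46),
               sat(200000),
               seg("other", 108000)),
      links = list(c(1L, 1L))),
    SSTY_ARRAY = list(
      y = list(seg("other", 50000),
               seg("ampliconic", 2040000, 0.005, unit_length_bp = 85000, copies = 24),
               seg("other", 50000)),
      x = list(), links = list()),
    LARGEST_AMPLICON = list(
      y = list(seg("other", 50000),
               seg("ampliconic", 3500000, 0.005, unit_length_bp = 50000, copies = 70),
               seg("other", 50000)),
      x = list(), links = list()),
    MED14 = list(
      y = list(seg("ancestral", 5000, 0.07)),
      x = list(seg("ancestral", 5000, 0.07)),
      links = list(c(1L, 1L))),
    HET_ASYMMETRY = list(
      y = list(seg("other", 10000), sat(40000), seg("other", 50000)),
      x = list(seg("other", 10000), sat(160000), seg("other", 30000)),
      links = list()),
    FULL_ARCHITECTURE = list(
      y = list(seg("XTR", 60000, 0.005, gc = 0.46),
               seg("other", 30000),
               seg("ancestral", 40000, 0.12),
               seg("ampliconic", 120000, 0.002, unit_length_bp = 30000, copies = 4),
               seg("other", 50000),
               sat(60000),
               seg("other", 40000),
               seg("PAR", 120000, 2e-5)),
      x = list(seg("XTR", 60000, 0.005, gc = 0.46),
               seg("other", 30000),
               seg("ancestral", 40000, 0.12),
               seg("other", 120000),
               seg("other", 50000),
               sat(60000),
               seg("other", 40000),
               seg("PAR", 120000, 2e-5)),
      links = list(c(1L, 1L), c(3L, 3L), c(8L, 8L)))
  )
}

#' Available blueprint presets
#' @return Character vector of preset names accepted by [build_blueprint()].
#' @export
blueprint_presets <- function() names(preset_definitions())

#' Build a blueprint from a preset
#'
#' Resolves a named architecture preset into a fully specified [blueprint]
#' of ordered X and Y segment specs plus homology links. Unmodified presets
#' are identical across calls; the seed only parameterises the later
#' simulation, never the structure.
#'
#' @param preset_name One of [blueprint_presets()] (a trailing `_PRESET`
#'   suffix is accepted).
#' @param overrides Named list. `seed` overrides the blueprint seed; segment
#'   fields are addressed as `"y.2.divergence"` / `"x.1.gc"` (chromosome,
#'   1-based segment index, field).
#' @return A `blueprint` object.
#' @examples
#' bp <- build_blueprint("PAR")
#' bp$y_segments[[2]]$length_bp  # 282000
#' @export
build_blueprint <- function(preset_name, overrides = list()) {
  key <- sub("_PRESET$", "", toupper(preset_name))
  defs <- preset_definitions()
  if (!key %in% names(defs)) stop("unknown preset: ", preset_name)
  d <- defs[[key]]
  bp <- new_blueprint(key, d$y, d$x, d$links, seed = 1L)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be named")
    for (nm in names(overrides)) {
      val <- overrides[[nm]]
      if (nm == "seed") { bp$seed <- as.integer(val); next }
      if (nm == "name") { bp$name <- as.character(val); next }
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(parts) != 3 || !parts[1] %in% c("x", "y"))
        stop("unknown override field: ", nm)
      side <- paste0(parts[1], "_segments")
      idx <- as.integer(parts[2])
      if (is.na(idx) || idx < 1 || idx > length(bp[[side]]))
        stop("override addresses a missing segment: ", nm)
      if (!parts[3] %in% names(bp[[side]][[idx]]))
        stop("unknown segment field: ", parts[3])
      bp[[side]][[idx]][[parts[3]]] <- val
    }
    validate_blueprint(bp)
  }
  bp
}

#' @export
print.blueprint <- function(x, ...) {
  cat("<blueprint>", x$name, " seed:", x$seed, "\n")
  show_side <- function(tag, segs) {
    if (!length(segs)) return(invisible())
    cat(" ", tag, ":\n", sep = "")
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      extra <- if (is_array_seg(s))
        sprintf(" [%d x %d bp]", s$copies, s$unit_length_bp)
      else if (is_satellite_seg(s)) paste0(" [", s$satellite_monomer, "]")
      else ""
      cat(sprintf("   %d. %-15s %9d bp  d=%-8g%s\n", i, s$label, s$length_bp,
                  s$divergence, extra))
    }
  }
  show_side("Y", x$y_segments)
  show_side("X", x$x_segments)
  if (length(x$homology_links))
    cat("  links (y,x):", paste(vapply(x$homology_links,
                                       function(l) paste0("(", l[1], ",", l[2], ")"), ""),
                                collapse = " "), "\n")
  invisible(x)
}
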