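# Synthetic X/Y genome simulator: emits sequence pairs with the statistical
# structure the downstream analyses assume (near-identical terminal PAR,
# ~99.5%-identical X-transposed block, deep-diverged gametologs, tandem
# amplicon arrays, satellite heterochromatin, distance-decaying Hi-C pairs,
# and sex-labelled read sets), together with exact truth annotations.

# Synthetic 234-bp satellite monomer. Only its repetitiveness matters; the
# sequence itself is an arbitrary fixed draw (also shipped in
# inst/extdata/satellite_monomer_synthetic.fa).
SAT234 <- paste0(
  "GGAGAGCGCATTTTATTGACTTCGTTGACCGAAGTGGATTTCCAGGAGTAGTACAAATCGTTACTTGTGG",
  "CTTTATTTAATTTCCGACTCCCAATCTTGTGGATTCAAATGAGGAAAAGTGTTTGAGGAATTGCTCGAGA",
  "CCTGCCTTATTTCTAAATTTGAAAGAGCAATTCGAATTTTTAAGCGGACCTTCACCTACCTTGAAGGTAG",
  "TTGTACAATTACATCTAGTATTTG")

#' Packaged satellite monomer
#'
#' The 234-bp synthetic satellite monomer used for heterochromatic segments
#' and as the default query of [satellite_profile()].
#' @return Named character vector of monomer sequences (currently `sat234`).
#' @export
satellite_monomer <- function() c(sat234 = SAT234)

satellite_array <- function(len, monomer = SAT234) {
  reps <- ceiling(len / nchar(monomer))
  substr(paste(rep(monomer, reps), collapse = ""), 1L, len)
}

emit_segment <- function(s) {
  if (is_satellite_seg(s)) return(satellite_array(s$length_bp))
  if (is_array_seg(s)) {
    anc <- random_dna(s$unit_length_bp, s$gc)
    # copies diverge from the unit ancestor at d/2 each, so pairwise
    # inter-copy divergence ~ d (small-d approximation)
    paste(vapply(seq_len(s$copies),
                 function(i) mutate_seq(anc, s$divergence / 2), ""),
          collapse = "")
  } else {
    random_dna(s$length_bp, s$gc)
  }
}

#' Simulate a homologous block pair
#'
#' The core homology emitter behind [simulate_pair()]: one ancestral block
#' and one copy with independent per-site substitutions at the given rate, so
#' the pairwise mismatch count is Binomial(`length_bp`, `divergence`).
#'
#' @param length_bp Block length.
#' @param divergence Pairwise per-site substitution probability.
#' @param gc Target GC fraction.
#' @param seed Integer seed (optional; uses current RNG state if `NULL`).
#' @return List with elements `a` and `b` (DNA strings of equal length).
#' @export
simulate_block_pair <- function(length_bp, divergence, gc = 0.4, seed = NULL) {
  gen <- function() {
    a <- random_dna(length_bp, gc)
    list(a = a, b = mutate_seq(a, divergence))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate an X/Y sequence pair from a blueprint
#'
#' Emits chromosome sequences segment by segment (telomere to telomere).
#' Linked X-Y segments share a common ancestor: one chromosome carries the
#' ancestral copy, the other a copy substituted per site at the segment's
#' divergence, so realized X-Y mismatch rates equal the blueprint divergence
#' in expectation. Tandem arrays mutate each copy at half the inter-copy
#' divergence from a shared unit ancestor. Truth annotations tile each
#' chromosome exactly (0-based half-open). Identical blueprints (including
#' seed) give identical output.
#'
#' @param bp A [build_blueprint()] result.
#' @return A `simulated_genome`: list with `sequences` (named character;
#'   `chrY` and, when the blueprint has X segments, `chrX`), `truth`
#'   (data.frame `seq_name,start,end,label`), `segments` (per-segment
#'   coordinate table), `blueprint`, `provenance`.
#' @export
simulate_pair <- function(bp) {
  stopifnot(inherits(bp, "blueprint"))
  validate_blueprint(bp)
  for (ln in bp$homology_links) {
    ys <- bp$y_segments[[ln[[1]]]]; xs <- bp$x_segments[[ln[[2]]]]
    if (is_array_seg(ys) || is_satellite_seg(ys) || is_array_seg(xs) || is_satellite_seg(xs))
      stop("homology links must join plain (non-array, non-satellite) segments")
  }
  with_seed(bp$seed, {
    xlink <- rep(NA_integer_, length(bp$x_segments))
    for (ln in bp$homology_links) xlink[ln[[2]]] <- ln[[1]]
    yparts <- character(length(bp$y_segments))
    xparts <- character(length(bp$x_segments))
    for (i in seq_along(bp$y_segments)) yparts[i] <- emit_segment(bp$y_segments[[i]])
    for (j in seq_along(bp$x_segments)) {
      if (!is.na(xlink[j])) {
        xparts[j] <- mutate_seq(yparts[xlink[j]], bp$x_segments[[j]]$divergence)
      } else {
        xparts[j] <- emit_segment(bp$x_segments[[j]])
      }
    }
    seg_table <- function(seq_name, segs, linked) {
      if (!length(segs)) return(NULL)
      len <- vapply(segs, function(s) s$length_bp, 0L)
      end <- cumsum(len)
      data.frame(seq_name = seq_name, idx = seq_along(segs),
                 start = end - len, end = end,
                 label = vapply(segs, function(s) s$label, ""),
                 divergence = vapply(segs, function(s) s$divergence, 0),
                 unit_length_bp = vapply(segs, function(s) s$unit_length_bp, 0L),
                 copies = vapply(segs, function(s) s$copies, 0L),
                 linked = linked, stringsAsFactors = FALSE)
    }
    ylinked <- rep(NA_integer_, length(bp$y_segments))
    for (ln in bp$homology_links) ylinked[ln[[1]]] <- ln[[2]]
    segs <- rbind(seg_table("chrY", bp$y_segments, ylinked),
                  seg_table("chrX", bp$x_segments, xlink))
    sequences <- c(chrY = paste(yparts, collapse = ""))
    if (length(xparts)) sequences <- c(sequences, chrX = paste(xparts, collapse = ""))
    truth <- segs[, c("seq_name", "start", "end", "label")]
    rownames(truth) <- rownames(segs) <- NULL
    structure(list(sequences = sequences, truth = truth, segments = segs,
                   blueprint = bp,
                   provenance = paste0(bp$name, ":seed=", bp$seed)),
              class = "simulated_genome")
  })
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat("<simulated_genome>", x$provenance, "\n")
  for (nm in names(x$sequences))
    cat(sprintf("  %s: %d bp, %d truth regions\n", nm, nchar(x$sequences[[nm]]),
                sum(x$truth$seq_name == nm)))
  invisible(x)
}

#' Extract a linked homologous block pair
#'
#' @param g A `simulated_genome`.
#' @param which Homology-link index (order of the blueprint's
#'   `homology_links`) or a class label, in which case the longest linked
#'   block with that label is returned.
#' @return List with `y` and `x` block sequences plus their coordinates.
#' @export
linked_block_pair <- function(g, which = 1) {
  stopifnot(inherits(g, "simulated_genome"))
  links <- g$blueprint$homology_links
  if (!length(links)) stop("blueprint has no homology links")
  if (is.character(which)) {
    ysegs <- g$segments[g$segments$seq_name == "chrY", ]
    cand <- which(vapply(links, function(ln) ysegs$label[ln[[1]]] == which, TRUE))
    if (!length(cand)) stop("no linked block labelled ", which)
    lens <- vapply(cand, function(i) {
      yi <- links[[i]][[1]]
      ysegs$end[yi] - ysegs$start[yi]
    }, 0)
    which <- cand[which.max(lens)]
  }
  ln <- links[[which]]
  ys <- g$segments[g$segments$seq_name == "chrY" & g$segments$idx == ln[[1]], ]
  xs <- g$segments[g$segments$seq_name == "chrX" & g$segments$idx == ln[[2]], ]
  list(y = substr(g$sequences[["chrY"]], ys$start + 1L, ys$end),
       x = substr(g$sequences[["chrX"]], xs$start + 1L, xs$end),
       y_start = ys$start, y_end = ys$end, x_start = xs$start, x_end = xs$end,
       label = ys$label)
}

#' Simulate shotgun reads
#'
#' Error-prone substrings with uniform start positions; per contig the read
#' count is `round(coverage * length / read_length_bp)`, so total bases match
#' the requested coverage to within one read per contig. The source contig is
#' retained per read as a truth label.
#'
#' @param g `simulated_genome`, named character sequences, or `DNAStringSet`.
#' @param coverage Fold coverage (> 0).
#' @param read_length_bp Read length; must not exceed the shortest contig.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A `read_set` data.frame: `read_id`, `source`, `start`, `seq`.
#' @export
simulate_reads <- function(g, coverage, read_length_bp, error_rate = 0, seed = 1) {
  seqs <- as_sequences(g)
  stopifnot(coverage > 0, read_length_bp >= 1)
  lens <- nchar(seqs)
  if (read_length_bp > min(lens))
    stop("read_length_bp exceeds the shortest contig")
  with_seed(seed, {
    out <- lapply(names(seqs), function(nm) {
      L <- lens[[nm]]
      n <- round(coverage * L / read_length_bp)
      if (n == 0) return(NULL)
      starts <- sample.int(L - read_length_bp + 1L, n, replace = TRUE) - 1L
      rd <- substring(seqs[[nm]], starts + 1L, starts + read_length_bp)
      if (error_rate > 0)
        rd <- vapply(rd, mutate_seq, "", rate = error_rate, USE.NAMES = FALSE)
      data.frame(read_id = sprintf("%s_r%d", nm, seq_len(n)), source = nm,
                 start = starts, seq = rd, stringsAsFactors = FALSE)
    })
    structure(do.call(rbind, out), class = c("read_set", "data.frame"))
  })
}

#' Fragment scaffold sequences into contigs
#'
#' @param g Sequences (as in [simulate_reads()]).
#' @param breaks Named list: for each scaffold, sorted 0-based internal cut
#'   positions. Scaffolds without an entry stay whole.
#' @return Named character vector of contig sequences (`<scaffold>_c<i>`),
#'   in scaffold order.
#' @export
fragment_genome <- function(g, breaks = list()) {
  seqs <- as_sequences(g)
  out <- character(0)
  for (nm in names(seqs)) {
    b <- breaks[[nm]]
    L <- nchar(seqs[[nm]])
    cuts <- sort(unique(as.integer(b)))
    if (any(cuts <= 0 | cuts >= L)) stop("breakpoints must lie strictly inside ", nm)
    bounds <- c(0L, cuts, L)
    if (length(bounds) == 2L) { out[nm] <- seqs[[nm]]; next }
    frag <- substring(seqs[[nm]], head(bounds, -1) + 1L, bounds[-1])
    names(frag) <- sprintf("%s_c%d", nm, seq_along(frag))
    out <- c(out, frag)
  }
  out
}

#' Simulate Hi-C mate pairs
#'
#' Pair separation `d` on the true (unfragmented) scaffold is drawn with
#' density proportional to `d^-decay_exponent` on `[min_sep, scaffold length)`;
#' both ends are then re-expressed in fragmented-contig coordinates under the
#' given partition.
#'
#' @param g Sequences (the true scaffolds).
#' @param n_pairs Number of mate pairs (> 0).
#' @param decay_exponent Contact-decay exponent (1.0 is the classic
#'   polymer-like decay).
#' @param seed Integer seed.
#' @param breaks Contig partition as in [fragment_genome()]; `NULL` keeps
#'   scaffolds whole.
#' @param min_sep Minimum pair separation in bp.
#' @return A `mate_pairs` data.frame: `contig_a,pos_a,contig_b,pos_b`
#'   (0-based positions within each contig).
#' @export
simulate_hic_pairs <- function(g, n_pairs, decay_exponent = 1.0, seed = 1,
                               breaks = NULL, min_sep = 1000) {
  seqs <- as_sequences(g)
  if (!length(seqs)) stop("empty genome")
  if (n_pairs <= 0) stop("n_pairs must be > 0")
  lens <- nchar(seqs)
  elig <- names(seqs)[lens > min_sep]
  if (!length(elig)) stop("no scaffold longer than min_sep")
  with_seed(seed, {
    src <- if (length(elig) == 1) rep(elig, n_pairs) else
      sample(elig, n_pairs, replace = TRUE, prob = lens[elig])
    res <- lapply(elig, function(nm) {
      n <- sum(src == nm)
      if (!n) return(NULL)
      L <- lens[[nm]]
      a <- decay_exponent
      draw_sep <- function(m) {
        u <- runif(m)
        d <- if (abs(a - 1) < 1e-9) {
          min_sep * (L / min_sep)^u
        } else {
          (min_sep^(1 - a) + u * (L^(1 - a) - min_sep^(1 - a)))^(1 / (1 - a))
        }
        pmin(floor(d), L - 1L)
      }
      # locus-pair model: uniform anchor, random direction, rejection at the
      # scaffold boundary, so each locus pair at separation d has contact
      # probability proportional to d^-decay_exponent
      pa <- integer(0); pb <- integer(0)
      while (length(pa) < n) {
        m <- max(2L * (n - length(pa)), 100L)
        d <- draw_sep(m)
        x <- floor(runif(m) * L)
        sgn <- sample(c(-1L, 1L), m, replace = TRUE)
        y <- x + sgn * d
        ok <- y >= 0 & y < L
        pa <- c(pa, as.integer(x[ok]))
        pb <- c(pb, as.integer(y[ok]))
      }
      pa <- pa[seq_len(n)]; pb <- pb[seq_len(n)]
      data.frame(scaffold = nm, pos_a = pmin(pa, pb), pos_b = pmax(pa, pb),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    # re-express in contig coordinates
    map_end <- function(scaf, pos) {
      out_ctg <- character(length(pos)); out_pos <- integer(length(pos))
      for (nm in unique(scaf)) {
        sel <- scaf == nm
        b <- if (!is.null(breaks)) sort(unique(as.integer(breaks[[nm]]))) else integer(0)
        bounds <- c(0L, b, lens[[nm]])
        idx <- findInterval(pos[sel], bounds, rightmost.closed = FALSE, left.open = FALSE)
        nmout <- if (length(bounds) == 2L) rep(nm, sum(sel)) else
          sprintf("%s_c%d", nm, idx)
        out_ctg[sel] <- nmout
        out_pos[sel] <- pos[sel] - bounds[idx]
      }
      list(ctg = out_ctg, pos = out_pos)
    }
    ea <- map_end(res$scaffold, res$pos_a)
    eb <- map_end(res$scaffold, res$pos_b)
    structure(data.frame(contig_a = ea$ctg, pos_a = ea$pos,
                         contig_b = eb$ctg, pos_b = eb$pos,
                         stringsAsFactors = FALSE),
              class = c("mate_pairs", "data.frame"))
  })
}
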