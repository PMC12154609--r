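# Hi-C flank-linkage contig ordering: genome-wide unique k-mer discovery
# (default 32-mers), mate-pair filtering to uniquely placeable ends, link
# counting between contig flank windows (default 50 kb), and greedy
# order/orientation inference over the flank graph.

#' Genome-wide unique k-mers
#'
#' Positions (0-based, per contig) of k-mers whose canonical form occurs
#' exactly once across all contigs.
#'
#' @param contigs Named character vector of contig sequences (or a
#'   `simulated_genome` / `DNAStringSet`).
#' @param k K-mer size, 1-32 (default 32).
#' @return `unique_kmer_set` list: `k`, `positions` (named list of sorted
#'   integer vectors).
#' @export
unique_kmers <- function(contigs, k = 32) {
  seqs <- as_sequences(contigs)
  pos <- cpp_unique_kmer_positions(seqs, as.integer(k))
  names(pos) <- names(seqs)
  structure(list(k = as.integer(k), positions = pos),
            class = "unique_kmer_set")
}

#' @export
print.unique_kmer_set <- function(x, ...) {
  cat(sprintf("<unique_kmer_set> k=%d, %d contigs, %d unique positions\n",
              x$k, length(x$positions), sum(lengths(x$positions))))
  invisible(x)
}

#' Filter mate pairs to uniquely placeable ends
#'
#' A pair is retained when its read footprints `[pos, pos + read_span)`
#' overlap at least one genome-wide-unique k-mer start position — by default
#' on both ends (the stricter reading); `either_end = TRUE` relaxes to one.
#'
#' @param pairs `mate_pairs` data.frame (`contig_a,pos_a,contig_b,pos_b`).
#' @param uks A [unique_kmers()] result.
#' @param read_span Read footprint length in bp (default 100).
#' @param either_end Retain pairs with at least one placeable end.
#' @return Filtered `mate_pairs` data.frame.
#' @export
filter_pairs <- function(pairs, uks, read_span = 100, either_end = FALSE) {
  stopifnot(inherits(uks, "unique_kmer_set"))
  end_ok <- function(ctg, pos) {
    ok <- logical(length(pos))
    for (nm in unique(ctg)) {
      up <- uks$positions[[nm]]
      sel <- ctg == nm
      if (is.null(up) || !length(up)) { ok[sel] <- FALSE; next }
      # any unique-kmer start in [pos, pos + read_span - 1]
      lo <- findInterval(pos[sel] - 1L, up)
      hi <- findInterval(pos[sel] + read_span - 1L, up)
      ok[sel] <- hi > lo
    }
    ok
  }
  a <- end_ok(pairs$contig_a, pairs$pos_a)
  b <- end_ok(pairs$contig_b, pairs$pos_b)
  keep <- if (either_end) a | b else a & b
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

flank_ids <- function(contig_names, ambiguous) {
  unlist(lapply(seq_along(contig_names), function(i) {
    if (ambiguous[i]) paste0(contig_names[i], ":B")
    else paste0(contig_names[i], c(":L", ":R"))
  }))
}

#' Count mate-pair links between contig flanks
#'
#' For each pair of flank windows (default 50 kb) at contig ends, counts the
#' retained mate pairs whose two ends fall in the two flanks. Pairs landing
#' mid-contig are not counted. Contigs shorter than twice the flank use the
#' whole contig as a single ambiguous-orientation flank (`:B`).
#'
#' @param pairs `mate_pairs` data.frame (ideally [filter_pairs()] output).
#' @param contigs Named character vector of contig sequences, or a named
#'   integer vector of contig lengths.
#' @param flank Flank window size in bp (default 50000).
#' @return `link_matrix` list: `counts` (symmetric matrix over flank ids,
#'   zero diagonal), `flank`, `contig_lengths`.
#' @export
flank_link_matrix <- function(pairs, contigs, flank = 50000) {
  lens <- if (is.numeric(contigs)) {
    setNames(as.integer(contigs), names(contigs))
  } else nchar(as_sequences(contigs))
  if (is.null(names(lens))) stop("contigs must be named")
  ambiguous <- lens < 2L * flank
  ids <- flank_ids(names(lens), ambiguous)
  counts <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  assign_flank <- function(ctg, pos) {
    out <- rep(NA_character_, length(pos))
    for (nm in unique(ctg)) {
      sel <- ctg == nm
      L <- lens[[nm]]
      if (any(pos[sel] < 0 | pos[sel] >= L))
        stop("pair position outside contig ", nm)
      if (ambiguous[[nm]]) { out[sel] <- paste0(nm, ":B"); next }
      p <- pos[sel]
      out[sel] <- ifelse(p < flank, paste0(nm, ":L"),
                  ifelse(p >= L - flank, paste0(nm, ":R"), NA_character_))
    }
    out
  }
  fa <- assign_flank(pairs$contig_a, pairs$pos_a)
  fb <- assign_flank(pairs$contig_b, pairs$pos_b)
  keep <- !is.na(fa) & !is.na(fb) & fa != fb
  if (any(keep)) {
    tab <- table(factor(pmin(fa[keep], fb[keep]), levels = ids),
                 factor(pmax(fa[keep], fb[keep]), levels = ids))
    tm <- matrix(as.integer(tab), nrow = length(ids),
                 dimnames = dimnames(counts))
    counts <- counts + tm + t(tm)
  }
  structure(list(counts = counts, flank = as.integer(flank),
                 contig_lengths = lens),
            class = "link_matrix")
}

#' @export
print.link_matrix <- function(x, ...) {
  cat(sprintf("<link_matrix> %d contigs, flank %d bp, %d links\n",
              length(x$contig_lengths), x$flank, sum(x$counts) / 2))
  print(x$counts)
  invisible(x)
}

#' Greedy contig order and orientation from flank links
#'
#' Repeatedly joins the highest-count unused inter-contig flank pair that
#' keeps the join graph a set of simple paths (each flank used at most once,
#' no cycles); ties break lexicographically on flank ids. Orientation `+`
#' means the contig runs left-to-right along the path; the path direction is
#' canonicalised to start at the lexicographically smaller endpoint contig,
#' and recovery is meaningful up to whole-scaffold reversal. Isolated contigs
#' are appended in input order with `+` orientation; ambiguous single-flank
#' contigs report `+`.
#'
#' @param m A [flank_link_matrix()] result.
#' @return `scaffold_order` data.frame: `contig`, `orientation`, `path`
#'   (path membership index).
#' @export
order_and_orient <- function(m) {
  stopifnot(inherits(m, "link_matrix"))
  cnames <- names(m$contig_lengths)
  ids <- rownames(m$counts)
  ctg_of <- sub(":[LRB]$", "", ids)
  # candidate edges: upper triangle, different contigs, count > 0
  ut <- which(upper.tri(m$counts) & m$counts > 0, arr.ind = TRUE)
  if (nrow(ut)) {
    diffc <- ctg_of[ut[, 1]] != ctg_of[ut[, 2]]
    ut <- ut[diffc, , drop = FALSE]
  }
  edges <- data.frame(f1 = ids[ut[, 1]], f2 = ids[ut[, 2]],
                      n = m$counts[ut], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$n, edges$f1, edges$f2), , drop = FALSE]
  used <- setNames(integer(length(ids)), ids)   # degree per flank
  maxdeg <- ifelse(grepl(":B$", ids), 2L, 1L)
  parent <- setNames(cnames, cnames)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  accepted <- edges[0, ]
  for (k in seq_len(nrow(edges))) {
    e <- edges[k, ]
    c1 <- sub(":[LRB]$", "", e$f1); c2 <- sub(":[LRB]$", "", e$f2)
    if (used[[e$f1]] >= maxdeg[[match(e$f1, ids)]]) next
    if (used[[e$f2]] >= maxdeg[[match(e$f2, ids)]]) next
    r1 <- find(c1); r2 <- find(c2)
    if (r1 == r2) next
    parent[[r1]] <- r2
    used[[e$f1]] <- used[[e$f1]] + 1L
    used[[e$f2]] <- used[[e$f2]] + 1L
    accepted <- rbind(accepted, e)
  }
  # walk the accepted flank graph into paths
  adj <- list()
  add_adj <- function(a, b) { adj[[a]] <<- c(adj[[a]], b) }
  for (k in seq_len(nrow(accepted))) {
    add_adj(accepted$f1[k], accepted$f2[k])
    add_adj(accepted$f2[k], accepted$f1[k])
  }
  other_end <- function(f) {
    ctg <- sub(":[LRB]$", "", f)
    side <- sub("^.*:", "", f)
    if (side == "B") paste0(ctg, ":B") else
      paste0(ctg, ":", if (side == "L") "R" else "L")
  }
  deg_ctg <- vapply(cnames, function(cn) {
    fl <- ids[ctg_of == cn]
    sum(used[fl])
  }, 0L)
  visited <- setNames(rep(FALSE, length(cnames)), cnames)
  paths <- list()
  # endpoints: contigs with total degree < 2 (or isolated)
  repeat {
    endpoints <- cnames[!visited & deg_ctg <= 1L]
    if (!length(endpoints)) break
    start <- sort(endpoints)[1]
    # choose the free flank to start from (prefer L for isolated)
    fl <- ids[ctg_of == start]
    free <- fl[used[fl] < maxdeg[match(fl, ids)]]
    entry <- if (length(free)) sort(free)[1] else fl[1]
    path <- character(0); orient <- character(0)
    cur_entry <- entry
    repeat {
      ctg <- sub(":[LRB]$", "", cur_entry)
      side <- sub("^.*:", "", cur_entry)
      path <- c(path, ctg)
      visited[[ctg]] <- TRUE
      # entering through L means the contig runs + along the path
      orient <- c(orient, if (side == "R") "-" else "+")
      exit <- other_end(cur_entry)
      nxt <- setdiff(adj[[exit]] %||% character(0), character(0))
      nxt <- nxt[!visited[sub(":[LRB]$", "", nxt)]]
      if (!length(nxt)) break
      cur_entry <- nxt[1]
    }
    # canonical direction: smaller endpoint name first
    if (path[length(path)] < path[1]) {
      path <- rev(path)
      orient <- rev(ifelse(orient == "+", "-", "+"))
    }
    paths[[length(paths) + 1]] <- data.frame(contig = path, orientation = orient,
                                             stringsAsFactors = FALSE)
  }
  # anything left (cycle remnants cannot occur; isolated handled above)
  left <- cnames[!visited]
  for (cn in left)
    paths[[length(paths) + 1]] <- data.frame(contig = cn, orientation = "+",
                                             stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_along(paths), function(i)
    cbind(paths[[i]], path = i)))
  rownames(out) <- NULL
  structure(out, class = c("scaffold_order", "data.frame"))
}

#' @export
print.scaffold_order <- function(x, ...) {
  cat("<scaffold_order>", nrow(x), "contigs in", max(x$path), "path(s)\n")
  for (p in unique(x$path)) {
    sub <- x[x$path == p, ]
    cat(sprintf("  path %d: %s\n", p,
                paste0(sub$contig, "(", sub$orientation, ")", collapse = " - ")))
  }
  invisible(x)
}
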