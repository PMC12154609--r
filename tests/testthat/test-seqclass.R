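test_that("satellite_profile measures monomer coverage per window", {
  mono <- satellite_monomer()
  pure <- strrep(mono[[1]], 100)                     # 23,400 bp of satellite
  prof <- satellite_profile(pure, window = 10000)
  expect_true(all(prof$satellite_fraction == 1))
  set.seed(30)
  rnd <- random_dna(30000)
  prnd <- satellite_profile(rnd, window = 10000)
  expect_true(all(prnd$satellite_fraction < 0.01))
  # half-satellite window
  half <- paste0(substr(strrep(mono[[1]], 30), 1, 5000), random_dna(5000))
  ph <- satellite_profile(half, window = 10000)
  expect_equal(ph$satellite_fraction, 0.5, tolerance = 0.01)
  expect_error(satellite_profile(rnd, monomers = character(0)), "empty monomer")
  expect_error(satellite_profile(rnd, k = 500), "monomer length")
})

test_that("call_heterochromatin merges qualifying windows into regions", {
  prof <- structure(data.frame(window_start = seq(0, 40000, 10000),
                               satellite_fraction = c(0, 1, 1, 0, 0.6)),
                    window = 10000L,
                    class = c("satellite_profile", "data.frame"))
  het <- call_heterochromatin(prof)
  expect_identical(het$start, c(10000, 40000))
  expect_identical(het$end, c(30000, 50000))
  none <- call_heterochromatin(transform(prof, satellite_fraction = 0))
  expect_identical(nrow(none), 0L)
})

test_that("heterochromatin asymmetry preset yields a 4-fold X:Y ratio", {
  g <- simulate_pair(build_blueprint("HET_ASYMMETRY"))
  hx <- call_heterochromatin(satellite_profile(g$sequences["chrX"]))
  hy <- call_heterochromatin(satellite_profile(g$sequences["chrY"]))
  ratio <- sum(hx$end - hx$start) / sum(hy$end - hy$start)
  expect_identical(round(ratio), 4)
})

test_that("classify applies precedence, tiles the sequence, and handles trivial input", {
  set.seed(31)
  s <- random_dna(50000)
  # no evidence: one 'other' region
  ann <- classify(s)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$label, "other")
  expect_identical(ann$end, 50000L)
  # identical X and Y: a single telomere-anchored >= 99.9 arc becomes PAR
  prof <- sliding_identity(s, s)
  arcs <- homology_arcs(prof, threshold = 70)
  ann2 <- classify(s, arcs = arcs)
  expect_identical(ann2$label, "PAR")
  # heterochromatin outranks PAR where they overlap
  het <- data.frame(start = 10000, end = 20000, label = "heterochromatic")
  ann3 <- classify(s, arcs = arcs, het_regions = het)
  expect_identical(ann3$label, c("PAR", "heterochromatic", "PAR"))
  # tiling invariant: starts chain to ends, full coverage
  for (ann_k in list(ann, ann2, ann3)) {
    expect_identical(ann_k$start[1], 0L)
    expect_identical(ann_k$end[nrow(ann_k)], 50000L)
    if (nrow(ann_k) > 1)
      expect_identical(ann_k$start[-1], ann_k$end[-nrow(ann_k)])
  }
  # unanchored near-identity arc falls back to XTR, not PAR
  mid_arc <- data.frame(start = 20000, end = 30000, mean_identity = 99.99,
                        n_windows = 10L)
  ann4 <- classify(s, arcs = mid_arc)
  expect_identical(ann4$label, c("other", "XTR", "other"))
  expect_error(classify(s, het_regions = data.frame(start = 0, end = 60000,
                                                    label = "heterochromatic")),
               "outside")
})

test_that("classification is deterministic and stable under re-application", {
  g <- simulate_pair(build_blueprint("FULL_ARCHITECTURE", list(seed = 32)))
  res1 <- classify_pipeline(g$sequences["chrY"], g$sequences["chrX"])
  res2 <- classify_pipeline(g$sequences["chrY"], g$sequences["chrX"])
  expect_identical(res1$annotation, res2$annotation)
  # re-running classify on its own intervals (as the sole evidence of each
  # class) reproduces the same tiling
  ann <- res1$annotation
  again <- classify(g$sequences["chrY"],
                    arcs = local({
                      sel <- ann[ann$label %in% c("PAR", "XTR", "ancestral"), ]
                      data.frame(start = sel$start, end = sel$end,
                                 mean_identity = c(PAR = 99.99, XTR = 99.5,
                                                   ancestral = 88)[sel$label],
                                 n_windows = 1L)
                    }),
                    footprint = ann[ann$label == "ampliconic", c("start", "end")],
                    het_regions = ann[ann$label == "heterochromatic", ])
  expect_identical(again, ann)
})

test_that("full-architecture classification recovers truth labels per base", {
  accs <- vapply(1:5, function(s) {
    g <- simulate_pair(build_blueprint("FULL_ARCHITECTURE", list(seed = 40 + s)))
    res <- classify_pipeline(g$sequences["chrY"], g$sequences["chrX"])
    L <- nchar(g$sequences[["chrY"]])
    truth <- label_vector(g$truth[g$truth$seq_name == "chrY", ], L)
    mean(truth == label_vector(res$annotation, L))
  }, 0)
  expect_true(all(accs >= 0.99))
})
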