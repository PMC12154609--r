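test_that("unique_kmers matches a brute-force census", {
  set.seed(60)
  contigs <- c(c1 = random_dna(3000), c2 = random_dna(2000))
  for (k in c(8L, 32L)) {
    uk <- unique_kmers(contigs, k = k)
    # brute force: canonical k-mer counts across both contigs
    census <- table(unlist(lapply(contigs, function(s) {
      st <- seq_len(nchar(s) - k + 1)
      km <- substring(s, st, st + k - 1)
      pmin(km, rc_oracle(km))
    })))
    singles <- names(census)[census == 1]
    for (nm in names(contigs)) {
      s <- contigs[[nm]]
      st <- seq_len(nchar(s) - k + 1)
      km <- substring(s, st, st + k - 1)
      want <- st[pmin(km, rc_oracle(km)) %in% singles] - 1L
      expect_identical(uk$positions[[nm]], as.integer(want))
    }
  }
})

test_that("unique_kmers handles degenerate repeats", {
  # homopolymer: its single 32-mer occurs 69 times
  expect_identical(lengths(unique_kmers(c(a = strrep("A", 100)))$positions),
                   c(a = 0L))
  # two identical contigs: nothing is unique
  set.seed(61)
  dup <- random_dna(5000)
  expect_identical(sum(lengths(unique_kmers(c(x = dup, y = dup))$positions)), 0L)
  # a random contig is almost entirely unique
  r <- random_dna(10000)
  expect_gt(length(unique_kmers(c(r = r))$positions$r), 9900)
})

test_that("filter_pairs keeps only pairs anchored in unique sequence", {
  set.seed(62)
  core <- random_dna(30000)
  contigs <- c(u = random_dna(30000), d1 = core, d2 = core)
  uk <- unique_kmers(contigs)
  pairs <- data.frame(contig_a = c("u", "u", "d1"),
                      pos_a = c(100L, 200L, 500L),
                      contig_b = c("u", "d1", "d2"),
                      pos_b = c(20000L, 1000L, 2000L))
  kept <- filter_pairs(pairs, uk)
  expect_identical(nrow(kept), 1L)                     # only u-u survives
  expect_identical(kept$contig_a, "u")
  either <- filter_pairs(pairs, uk, either_end = TRUE)
  expect_identical(nrow(either), 2L)                   # u-d1 regains entry
  # an empty unique set removes everything
  empty_uk <- unique_kmers(c(x = core, y = core))
  pxy <- data.frame(contig_a = "x", pos_a = 10L, contig_b = "y", pos_b = 10L)
  expect_identical(nrow(filter_pairs(pxy, empty_uk)), 0L)
  # an all-unique genome passes everything through
  expect_identical(filter_pairs(pairs[1, ], unique_kmers(contigs["u"])),
                   pairs[1, ])
})

test_that("flank_link_matrix counts flank-to-flank pairs symmetrically", {
  lens <- c(a = 100000L, b = 100000L)
  pairs <- data.frame(
    contig_a = c("a", "a", "a", "b"),
    pos_a = c(95000L, 60000L, 10L, 99000L),
    contig_b = c("b", "b", "a", "b"),
    pos_b = c(2000L, 2000L, 99999L, 99500L))
  m <- flank_link_matrix(pairs, lens, flank = 50000)
  expect_true(isSymmetric(m$counts))
  expect_true(all(diag(m$counts) == 0))
  expect_identical(m$counts["a:R", "b:L"], 2L)   # both ends in flanks
  expect_identical(m$counts["a:L", "a:R"], 1L)   # intra-contig flank pair
  expect_identical(sum(m$counts) / 2, 3)         # mid-contig end dropped
  # short contigs collapse to one ambiguous flank
  ms <- flank_link_matrix(pairs[1, ], c(a = 100000L, b = 60000L), flank = 50000)
  expect_true("b:B" %in% rownames(ms$counts))
  expect_identical(ms$counts["a:R", "b:B"], 1L)
})

test_that("order_and_orient recovers paths and breaks ties deterministically", {
  # single contig
  m1 <- flank_link_matrix(data.frame(contig_a = character(0), pos_a = integer(0),
                                     contig_b = character(0), pos_b = integer(0)),
                          c(solo = 120000L))
  o1 <- order_and_orient(m1)
  expect_identical(o1$contig, "solo")
  expect_identical(o1$orientation, "+")
  # symmetric two-contig tie: resolved lexicographically, reproducibly
  lens <- c(a = 120000L, b = 120000L)
  mk <- function() {
    pairs <- data.frame(contig_a = c("a", "a"), pos_a = c(1000L, 119000L),
                        contig_b = c("b", "b"), pos_b = c(1000L, 119000L))
    order_and_orient(flank_link_matrix(pairs, lens, flank = 50000))
  }
  expect_identical(mk(), mk())
  expect_identical(mk()$contig, c("a", "b"))
})

test_that("scaffold order is recovered from simulated mate pairs", {
  ok <- vapply(1:10, function(s) recover_scaffold(700 + s), TRUE)
  expect_gte(sum(ok), 9)
})
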