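mk_matches <- function(i, j, w) {
  structure(data.frame(i = as.integer(i), j = as.integer(j),
                       strand = rep_len("+", length(i)),
                       w = rep_len(as.integer(w), length(i))),
            mode = "self", class = c("dot_matches", "data.frame"))
}

test_that("diagonal_runs chains matches by offset and gap", {
  m <- mk_matches(c(0, 50, 100), c(100, 150, 200), w = 50)
  r <- diagonal_runs(m, max_gap = 0)
  expect_identical(nrow(r), 1L)
  expect_equal(r$offset, 100)
  expect_identical(r$span, 150L)
  expect_identical(r$a_start, 0L)
  expect_identical(r$b_end, 250L)
  # a 10-kb hole on one diagonal splits the run at max_gap = 2 kb
  m2 <- mk_matches(c(0, 10000), c(5000, 15000), w = 50)
  expect_identical(nrow(diagonal_runs(m2, max_gap = 2000)), 2L)
  # empty in, empty out
  expect_identical(nrow(diagonal_runs(mk_matches(integer(0), integer(0), 50))), 0L)
})

test_that("call_amplicons enforces the >99% / >10 kb definition", {
  set.seed(20)
  unit <- random_dna(15000)
  seq1 <- paste0(unit, random_dna(50000), unit)
  runs <- diagonal_runs(self_dotplot(seq1, w = 250))
  amp <- call_amplicons(seq1, runs)
  expect_identical(nrow(amp), 1L)
  expect_equal(amp$identity, 100)
  fp <- amplicon_footprint(amp)
  expect_identical(sum(fp$end - fp$start), 30000)
  # two exact 5-kb copies: span below the threshold, no call
  short <- paste0(u5 <- random_dna(5000), random_dna(30000), u5)
  runs5 <- diagonal_runs(self_dotplot(short, w = 250))
  expect_identical(nrow(call_amplicons(short, runs5)), 0L)
  # with min_identity = 100 a diverged copy pair is rejected
  p <- simulate_block_pair(15000, 0.002, seed = 1)
  div <- paste0(p$a, random_dna(50000), p$b)
  div_runs <- diagonal_runs(self_dotplot(div, w = 250))
  expect_identical(nrow(call_amplicons(div, div_runs, min_identity = 100)), 0L)
  expect_identical(nrow(call_amplicons(div, div_runs)), 1L)
  # runs outside the sequence are rejected
  bad_runs <- data.frame(a_start = 0, a_end = 100, b_start = 200, b_end = 300,
                         offset = 200, n_matches = 1L, span = 100)
  expect_error(call_amplicons("ACGT", bad_runs), "outside")
})

test_that("footprint is invariant to run order and exclusion masks amplicons", {
  set.seed(21)
  u <- random_dna(12000)
  s <- paste0(u, random_dna(20000), u, random_dna(20000), u)
  runs <- diagonal_runs(self_dotplot(s, w = 250))
  amp1 <- call_amplicons(s, runs)
  amp2 <- call_amplicons(s, runs[rev(seq_len(nrow(runs))), ])
  expect_identical(amplicon_footprint(amp1), amplicon_footprint(amp2))
  # excluding the first copy's interval drops the pairs that touch it
  excl <- data.frame(start = 0, end = 12000)
  amp3 <- call_amplicons(s, runs, exclude = excl)
  expect_true(all(amp3$a_start >= 12000))
})

test_that("tandem periodicity finds the unit offset", {
  # exact dimer of a 1-kb unit
  set.seed(22)
  d <- self_dotplot(tandem(random_dna(1000), 2), w = 250)
  expect_equal(tandem_periodicity(d, min_offset = 500), 1000)
  # random sequence: no periodic matches
  expect_error(tandem_periodicity(self_dotplot(random_dna(20000), w = 250)),
               "no periodic matches")
})

test_that("array_span measures exact arrays to the unit", {
  set.seed(23)
  tri <- tandem(random_dna(10000), 3)
  d <- self_dotplot(tri, w = 250)
  u <- tandem_periodicity(d)
  expect_equal(u, 10000)
  a <- array_span(d, u)
  expect_identical(a$span, 30000)
  expect_identical(a$n_units, 3)
  # matches only at twice the unit: error at tolerance below the unit
  m2 <- mk_matches(0, 20000, 250)
  expect_error(array_span(m2, unit = 10000, tolerance = 500), "no matches")
})

test_that("periodicity and span are recovered on diverged arrays across seeds", {
  unitlen <- 20000; copies <- 4
  for (s in 1:6) {
    g <- simulate_pair(build_blueprint("SSTY_ARRAY", list(
      seed = 600 + s,
      "y.1.length_bp" = 10000L, "y.3.length_bp" = 10000L,
      "y.2.length_bp" = as.integer(unitlen * copies),
      "y.2.unit_length_bp" = as.integer(unitlen),
      "y.2.copies" = as.integer(copies),
      "y.2.divergence" = 0.004)))
    d <- self_dotplot(g$sequences["chrY"], w = 250)
    u <- tandem_periodicity(d)
    expect_equal(u, unitlen)
    a <- array_span(d, u)
    expect_lte(abs(a$span - unitlen * copies), unitlen)
    expect_identical(a$n_units, copies)
  }
})
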