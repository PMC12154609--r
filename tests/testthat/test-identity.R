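test_that("count_differences counts mismatching ACGT positions only", {
  expect_identical(count_differences("ACGT", "ACGT"), 0L)
  expect_identical(count_differences("ACGTACGTAC", "ACGAACGTAT"), 2L)
  expect_identical(count_differences("ACGT", "ANGT"), 0L)   # N never counted
  expect_identical(count_differences("AAAA", "TTTT"),
                   count_differences("TTTT", "AAAA"))       # symmetric
  s <- random_dna(200)
  expect_identical(count_differences(s, s), 0L)
  expect_error(count_differences("ACGT", "ACG"), "equal length")
})

test_that("sliding identity windows aggregate to the global identity", {
  set.seed(7)
  p <- simulate_block_pair(20000, 0.03)
  prof <- sliding_identity(p$a, p$b, window = 1000)
  expect_identical(nrow(prof), 20L)
  weighted <- sum(prof$identity * prof$n_compared) / sum(prof$n_compared)
  expect_equal(weighted, global_identity(p$a, p$b))
  ident <- sliding_identity(p$a, p$a, window = 1000)
  expect_true(all(ident$identity == 100))
  # windows with nothing comparable are missing, not zero
  prof2 <- sliding_identity(strrep("N", 2000), strrep("N", 2000), window = 1000)
  expect_true(all(is.na(prof2$identity)))
  expect_true(all(prof2$n_compared == 0))
})

test_that("XTR and Med14 blocks report their characteristic identities", {
  xtr <- vapply(1:5, function(s) {
    g <- simulate_pair(build_blueprint("XTR", list(seed = s)))
    b <- linked_block_pair(g, 1)
    global_identity(b$y, b$x)
  }, 0)
  expect_equal(round(mean(xtr), 1), 99.5)
  med <- vapply(1:10, function(s) {
    p <- simulate_block_pair(5000, 0.07, seed = 100 + s)
    global_identity(p$a, p$b)
  }, 0)
  expect_equal(round(mean(med)), 93)
})

test_that("PAB detection finds the first sustained identity collapse", {
  # all-pseudoautosomal profile: no boundary
  flat <- sliding_identity(s <- random_dna(20000), s, window = 1000)
  expect_true(is.na(detect_pab(flat)))
  # constructed switch at 10 kb
  set.seed(8)
  a10 <- random_dna(10000)
  tail_pair <- simulate_block_pair(10000, 0.05)
  prof <- sliding_identity(paste0(a10, tail_pair$a), paste0(a10, tail_pair$b),
                           window = 1000)
  expect_identical(detect_pab(prof, threshold = 99.9, k_consecutive = 3), 10000L)
  # a short dip (< k windows) does not trigger a boundary
  dip <- data.frame(window_start = seq(0, 9000, 1000), window_len = 1000L,
                    identity = c(100, 100, 95, 95, 100, 100, 100, 100, 100, 100),
                    n_compared = 1000L)
  expect_true(is.na(detect_pab(dip, threshold = 99.9, k_consecutive = 3)))
  expect_identical(detect_pab(dip, threshold = 99.9, k_consecutive = 2), 2000)
  expect_error(detect_pab(dip[0, ]), "empty")
})

test_that("PAB recovery on PAR-preset chromosomes is within one window", {
  hits <- vapply(1:10, function(s) {
    g <- simulate_pair(build_blueprint("PAR", list(seed = 300 + s)))
    prof <- sliding_identity(g$sequences["chrY"], g$sequences["chrX"])
    detect_pab(prof)
  }, 0)
  expect_true(all(abs(hits - 300000) <= 1000))
})

test_that("homology arcs merge runs above threshold and respect min_len", {
  mkprof <- function(idy) data.frame(window_start = seq_along(idy) * 1000 - 1000,
                                     window_len = 1000L, identity = idy,
                                     n_compared = 1000L)
  # uniform 99.5% block: one arc spanning everything
  a1 <- homology_arcs(mkprof(rep(99.5, 207)), threshold = 95)
  expect_identical(nrow(a1), 1L)
  expect_identical(a1$end - a1$start, 207000)
  expect_equal(a1$mean_identity, 99.5)
  # uniform 90%: nothing above 95
  expect_identical(nrow(homology_arcs(mkprof(rep(90, 50)), threshold = 95)), 0L)
  # two runs split by a low valley
  a3 <- homology_arcs(mkprof(c(rep(99, 20), rep(80, 5), rep(99, 20))),
                      threshold = 95)
  expect_identical(nrow(a3), 2L)
  expect_identical(a3$start, c(0, 25000))
  # min_len filters the shorter arc
  a4 <- homology_arcs(mkprof(c(rep(99, 3), rep(80, 5), rep(99, 20))),
                      threshold = 95, min_len = 5000)
  expect_identical(nrow(a4), 1L)
})

test_that("PAR recombination rate follows the obligatory-crossover formula", {
  expect_equal(par_recombination_rate(1e6), 50)
  expect_equal(par_recombination_rate(5e5), 100)
  expect_identical(trunc(par_recombination_rate(3e5)), 166)
  expect_error(par_recombination_rate(0), "> 0")
})
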