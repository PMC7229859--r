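gr <- function(chrom, s0, e0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0))
}

test_that("shuffled controls conserve region count and lengths", {
  regions <- c(gr("chrA", 0, 200), gr("chrA", 5000, 5600))
  sizes <- c(chrA = 20000)
  sets <- shuffle_regions(regions, sizes, n_sets = 5, seed = 1)
  expect_length(sets, 5L)
  for (s in sets) {
    expect_length(s, 2L)
    expect_setequal(GenomicRanges::width(s), c(200, 600))
    expect_true(all(GenomicRanges::end(s) <= 20000))
    # non-overlapping within a set
    expect_equal(sum(GenomicRanges::width(GenomicRanges::reduce(s, min.gapwidth = 0L))),
                 sum(GenomicRanges::width(s)))
  }
  # same seed, same placements
  again <- shuffle_regions(regions, sizes, n_sets = 5, seed = 1)
  expect_identical(lapply(sets, as.character), lapply(again, as.character))
})

test_that("infeasible placements raise a placement error", {
  regions <- gr("chrA", 0, 200)
  sizes <- c(chrA = 1000)
  wall <- gr("chrA", 0, 1000)  # exclusion covers the whole chromosome
  expect_error(shuffle_regions(regions, sizes, exclude = wall, seed = 1,
                               max_attempts = 50), "could not place")
  # region longer than its chromosome
  expect_error(shuffle_regions(gr("chrA", 0, 2000), sizes, seed = 1),
               "longer than its chromosome")
})

test_that("shuffled overlap rate converges to the uniform-placement expectation", {
  # single 100 bp region on a 10 kb chromosome; feature = [0, 1000).
  # a placement overlaps iff its 0-based start is in [0, 999], i.e.
  # 1000 of the 9901 equally likely starts
  region <- gr("chrA", 4000, 4100)
  feature <- gr("chrA", 0, 1000)
  sizes <- c(chrA = 10000)
  sets <- shuffle_regions(region, sizes, n_sets = 400, seed = 7)
  hits <- vapply(sets, function(s)
    GenomicRanges::countOverlaps(s, feature) > 0L, TRUE)
  p_exact <- 1000 / 9901
  se <- sqrt(p_exact * (1 - p_exact) / 400)
  expect_lt(abs(mean(hits) - p_exact), 3 * se)
})

test_that("enrichment is the observed/simulated overlap ratio", {
  regions <- c(gr("chrA", 0, 200), gr("chrA", 1000, 1200))
  feature <- gr("chrA", 100, 1100)
  # identity controls give ratio 1
  e <- enrichment(regions, feature, controls = list(regions))
  expect_equal(e$ratio, 1.0)
  # hand-built controls: 2 then 0 overlapping -> simulated mean 1
  c1 <- regions
  c2 <- c(gr("chrA", 5000, 5200), gr("chrA", 6000, 6200))
  e2 <- enrichment(regions, feature, controls = list(c1, c2))
  expect_equal(e2$observed, 2)
  expect_equal(e2$simulated, 1)
  expect_equal(e2$ratio, 2.0)
  # disjoint feature: observed 0, defined ratio 0
  far <- gr("chrA", 9000, 9100)
  e3 <- enrichment(regions, far, controls = list(c(far, far[1])))
  expect_equal(e3$observed, 0)
  expect_equal(e3$ratio, 0)
  # empty denominator flagged undefined
  e4 <- enrichment(regions, far, controls = list(regions))
  expect_false(e4$defined)
})

test_that("whole-genome feature gives enrichment 1 for any controls", {
  sizes <- c(chrA = 10000)
  genome_feature <- gr("chrA", 0, 10000)
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    s0 <- sample(0:9000, n)
    regions <- gr("chrA", s0, s0 + sample(50:300, n, replace = TRUE))
    controls <- shuffle_regions(regions, sizes, n_sets = 3, seed = rep)
    e <- enrichment(regions, genome_feature, controls)
    expect_equal(e$ratio, 1.0)
  }
})

test_that("segment-level Fisher test matches the worked table", {
  # universe of 8 segments: 4 in A (3 shared with B), 4 outside A (1 in B)
  g <- toy_grid(8, 100)
  a <- gr("chrT", 0, 400)
  b <- c(gr("chrT", 0, 300), gr("chrT", 400, 500))
  res <- overlap_fisher(a, b, g)
  expect_equal(unname(as.vector(res$table)), c(3L, 1L, 1L, 3L))
  expect_equal(res$p_value, oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-12)
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-9)
})

test_that("Fisher p equals exhaustive hypergeometric enumeration on small tables", {
  count <- 0
  for (a in 0:6) for (b in 0:6) for (c in 0:6) for (d in 0:6) {
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    p_impl <- stats::fisher.test(tab)$p.value
    expect_equal(p_impl, oracle_fisher_p(a, b, c, d), tolerance = 1e-12)
    count <- count + 1
  }
  expect_gt(count, 1000)
})

test_that("concordance and depletion point the expected directions", {
  g <- toy_grid(30, 100)
  a <- gr("chrT", 0, 1000)
  res_same <- overlap_fisher(a, a, g)
  expect_gt(res_same$odds_ratio, 1)
  b <- gr("chrT", 1500, 2500)
  res_disj <- overlap_fisher(a, b, g)
  expect_lt(res_disj$odds_ratio, 1)
  expect_lt(res_same$p_value, res_disj$p_value)
})

test_that("dinucleotide frequencies use overlapping windows and skip Ns", {
  genome <- Biostrings::DNAStringSet(c(chrA = "CGCGAAAAACGTNNCG"))
  f <- function(s0, e0, dn) dinucleotide_freq(gr("chrA", s0, e0), genome, dn)
  expect_equal(f(0, 4, "CG"), 2 / 3)    # CGCG
  expect_equal(f(4, 8, "CG"), 0)        # AAAA
  expect_equal(f(8, 12, "CG"), 1 / 3)   # ACGT
  # windows containing N are removed from numerator and denominator:
  # TNNCG has windows TN, NN, NC, CG -> 1 valid window, 1 match
  expect_equal(f(11, 16, "CG"), 1)
  # length-1 region is undefined
  expect_true(is.na(f(0, 1, "CG")))
  # case-insensitive
  genome_lc <- Biostrings::DNAStringSet(c(chrA = "cgcg"))
  expect_equal(dinucleotide_freq(gr("chrA", 0, 4), genome_lc, "cg"), 2 / 3)
})

test_that("Welch t-test matches the hand-computed example", {
  a <- c(0.1, 0.2, 0.3); b <- c(0.4, 0.5, 0.6)
  # means 0.2 and 0.5, both variances 0.01:
  # t = -0.3 / sqrt(0.01/3 + 0.01/3) = -3.674235, df = 4
  res <- compare_composition(a, b)
  expect_equal(res$t_statistic, -0.3 / sqrt(0.02 / 3), tolerance = 1e-9)
  expect_equal(res$t_statistic, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4, tolerance = 1e-9)

  same <- compare_composition(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  jit <- compare_composition(c(0, 1e-9, 0), c(1, 1 - 1e-9, 1))
  expect_lt(jit$p_value, 1e-6)

  und <- compare_composition(c(0.5, 0.5), c(0.5, 0.5))
  expect_true(is.na(und$t_statistic))
})
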