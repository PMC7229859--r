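test_that("final score averages rows with at most one missing protein", {
  vals <- rbind(c(1, 1, 0, NA),   # 2/3
                c(1, 0, NA, NA),  # too many NA
                c(1, 1, 1, 1),    # 1
                c(0, 0, 0, NA),   # 0
                c(NA, NA, NA, NA))
  fs <- final_scores(vals, min_non_na = 3L)
  expect_equal(fs, c(2 / 3, NA, 1, 0, NA))
  # generalization: 5 proteins, 4 non-NA, min 4
  fs5 <- final_scores(rbind(c(1, 1, 0, 1, NA)), min_non_na = 4L)
  expect_equal(fs5, 3 / 4)
})

test_that("build_rsm validates tracks and is column-permutation invariant", {
  g <- toy_grid(6)
  tr <- function(p, P, N = 2) score_protein(P, N, grid = g, protein = p)
  tracks <- list(tr("A", c(0, 2, 2, 1, 0, 1)),
                 tr("B", c(1, 2, 0, 0, 1, 1)),
                 tr("C", c(2, 2, 1, 0, 0, 0)))
  rsm <- build_rsm(tracks, g, min_non_na = 2L)
  rsm_perm <- build_rsm(tracks[c(3, 1, 2)], g, min_non_na = 2L)
  expect_equal(rsm$fs, rsm_perm$fs)
  expect_error(build_rsm(tracks[1], g), ">= 2")
  short <- list(tr("A", c(0, 2, 2, 1, 0, 1)),
                score_protein(c(1, 1), 2, protein = "B"))
  expect_error(build_rsm(short, g), "grid")
})

test_that("with four proteins the attainable FS values match the canonical list", {
  expect_equal(attainable_scores(4L),
               sort(unique(c(0, 1/4, 1/3, 1/2, 2/3, 3/4, 1))))
  set.seed(3)
  for (rep in 1:40) {
    vals <- matrix(sample(c(1L, 0L, NA), 80, replace = TRUE), ncol = 4)
    fs <- final_scores(vals, 3L)
    obs <- unique(fs[!is.na(fs)])
    expect_true(all(vapply(obs, function(v)
      any(abs(v - c(0, 1/4, 1/3, 1/2, 2/3, 3/4, 1)) < 1e-12), TRUE)))
  }
})

test_that("extract_regions merges maximal same-score runs per chromosome", {
  rsm <- toy_rsm(rbind(c(0, 0), c(0, 0), c(NA, NA), c(1, 1), c(0, 0)),
                 min_non_na = 2L)
  at0 <- extract_regions(rsm, 0)
  expect_length(at0, 2L)
  expect_equal(GenomicRanges::start(at0) - 1L, c(0L, 800L))
  expect_equal(GenomicRanges::end(at0), c(400L, 1000L))
  expect_equal(at0$n_segments, c(2L, 1L))
  # all-NA matrix yields nothing
  rsm_na <- toy_rsm(matrix(NA_integer_, 3, 2), min_non_na = 1L)
  expect_length(extract_regions(rsm_na, 0), 0L)
})

test_that("adjacent same-score segments on different chromosomes stay separate", {
  g <- bin_genome(c(chrA = 200, chrB = 200), 200)
  vals <- rbind(c(0L, 0L), c(0L, 0L))
  rsm <- structure(list(grid = g, proteins = c("p1", "p2"), values = vals,
                        fs = final_scores(vals, 2L), min_non_na = 2L),
                   class = "score_matrix")
  expect_length(extract_regions(rsm, 0), 2L)
})

test_that("regions at all attainable scores partition the scored segments", {
  set.seed(5)
  for (rep in 1:20) {
    vals <- matrix(sample(c(1L, 0L, NA), 120, replace = TRUE), ncol = 4)
    rsm <- toy_rsm(vals, min_non_na = 3L)
    scores <- attainable_scores(rsm)
    covered <- sum(vapply(scores, function(s)
      sum(extract_regions(rsm, s)$n_segments), 0L))
    expect_equal(covered, sum(!is.na(rsm$fs)))
  }
})

test_that("extract_regions round-trips to the originating segments", {
  set.seed(9)
  vals <- matrix(sample(c(1L, 0L, NA), 80, replace = TRUE), ncol = 4)
  rsm <- toy_rsm(vals, min_non_na = 3L)
  w <- rsm$grid$bin_width
  for (s in attainable_scores(rsm)) {
    regions <- extract_regions(rsm, s)
    segs <- sort(unlist(lapply(seq_along(regions), function(i) {
      seq((GenomicRanges::start(regions)[i] - 1L) %/% w,
          (GenomicRanges::end(regions)[i] - 1L) %/% w)
    })))
    expect_equal(segs + 1L, which(!is.na(rsm$fs) & abs(rsm$fs - s) <= 1e-9),
                 ignore_attr = TRUE)
  }
})

test_that("call_vots returns sorted FS = 0 regions and honors the score knob", {
  rsm <- toy_rsm(rbind(c(0, 0, 0, NA), c(1, 1, 1, 1), c(1, 0, 0, 0),
                       c(0, 0, 0, 0)), min_non_na = 3L)
  vots <- call_vots(rsm)
  expect_length(vots, 2L)  # rows 1 and 4
  expect_equal(GenomicRanges::start(vots) - 1L, c(0L, 600L))
  # FS = 0.25 row is not a VOT under the default, but is at 0.25
  expect_length(call_vots(rsm, variable_score = 0.25), 1L)
  # all-reproducible matrix yields zero VOTs
  rsm1 <- toy_rsm(matrix(1L, 4, 4), min_non_na = 3L)
  expect_length(call_vots(rsm1), 0L)
})

test_that("RSM TSV round-trips through write and read", {
  rsm <- toy_rsm(rbind(c(0, 0, 1, NA), c(1, 1, 1, 1), c(NA, NA, 0, 0)),
                 min_non_na = 3L)
  path <- tempfile(fileext = ".tsv")
  write_rsm_tsv(rsm, path, header = "# test")
  back <- read_rsm_tsv(path, bin_width = 200L)
  expect_equal(back$values, rsm$values, ignore_attr = TRUE)
  expect_equal(back$fs, rsm$fs)
  expect_identical(back$proteins, rsm$proteins)
})

test_that("VOT BED export writes BED5 with scaled scores", {
  rsm <- toy_rsm(rbind(c(0, 0, 0, 0), c(NA, NA, NA, NA)), min_non_na = 3L)
  path <- tempfile(fileext = ".bed")
  write_regions_bed(call_vots(rsm), path, header = "# prov")
  lines <- readLines(path)
  expect_equal(lines[1], "# prov")
  rec <- strsplit(lines[2], "\t")[[1]]
  expect_equal(rec, c("chrT", "0", "200", "VOT_1", "0"))
})
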