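#' Read a BED3+ feature file as a GRanges
#'
#' @param path BED path (0-based half-open).
#' @param name Feature-set label stored in the \code{feature} metadata
#'   column; default the file name.
#' @return \code{GRanges}.
#' @export
read_features <- function(path, name = basename(path)) {
  gr <- read_peaks(path, format = "bed3plus")
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$feature <- rep(name, length(gr))
  gr
}

#' Randomly relocate regions to build matched control sets
#'
#' Each control set contains the same number of regions with identical
#' lengths as the input. Placements are uniform over valid start
#' positions, non-overlapping within a set, and avoid \code{exclude}
#' intervals when given. By default each region stays on its own
#' chromosome; with \code{across_chroms = TRUE} a chromosome is drawn
#' with probability proportional to its length among those that can hold
#' the region.
#'
#' @param regions \code{GRanges} to relocate.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_sets Number of independent control sets; default 1.
#' @param exclude Optional \code{GRanges} the placements must not touch.
#' @param across_chroms Allow relocation to other chromosomes.
#' @param max_attempts Placement attempts per region before giving up.
#' @param seed Optional integer seed; when NULL the current RNG state is
#'   used.
#' @return List of \code{GRanges}, one per control set.
#' @export
shuffle_regions <- function(regions, chrom_sizes, n_sets = 1L,
                            exclude = NULL, across_chroms = FALSE,
                            max_attempts = 1000L, seed = NULL) {
  stopifnot(length(regions) > 0L, length(chrom_sizes) > 0L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  widths <- GenomicRanges::width(regions)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  if (!across_chroms && any(widths > chrom_sizes[chroms])) {
    stop("a region is longer than its chromosome")
  }
  lapply(seq_len(n_sets), function(set) {
    placed_start <- integer(0)
    placed_end <- integer(0)
    placed_chrom <- character(0)
    for (i in order(widths, decreasing = TRUE)) {
      w <- widths[i]
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        if (across_chroms) {
          fits <- names(chrom_sizes)[chrom_sizes >= w]
          if (length(fits) == 0L) break
          chrom <- sample(fits, 1L, prob = chrom_sizes[fits])
        } else {
          chrom <- chroms[i]
        }
        max_start <- chrom_sizes[[chrom]] - w + 1L
        if (max_start < 1L) next
        s <- sample.int(max_start, 1L)  # 1-based start
        e <- s + w - 1L
        same <- placed_chrom == chrom
        if (any(same & placed_start <= e & placed_end >= s)) next
        if (!is.null(exclude) && length(exclude)) {
          cand <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
          if (GenomicRanges::countOverlaps(cand, exclude,
                                           ignore.strand = TRUE) > 0L) next
        }
        placed_start <- c(placed_start, s)
        placed_end <- c(placed_end, e)
        placed_chrom <- c(placed_chrom, chrom)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf("could not place region %d (width %d on %s) after %d attempts",
                     i, w, chroms[i], max_attempts))
      }
    }
    GenomicRanges::GRanges(placed_chrom,
                           IRanges::IRanges(placed_start, placed_end))
  })
}

#' Feature enrichment against matched control regions
#'
#' The enrichment of a region set at a feature is the number of regions
#' with >= 1 bp overlap with the feature, divided by the mean such count
#' over the control sets.
#'
#' @param regions \code{GRanges} (e.g. called VOTs).
#' @param feature \code{GRanges} of the feature intervals.
#' @param controls List of control \code{GRanges} (see
#'   [shuffle_regions()]).
#' @param pseudocount Added to numerator and denominator counts;
#'   default 0 (an all-zero denominator is reported as undefined).
#' @return List with \code{observed}, \code{simulated} (mean count),
#'   \code{ratio} (NA with \code{defined = FALSE} when the denominator is
#'   0) and \code{defined}.
#' @export
enrichment <- function(regions, feature, controls, pseudocount = 0) {
  stopifnot(length(controls) >= 1L)
  n_overlap <- function(x) {
    sum(GenomicRanges::countOverlaps(x, feature, ignore.strand = TRUE) > 0L)
  }
  obs <- n_overlap(regions) + pseudocount
  sim <- mean(vapply(controls, n_overlap, 0)) + pseudocount
  if (sim > 0) {
    list(observed = obs, simulated = sim, ratio = obs / sim, defined = TRUE)
  } else {
    list(observed = obs, simulated = sim, ratio = NA_real_, defined = FALSE)
  }
}

#' Segment-level Fisher exact test of two interval sets
#'
#' Classifies every grid segment by whether it overlaps set A and set B,
#' and applies the two-sided Fisher exact test to the resulting 2x2
#' table. The segment is the counting unit.
#'
#' @param regions_a,regions_b \code{GRanges}.
#' @param grid A \code{segment_grid} defining the universe.
#' @return List with \code{table} (2x2 matrix), \code{odds_ratio}
#'   (conditional MLE; NA when a margin is empty), \code{p_value}.
#' @export
overlap_fisher <- function(regions_a, regions_b, grid) {
  stopifnot(inherits(grid, "segment_grid"),
            length(regions_a) > 0L, length(regions_b) > 0L)
  in_a <- GenomicRanges::countOverlaps(grid$bins, regions_a,
                                       ignore.strand = TRUE) > 0L
  in_b <- GenomicRanges::countOverlaps(grid$bins, regions_b,
                                       ignore.strand = TRUE) > 0L
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(A = c("in_A", "not_A"),
                                B = c("in_B", "not_B")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    ft <- stats::fisher.test(tab)
    return(list(table = tab, odds_ratio = NA_real_, p_value = ft$p.value))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Per-region dinucleotide frequency
#'
#' For each region, the frequency of a dinucleotide is the number of
#' positions i with seq[i..i+1] equal to it, divided by the number of
#' valid windows (region length - 1, excluding windows containing N).
#' Matching is case-insensitive.
#'
#' @param regions \code{GRanges}.
#' @param genome Sequence source: a \code{DNAStringSet} whose names cover
#'   the region chromosomes, or a FASTA file path.
#' @param dinucleotide Two-letter string over A/C/G/T, e.g. \code{"CG"}.
#' @return Numeric vector of per-region frequencies; NA for regions of
#'   length 1 or with no valid window.
#' @export
dinucleotide_freq <- function(regions, genome, dinucleotide = "CG") {
  dinucleotide <- toupper(dinucleotide)
  stopifnot(nchar(dinucleotide) == 2L,
            all(strsplit(dinucleotide, "")[[1]] %in% c("A", "C", "G", "T")))
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  vapply(seq_along(regions), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(regions))[i]
    if (!chrom %in% names(genome)) {
      stop("no sequence for chromosome ", chrom)
    }
    seq <- toupper(as.character(Biostrings::subseq(
      genome[[chrom]],
      start = GenomicRanges::start(regions)[i],
      end = GenomicRanges::end(regions)[i]
    )))
    n <- nchar(seq)
    if (n < 2L) return(NA_real_)
    win <- substring(seq, 1:(n - 1L), 2:n)
    valid <- !grepl("N", win, fixed = TRUE)
    if (!any(valid)) return(NA_real_)
    sum(win[valid] == dinucleotide) / sum(valid)
  }, 0)
}

#' Compare dinucleotide composition of two region sets
#'
#' Two-sided Welch (unequal-variance) t-test on two samples of per-region
#' frequencies.
#'
#' @param freq_a,freq_b Numeric vectors (NAs removed); each needs >= 2
#'   finite values.
#' @return List with \code{t_statistic}, \code{p_value}, \code{df}.
#' @export
compare_composition <- function(freq_a, freq_b) {
  freq_a <- freq_a[is.finite(freq_a)]
  freq_b <- freq_b[is.finite(freq_b)]
  stopifnot(length(freq_a) >= 2L, length(freq_b) >= 2L)
  if (stats::sd(freq_a) == 0 && stats::sd(freq_b) == 0) {
    # degenerate: no within-group variance, Welch denominator is 0
    if (mean(freq_a) == mean(freq_b)) {
      return(list(t_statistic = NA_real_, p_value = NA_real_, df = NA_real_))
    }
    return(list(t_statistic = sign(mean(freq_a) - mean(freq_b)) * Inf,
                p_value = 0, df = NA_real_))
  }
  tt <- stats::t.test(freq_a, freq_b, var.equal = FALSE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}
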