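#' Partition a genome into consecutive fixed-width segments
#'
#' Tiles each chromosome with consecutive, non-overlapping windows of
#' \code{bin_width} bp; the final window of a chromosome is truncated to the
#' chromosome end, so each chromosome contributes
#' \code{ceiling(length / bin_width)} segments. Segment ids are contiguous
#' integers ordered by (chromosome order in \code{chrom_sizes}, start), and
#' never interleave chromosomes.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp), as returned
#'   by [read_chrom_sizes()]; names fix the chromosome order.
#' @param bin_width Segment width in bp; default 200.
#' @return An object of class \code{segment_grid}: a list with \code{bins}
#'   (a \code{GRanges}, one range per segment), \code{bin_width} and
#'   \code{chrom_sizes}.
#' @export
bin_genome <- function(chrom_sizes, bin_width = 200L) {
  if (length(chrom_sizes) == 0L || is.null(names(chrom_sizes)) ||
      any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a non-empty named vector")
  }
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width <= 0L) stop("bin_width must be positive")
  sl <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  starts <- lapply(sl, function(len) seq.int(1L, len, by = bin_width))
  bins <- GenomicRanges::GRanges(
    seqnames = rep(names(sl), lengths(starts)),
    ranges = IRanges::IRanges(
      start = unlist(starts, use.names = FALSE),
      end = pmin(unlist(starts, use.names = FALSE) + bin_width - 1L,
                 rep(unname(sl), lengths(starts)))
    ),
    seqlengths = sl
  )
  structure(list(bins = bins, bin_width = bin_width, chrom_sizes = sl),
            class = "segment_grid")
}

#' @export
print.segment_grid <- function(x, ...) {
  cat(sprintf("segment_grid: %d segments of %d bp over %d chromosome(s)\n",
              length(x$bins), x$bin_width, length(x$chrom_sizes)))
  invisible(x)
}

#' @export
length.segment_grid <- function(x) length(x$bins)

#' Per-segment chromosome names of a grid
#' @param grid A \code{segment_grid}.
#' @return Character vector, one entry per segment.
#' @export
grid_chroms <- function(grid) {
  as.character(GenomicRanges::seqnames(grid$bins))
}

#' Export a segment grid as BED4
#'
#' @param grid A \code{segment_grid}.
#' @param path Output path; the name column carries the 0-based segment id.
#' @return \code{path}, invisibly.
#' @export
write_grid_bed <- function(grid, path) {
  df <- data.frame(
    chrom = grid_chroms(grid),
    start = GenomicRanges::start(grid$bins) - 1L,
    end = GenomicRanges::end(grid$bins),
    name = paste0("seg_", seq_along(grid$bins) - 1L)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map a replicate's peaks onto the grid as binary occupancy
#'
#' A segment is occupied (1) iff at least \code{min_overlap} bp of at least
#' one peak intersects it; several peaks in one segment still give 1.
#'
#' @param peaks \code{GRanges} of one replicate's peaks.
#' @param grid A \code{segment_grid}.
#' @param protein,replicate Labels attached to the result.
#' @param min_overlap Minimum overlap in bp to mark a segment; default 1.
#' @return Integer vector of 0/1 with one entry per segment and class
#'   \code{occupancy}; attributes \code{protein} and \code{replicate}.
#' @export
map_peaks <- function(peaks, grid, protein = NA_character_,
                      replicate = NA_character_, min_overlap = 1L) {
  stopifnot(inherits(grid, "segment_grid"))
  hits <- GenomicRanges::countOverlaps(grid$bins, peaks,
                                       minoverlap = as.integer(min_overlap),
                                       ignore.strand = TRUE)
  structure(as.integer(hits > 0L), class = "occupancy",
            protein = as.character(protein),
            replicate = as.character(replicate))
}

#' Sum replicate occupancies into the per-segment peak count P
#'
#' For one protein with N replicates, P[s] counts the replicates whose
#' binary occupancy marks segment s, so 0 <= P[s] <= N always.
#'
#' @param occupancies List of \code{occupancy} vectors for one protein on
#'   one grid.
#' @return Integer vector P with attributes \code{protein} and \code{N}.
#' @export
sum_replicates <- function(occupancies) {
  stopifnot(length(occupancies) >= 1L)
  lens <- vapply(occupancies, length, 0L)
  if (length(unique(lens)) != 1L) {
    stop("occupancy vectors are on different grids (lengths differ)")
  }
  prots <- unique(vapply(occupancies, function(o) attr(o, "protein"), ""))
  prots <- prots[!is.na(prots)]
  if (length(prots) > 1L) {
    stop("occupancy vectors mix proteins: ", paste(prots, collapse = ", "))
  }
  P <- Reduce(`+`, lapply(occupancies, as.integer))
  structure(as.integer(P),
            protein = if (length(prots)) prots else NA_character_,
            N = length(occupancies))
}
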