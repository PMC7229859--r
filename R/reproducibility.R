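#' Per-protein block reproducibility score
#'
#' Segments with no peak in any replicate (P = 0) are scored NA. The
#' remaining segments form blocks: maximal runs of consecutive
#' same-chromosome segments with P > 0. A block is reproducible (every
#' member scored 1) when at least one of its segments was detected in all
#' N replicates (P = N); otherwise the whole block is variable (scored 0).
#' Blocks never extend across a chromosome boundary.
#'
#' @param P Integer vector of per-segment replicate counts (see
#'   [sum_replicates()]).
#' @param N Number of replicates for the protein; \code{N >= 1}.
#' @param grid The \code{segment_grid} the counts live on; supplies the
#'   chromosome of each segment. May be omitted for a single implicit
#'   chromosome.
#' @param protein Protein label carried through to the result.
#' @return A list of class \code{repro_track} with elements
#'   \code{protein}, \code{N}, \code{P} and \code{score} (integer vector
#'   in \{1, 0, NA\}, same length as \code{P}).
#' @export
score_protein <- function(P, N, grid = NULL, protein = attr(P, "protein")) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer")
  P <- as.integer(P)
  if (anyNA(P) || any(P < 0L)) stop("P must be non-negative integers")
  if (any(P > N)) {
    stop("P exceeds N at segment ", which(P > N)[1L],
         " (binary per-replicate counts cannot exceed N)")
  }
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "segment_grid"))
    if (length(grid) != length(P)) {
      stop("P length does not match the grid")
    }
    chrom <- grid_chroms(grid)
  } else {
    chrom <- rep("*", length(P))
  }
  score <- rep(NA_integer_, length(P))
  if (length(P)) {
    # block id changes where the signal run breaks or the chromosome changes
    occupied <- P > 0L
    brk <- c(TRUE, occupied[-1L] != occupied[-length(P)] |
                    chrom[-1L] != chrom[-length(P)])
    block <- cumsum(brk)
    for (ix in split(seq_along(P), block)) {
      if (P[ix[1L]] == 0L) next  # signal-free run stays NA
      score[ix] <- if (any(P[ix] == N)) 1L else 0L
    }
  }
  structure(list(protein = if (is.null(protein)) NA_character_ else protein,
                 N = N, P = P, score = score),
            class = "repro_track")
}

#' @export
print.repro_track <- function(x, ...) {
  cat(sprintf("repro_track: %s (N = %d), %d segments, %d scored 1, %d scored 0\n",
              x$protein, x$N, length(x$score),
              sum(x$score == 1L, na.rm = TRUE),
              sum(x$score == 0L, na.rm = TRUE)))
  invisible(x)
}

#' Export a per-protein track as TSV
#'
#' Writes segment coordinates with the P count and reproducibility score.
#'
#' @param track A \code{repro_track}.
#' @param grid The grid the track was computed on.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_track_tsv <- function(track, grid, path) {
  df <- data.frame(
    chrom = grid_chroms(grid),
    start = GenomicRanges::start(grid$bins) - 1L,
    end = GenomicRanges::end(grid$bins),
    P = track$P,
    score = track$score
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
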