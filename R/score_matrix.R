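#' Aggregate per-protein tracks into a reproducibility score matrix
#'
#' Columns are proteins, rows are segments; entries are the per-protein
#' reproducibility scores (1, 0 or NA). The per-segment final score FS is
#' the row mean over non-NA entries, computed only for rows where at least
#' \code{min_non_na} proteins have data (default: all but one, which with
#' four proteins reproduces the at-least-three rule); other rows get NA.
#'
#' @param tracks List of \code{repro_track} objects on one grid.
#' @param grid The shared \code{segment_grid}.
#' @param min_non_na Minimum number of non-NA protein scores per row for
#'   FS to be defined; default \code{length(tracks) - 1}.
#' @return Object of class \code{score_matrix}: list with \code{grid},
#'   \code{proteins}, \code{values} (segments x proteins integer matrix),
#'   \code{fs} (numeric vector) and \code{min_non_na}.
#' @export
build_rsm <- function(tracks, grid, min_non_na = length(tracks) - 1L) {
  stopifnot(length(tracks) >= 2L, inherits(grid, "segment_grid"))
  lens <- vapply(tracks, function(t) length(t$score), 0L)
  if (any(lens != length(grid))) {
    stop("all tracks must be on the supplied grid")
  }
  proteins <- vapply(tracks, function(t) t$protein, "")
  if (anyDuplicated(proteins)) stop("duplicate protein names in tracks")
  values <- do.call(cbind, lapply(tracks, function(t) t$score))
  colnames(values) <- proteins
  fs <- final_scores(values, min_non_na)
  structure(list(grid = grid, proteins = proteins, values = values,
                 fs = fs, min_non_na = as.integer(min_non_na)),
            class = "score_matrix")
}

#' Final score of each row of a score matrix
#'
#' @param values Segments x proteins matrix with entries in \{1, 0, NA\}.
#' @param min_non_na Minimum non-NA entries for a defined FS.
#' @return Numeric vector of row means, NA where too few proteins scored.
#' @export
final_scores <- function(values, min_non_na) {
  stopifnot(min_non_na >= 1L)
  n_ok <- rowSums(!is.na(values))
  fs <- rowMeans(values, na.rm = TRUE)
  fs[n_ok < min_non_na] <- NA_real_
  fs[n_ok == 0L] <- NA_real_
  fs
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d segments x %d proteins (%s); %d segments with FS\n",
              nrow(x$values), length(x$proteins),
              paste(x$proteins, collapse = ", "), sum(!is.na(x$fs))))
  invisible(x)
}

#' Attainable final-score values of a matrix
#'
#' Enumerates every mean k/m over m = min_non_na .. n_proteins non-NA
#' entries with k of them equal to 1, i.e. the exact values FS can take
#' for this protein count and missingness rule.
#'
#' @param rsm A \code{score_matrix}, or an integer protein count.
#' @param min_non_na Missingness rule when \code{rsm} is a count.
#' @return Sorted numeric vector of attainable FS values.
#' @export
attainable_scores <- function(rsm, min_non_na = NULL) {
  if (inherits(rsm, "score_matrix")) {
    p <- length(rsm$proteins)
    m_min <- rsm$min_non_na
  } else {
    p <- as.integer(rsm)
    m_min <- if (is.null(min_non_na)) p - 1L else as.integer(min_non_na)
  }
  vals <- unlist(lapply(max(1L, m_min):p, function(m) (0:m) / m))
  sort(unique(vals))
}

#' Extract maximal same-score regions from a score matrix
#'
#' Merges maximal runs of consecutive same-chromosome segments whose FS
#' lies within \code{tol} of \code{score} into regions; a segment with a
#' different or undefined FS breaks the run.
#'
#' @param rsm A \code{score_matrix}.
#' @param score Target FS value in [0, 1].
#' @param tol Absolute matching tolerance; default 1e-9.
#' @return \code{GRanges} of regions with metadata columns \code{score}
#'   and \code{n_segments}.
#' @export
extract_regions <- function(rsm, score, tol = 1e-9) {
  stopifnot(inherits(rsm, "score_matrix"), score >= 0, score <= 1)
  match_ <- !is.na(rsm$fs) & abs(rsm$fs - score) <= tol
  regions_from_mask(match_, rsm$grid, score)
}

# merge a logical per-segment mask into maximal per-chromosome runs
regions_from_mask <- function(mask, grid, score = NA_real_) {
  if (!any(mask)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    S4Vectors::mcols(gr)$n_segments <- integer(0)
    return(gr)
  }
  bins <- grid$bins[mask]
  # min.gapwidth = 1 merges touching bins (consecutive segments) but not
  # bins separated by an unselected segment
  merged <- GenomicRanges::reduce(bins, min.gapwidth = 1L)
  n_seg <- GenomicRanges::countOverlaps(merged, bins)
  S4Vectors::mcols(merged)$score <- rep(score, length(merged))
  S4Vectors::mcols(merged)$n_segments <- n_seg
  merged
}

#' Count regions at a set of scores
#'
#' @param rsm A \code{score_matrix}.
#' @param scores Numeric vector of FS values.
#' @param tol Matching tolerance passed to [extract_regions()].
#' @return Named integer vector of region counts.
#' @export
count_regions <- function(rsm, scores, tol = 1e-9) {
  stats::setNames(
    vapply(scores, function(s) length(extract_regions(rsm, s, tol)), 0L),
    format(scores)
  )
}

#' Call variable-occupancy target regions (VOTs)
#'
#' VOTs are the merged regions whose final score equals
#' \code{variable_score} (default 0: no counted protein reproduced its
#' peaks there), sorted by (chromosome, start).
#'
#' @param rsm A \code{score_matrix}.
#' @param variable_score FS value defining "variable"; default 0.
#' @param tol Matching tolerance.
#' @return \code{GRanges} of VOTs.
#' @export
call_vots <- function(rsm, variable_score = 0, tol = 1e-9) {
  vots <- extract_regions(rsm, variable_score, tol)
  sort(vots, ignore.strand = TRUE)
}

#' Write regions as BED5
#'
#' @param regions \code{GRanges} with a \code{score} metadata column.
#' @param path Output path.
#' @param name_prefix Prefix of the name column; default \code{"VOT"}.
#' @param header Optional character vector of \code{#}-prefixed header
#'   lines written before the records.
#' @return \code{path}, invisibly.
#' @export
write_regions_bed <- function(regions, path, name_prefix = "VOT",
                              header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (length(regions)) {
    sc <- S4Vectors::mcols(regions)$score
    if (is.null(sc)) sc <- rep(0, length(regions))
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(regions)),
      start = GenomicRanges::start(regions) - 1L,
      end = GenomicRanges::end(regions),
      name = paste0(name_prefix, "_", seq_along(regions)),
      score = as.integer(round(sc * 1000))
    )
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Export a score matrix as TSV
#'
#' One row per segment: coordinates, one 1/0/NA column per protein, FS.
#'
#' @param rsm A \code{score_matrix}.
#' @param path Output path.
#' @param header Optional \code{#}-prefixed provenance lines.
#' @return \code{path}, invisibly.
#' @export
write_rsm_tsv <- function(rsm, path, header = NULL) {
  df <- data.frame(
    chrom = grid_chroms(rsm$grid),
    start = GenomicRanges::start(rsm$grid$bins) - 1L,
    end = GenomicRanges::end(rsm$grid$bins)
  )
  for (p in rsm$proteins) df[[p]] <- rsm$values[, p]
  df$FS <- rsm$fs
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a score matrix back from its TSV export
#'
#' @param path TSV written by [write_rsm_tsv()].
#' @param bin_width Bin width of the originating grid; default inferred
#'   from the modal segment length.
#' @return A \code{score_matrix}.
#' @export
read_rsm_tsv <- function(path, bin_width = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  fixed <- c("chrom", "start", "end", "FS")
  if (!all(fixed %in% names(df))) {
    stop("malformed RSM TSV; expected columns chrom, start, end, <proteins>, FS")
  }
  proteins <- setdiff(names(df), fixed)
  if (length(proteins) < 2L) stop("RSM TSV must carry >= 2 protein columns")
  widths <- df$end - df$start
  if (is.null(bin_width)) bin_width <- max(widths)
  sizes <- tapply(df$end, df$chrom, max)
  chrom_order <- unique(df$chrom)
  chrom_sizes <- stats::setNames(as.integer(sizes[chrom_order]), chrom_order)
  grid <- bin_genome(chrom_sizes, bin_width)
  if (length(grid) != nrow(df)) stop("RSM TSV rows do not tile the genome")
  values <- as.matrix(df[proteins])
  storage.mode(values) <- "integer"
  min_non_na <- length(proteins) - 1L
  structure(list(grid = grid, proteins = proteins, values = values,
                 fs = final_scores(values, min_non_na),
                 min_non_na = min_non_na),
            class = "score_matrix")
}
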