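#' Build the samples x segments feature matrix
#'
#' Rows are replicate samples (protein, replicate); columns are the
#' segments occupied in at least one sample; values are the binary
#' occupancies. All-zero segments are dropped.
#'
#' @param occupancies List of \code{occupancy} vectors (see
#'   [map_peaks()]) on one grid, >= 2 samples.
#' @return Object of class \code{feature_matrix}: list with \code{values}
#'   (binary matrix), \code{proteins}, \code{replicates},
#'   \code{segment_ids} (1-based grid indices of the kept columns).
#' @export
build_feature_matrix <- function(occupancies) {
  stopifnot(length(occupancies) >= 2L)
  lens <- vapply(occupancies, length, 0L)
  if (length(unique(lens)) != 1L) stop("occupancies are on different grids")
  values <- do.call(rbind, lapply(occupancies, as.integer))
  keep <- colSums(values) > 0L
  if (!any(keep)) stop("no occupied segment in any sample")
  values <- values[, keep, drop = FALSE]
  structure(list(
    values = values,
    proteins = vapply(occupancies, function(o) attr(o, "protein"), ""),
    replicates = vapply(occupancies, function(o) attr(o, "replicate"), ""),
    segment_ids = which(keep)
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d segments\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Remove segments lying in variable regions from the feature set
#'
#' @param fm A \code{feature_matrix}.
#' @param vots \code{GRanges} of variable regions on the same grid.
#' @param grid The \code{segment_grid} the matrix columns refer to.
#' @return A \code{feature_matrix} without the columns whose segment
#'   overlaps a VOT.
#' @export
drop_variable_segments <- function(fm, vots, grid) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(grid, "segment_grid"))
  if (length(vots) == 0L) return(fm)
  seg_in_vot <- GenomicRanges::countOverlaps(grid$bins[fm$segment_ids], vots,
                                             ignore.strand = TRUE) > 0L
  keep <- !seg_in_vot
  if (!any(keep)) stop("all feature segments lie in variable regions")
  structure(list(values = fm$values[, keep, drop = FALSE],
                 proteins = fm$proteins, replicates = fm$replicates,
                 segment_ids = fm$segment_ids[keep]),
            class = "feature_matrix")
}

#' Within-protein pairwise Euclidean distances between replicates
#'
#' Distances are computed in the full binary feature space.
#'
#' @param fm A \code{feature_matrix}; every protein needs >= 2 rows.
#' @return \code{data.frame} with columns \code{protein}, \code{rep_i},
#'   \code{rep_j}, \code{distance}.
#' @export
replicate_distances <- function(fm) {
  out <- list()
  for (p in unique(fm$proteins)) {
    rows <- which(fm$proteins == p)
    if (length(rows) < 2L) stop("protein ", p, " has fewer than 2 replicates")
    for (a in seq_along(rows)[-length(rows)]) {
      for (b in (a + 1L):length(rows)) {
        d <- sqrt(sum((fm$values[rows[a], ] - fm$values[rows[b], ])^2))
        out[[length(out) + 1L]] <- data.frame(
          protein = p,
          rep_i = fm$replicates[rows[a]],
          rep_j = fm$replicates[rows[b]],
          distance = d
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Project samples onto the top two principal components
#'
#' Mean-centered (unscaled) PCA of the binary feature matrix; binary
#' presence values share a scale, so no standardization is applied.
#'
#' @param fm A \code{feature_matrix} with >= 2 rows and >= 2 columns.
#' @return List with \code{coords} (samples x 2 matrix, columns PC1/PC2),
#'   \code{explained} (variance fractions of PC1 and PC2, non-increasing)
#'   and \code{degenerate} (TRUE when total variance is 0: all rows
#'   identical).
#' @export
project_2d <- function(fm) {
  stopifnot(nrow(fm$values) >= 2L, ncol(fm$values) >= 2L)
  total_var <- sum(apply(fm$values, 2L, stats::var))
  if (total_var == 0) {
    coords <- matrix(0, nrow(fm$values), 2L,
                     dimnames = list(NULL, c("PC1", "PC2")))
    return(list(coords = coords, explained = c(0, 0), degenerate = TRUE))
  }
  pc <- stats::prcomp(fm$values, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- matrix(0, nrow(fm$values), 2L,
                   dimnames = list(NULL, c("PC1", "PC2")))
  coords[, seq_len(k)] <- pc$x[, seq_len(k)]
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  explained <- c(expl, 0, 0)[1:2]
  list(coords = coords, explained = explained, degenerate = FALSE)
}
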