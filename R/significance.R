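#' Randomize a score matrix
#'
#' Builds one draw from the permutation null. Under the default
#' \code{"column"} scheme each protein column (1/0/NA values) is permuted
#' independently over segment positions, so every column's value multiset
#' — including the number and identity of NAs — is conserved exactly.
#' The \code{"global"} scheme shuffles all cells of the matrix jointly.
#' FS is recomputed on the permuted values.
#'
#' @param rsm A \code{score_matrix}.
#' @param scheme \code{"column"} (default) or \code{"global"}.
#' @return A new \code{score_matrix} with permuted values. Uses the
#'   current RNG state; seed externally (e.g. \code{set.seed}) for
#'   reproducibility.
#' @export
randomize_rsm <- function(rsm, scheme = c("column", "global")) {
  scheme <- match.arg(scheme)
  values <- rsm$values
  n <- nrow(values)
  if (n > 0L) {
    if (scheme == "column") {
      for (j in seq_len(ncol(values))) {
        values[, j] <- values[sample.int(n), j]
      }
    } else {
      values[] <- values[sample.int(length(values))]
    }
  }
  structure(list(grid = rsm$grid, proteins = rsm$proteins, values = values,
                 fs = final_scores(values, rsm$min_non_na),
                 min_non_na = rsm$min_non_na),
            class = "score_matrix")
}

#' Build the null distribution of region counts per score
#'
#' Randomizes the matrix \code{n_iter} times; at each iteration the
#' regions at each requested score are counted with the same merge rule
#' as the observed data. The observed count, null mean, null standard
#' deviation, z-score and upper-tail normal p-value are reported per
#' score.
#'
#' @param rsm The observed \code{score_matrix}.
#' @param scores Score levels to test; default: the attainable FS values.
#' @param n_iter Number of randomizations; default 1000.
#' @param seed Integer seed controlling all randomizations.
#' @param scheme Randomization scheme, see [randomize_rsm()].
#' @param alternative \code{"greater"} (upper tail, default) or
#'   \code{"two.sided"}.
#' @return Object of class \code{vot_null}: list with \code{table} (a
#'   \code{data.frame}: score, observed, null_mean, null_sd, z, p_value,
#'   significant) and \code{counts} (scores x iterations integer matrix).
#' @export
build_null <- function(rsm, scores = attainable_scores(rsm), n_iter = 1000L,
                       seed = 1L, scheme = c("column", "global"),
                       alternative = c("greater", "two.sided")) {
  scheme <- match.arg(scheme)
  alternative <- match.arg(alternative)
  stopifnot(n_iter >= 2L)
  observed <- count_regions(rsm, scores)
  counts <- matrix(0L, nrow = length(scores), ncol = n_iter,
                   dimnames = list(format(scores), NULL))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  for (it in seq_len(n_iter)) {
    rnd <- randomize_rsm(rsm, scheme)
    counts[, it] <- count_regions(rnd, scores)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  mu <- rowMeans(counts)
  sdev <- apply(counts, 1L, stats::sd)
  res <- lapply(seq_along(scores), function(i) {
    z_test(observed[i], mu[i], sdev[i], alternative)
  })
  tab <- data.frame(
    score = scores,
    observed = as.integer(observed),
    null_mean = mu,
    null_sd = sdev,
    z = vapply(res, `[[`, 0, "z"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    significant = vapply(res, `[[`, TRUE, "significant"),
    row.names = NULL
  )
  if (any(sdev == 0)) {
    warning("null standard deviation is 0 for score(s) ",
            paste(format(scores[sdev == 0]), collapse = ", "),
            "; z and p undefined there")
  }
  structure(list(table = tab, counts = counts, n_iter = n_iter,
                 seed = as.integer(seed), scheme = scheme),
            class = "vot_null")
}

#' @export
print.vot_null <- function(x, ...) {
  cat(sprintf("vot_null: %d randomizations (%s scheme, seed %d)\n",
              x$n_iter, x$scheme, x$seed))
  print(x$table)
  invisible(x)
}

#' z-test of an observed region count against its null
#'
#' z = (observed - null mean) / null sd; assuming normality of the null,
#' the upper-tail p-value is P(Z >= z). Significance is flagged at
#' alpha = 0.05.
#'
#' @param observed Observed region count (delta).
#' @param null_mean,null_sd Mean and standard deviation of the null
#'   counts.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @param alpha Significance level; default 0.05.
#' @return List with \code{z}, \code{p_value}, \code{significant}. When
#'   \code{null_sd} is 0 both z and p are NA (undefined).
#' @export
z_test <- function(observed, null_mean, null_sd,
                   alternative = c("greater", "two.sided"), alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (is.na(null_sd) || null_sd <= 0) {
    return(list(z = NA_real_, p_value = NA_real_, significant = NA))
  }
  z <- (observed - null_mean) / null_sd
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (alternative == "two.sided") p <- 2 * min(p, 1 - p)
  list(z = z, p_value = p, significant = p < alpha)
}

#' Write a significance report as TSV
#'
#' @param null A \code{vot_null}.
#' @param path Output path.
#' @param header Optional \code{#}-prefixed provenance lines.
#' @param dump_counts If TRUE, per-iteration counts are appended as extra
#'   commented lines.
#' @return \code{path}, invisibly.
#' @export
write_null_tsv <- function(null, path, header = NULL, dump_counts = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(null$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (dump_counts) {
    for (i in seq_len(nrow(null$counts))) {
      writeLines(paste0("# counts ", rownames(null$counts)[i], "\t",
                        paste(null$counts[i, ], collapse = ",")), con)
    }
  }
  invisible(path)
}
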