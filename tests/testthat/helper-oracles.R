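# Independent brute-force oracles used to validate the fast implementations.

# Neighbor-walk reproducibility oracle: for each segment with P > 0, walk
# left and right through consecutive same-chromosome segments with P > 0
# and ask whether any of them reaches N.
oracle_score <- function(P, N, chrom = rep("*", length(P))) {
  n <- length(P)
  out <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    if (P[s] == 0L) next
    hit <- P[s] == N
    i <- s - 1L
    while (i >= 1L && P[i] > 0L && chrom[i] == chrom[s]) {
      if (P[i] == N) hit <- TRUE
      i <- i - 1L
    }
    i <- s + 1L
    while (i <= n && P[i] > 0L && chrom[i] == chrom[s]) {
      if (P[i] == N) hit <- TRUE
      i <- i + 1L
    }
    out[s] <- if (hit) 1L else 0L
  }
  out
}

# Exhaustive two-sided Fisher p for a 2x2 table: enumerate every table
# with the observed margins, sum the hypergeometric probabilities of
# tables no more probable than the observed one (standard relative tie
# tolerance of the conditional exact test).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1
  n <- c + d          # row 2
  k <- a + c          # col 1
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Tiny helper: single-chromosome grid with n segments of width w
toy_grid <- function(n, w = 200L, chrom = "chrT") {
  sizes <- stats::setNames(n * w, chrom)
  bin_genome(sizes, w)
}

# Build a score_matrix directly from a values matrix (bypassing peak IO)
toy_rsm <- function(values, min_non_na = ncol(values) - 1L, w = 200L) {
  grid <- toy_grid(nrow(values), w)
  colnames(values) <- sprintf("p%d", seq_len(ncol(values)))
  storage.mode(values) <- "integer"
  structure(list(grid = grid, proteins = colnames(values), values = values,
                 fs = final_scores(values, min_non_na),
                 min_non_na = as.integer(min_non_na)),
            class = "score_matrix")
}

# Write peak lines to a temporary narrowPeak file
write_np <- function(df, path = tempfile(fileext = ".narrowPeak")) {
  np <- data.frame(df$chrom, df$start, df$end,
                   name = sprintf("p%d", seq_len(nrow(df))), score = 0L,
                   strand = ".",
                   signal = if (!is.null(df$signal)) df$signal else 10,
                   pval = -1,
                   qval = if (!is.null(df$qval)) df$qval else 5,
                   summit = -1)
  utils::write.table(np, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}
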