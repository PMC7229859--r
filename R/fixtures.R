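#' Simulation configuration for replicated multi-protein peak data
#'
#' Defines a synthetic genome with planted reproducible blocks (a peak in
#' every replicate of every protein) and variable blocks (for every
#' protein, at least one replicate lacks the block while at least one has
#' it, so the block can never reach P = N). Blocks are separated by at
#' least one empty segment, which keeps the truth regions unambiguous.
#'
#' @param chrom_sizes Named vector; default one 200 kb chromosome
#'   \code{chrS}.
#' @param bin_width Segment width in bp; default 200.
#' @param n_proteins Number of protein targets; default 4.
#' @param n_replicates Replicates per protein; default 2.
#' @param n_reproducible_blocks,n_variable_blocks Planted block counts;
#'   defaults 20 and 10.
#' @param block_len_range Block length range in segments; default c(1, 3).
#' @param dropout Probability that a replicate lacks a variable block in
#'   \code{"bernoulli"} mode; in [0, 1); default 0.5.
#' @param noise_rate Per-segment, per-replicate probability of a spurious
#'   single-segment noise peak outside planted blocks; default 0.
#' @param mode \code{"guaranteed"} (exactly one replicate per protein is
#'   dropped from each variable block; truth recovery is exact) or
#'   \code{"bernoulli"} (each replicate dropped independently with
#'   probability \code{dropout}, redrawn until the block keeps >= 1
#'   present and >= 1 absent replicate).
#' @param cell_type Label used in the manifest; default \code{"simCell"}.
#' @param seed Integer seed; all randomness derives from it.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(chrom_sizes = c(chrS = 200000L), bin_width = 200L,
                       n_proteins = 4L, n_replicates = 2L,
                       n_reproducible_blocks = 20L, n_variable_blocks = 10L,
                       block_len_range = c(1L, 3L), dropout = 0.5,
                       noise_rate = 0, mode = c("guaranteed", "bernoulli"),
                       cell_type = "simCell", seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(dropout >= 0, dropout < 1, noise_rate >= 0, noise_rate <= 1,
            n_proteins >= 2L, n_replicates >= 2L,
            block_len_range[1] >= 1L,
            block_len_range[2] >= block_len_range[1])
  structure(list(chrom_sizes = chrom_sizes, bin_width = as.integer(bin_width),
                 n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 n_reproducible_blocks = as.integer(n_reproducible_blocks),
                 n_variable_blocks = as.integer(n_variable_blocks),
                 block_len_range = as.integer(block_len_range),
                 dropout = dropout, noise_rate = noise_rate, mode = mode,
                 cell_type = cell_type, seed = as.integer(seed)),
            class = "sim_config")
}

# place blocks on the grid: returns data.frame(chrom, first_seg, last_seg,
# type) with >= 1 empty segment between consecutive blocks per chromosome
place_blocks <- function(config, grid) {
  k <- config$n_reproducible_blocks + config$n_variable_blocks
  if (k == 0L) {
    return(data.frame(chrom = character(0), first = integer(0),
                      last = integer(0), type = character(0)))
  }
  lens <- sample(seq(config$block_len_range[1], config$block_len_range[2]),
                 k, replace = TRUE)
  types <- sample(c(rep("reproducible", config$n_reproducible_blocks),
                    rep("variable", config$n_variable_blocks)))
  # assign blocks to chromosomes proportionally to segment counts
  chrom <- grid_chroms(grid)
  seg_per_chrom <- table(factor(chrom, levels = names(config$chrom_sizes)))
  assignment <- sample(names(config$chrom_sizes), k, replace = TRUE,
                       prob = as.numeric(seg_per_chrom))
  out <- list()
  for (cn in unique(assignment)) {
    idx <- which(assignment == cn)
    n_seg <- as.integer(seg_per_chrom[[cn]])
    need <- sum(lens[idx]) + (length(idx) - 1L)
    if (need > n_seg) {
      stop("infeasible packing: blocks do not fit on ", cn,
           " with 1-segment spacing")
    }
    ord <- sample(idx)  # random left-to-right order
    slack <- n_seg - need
    extras <- as.integer(stats::rmultinom(1L, slack,
                                          rep(1, length(ord) + 1L)))
    pos <- 1L + extras[1L]
    first_chrom_seg <- min(which(chrom == cn))
    for (j in seq_along(ord)) {
      b <- ord[j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn,
        first = first_chrom_seg + pos - 1L,
        last = first_chrom_seg + pos + lens[b] - 2L,
        type = types[b]
      )
      pos <- pos + lens[b] + 1L + extras[j + 1L]
    }
  }
  do.call(rbind, out)
}

#' Simulate a replicated multi-protein ChIP-seq peak dataset
#'
#' Writes one narrowPeak file per protein x replicate, a manifest TSV, a
#' chrom.sizes table, and truth BEDs of the planted variable and
#' reproducible blocks to \code{out_dir}. See [sim_config()] for the
#' generative model.
#'
#' @param config A \code{sim_config}.
#' @param out_dir Output directory (created if needed).
#' @return List with \code{manifest} (path), \code{chrom_sizes} (path),
#'   \code{truth_variable} and \code{truth_reproducible} (\code{GRanges}
#'   plus BED paths \code{truth_variable_bed},
#'   \code{truth_reproducible_bed}), \code{peak_files} (character matrix
#'   proteins x replicates), and \code{grid}.
#' @export
simulate_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  grid <- bin_genome(config$chrom_sizes, config$bin_width)
  blocks <- place_blocks(config, grid)
  chrom <- grid_chroms(grid)
  n_seg <- length(grid)
  in_block <- rep(FALSE, n_seg)
  for (i in seq_len(nrow(blocks))) {
    in_block[blocks$first[i]:blocks$last[i]] <- TRUE
  }

  proteins <- sprintf("prot%d", seq_len(config$n_proteins))
  reps <- sprintf("rep%d", seq_len(config$n_replicates))
  peak_files <- matrix("", config$n_proteins, config$n_replicates,
                       dimnames = list(proteins, reps))

  seg_start0 <- GenomicRanges::start(grid$bins) - 1L  # 0-based
  seg_end0 <- GenomicRanges::end(grid$bins)

  block_peak <- function(i) {
    c(seg_start0[blocks$first[i]], seg_end0[blocks$last[i]])
  }

  # which replicate(s) miss each variable block, per protein
  var_idx <- which(blocks$type == "variable")
  manifest <- list()
  for (pi in seq_along(proteins)) {
    missing <- matrix(FALSE, nrow(blocks), config$n_replicates)
    for (i in var_idx) {
      if (config$mode == "guaranteed") {
        missing[i, sample.int(config$n_replicates, 1L)] <- TRUE
      } else {
        repeat {
          drop <- stats::runif(config$n_replicates) < config$dropout
          if (any(drop) && !all(drop)) break
        }
        missing[i, ] <- drop
      }
    }
    for (ri in seq_along(reps)) {
      rows <- list()
      for (i in seq_len(nrow(blocks))) {
        if (missing[i, ri]) next
        pe <- block_peak(i)
        rows[[length(rows) + 1L]] <- c(blocks$chrom[i], pe[1], pe[2])
      }
      if (config$noise_rate > 0) {
        noisy <- which(!in_block & stats::runif(n_seg) < config$noise_rate)
        for (s in noisy) {
          rows[[length(rows) + 1L]] <- c(chrom[s], seg_start0[s], seg_end0[s])
        }
      }
      path <- file.path(out_dir, sprintf("%s_%s_%s.narrowPeak",
                                         config$cell_type, proteins[pi],
                                         reps[ri]))
      if (length(rows)) {
        m <- do.call(rbind, rows)
        df <- data.frame(chrom = m[, 1],
                         start = as.integer(m[, 2]),
                         end = as.integer(m[, 3]))
        df <- df[order(df$chrom, df$start), ]
        np <- data.frame(df$chrom, df$start, df$end,
                         name = sprintf("peak_%d", seq_len(nrow(df))),
                         score = 0L, strand = ".",
                         signal = 15, pval = -1, qval = 5, summit = -1)
        utils::write.table(np, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
      } else {
        file.create(path)
      }
      peak_files[pi, ri] <- path
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = basename(path), cell_type = config$cell_type,
        protein = proteins[pi], replicate = reps[ri])
    }
  }

  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(do.call(rbind, manifest), manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  sizes_path <- file.path(out_dir, "chrom.sizes")
  utils::write.table(
    data.frame(names(config$chrom_sizes), unname(config$chrom_sizes)),
    sizes_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  truth_gr <- function(type) {
    sel <- blocks[blocks$type == type, , drop = FALSE]
    if (nrow(sel) == 0L) return(GenomicRanges::GRanges())
    sort(GenomicRanges::GRanges(
      sel$chrom,
      IRanges::IRanges(start = seg_start0[sel$first] + 1L,
                       end = seg_end0[sel$last])), ignore.strand = TRUE)
  }
  tv <- truth_gr("variable")
  tr <- truth_gr("reproducible")
  tv_path <- file.path(out_dir, "truth_variable.bed")
  tr_path <- file.path(out_dir, "truth_reproducible.bed")
  write_peaks_bed(tv, tv_path)
  write_peaks_bed(tr, tr_path)

  list(manifest = manifest_path, chrom_sizes = sizes_path,
       truth_variable = tv, truth_reproducible = tr,
       truth_variable_bed = tv_path, truth_reproducible_bed = tr_path,
       peak_files = peak_files, grid = grid)
}

#' Precision, recall and Jaccard of called regions against truth
#'
#' Region-level precision and recall use >= 1 bp overlap matching; the
#' Jaccard index is base-pair-level (intersection width over union
#' width).
#'
#' @param called,truth \code{GRanges} on one genome.
#' @return List with \code{precision}, \code{recall}, \code{jaccard} and
#'   \code{precision_defined} (FALSE when nothing was called; precision
#'   is then reported as 0).
#' @export
recovery_metrics <- function(called, truth) {
  if (length(called) == 0L) {
    return(list(precision = 0, recall = 0, jaccard = 0,
                precision_defined = FALSE))
  }
  hit_called <- GenomicRanges::countOverlaps(called, truth,
                                             ignore.strand = TRUE) > 0L
  hit_truth <- if (length(truth)) {
    GenomicRanges::countOverlaps(truth, called, ignore.strand = TRUE) > 0L
  } else logical(0)
  inter <- sum(GenomicRanges::width(
    GenomicRanges::intersect(called, truth, ignore.strand = TRUE)))
  uni <- sum(GenomicRanges::width(
    GenomicRanges::union(called, truth, ignore.strand = TRUE)))
  list(precision = mean(hit_called),
       recall = if (length(truth)) mean(hit_truth) else NA_real_,
       jaccard = if (uni > 0) inter / uni else NA_real_,
       precision_defined = TRUE)
}
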