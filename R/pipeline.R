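#' @keywords internal
provenance_header <- function(params) {
  c(paste0("# votcaller ", as.character(utils::packageVersion("votcaller"))),
    paste0("# ", names(params), " = ", vapply(params, as.character, "")))
}

#' Run the VOT-calling pipeline on a manifest
#'
#' Reads every replicate peak file, applies the significance filters,
#' maps peaks to the segment grid, scores each protein's blocks,
#' aggregates the reproducibility score matrix and calls VOTs.
#'
#' @param manifest Path to a manifest TSV (see [load_manifest()]) or a
#'   \code{vot_manifest}.
#' @param chrom_sizes Path to a chrom.sizes file or a named vector.
#' @param bin_width Segment width in bp; default 200.
#' @param fdr_max,fc_min Peak filters (see [filter_peaks()]); defaults
#'   0.05 and 0 (fold-change filter off).
#' @param variable_score FS value called as variable; default 0.
#' @param min_non_na Minimum proteins with data per segment; default
#'   number of proteins - 1.
#' @param format Peak file format; default \code{"narrowPeak"}.
#' @param min_overlap Minimum peak/segment overlap in bp; default 1.
#' @return List with \code{grid}, \code{occupancies}, \code{tracks},
#'   \code{rsm}, \code{vots}.
#' @export
run_call <- function(manifest, chrom_sizes, bin_width = 200L,
                     fdr_max = 0.05, fc_min = 0, variable_score = 0,
                     min_non_na = NULL, format = "narrowPeak",
                     min_overlap = 1L) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  proteins <- unique(manifest$protein)
  if (length(proteins) < 2L) {
    stop("at least 2 proteins are required to build a score matrix")
  }
  grid <- bin_genome(chrom_sizes, bin_width)
  occupancies <- list()
  tracks <- list()
  for (p in proteins) {
    rows <- manifest[manifest$protein == p, , drop = FALSE]
    occs <- lapply(seq_len(nrow(rows)), function(i) {
      peaks <- read_peaks(rows$file[i], format = format,
                          chrom_sizes = chrom_sizes)
      peaks <- filter_peaks(peaks, fdr_max = fdr_max, fc_min = fc_min)
      map_peaks(peaks, grid, protein = p, replicate = rows$replicate[i],
                min_overlap = min_overlap)
    })
    occupancies <- c(occupancies, occs)
    tracks[[p]] <- score_protein(sum_replicates(occs), N = length(occs),
                                 grid = grid, protein = p)
  }
  if (is.null(min_non_na)) min_non_na <- length(proteins) - 1L
  rsm <- build_rsm(tracks, grid, min_non_na = min_non_na)
  vots <- call_vots(rsm, variable_score = variable_score)
  list(grid = grid, occupancies = occupancies, tracks = tracks,
       rsm = rsm, vots = vots)
}

#' Call VOTs and write the RSM TSV and VOT BED
#'
#' File-writing wrapper around [run_call()]; both outputs carry a
#' machine-readable provenance header.
#'
#' @inheritParams run_call
#' @param out_dir Output directory.
#' @return The [run_call()] result, invisibly, with \code{rsm_tsv} and
#'   \code{vot_bed} paths attached.
#' @export
cmd_call <- function(manifest, chrom_sizes, out_dir, bin_width = 200L,
                     fdr_max = 0.05, fc_min = 0, variable_score = 0,
                     format = "narrowPeak") {
  res <- run_call(manifest, chrom_sizes, bin_width = bin_width,
                  fdr_max = fdr_max, fc_min = fc_min,
                  variable_score = variable_score, format = format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(list(bin_width = bin_width, fdr_max = fdr_max,
                                fc_min = fc_min,
                                variable_score = variable_score))
  res$rsm_tsv <- write_rsm_tsv(res$rsm, file.path(out_dir, "rsm.tsv"),
                               header = hdr)
  res$vot_bed <- write_regions_bed(res$vots, file.path(out_dir, "vots.bed"),
                                   header = hdr)
  invisible(res)
}

#' Significance of region counts per score level
#'
#' @param rsm A \code{score_matrix} or the path of an RSM TSV written by
#'   [cmd_call()].
#' @param scores Score levels; default the attainable FS values of the
#'   input.
#' @param n_iter Randomizations; default 1000.
#' @param seed Integer seed; default 1.
#' @param scheme Null scheme (see [randomize_rsm()]).
#' @param out Optional report TSV path.
#' @return A \code{vot_null}.
#' @export
run_significance <- function(rsm, scores = NULL, n_iter = 1000L, seed = 1L,
                             scheme = "column", out = NULL) {
  if (is.character(rsm)) rsm <- read_rsm_tsv(rsm)
  if (is.null(scores)) scores <- attainable_scores(rsm)
  null <- build_null(rsm, scores = scores, n_iter = n_iter, seed = seed,
                     scheme = scheme)
  if (!is.null(out)) {
    write_null_tsv(null, out,
                   header = provenance_header(list(n_iter = n_iter,
                                                   seed = seed,
                                                   scheme = scheme)))
  }
  null
}

#' Feature enrichment of a region set with shuffled controls
#'
#' @param regions \code{GRanges} or BED path of the regions (e.g. VOTs).
#' @param features Named list of \code{GRanges} (or BED paths), one per
#'   feature.
#' @param chrom_sizes Named vector or chrom.sizes path.
#' @param n_sets Number of shuffled control sets; default 10.
#' @param seed Integer seed for the shuffling.
#' @param out Optional report TSV path.
#' @return \code{data.frame}: feature, observed, simulated, ratio.
#' @export
run_enrich <- function(regions, features, chrom_sizes, n_sets = 10L,
                       seed = 1L, out = NULL) {
  if (is.character(regions)) regions <- read_features(regions, "regions")
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  features <- lapply(features, function(f) {
    if (is.character(f)) read_features(f) else f
  })
  controls <- shuffle_regions(regions, chrom_sizes, n_sets = n_sets,
                              seed = seed)
  rows <- lapply(names(features), function(nm) {
    e <- enrichment(regions, features[[nm]], controls)
    data.frame(feature = nm, observed = e$observed, simulated = e$simulated,
               ratio = e$ratio)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out)) {
    con <- file(out, "w"); on.exit(close(con))
    writeLines(provenance_header(list(n_sets = n_sets, seed = seed)), con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  tab
}

#' Dinucleotide composition of regions versus shuffled controls
#'
#' @param regions \code{GRanges} or BED path.
#' @param genome FASTA path or \code{DNAStringSet}.
#' @param chrom_sizes Named vector or chrom.sizes path.
#' @param dinucleotide Two-letter string; default \code{"CG"}.
#' @param seed Integer seed for the control shuffle.
#' @return List with \code{freq_regions}, \code{freq_controls}, and the
#'   Welch test result of [compare_composition()].
#' @export
run_nuc <- function(regions, genome, chrom_sizes, dinucleotide = "CG",
                    seed = 1L) {
  if (is.character(regions)) regions <- read_features(regions, "regions")
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  controls <- shuffle_regions(regions, chrom_sizes, n_sets = 1L, seed = seed)
  fa <- dinucleotide_freq(regions, genome, dinucleotide)
  fb <- dinucleotide_freq(controls[[1]], genome, dinucleotide)
  c(list(freq_regions = fa, freq_controls = fb),
    compare_composition(fa, fb))
}

#' Replicate clustering with and without variable segments
#'
#' Builds the binary sample x segment feature matrix from a pipeline
#' result, computes within-protein Euclidean replicate distances and the
#' 2D principal-component projection, both before and after removing
#' segments inside the called VOTs.
#'
#' @param call_result A [run_call()] result.
#' @return List with \code{with_vots} and \code{without_vots}, each
#'   holding \code{distances} and \code{projection}.
#' @export
run_pca_eval <- function(call_result) {
  fm <- build_feature_matrix(call_result$occupancies)
  fm2 <- drop_variable_segments(fm, call_result$vots, call_result$grid)
  with_d <- replicate_distances(fm)
  with_d$condition <- "with_vots"
  wo_d <- replicate_distances(fm2)
  wo_d$condition <- "without_vots"
  list(
    with_vots = list(distances = with_d, projection = project_2d(fm)),
    without_vots = list(distances = wo_d, projection = project_2d(fm2))
  )
}
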