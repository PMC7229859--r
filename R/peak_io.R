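#' Read a chromosome-sizes table
#'
#' Parses a two-column UCSC-style \code{chrom.sizes} file (chromosome name,
#' length in bp). Chromosome order in the file is preserved and later fixes
#' the segment-id order of the genome grid.
#'
#' @param path Path to a tab-separated two-column file without header.
#' @return Named integer vector of chromosome lengths, in file order.
#' @export
read_chrom_sizes <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) {
    stop("chrom.sizes file must have two columns (chrom, length): ", path)
  }
  len <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(len) || any(len <= 0) || any(len != floor(len))) {
    stop("chrom.sizes lengths must be positive integers: ", path)
  }
  if (anyDuplicated(tab[[1]])) {
    stop("duplicated chromosome names in ", path)
  }
  stats::setNames(as.integer(len), as.character(tab[[1]]))
}

#' Read ChIP-seq peaks from narrowPeak or BED
#'
#' Peaks are returned as a \code{GRanges} in the 0-based half-open BED
#' convention internally converted to the 1-based closed convention of
#' \code{IRanges} (\code{start+1}). For narrowPeak (BED6+4) input, column 7
#' (signalValue, the fold-change enrichment) is kept as metadata column
#' \code{signal} and column 9 as \code{neg_log10_q}; BED3+ input yields
#' \code{NA} for both.
#'
#' @param path Peak file path.
#' @param format One of \code{"narrowPeak"} or \code{"bed3plus"}.
#' @param chrom_sizes Optional named vector of chromosome lengths; peaks on
#'   chromosomes absent from it are dropped with a warning.
#' @return \code{GRanges} with metadata columns \code{signal} and
#'   \code{neg_log10_q}.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed3plus"),
                       chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$signal <- numeric(0)
    S4Vectors::mcols(gr)$neg_log10_q <- numeric(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (format == "narrowPeak") 10L else 3L
  if (any(nf < need)) {
    bad <- which(nf < need)[1L]
    stop(sprintf("line %d of %s has %d fields; %s requires >= %d",
                 bad, path, nf[bad], format, need))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  ok <- !is.na(start) & !is.na(end) & start == floor(start) & end == floor(end)
  if (any(!ok)) {
    stop(sprintf("line %d of %s: non-integer coordinates", which(!ok)[1L], path))
  }
  if (any(start < 0)) {
    stop(sprintf("line %d of %s: negative start", which(start < 0)[1L], path))
  }
  if (any(start >= end)) {
    stop(sprintf("line %d of %s: start >= end", which(start >= end)[1L], path))
  }
  if (format == "narrowPeak") {
    signal <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
    nlq <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 9L)))
    nlq[!is.na(nlq) & nlq < 0] <- NA_real_  # -1 encodes "not available"
  } else {
    signal <- rep(NA_real_, length(chrom))
    nlq <- rep(NA_real_, length(chrom))
  }
  if (!is.null(chrom_sizes)) {
    known <- chrom %in% names(chrom_sizes)
    if (any(!known)) {
      warning(sum(!known), " peak(s) on chromosomes absent from the ",
              "chrom.sizes table were dropped")
      chrom <- chrom[known]; start <- start[known]; end <- end[known]
      signal <- signal[known]; nlq <- nlq[known]
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    signal = signal,
    neg_log10_q = nlq
  )
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  }
  gr
}

#' Filter peaks by FDR and fold-change enrichment
#'
#' Retains peaks with q-value \eqn{\le} \code{fdr_max} (where the
#' narrowPeak file stores \eqn{-\log_{10} q}) and fold-change enrichment
#' \code{signal} \eqn{\ge} \code{fc_min}. Peaks missing a field needed by
#' an active filter are dropped and their number reported via a message.
#'
#' @param peaks \code{GRanges} from [read_peaks()].
#' @param fdr_max Maximum q-value; in (0, 1]. Default 0.05.
#' @param fc_min Minimum fold-change enrichment; >= 0. Use 0 to disable.
#' @return Filtered \code{GRanges}.
#' @export
filter_peaks <- function(peaks, fdr_max = 0.05, fc_min = 0) {
  stopifnot(fdr_max > 0, fdr_max <= 1, fc_min >= 0)
  if (length(peaks) == 0L) return(peaks)
  nlq <- S4Vectors::mcols(peaks)$neg_log10_q
  sig <- S4Vectors::mcols(peaks)$signal
  keep <- rep(TRUE, length(peaks))
  missing_n <- 0L
  if (fdr_max < 1) {
    miss <- is.na(nlq)
    missing_n <- missing_n + sum(miss & keep)
    # q <= fdr_max  <=>  -log10(q) >= -log10(fdr_max)
    keep <- keep & !miss & nlq >= -log10(fdr_max)
  }
  if (fc_min > 0) {
    miss <- is.na(sig)
    missing_n <- missing_n + sum(miss & keep)
    keep <- keep & !miss & sig >= fc_min
  }
  if (missing_n > 0L) {
    message(missing_n, " peak(s) dropped for missing filter fields")
  }
  peaks[keep]
}

#' Load and validate a sample manifest
#'
#' The manifest is a tab-separated file with header columns \code{file},
#' \code{cell_type}, \code{protein} and \code{replicate}, one row per
#' replicate peak file. Validation enforces unique (protein, replicate)
#' pairs within a cell type and at least two replicates per protein.
#'
#' @param path Manifest TSV path.
#' @param base_dir Directory against which relative \code{file} entries are
#'   resolved; defaults to the manifest's own directory.
#' @return A \code{data.frame} of class \code{vot_manifest} with columns
#'   \code{file}, \code{cell_type}, \code{protein}, \code{replicate}, plus
#'   attribute \code{n_replicates} (named integer vector per protein).
#' @export
load_manifest <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("file", "cell_type", "protein", "replicate")
  if (!all(need %in% names(tab))) {
    stop("manifest must have header columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[need]
  tab$replicate <- as.character(tab$replicate)
  key <- paste(tab$cell_type, tab$protein, tab$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (protein, replicate) pair in manifest: %s / %s",
                 dup$protein, dup$replicate))
  }
  n_rep <- table(tab$protein)
  if (any(n_rep < 2L)) {
    stop("each protein needs N >= 2 replicates; offending: ",
         paste(names(n_rep)[n_rep < 2L], collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", tab$file)
  tab$file[rel] <- file.path(base_dir, tab$file[rel])
  attr(tab, "n_replicates") <- stats::setNames(as.integer(n_rep), names(n_rep))
  class(tab) <- c("vot_manifest", "data.frame")
  tab
}

#' Write peaks back to a BED3 file (0-based half-open)
#'
#' @param peaks \code{GRanges}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
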