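#' Genomic bins
#'
#' Fixed-width, non-overlapping, contiguous windows over one or more named
#' sequences. Coordinates are 0-based half-open internally; user-facing
#' region strings are 1-based inclusive.
#'
#' @param seq_lengths named integer vector (or named list) of sequence
#'   lengths in nucleotides.
#' @param bin_size bin width in nucleotides (default 100000, i.e. 100 kb).
#' @param mask_partial logical; mask the trailing partial bin (default
#'   `TRUE`: model fits assume equal length across bins).
#'
#' @return An object of class `genomic_bins`: a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open), `width` and `mask`
#'   (`TRUE` = excluded), plus attribute `bin_size`.
#' @export
make_bins <- function(seq_lengths, bin_size = 100000L, mask_partial = TRUE) {
  seq_lengths <- unlist(seq_lengths)
  if (is.null(names(seq_lengths)) || any(!nzchar(names(seq_lengths))))
    stop("seq_lengths must be named by sequence")
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 2L)
    stop("bin_size must be an integer >= 2")
  if (any(seq_lengths < 1L))
    stop("all sequence lengths must be >= 1")
  pieces <- lapply(names(seq_lengths), function(chrom) {
    len <- as.numeric(seq_lengths[[chrom]])
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    data.frame(chrom = chrom, start = starts, end = ends,
               width = ends - starts, stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$mask <- if (mask_partial) bins$width < bin_size else FALSE
  attr(bins, "bin_size") <- bin_size
  class(bins) <- c("genomic_bins", "data.frame")
  bins
}

#' Bin labels in "chrom-start" form
#'
#' The label scheme used for matrix headers (HOMER-style) and walk names.
#'
#' @param bins a `genomic_bins` object.
#' @return character vector, one label per bin.
#' @export
bin_labels <- function(bins) paste(bins$chrom, bins$start, sep = "-")

#' @export
print.genomic_bins <- function(x, ...) {
  cat(sprintf("genomic_bins: %d bins of %d nt over %d sequence(s); %d masked\n",
              nrow(x), attr(x, "bin_size"),
              length(unique(x$chrom)), sum(x$mask)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Convert bins to GRanges
#'
#' @param bins a `genomic_bins` object.
#' @return a [GenomicRanges::GRanges] with 1-based coordinates and a
#'   `mask` metadata column.
#' @export
bins_to_granges <- function(bins) {
  GenomicRanges::GRanges(
    seqnames = bins$chrom,
    ranges = IRanges::IRanges(start = bins$start + 1L, end = bins$end),
    mask = bins$mask)
}

#' Mask bins overlapping exclusion regions
#'
#' Marks as excluded every bin that overlaps a region from a BED-style
#' exclusion set (centromeres, blacklists, ...).
#'
#' @param bins a `genomic_bins` object.
#' @param exclude a data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), a `GRanges`, or a path to a BED file.
#' @return the bins with an updated `mask`.
#' @export
mask_regions <- function(bins, exclude) {
  if (is.character(exclude)) exclude <- read_bed(exclude)
  if (methods::is(exclude, "GRanges")) {
    gr <- exclude
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = exclude$chrom,
      ranges = IRanges::IRanges(start = exclude$start + 1L, end = exclude$end))
  }
  hits <- GenomicRanges::findOverlaps(bins_to_granges(bins), gr)
  bins$mask[unique(S4Vectors::queryHits(hits))] <- TRUE
  bins
}

#' Parse a 1-based inclusive region string
#'
#' @param region string of the form `"chr22:16200001-36200000"`.
#' @return list with `chrom`, `start` (0-based) and `end` (half-open).
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", region)
  list(chrom = m[2], start = as.numeric(m[3]) - 1, end = as.numeric(m[4]))
}
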