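#' Read a BED file
#'
#' @param path BED(3+) file path.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   plus any name/score columns present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md)) df <- cbind(df, md)
  df
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); extra columns `name` and `score` are written if present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE))
  if (!is.null(df$name)) {
    cols <- c(cols, list(df$name))
    if (!is.null(df$score)) cols <- c(cols, list(df$score))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a compartment track as bedGraph (signed PC) and BED (labels)
#'
#' The bedGraph carries the signed PC value per unmasked bin; the BED
#' carries the A/B label (A = positive PC). Masked bins are omitted.
#'
#' @param track a `compartment_track`.
#' @param bins the `genomic_bins` the track is defined on.
#' @param prefix output path prefix; writes `<prefix>.bedgraph` and
#'   `<prefix>_labels.bed`.
#' @return invisibly, the two paths.
#' @export
write_track <- function(track, bins, prefix) {
  stopifnot(inherits(track, "compartment_track"),
            nrow(bins) == length(track$pc))
  keep <- which(!track$mask)
  bg <- file.path(paste0(prefix, ".bedgraph"))
  writeLines(sprintf("%s\t%d\t%d\t%.10g", bins$chrom[keep],
                     bins$start[keep], bins$end[keep], track$pc[keep]), bg)
  bed <- file.path(paste0(prefix, "_labels.bed"))
  write_bed(data.frame(chrom = bins$chrom[keep], start = bins$start[keep],
                       end = bins$end[keep], name = track$label[keep]),
            bed)
  invisible(c(bedgraph = bg, labels = bed))
}

#' Read a bedGraph PC track onto a set of bins
#'
#' @param path bedGraph file.
#' @param bins `genomic_bins` to align to; intervals are matched by
#'   exact `chrom`/`start`; bins without a record become `NA`.
#' @return numeric PC vector, one value per bin.
#' @export
read_track <- function(path, bins) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  key <- paste(df$chrom, df$start, sep = "-")
  out <- df$value[match(bin_labels(bins), key)]
  as.numeric(out)
}
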