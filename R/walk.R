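#' Encode a nucleotide sequence as a 1D DNA walk
#'
#' Hydrogen-bond (SW) rule: the walker starts at `x(1) = 0` and, for every
#' position `t + 1`, steps up (+1) if the base there is C or G (strongly
#' bonded pair) and down (-1) if it is A or T (weakly bonded pair).
#' Ambiguous IUPAC bases (N etc.) contribute a zero step and do not count
#' as informative. The base at position 1 never contributes a step. Case
#' insensitive; soft-masked (lowercase) bases are treated as their
#' uppercase value.
#'
#' @param seq a single nucleotide string, or a `Biostrings::DNAString`.
#' @return An object of class `dna_walk`: list with `values` (numeric
#'   series `x(t)`, `t = 1..L`), `L`, and `n_informative` (positions with
#'   an A/C/G/T call).
#' @export
encode_walk <- function(seq) {
  steps <- walk_steps(seq)
  L <- length(steps)
  if (L == 0L) stop("empty sequence")
  values <- cumsum(c(0, steps[-1L]))
  structure(list(values = values, L = L,
                 n_informative = sum(steps != 0)),
            class = "dna_walk")
}

# per-position +1/-1/0 step vector (position 1 included; dropped by the
# first-base convention in encode_walk)
walk_steps <- function(seq) {
  if (methods::is(seq, "XString")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L) stop("seq must be one string")
  if (!nzchar(seq)) stop("empty sequence")
  codes <- utf8ToInt(toupper(seq))
  step <- integer(length(codes))
  step[codes == 67L | codes == 71L] <- 1L   # C, G
  step[codes == 65L | codes == 84L] <- -1L  # A, T
  step
}

#' @export
print.dna_walk <- function(x, ...) {
  cat(sprintf("dna_walk: L = %d, informative = %d (%.1f%%), endpoint = %g\n",
              x$L, x$n_informative, 100 * x$n_informative / x$L,
              x$values[x$L]))
  invisible(x)
}

#' GC fraction of a sequence
#'
#' `(#C + #G) / (#A + #C + #G + #T)`; ambiguous bases are excluded from
#' the denominator. Returns `NA` when no unambiguous base is present.
#'
#' @param seq nucleotide string or `DNAString`.
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
gc_fraction <- function(seq) {
  steps <- walk_steps(seq)
  n <- sum(steps != 0)
  if (n == 0L) return(NA_real_)
  sum(steps == 1L) / n
}

#' DNA walks for every unmasked bin
#'
#' Extracts the sequence of each unmasked bin and encodes it as a DNA
#' walk restarting at 0. Bins whose informative-base occupancy is below
#' `min_occupancy` of the bin width ("empty bins", e.g. all-N assembly
#' gaps) are masked and excluded.
#'
#' @param fasta path to a (possibly gzipped) multi-record FASTA file, or a
#'   `Biostrings::DNAStringSet`.
#' @param bins a `genomic_bins` object covering the sequences.
#' @param min_occupancy minimum fraction of A/C/G/T calls for a bin to be
#'   kept (default 0.5).
#' @return list with `walks` (named list of `dna_walk`, names =
#'   [bin_labels()] of the unmasked bins, in bin order) and `bins` (input
#'   bins with the occupancy mask applied).
#' @export
bin_walks <- function(fasta, bins, min_occupancy = 0.5) {
  seqs <- as_dnastringset(fasta)
  widths <- stats::setNames(Biostrings::width(seqs), names(seqs))
  bad <- !(bins$chrom %in% names(seqs))
  if (any(bad))
    stop("bins refer to unknown sequence(s): ",
         paste(unique(bins$chrom[bad]), collapse = ", "))
  if (any(bins$end > widths[bins$chrom]))
    stop("bin outside sequence bounds")
  mask <- bins$mask
  walks <- vector("list", nrow(bins))
  for (i in seq_len(nrow(bins))) {
    if (mask[i]) next
    sub <- as.character(Biostrings::subseq(
      seqs[[bins$chrom[i]]], start = bins$start[i] + 1L, end = bins$end[i]))
    w <- encode_walk(sub)
    if (w$n_informative < min_occupancy * bins$width[i]) {
      mask[i] <- TRUE
    } else {
      walks[[i]] <- w
    }
  }
  bins$mask <- mask
  keep <- !mask
  structure(list(
    walks = stats::setNames(walks[keep], bin_labels(bins)[keep]),
    bins = bins), class = "bin_walks")
}

as_dnastringset <- function(fasta) {
  if (methods::is(fasta, "DNAStringSet")) return(fasta)
  if (is.character(fasta) && length(fasta) == 1L)
    return(Biostrings::readDNAStringSet(fasta))
  stop("fasta must be a path or a DNAStringSet")
}

#' Per-bin GC fractions
#'
#' The AT/CG-percentage baseline track over the bins (masked bins `NA`).
#'
#' @inheritParams bin_walks
#' @return numeric vector, one GC fraction per bin.
#' @export
bin_gc <- function(fasta, bins) {
  seqs <- as_dnastringset(fasta)
  vapply(seq_len(nrow(bins)), function(i) {
    if (bins$mask[i]) return(NA_real_)
    gc_fraction(as.character(Biostrings::subseq(
      seqs[[bins$chrom[i]]], start = bins$start[i] + 1L, end = bins$end[i])))
  }, numeric(1))
}

#' Write walks as single-column text files (debugging aid)
#'
#' @param bw result of [bin_walks()].
#' @param dir output directory; one `<label>.txt` per walk.
#' @return invisibly, the written paths.
#' @export
write_walks <- function(bw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(bw$walks), function(lab) {
    p <- file.path(dir, paste0(lab, ".txt"))
    utils::write.table(bw$walks[[lab]]$values, p,
                       row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
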