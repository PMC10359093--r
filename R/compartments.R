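#' Pearson correlation matrix of a contact map
#'
#' Entry `(i, j)` is the Pearson correlation of rows `i` and `j` of the
#' contact map over unmasked columns (missing values dropped pairwise);
#' the diagonal is 1. Zero-variance rows are masked.
#'
#' @param M a `contact_matrix`.
#' @return a `contact_matrix` of kind `"pearson"`.
#' @export
pearson_matrix <- function(M) {
  stopifnot(inherits(M, "contact_matrix"))
  mask <- M$mask
  ok <- which(!mask)
  if (length(ok) < 3L) stop("need at least 3 unmasked bins")
  sub <- M$values[ok, ok, drop = FALSE]
  zero_var <- apply(sub, 1L, function(r) stats::sd(r, na.rm = TRUE) == 0)
  if (any(zero_var)) {
    mask[ok[zero_var]] <- TRUE
    ok <- which(!mask)
    if (length(ok) < 3L) stop("fewer than 3 bins after dropping zero-variance rows")
    sub <- M$values[ok, ok, drop = FALSE]
  }
  C <- stats::cor(t(sub), use = "pairwise.complete.obs")
  diag(C) <- 1
  n <- length(mask)
  v <- matrix(NA_real_, n, n)
  v[ok, ok] <- C
  contact_matrix(v, bins = mask_into_bins(M$bins, mask), mask = mask,
                 kind = "pearson")
}

#' Candidate principal-component tracks
#'
#' PCA of the Pearson correlation matrix with bins as observations
#' (column centering, no scaling). Each component is given a
#' deterministic sign before any ChIP-based orientation: the
#' largest-magnitude entry is made positive (first index on ties).
#' Masked bins are reinserted as `NA`.
#'
#' @param C a `contact_matrix` of kind `"pearson"` (any square symmetric
#'   contact matrix is accepted).
#' @param n_pcs number of components to return (default 4; fewer are
#'   returned, with a message, when fewer unmasked bins exist).
#' @return numeric matrix, one column per PC, one row per bin (`NA` on
#'   masked bins); column names `PC1..`.
#' @export
pca_tracks <- function(C, n_pcs = 4L) {
  stopifnot(inherits(C, "contact_matrix"))
  ok <- which(!C$mask)
  sub <- C$values[ok, ok, drop = FALSE]
  k <- min(n_pcs, length(ok) - 1L, ncol(sub))
  if (k < n_pcs)
    message("only ", k, " principal components available")
  p <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  scores <- p$x[, seq_len(k), drop = FALSE]
  scores <- apply(scores, 2L, fix_sign)
  out <- matrix(NA_real_, length(C$mask), k,
                dimnames = list(NULL, paste0("PC", seq_len(k))))
  out[ok, ] <- scores
  out
}

# deterministic pre-orientation sign: largest |entry| positive
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Replace extreme outliers and z-normalize a PC track
#'
#' Values farther than `n_mads` scaled median absolute deviations
#' (constant 1.4826, normal consistency) from the median are replaced by
#' the nearest non-outlier *value*; the series is then normalized to
#' zero mean and unit variance. `NA`s pass through untouched. When the
#' MAD is zero no replacement is done (z-normalization only); a constant
#' series is returned centered with a `zero_variance` attribute.
#'
#' @param pc numeric series (may contain `NA` on masked bins).
#' @param n_mads outlier cut in scaled-MAD units (default 3).
#' @return the filtered, z-normalized series.
#' @export
filter_outliers <- function(pc, n_mads = 3) {
  fin <- which(is.finite(pc))
  if (length(fin) < 3L) stop("need at least 3 finite values")
  v <- pc[fin]
  med <- stats::median(v)
  smad <- stats::mad(v)  # 1.4826 * median(|v - med|)
  if (smad > 0) {
    out <- abs(v - med) > n_mads * smad
    if (any(out)) {
      keep <- v[!out]
      v[out] <- vapply(v[out], function(x) keep[which.min(abs(keep - x))],
                       numeric(1))
    }
  }
  mu <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    res <- v - mu
    pc[fin] <- res
    attr(pc, "zero_variance") <- TRUE
    return(pc)
  }
  pc[fin] <- (v - mu) / s
  pc
}

#' ChIP-seq peak profile over bins
#'
#' Builds a per-bin peak-count vector: +1 is added to a bin for each
#' called peak assigned to it. Assignment is by peak midpoint (default)
#' or by any overlap (`method = "overlap"`, then a peak can increment
#' several bins).
#'
#' @param peaks BED path, data.frame with `chrom`/`start`/`end` (0-based
#'   half-open), or `GRanges`.
#' @param bins a `genomic_bins` object.
#' @param method `"midpoint"` or `"overlap"`.
#' @param mark free-text label for the profile (e.g. `"H3K4me1"`).
#' @return object of class `chip_profile`: list with `counts` (`NA` on
#'   masked bins), `mark`, `n_skipped` (peaks on unknown sequences).
#' @export
chip_profile <- function(peaks, bins, method = c("midpoint", "overlap"),
                         mark = "chip") {
  method <- match.arg(method)
  peaks <- as_bed_df(peaks)
  known <- peaks$chrom %in% unique(bins$chrom)
  n_skipped <- sum(!known)
  if (n_skipped > 0)
    warning(n_skipped, " peak(s) on unknown sequence(s) skipped")
  peaks <- peaks[known, , drop = FALSE]
  counts <- integer(nrow(bins))
  if (nrow(peaks) > 0) {
    if (method == "midpoint") {
      mids <- floor((peaks$start + peaks$end) / 2)
      gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(mids + 1L, width = 1L))
    } else {
      gr <- GenomicRanges::GRanges(
        peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
    }
    hits <- GenomicRanges::findOverlaps(gr, bins_to_granges(bins))
    tab <- table(S4Vectors::subjectHits(hits))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts[bins$mask] <- NA_integer_
  structure(list(counts = counts, mark = mark, n_skipped = n_skipped),
            class = "chip_profile")
}

as_bed_df <- function(x) {
  if (is.character(x)) x <- read_bed(x)
  if (methods::is(x, "GRanges")) {
    x <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                    start = GenomicRanges::start(x) - 1L,
                    end = GenomicRanges::end(x))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  x
}

#' Centered moving average with shrinking edges
#'
#' Window-`k` moving mean; at the edges the window shrinks to the
#' available neighbors (the `movmean` default).
#'
#' @param v numeric vector (`NA`s are ignored within each window).
#' @param k window size (default 5).
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(v, k = 5L) {
  half <- (k - 1L) %/% 2L
  n <- length(v)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    w <- v[lo:hi]
    if (any(is.finite(w))) out[i] <- mean(w, na.rm = TRUE)
  }
  out[!is.finite(v)] <- NA_real_
  out
}

#' Select and orient the compartment PC with a ChIP profile
#'
#' Among the first (up to) four candidate PCs, selects the one with the
#' largest absolute Pearson correlation to the ChIP peak profile (ties
#' go to the lowest PC index), flips its sign when the correlation is
#' negative so that positive values mean the A (open) compartment, and
#' applies the display scaling (A linearly into `[0, 0.5]`, B into
#' `[0.5, 1]`). In DNA-DDA mode each candidate is smoothed with a
#' centered window-5 moving average before correlation and the smoothed
#' series (re-z-scored) is returned as the track.
#'
#' @param pcs matrix of candidate PC tracks (columns), as from
#'   [pca_tracks()], already outlier-filtered.
#' @param chip a `chip_profile` (or plain numeric vector of counts).
#' @param smooth smooth candidates before correlation (DNA-DDA mode).
#' @param pc_index optional explicit override of the selected component.
#' @param window smoothing window (default 5).
#' @return object of class `compartment_track`: list with `pc` (signed,
#'   zero mean/unit variance over unmasked bins), `label` (`"A"` iff
#'   `pc > 0`, `NA` on masked bins), `display` in `[0, 1]`, `pc_index`,
#'   `orientation_r` (>= 0), `mask`.
#' @export
select_and_orient <- function(pcs, chip, smooth = FALSE, pc_index = NULL,
                              window = 5L) {
  counts <- if (inherits(chip, "chip_profile")) chip$counts else chip
  pcs <- as.matrix(pcs)
  k <- min(4L, ncol(pcs))
  cand <- lapply(seq_len(k), function(j) {
    v <- pcs[, j]
    if (smooth) v <- moving_average(v, window)
    v
  })
  rs <- vapply(cand, function(v)
    suppressWarnings(stats::cor(v, counts, use = "pairwise.complete.obs")),
    numeric(1))
  if (is.null(pc_index)) {
    if (all(!is.finite(rs)))
      stop("all PC/ChIP correlations undefined (constant profile?); ",
           "supply pc_index explicitly")
    best <- which.max(abs(rs))  # ties: lowest index wins
    ties <- which(abs(abs(rs) - abs(rs[best])) < .Machine$double.eps^0.5)
    if (length(ties) > 1L)
      message("|r| tie between PCs ", paste(ties, collapse = ", "),
              "; choosing PC", best)
  } else {
    best <- as.integer(pc_index)
    if (best < 1L || best > ncol(pcs)) stop("pc_index out of range")
    if (best > k) cand[[best]] <- if (smooth)
      moving_average(pcs[, best], window) else pcs[, best]
  }
  v <- cand[[best]]
  r <- if (best <= length(rs)) rs[best] else suppressWarnings(
    stats::cor(v, counts, use = "pairwise.complete.obs"))
  if (is.finite(r) && r < 0) v <- -v
  fin <- is.finite(v)
  v[fin] <- (v[fin] - mean(v[fin])) / stats::sd(v[fin])
  new_compartment_track(v, pc_index = best,
                        orientation_r = if (is.finite(r)) abs(r) else NA_real_)
}

new_compartment_track <- function(pc, pc_index, orientation_r) {
  mask <- !is.finite(pc)
  label <- ifelse(mask, NA_character_, ifelse(pc > 0, "A", "B"))
  structure(list(pc = pc, label = label, display = display_scale(pc),
                 pc_index = pc_index, orientation_r = orientation_r,
                 mask = mask),
            class = "compartment_track")
}

# cosmetic [0,1] scaling: strongest A -> 0, pc -> 0+ maps to 0.5,
# pc -> 0- maps to 0.5, most negative (strongest B) -> 1
display_scale <- function(pc) {
  d <- rep(NA_real_, length(pc))
  pos <- which(is.finite(pc) & pc > 0)
  neg <- which(is.finite(pc) & pc <= 0)
  if (length(pos)) d[pos] <- 0.5 - 0.5 * pc[pos] / max(pc[pos])
  if (length(neg)) {
    mn <- min(pc[neg])
    d[neg] <- if (mn < 0) 0.5 + 0.5 * pc[neg] / mn else 0.5
  }
  d
}

#' @export
print.compartment_track <- function(x, ...) {
  n <- sum(!x$mask)
  cat(sprintf(
    "compartment_track: %d bins (%d masked), PC%d, |r|=%.3f, A: %d, B: %d\n",
    length(x$pc), sum(x$mask), x$pc_index,
    ifelse(is.na(x$orientation_r), NaN, x$orientation_r),
    sum(x$label == "A", na.rm = TRUE), sum(x$label == "B", na.rm = TRUE)))
  invisible(x)
}

#' Call A/B compartments from a contact map
#'
#' Full compartment-calling composition: Pearson correlation matrix,
#' PCA (first four components), per-PC outlier filtering, ChIP-guided
#' selection and orientation. In `"dda"` mode the candidate PCs are
#' smoothed (window 5) before correlation; `"hic"` mode differs only in
#' skipping the smoothing.
#'
#' @param M a `contact_matrix` (normalized DNA-DDA map or Hi-C map).
#' @param chip a `chip_profile` (or count vector) for PC selection and
#'   orientation.
#' @param mode `"dda"` or `"hic"`.
#' @param pc_index optional manual override of the selected PC.
#' @param n_pcs number of candidate components (default 4).
#' @return a `compartment_track` with a `provenance` attribute.
#' @export
call_compartments <- function(M, chip, mode = c("dda", "hic"),
                              pc_index = NULL, n_pcs = 4L) {
  mode <- match.arg(mode)
  C <- pearson_matrix(M)
  pcs <- pca_tracks(C, n_pcs = n_pcs)
  pcs <- apply(pcs, 2L, filter_outliers)
  track <- select_and_orient(pcs, chip, smooth = (mode == "dda"),
                             pc_index = pc_index)
  attr(track, "provenance") <- list(
    mode = mode, pc_index = track$pc_index,
    orientation_r = track$orientation_r, n_masked = sum(track$mask))
  track
}
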