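#' Contact matrix container
#'
#' Square symmetric matrix of pairwise scores over genomic bins, with a
#' per-bin exclusion mask. Masked rows/columns carry `NA`. Used for raw
#' dynamical-ergodicity maps, normalized DNA-DDA maps, Hi-C maps, Pearson
#' correlation matrices and observed/expected matrices.
#'
#' @param values square numeric matrix (symmetric within 1e-12 on
#'   unmasked entries).
#' @param bins optional `genomic_bins` (row `i` of the matrix is bin `i`).
#' @param mask logical per-bin exclusion flags; defaults to the bins'
#'   mask, or all-`FALSE`.
#' @param kind one of `"raw-dda"`, `"normalized"`, `"hic"`, `"pearson"`,
#'   `"observed-expected"`.
#' @return object of class `contact_matrix` with fields `values`, `bins`,
#'   `mask`, `kind`.
#' @export
contact_matrix <- function(values, bins = NULL, mask = NULL,
                           kind = c("raw-dda", "normalized", "hic",
                                    "pearson", "observed-expected")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("contact matrix must be square")
  if (is.null(mask)) mask <- if (!is.null(bins)) bins$mask else rep(FALSE, n)
  if (length(mask) != n) stop("mask length must equal matrix dimension")
  if (!is.null(bins) && nrow(bins) != n)
    stop("bins and matrix dimension disagree")
  ok <- !mask
  sub <- values[ok, ok, drop = FALSE]
  # entry-wise NA is allowed (e.g. zero-expected O/E cells) but must be
  # placed symmetrically; symmetry is checked on the finite entries
  fin <- is.finite(sub)
  if (any(fin != t(fin)))
    stop("missing entries are not symmetric")
  dev <- abs(sub - t(sub))
  if (any(fin) && max(dev[fin], na.rm = TRUE) >
      1e-12 * max(1, max(abs(sub[fin]))))
    stop("matrix is not symmetric on unmasked entries")
  values[mask, ] <- NA_real_
  values[, mask] <- NA_real_
  if (!is.null(bins)) dimnames(values) <- rep(list(bin_labels(bins)), 2)
  structure(list(values = values, bins = bins, mask = mask, kind = kind),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix (%s): %d x %d bins, %d masked\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$values)

# min-norm solve of the K x K normal equations G a = b; G = M'M is
# symmetric PSD. Cholesky fast path, eigen pseudo-inverse fallback with
# the same relative tolerance as the SVD route (tol on singular values
# of M = sqrt of eigenvalues of G).
solve_gram <- function(G, b, tol = 1e-12) {
  a <- tryCatch(drop(chol2inv(chol(G)) %*% b), error = function(e) NULL)
  if (!is.null(a) && all(is.finite(a))) return(a)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  keep <- sqrt(lam) > tol * sqrt(max(lam, 0))
  if (!any(keep)) return(rep(0, length(b)))
  drop(eg$vectors[, keep, drop = FALSE] %*%
       (crossprod(eg$vectors[, keep, drop = FALSE], b) / lam[keep]))
}

# sufficient statistics of one bin's design: G = M'M, bvec = M'xdot,
# s = xdot'xdot, n rows. ST and CT fits reduce to K x K solves, so the
# n(n-1)/2 cross-trial fits cost O(1) each after an O(L) pass per bin —
# the practical payoff of the symmetric-model formulation.
gram_stats <- function(x, model, w, standardize) {
  d <- build_design(x, model, w = w, standardize = standardize)
  list(G = crossprod(d$M), b = crossprod(d$M, d$xdot),
       s = sum(d$xdot^2), n = d$n)
}

rho_from_gram <- function(G, b, s, n, a) {
  sqrt(max(0, (s - 2 * sum(a * b) + sum(a * (G %*% a))) / n))
}

#' Build the pairwise dynamical-ergodicity matrix
#'
#' For every unordered pair of unmasked bins, computes the ergodicity
#' score `E_ij` from the two single-trial errors and the cross-trial
#' error under the given model; the diagonal is 0. ST statistics are
#' computed once per bin and reused; cross-trial fits are solved from the
#' summed normal equations (identical to the stacked SVD solution within
#' numerical tolerance). Bins with a constant walk or an empty fit window
#' are masked and reported in the provenance.
#'
#' @param walks result of [bin_walks()], or a named list of `dna_walk`
#'   objects/numeric series (then all bins are unmasked).
#' @param model a `dda_model` with delays set.
#' @param w derivative half-width (default 1).
#' @param standardize standardize each bin's walk before embedding
#'   (default `TRUE`).
#' @return a `contact_matrix` of kind `"raw-dda"` with attribute
#'   `provenance` (model id, delays, fit counts, dropped bins).
#' @export
build_dda_matrix <- function(walks, model, w = 1L, standardize = TRUE) {
  bw <- as_bin_walks(walks)
  bins <- bw$bins
  n_total <- if (!is.null(bins)) nrow(bins) else length(bw$walks)
  mask <- if (!is.null(bins)) bins$mask else rep(FALSE, n_total)
  idx_unmasked <- which(!mask)
  if (length(idx_unmasked) < 2L) stop("need at least 2 unmasked bins")

  stats_by_bin <- vector("list", n_total)
  dropped <- character(0)
  st_fits <- 0L
  labels <- if (!is.null(bins)) bin_labels(bins) else names(bw$walks)
  for (pos in seq_along(idx_unmasked)) {
    i <- idx_unmasked[pos]
    g <- tryCatch(
      gram_stats(bw$walks[[pos]], model, w = w, standardize = standardize),
      error = function(e) e)
    if (inherits(g, "error") ||
        isTRUE(attr(standardize_series(walk_values(bw$walks[[pos]])),
                    "degenerate"))) {
      mask[i] <- TRUE
      dropped <- c(dropped, labels[i])
      next
    }
    a <- solve_gram(g$G, g$b)
    g$rho_s <- rho_from_gram(g$G, g$b, g$s, g$n, a)
    st_fits <- st_fits + 1L
    stats_by_bin[[i]] <- g
  }
  live <- which(!mask)
  if (length(live) < 2L) stop("fewer than 2 usable bins after fitting")

  E <- matrix(NA_real_, n_total, n_total)
  E[live, live] <- 0
  ct_fits <- 0L
  for (p in seq_len(length(live) - 1L)) {
    i <- live[p]
    gi <- stats_by_bin[[i]]
    for (q in (p + 1L):length(live)) {
      j <- live[q]
      gj <- stats_by_bin[[j]]
      G <- gi$G + gj$G
      b <- gi$b + gj$b
      a <- solve_gram(G, b)
      rho_c <- rho_from_gram(G, b, gi$s + gj$s, gi$n + gj$n, a)
      ct_fits <- ct_fits + 1L
      E[i, j] <- E[j, i] <- ergodicity(gi$rho_s, gj$rho_s, rho_c)
    }
  }
  if (!is.null(bins)) bins$mask <- mask
  out <- contact_matrix(replace(E, is.na(E), NA_real_), bins = bins,
                        mask = mask, kind = "raw-dda")
  attr(out, "provenance") <- list(
    model = model$id, delays = model$delays, w = w,
    standardize = standardize, n_st_fits = st_fits, n_ct_fits = ct_fits,
    dropped_bins = dropped)
  out
}

as_bin_walks <- function(walks) {
  if (inherits(walks, "bin_walks")) return(walks)
  if (is.list(walks))
    return(structure(list(walks = walks, bins = NULL), class = "bin_walks"))
  stop("walks must be a bin_walks result or a list of walks")
}

#' Post-process a raw ergodicity matrix into a DNA-DDA contact map
#'
#' Low ergodicity means similar dynamics, hence high contact, so the raw
#' matrix is (1) inverted by the linear flip `max + min - d` over
#' unmasked entries (highest values map to the lowest, spacing
#' preserved); (2) the natural logarithm is applied to each non-zero
#' entry, zeros left untouched; (3) unmasked entries are min-max rescaled
#' to `[0, 1]`; (4) bins excluded in the reference Hi-C map, if given,
#' are masked here too.
#'
#' @param D a `contact_matrix` of kind `"raw-dda"`.
#' @param hic_mask optional logical vector (or a `contact_matrix` whose
#'   mask is taken) of bins excluded in the reference map.
#' @return a `contact_matrix` of kind `"normalized"` with unmasked
#'   entries in `[0, 1]`.
#' @export
postprocess_dda <- function(D, hic_mask = NULL) {
  stopifnot(inherits(D, "contact_matrix"))
  v <- D$values
  ok <- !D$mask
  sub <- v[ok, ok, drop = FALSE]
  if (any(!is.finite(sub))) {
    # ergodicity undefined for some pair (rho_c = 0): mask those bins
    bad <- which(rowSums(!is.finite(sub)) > 0)
    stop("non-finite ergodicity entries; mask the offending bins first (",
         length(bad), " rows)")
  }
  rng <- range(sub)
  flipped <- rng[2] + rng[1] - sub
  nz <- flipped != 0
  flipped[nz] <- log(flipped[nz])
  rng2 <- range(flipped)
  if (rng2[2] == rng2[1])
    stop("degenerate matrix: zero range after flip/log, cannot normalize")
  scaled <- (flipped - rng2[1]) / (rng2[2] - rng2[1])
  v[ok, ok] <- scaled
  mask <- D$mask
  if (!is.null(hic_mask)) {
    if (inherits(hic_mask, "contact_matrix")) hic_mask <- hic_mask$mask
    mask <- mask | hic_mask
  }
  contact_matrix(v, bins = mask_into_bins(D$bins, mask), mask = mask,
                 kind = "normalized")
}

mask_into_bins <- function(bins, mask) {
  if (is.null(bins)) return(NULL)
  bins$mask <- mask
  bins
}

#' Min-max rescale a contact matrix to [0, 1]
#'
#' @param M a `contact_matrix` or plain numeric matrix.
#' @return same type as the input, unmasked entries rescaled to `[0, 1]`.
#' @export
normalize_range <- function(M) {
  if (inherits(M, "contact_matrix")) {
    v <- M$values
    ok <- !M$mask
    sub <- v[ok, ok, drop = FALSE]
    rng <- range(sub)
    if (rng[2] == rng[1]) stop("constant matrix: zero range")
    v[ok, ok] <- (sub - rng[1]) / (rng[2] - rng[1])
    M$values <- v
    return(M)
  }
  rng <- range(M, na.rm = TRUE)
  if (rng[2] == rng[1]) stop("constant matrix: zero range")
  (M - rng[1]) / (rng[2] - rng[1])
}

#' Mask low-coverage bins of a contact map
#'
#' Masks bins whose total contact (row sum over unmasked entries) falls
#' below `fraction` of a reference level: the mean unmasked row sum
#' (`method = "mean"`, default) or the total contact mass
#' (`method = "total"`).
#'
#' @param H a nonnegative `contact_matrix`.
#' @param fraction threshold fraction (default 0.10).
#' @param method reference level for the threshold.
#' @return the matrix with an updated mask.
#' @export
mask_low_coverage <- function(H, fraction = 0.10,
                              method = c("mean", "total")) {
  method <- match.arg(method)
  stopifnot(inherits(H, "contact_matrix"))
  if (fraction <= 0) return(H)
  ok <- !H$mask
  rs <- rowSums(H$values[, ok, drop = FALSE], na.rm = TRUE)
  rs[!ok] <- NA_real_
  ref <- if (method == "mean") mean(rs[ok]) else sum(rs[ok])
  newmask <- H$mask | (!is.na(rs) & rs < fraction * ref)
  contact_matrix(replace(H$values, is.na(H$values), NA_real_),
                 bins = mask_into_bins(H$bins, newmask),
                 mask = newmask, kind = H$kind)
}
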