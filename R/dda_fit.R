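#' Centered numerical derivative
#'
#' `xdot(t) = (x(t+w) - x(t-w)) / (2w)` with unit spacing, defined for
#' `t = w+1 .. L-w`. Exact for polynomials up to degree 2 when `w = 1`.
#'
#' @param x numeric series.
#' @param w derivative half-width (default 1: 3-point stencil).
#' @return numeric vector of length `length(x) - 2w`.
#' @export
center_derivative <- function(x, w = 1L) {
  L <- length(x)
  w <- as.integer(w)
  if (w < 1L) stop("w must be >= 1")
  if (L < 2L * w + 1L) stop("series too short for derivative half-width ", w)
  idx <- (w + 1L):(L - w)
  (x[idx + w] - x[idx - w]) / (2 * w)
}

#' Usable fit window for a delayed design
#'
#' All rows `t` for which every delay embedding `x(t - tau_n)` and the
#' centered derivative `xdot(t)` exist:
#' `t = max(tau) + w + 1 .. L - w`.
#'
#' @param L series length.
#' @param delays delay vector (only delays actually used by the model
#'   matter).
#' @param w derivative half-width.
#' @return list with `t_lo`, `t_hi`, `n` (number of rows; 0 if empty).
#' @export
fit_window <- function(L, delays, w = 1L) {
  t_lo <- max(delays) + w + 1L
  t_hi <- L - w
  list(t_lo = t_lo, t_hi = t_hi, n = max(0L, t_hi - t_lo + 1L))
}

# center/scale a series to zero mean, unit variance; constant series are
# centered only (all zeros) and flagged
standardize_series <- function(x) {
  mu <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    structure(x - mu, degenerate = TRUE)
  } else {
    (x - mu) / s
  }
}

#' Build the delayed design matrix and derivative vector
#'
#' One row per position in the [fit_window()]; column `k` holds
#' `prod_n x(t - tau_n)^(m_{n,k})`, and the derivative vector is aligned
#' row-wise. By default the series is standardized (zero mean, unit
#' variance) before embedding; raw DNA walks carry strong trends and DDA
#' practice standardizes inputs.
#'
#' @param x numeric series, a `dna_walk`, or anything with `$values`.
#' @param model a `dda_model` with delays set.
#' @param w derivative half-width (default 1).
#' @param standardize standardize the series before embedding (default
#'   `TRUE`).
#' @return list with `xdot` (length-n vector), `M` (n x K matrix), `n`.
#' @export
build_design <- function(x, model, w = 1L, standardize = TRUE) {
  x <- walk_values(x)
  if (is.null(model$delays)) stop("model delays are unset")
  if (standardize) x <- standardize_series(x)
  L <- length(x)
  used <- Reduce(`|`, lapply(model$terms, function(e) e > 0L))
  fw <- fit_window(L, model$delays[used], w)
  if (fw$n < 1L)
    stop(sprintf(
      "empty fit window: series length %d too short for delays (%s), w=%d",
      L, paste(model$delays, collapse = ","), w))
  t <- fw$t_lo:fw$t_hi
  lags <- lapply(seq_len(model$n_delays), function(n) x[t - model$delays[n]])
  M <- vapply(model$terms, function(e) {
    col <- rep(1, fw$n)
    for (n in seq_along(e)) if (e[n] > 0L) col <- col * lags[[n]]^e[n]
    col
  }, numeric(fw$n))
  M <- matrix(M, nrow = fw$n)
  xdot <- (x[t + w] - x[t - w]) / (2 * w)
  list(xdot = xdot, M = M, n = fw$n)
}

walk_values <- function(x) {
  if (inherits(x, "dna_walk")) x$values
  else if (is.list(x) && !is.null(x$values)) x$values
  else as.numeric(x)
}

# minimum-norm least squares by SVD; singular values below
# tol * sigma_max are truncated
lsq_svd <- function(M, y, tol = 1e-12) {
  sv <- svd(M)
  d <- sv$d
  keep <- d > tol * d[1L]
  if (!any(keep)) return(rep(0, ncol(M)))
  as.vector(sv$v[, keep, drop = FALSE] %*%
            ((crossprod(sv$u[, keep, drop = FALSE], y)) / d[keep]))
}

rho_from_residual <- function(y, M, a) {
  r <- y - as.vector(M %*% a)
  sqrt(sum(r * r) / length(y))
}

new_dda_features <- function(a, rho, n, kind, degenerate = FALSE) {
  structure(list(a = a, rho = rho, n_points = n, kind = kind,
                 degenerate = degenerate),
            class = "dda_features")
}

#' @export
print.dda_features <- function(x, ...) {
  cat(sprintf("dda_features (%s): a = (%s), rho = %.6g, n = %d%s\n",
              x$kind, paste(signif(x$a, 6), collapse = ", "),
              x$rho, x$n_points,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Single-trial (ST) DDA fit
#'
#' Fits the over-determined system `xdot = M a` for one series by SVD
#' (minimum-norm solution) and returns the classifying feature set: the
#' coefficients and the least-square error
#' `rho = sqrt(mean((xdot - M a)^2))` over the rows actually fitted.
#'
#' @inheritParams build_design
#' @return a `dda_features` object (`kind = "single-trial"`).
#' @export
fit_st <- function(x, model, w = 1L, standardize = TRUE) {
  d <- build_design(x, model, w = w, standardize = standardize)
  fit_system(d$xdot, d$M, kind = "single-trial")
}

#' Cross-trial (CT) DDA fit
#'
#' Fits one coefficient vector to two series simultaneously by
#' row-stacking their designs: `[xdot_i; xdot_j] = [M_i; M_j] a`. The
#' error `rho` is taken over all stacked rows.
#'
#' @param xi,xj two series (or `dna_walk`s) of compatible length.
#' @inheritParams build_design
#' @return a `dda_features` object (`kind = "cross-trial"`).
#' @export
fit_ct <- function(xi, xj, model, w = 1L, standardize = TRUE) {
  di <- build_design(xi, model, w = w, standardize = standardize)
  dj <- build_design(xj, model, w = w, standardize = standardize)
  fit_system(c(di$xdot, dj$xdot), rbind(di$M, dj$M), kind = "cross-trial")
}

fit_system <- function(y, M, kind) {
  if (all(y == 0) && all(M == 0))
    return(new_dda_features(rep(0, ncol(M)), 0, length(y), kind,
                            degenerate = TRUE))
  a <- lsq_svd(M, y)
  new_dda_features(a, rho_from_residual(y, M, a), length(y), kind)
}

#' Dynamical ergodicity score
#'
#' `E = | mean(rho_si, rho_sj) / rho_c - 1 |`: compares the temporal
#' average (mean of the two single-trial errors) with the ensemble
#' average (the cross-trial error). Near 0 when the two series are
#' dynamically similar.
#'
#' @param rho_si,rho_sj single-trial least-square errors of the two bins.
#' @param rho_c cross-trial least-square error of the pair.
#' @return `E >= 0`; `NA` when `rho_c = 0` but the ST errors are not both
#'   0 (undefined; the pair should be masked), 0 when all three are 0.
#' @export
ergodicity <- function(rho_si, rho_sj, rho_c) {
  if (rho_c == 0) {
    if (rho_si == 0 && rho_sj == 0) return(0)
    return(NA_real_)
  }
  abs((rho_si + rho_sj) / 2 / rho_c - 1)
}
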