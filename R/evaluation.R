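#' Agreement metrics between two compartment tracks
#'
#' Compares a predicted track with a reference over bins unmasked in
#' both. Reference labels come from the sign of the reference PC (A =
#' positive = positive class); prediction scores are the predicted PC
#' values. ACC and F1 are taken at threshold 0; AUC uses the rank
#' (Mann-Whitney) statistic with midrank ties.
#'
#' @param pred a `compartment_track` (or numeric score vector).
#' @param ref a `compartment_track` (or numeric vector whose sign gives
#'   the labels).
#' @return object of class `metric_report`: list with `r_pc`, `auc`,
#'   `acc`, `f1`, `n_bins`. `auc` is `NA` when the reference has a
#'   single class.
#' @export
track_metrics <- function(pred, ref) {
  score <- track_pc(pred)
  refpc <- track_pc(ref)
  if (length(score) != length(refpc)) stop("tracks must share bins")
  ok <- is.finite(score) & is.finite(refpc)
  score <- score[ok]
  labels <- refpc[ok] > 0
  r <- if (stats::sd(score) > 0 && stats::sd(refpc[ok]) > 0)
    stats::cor(score, refpc[ok]) else NA_real_
  auc <- auc_rank(score, labels)
  pred_a <- score > 0
  acc <- mean(pred_a == labels)
  tp <- sum(pred_a & labels)
  fp <- sum(pred_a & !labels)
  fn <- sum(!pred_a & labels)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  structure(list(r_pc = r, auc = auc, acc = acc, f1 = f1,
                 n_bins = length(score)),
            class = "metric_report")
}

track_pc <- function(x) {
  if (inherits(x, "compartment_track")) x$pc else as.numeric(x)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: r = %.3f, AUC = %.3f, ACC = %.3f, F1 = %.3f (n = %d)\n",
              x$r_pc, x$auc, x$acc, x$f1, x$n_bins))
  invisible(x)
}

#' Area under the ROC curve by the rank statistic
#'
#' Midrank handling of ties; equals brute-force counting of
#' concordant/tied (A, B) score pairs.
#'
#' @param score numeric prediction scores.
#' @param labels logical, `TRUE` = positive class.
#' @return AUC in `[0, 1]`, or `NA` if one class is absent.
#' @export
auc_rank <- function(score, labels) {
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  rk <- rank(score)  # midranks
  (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Observed/expected contact matrix
#'
#' The expected value at genomic distance `d` is the mean of the `d`-th
#' diagonal over entries whose two bins are both unmasked (the sum of
#' the diagonal divided by its number of elements); each entry is then
#' divided by the expected value at its distance. Entries whose expected
#' value is zero become `NA`.
#'
#' @param H a square `contact_matrix`.
#' @return a `contact_matrix` of kind `"observed-expected"`.
#' @export
observed_expected <- function(H) {
  stopifnot(inherits(H, "contact_matrix"))
  v <- H$values
  n <- nrow(v)
  ok <- !H$mask
  out <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    j <- i + d
    use <- ok[i] & ok[j]
    if (!any(use)) next
    vals <- v[cbind(i[use], j[use])]
    expected <- mean(vals)
    if (expected == 0) next
    oe <- vals / expected
    out[cbind(i[use], j[use])] <- oe
    out[cbind(j[use], i[use])] <- oe
  }
  contact_matrix(out, bins = H$bins, mask = H$mask,
                 kind = "observed-expected")
}

#' Saddle-plot analysis and compartment strength
#'
#' The PC track is scaled to `[-1, 1]` by its maximum absolute value,
#' bins are ranked by the scaled PC and split into `n_quantiles`
#' equal-count groups (stable bin order on ties), and the matrix is
#' reordered accordingly and aggregated per group pair. Compartment
#' strength is `S = (AA + BB) / (AB + BA)`, aggregating (by mean)
#' entries whose two endpoints both lie in the top 25% of the scaled PC
#' values (AA), both in the bottom 25% (BB), or one in each (AB, BA).
#' The extreme sets can alternatively be defined on quantile-group
#' indices (`corner_on = "groups"`), and sums used instead of means.
#'
#' @param M an observed/expected (Hi-C) or normalized DNA-DDA
#'   `contact_matrix`.
#' @param pc numeric PC series or `compartment_track` on the same bins.
#' @param n_quantiles number of quantile groups (default 30; reduced
#'   with a message when fewer bins are available).
#' @param top_frac extreme-quartile fraction (default 0.25).
#' @param corner_on define extremes on scaled `"values"` (default) or on
#'   `"groups"`.
#' @param agg corner aggregation, `"mean"` (default) or `"sum"`.
#' @return object of class `saddle_result`: list with `strength`,
#'   `sorted_oe` (group-aggregated matrix), `n_quantiles`, `corners`.
#' @export
saddle <- function(M, pc, n_quantiles = 30L, top_frac = 0.25,
                   corner_on = c("values", "groups"),
                   agg = c("mean", "sum")) {
  corner_on <- match.arg(corner_on)
  agg <- match.arg(agg)
  stopifnot(inherits(M, "contact_matrix"))
  pc <- track_pc(pc)
  if (length(pc) != nrow(M$values)) stop("pc must be defined on M's bins")
  ok <- which(!M$mask & is.finite(pc))
  n <- length(ok)
  if (n < n_quantiles) {
    message("only ", n, " usable bins; reducing quantile groups")
    n_quantiles <- n
  }
  scaled <- pc[ok] / max(abs(pc[ok]))
  ord <- order(scaled)  # stable
  groups <- integer(n)
  groups[ord] <- ceiling(seq_len(n) / (n / n_quantiles))
  aggfun <- if (agg == "mean") mean else sum
  sorted_oe <- matrix(NA_real_, n_quantiles, n_quantiles)
  sub <- M$values[ok, ok, drop = FALSE]
  for (g1 in seq_len(n_quantiles)) for (g2 in g1:n_quantiles) {
    vals <- sub[groups == g1, groups == g2, drop = FALSE]
    vals <- vals[is.finite(vals)]
    if (length(vals))
      sorted_oe[g1, g2] <- sorted_oe[g2, g1] <- aggfun(vals)
  }
  if (corner_on == "values") {
    hi <- scaled >= stats::quantile(scaled, 1 - top_frac)
    lo <- scaled <= stats::quantile(scaled, top_frac)
  } else {
    hi <- groups > n_quantiles * (1 - top_frac)
    lo <- groups <= n_quantiles * top_frac
  }
  corner <- function(a, b) {
    vals <- sub[a, b, drop = FALSE]
    vals <- vals[is.finite(vals)]
    if (length(vals)) aggfun(vals) else NA_real_
  }
  aa <- corner(hi, hi); bb <- corner(lo, lo)
  ab <- corner(hi, lo); ba <- corner(lo, hi)
  denom <- ab + ba
  strength <- if (is.finite(denom) && denom > 0) (aa + bb) / denom
              else NA_real_
  structure(list(strength = strength, sorted_oe = sorted_oe,
                 n_quantiles = n_quantiles,
                 corners = c(AA = aa, BB = bb, AB = ab, BA = ba)),
            class = "saddle_result")
}

#' @export
print.saddle_result <- function(x, ...) {
  cat(sprintf("saddle_result: S = %.4g over %d quantile groups\n",
              x$strength, x$n_quantiles))
  invisible(x)
}

#' GC-content baseline metrics
#'
#' Treats the per-bin GC fraction (z-scored, so threshold 0 means
#' above-average GC) as the prediction score and computes the same
#' metrics as [track_metrics()].
#'
#' @param gc per-bin GC fractions (`NA` on masked bins).
#' @param ref reference `compartment_track`.
#' @return a `metric_report`.
#' @export
gc_baseline_metrics <- function(gc, ref) {
  fin <- is.finite(gc)
  z <- gc
  s <- stats::sd(gc[fin])
  z[fin] <- if (is.finite(s) && s > 0) (gc[fin] - mean(gc[fin])) / s
            else gc[fin] - mean(gc[fin])
  track_metrics(z, ref)
}

#' Paired comparison of per-chromosome correlations
#'
#' Wilcoxon signed-rank test pairing one metric per chromosome from two
#' methods (e.g. DNA-DDA `r` vs the GC baseline `r`).
#'
#' @param r_a,r_b paired numeric vectors (one value per chromosome).
#' @return list with `p_value`, `statistic`, `n`.
#' @export
paired_wilcoxon <- function(r_a, r_b) {
  stopifnot(length(r_a) == length(r_b))
  ok <- is.finite(r_a) & is.finite(r_b)
  w <- stats::wilcox.test(r_a[ok], r_b[ok], paired = TRUE, exact = FALSE)
  list(p_value = w$p.value, statistic = unname(w$statistic), n = sum(ok))
}
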