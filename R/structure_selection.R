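#' Exhaustive delay-pair structure selection
#'
#' DDA models are not trained iteratively; instead every delay pair
#' `tau1 < tau2` in the configured range is evaluated on a training
#' region and scored. For each pair the full sequence-only pipeline is
#' run on the training walks (ergodicity matrix, post-processing,
#' compartment call in DNA-DDA mode) and scored as the absolute Pearson
#' correlation between the resulting PC track and the reference PC track
#' over mutually unmasked bins. The argmax pair is returned with a
#' deterministic tie-break (smallest `tau1`, then `tau2`).
#'
#' @param walks [bin_walks()] result (or named walk list) restricted to
#'   the training region.
#' @param reference_pc reference `compartment_track` (or numeric PC
#'   vector) on the same bins.
#' @param chip `chip_profile` (or count vector) used to select/orient
#'   the PC at every grid point.
#' @param tau_range integer vector `c(min, max)`; all pairs
#'   `min <= tau1 < tau2 <= max` are evaluated (`C(n, 2)` pairs, the
#'   symmetric model halves the effort relative to ordered pairs).
#' @param model model structure to sweep (default the symmetric
#'   quadratic model).
#' @param w,standardize fitting configuration, as in [build_design()].
#' @param min_bins minimum number of unmasked training bins (default 10).
#' @param verbose print progress every 100 pairs.
#' @return object of class `sweep_result`: list with `grid` (data.frame
#'   `tau1`, `tau2`, `r`), `best_pair`, `best_score`, `region`.
#' @export
sweep_delays <- function(walks, reference_pc, chip, tau_range = c(1L, 50L),
                         model = default_model(), w = 1L,
                         standardize = TRUE, min_bins = 10L,
                         verbose = FALSE) {
  bw <- as_bin_walks(walks)
  if (length(bw$walks) < min_bins)
    stop("training region has fewer than ", min_bins, " unmasked bins")
  ref <- track_pc(reference_pc)
  pairs <- delay_grid(tau_range)
  rs <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    rs[p] <- score_delay_pair(bw, ref, chip,
                              tau1 = pairs[1L, p], tau2 = pairs[2L, p],
                              model = model, w = w,
                              standardize = standardize)
    if (verbose && p %% 100L == 0L)
      message("swept ", p, "/", ncol(pairs), " delay pairs")
  }
  grid <- data.frame(tau1 = pairs[1L, ], tau2 = pairs[2L, ], r = rs)
  # argmax with tie-break smallest tau1 then tau2 (grid is already in
  # that order, so the first maximum wins)
  if (!any(is.finite(grid$r)))
    stop("no delay pair produced a finite score")
  finite_best <- max(grid$r[is.finite(grid$r)])
  best <- which(is.finite(grid$r) & grid$r == finite_best)[1L]
  region <- if (!is.null(bw$bins))
    sprintf("%s:%d-%d", bw$bins$chrom[1], min(bw$bins$start) + 1L,
            max(bw$bins$end)) else NA_character_
  structure(list(grid = grid,
                 best_pair = c(tau1 = grid$tau1[best],
                               tau2 = grid$tau2[best]),
                 best_score = grid$r[best], region = region),
            class = "sweep_result")
}

# unordered delay pairs tau1 < tau2 in sweep order (tau1 major): the
# symmetric default model makes ordered pairs redundant, so C(n, 2)
# pairs cover the range
delay_grid <- function(tau_range) {
  taus <- seq.int(tau_range[1], tau_range[2])
  if (length(taus) < 2L) stop("tau_range must span at least two delays")
  utils::combn(taus, 2L)
}

score_delay_pair <- function(bw, ref, chip, tau1, tau2, model, w,
                             standardize) {
  track <- tryCatch({
    m <- set_delays(model, c(tau1, tau2))
    D <- build_dda_matrix(bw, m, w = w, standardize = standardize)
    Dn <- postprocess_dda(D)
    call_compartments(Dn, chip, mode = "dda")
  }, error = function(e) NULL)
  if (is.null(track)) return(NA_real_)
  ok <- is.finite(track$pc) & is.finite(ref)
  if (sum(ok) < 3L) return(NA_real_)
  r <- suppressWarnings(stats::cor(track$pc[ok], ref[ok]))
  if (!is.finite(r)) NA_real_ else abs(r)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "sweep_result: %d delay pairs, best (tau1, tau2) = (%d, %d), |r| = %.3f\n",
    nrow(x$grid), x$best_pair[["tau1"]], x$best_pair[["tau2"]],
    x$best_score))
  invisible(x)
}

#' Apply a selected delay pair genome-wide
#'
#' Runs the full sequence-only pipeline (ergodicity matrix,
#' post-processing, DNA-DDA compartment call) independently for each
#' chromosome with a fixed delay pair.
#'
#' @param walks_by_chrom named list of per-chromosome [bin_walks()]
#'   results.
#' @param delays length-2 delay pair (e.g. `sweep$best_pair`).
#' @param chip_by_chrom named list of `chip_profile`s (or one shared
#'   profile if unnamed length-1).
#' @param model model structure (default symmetric quadratic).
#' @param ... passed to [build_dda_matrix()] and [call_compartments()].
#' @return named list of `compartment_track`s, one per chromosome (an
#'   all-masked chromosome yields `NULL` with a warning); each track's
#'   provenance records the delay pair.
#' @export
apply_model <- function(walks_by_chrom, delays, chip_by_chrom,
                        model = default_model(), w = 1L,
                        standardize = TRUE) {
  m <- set_delays(model, delays)
  out <- stats::setNames(vector("list", length(walks_by_chrom)),
                         names(walks_by_chrom))
  for (chrom in names(walks_by_chrom)) {
    bw <- as_bin_walks(walks_by_chrom[[chrom]])
    if (length(bw$walks) < 2L) {
      warning("chromosome ", chrom, " has <2 usable bins; empty track")
      next
    }
    chip <- if (inherits(chip_by_chrom, "chip_profile")) chip_by_chrom
            else chip_by_chrom[[chrom]]
    D <- build_dda_matrix(bw, m, w = w, standardize = standardize)
    Dn <- postprocess_dda(D)
    track <- call_compartments(Dn, chip, mode = "dda")
    prov <- attr(track, "provenance")
    prov$delays <- delays
    attr(track, "provenance") <- prov
    out[[chrom]] <- track
  }
  out
}
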