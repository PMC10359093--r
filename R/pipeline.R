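#' End-to-end sequence-only compartment prediction
#'
#' Orchestrates the three-step analysis per chromosome: (1) segment the
#' sequence into fixed-width bins and encode DNA walks, (2) build and
#' post-process the dynamical-ergodicity contact map for the configured
#' delay pair (or select one by sweeping a training region), (3) call
#' A/B compartments, and, when a reference track is supplied, evaluate
#' agreement.
#'
#' @param config named list:
#'   \describe{
#'     \item{fasta}{path or `DNAStringSet` (required)}
#'     \item{chip}{BED path / data.frame / `GRanges` of peaks (required
#'       unless `pc_index` is given)}
#'     \item{bin_size}{default 100000}
#'     \item{delays}{length-2 delay pair; omit to sweep}
#'     \item{sweep}{list with `region` ("chr:start-end", 1-based),
#'       `reference` (bedGraph path or numeric PC vector aligned to the
#'       region bins), `tau_range` (default c(1, 50))}
#'     \item{exclude}{optional BED of exclusion regions}
#'     \item{reference}{optional per-chromosome reference tracks (named
#'       list of numeric PC vectors) for evaluation}
#'     \item{pc_index}{optional manual PC override}
#'     \item{w, standardize}{fit configuration (defaults 1, TRUE)}
#'     \item{out_dir}{optional; when set, matrices (TSV), tracks
#'       (bedGraph/BED) and the provenance JSON are written}
#'   }
#' @return list with `tracks` (per chromosome), `matrices` (normalized
#'   DNA-DDA maps), `delays`, `sweep` (if performed), `metrics` (per
#'   chromosome, if reference given), `config`.
#' @export
run_predict <- function(config) {
  required <- c("fasta")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("configuration error: missing field(s) ",
         paste(missing, collapse = ", "))
  if (is.null(config$chip) && is.null(config$pc_index))
    stop("configuration error: supply a chip BED or an explicit pc_index ",
         "(the PC cannot be selected/oriented otherwise)")
  bin_size <- config$bin_size %||% 100000L
  w <- config$w %||% 1L
  standardize <- config$standardize %||% TRUE

  seqs <- as_dnastringset(config$fasta)
  bins_all <- make_bins(stats::setNames(Biostrings::width(seqs),
                                        names(seqs)), bin_size = bin_size)
  if (!is.null(config$exclude))
    bins_all <- mask_regions(bins_all, config$exclude)

  chroms <- unique(bins_all$chrom)
  walks_by_chrom <- stats::setNames(lapply(chroms, function(ch) {
    b <- bins_all[bins_all$chrom == ch, , drop = FALSE]
    attr(b, "bin_size") <- bin_size
    class(b) <- c("genomic_bins", "data.frame")
    bin_walks(seqs, b)
  }), chroms)

  chip_by_chrom <- NULL
  if (!is.null(config$chip)) {
    peaks <- as_bed_df(config$chip)
    chip_by_chrom <- stats::setNames(lapply(chroms, function(ch) {
      suppressWarnings(
        chip_profile(peaks[peaks$chrom == ch, , drop = FALSE],
                     walks_by_chrom[[ch]]$bins))
    }), chroms)
  }

  sweep_res <- NULL
  delays <- config$delays
  if (is.null(delays)) {
    if (is.null(config$sweep))
      stop("configuration error: supply either delays or a sweep block")
    sw <- config$sweep
    reg <- parse_region(sw$region)
    bw <- walks_by_chrom[[reg$chrom]]
    in_reg <- bw$bins$start >= reg$start & bw$bins$end <= reg$end
    b <- bw$bins[in_reg, , drop = FALSE]
    attr(b, "bin_size") <- bin_size
    class(b) <- c("genomic_bins", "data.frame")
    keep_lab <- bin_labels(b)[!b$mask]
    bw_reg <- structure(list(walks = bw$walks[keep_lab], bins = b),
                        class = "bin_walks")
    ref <- sw$reference
    if (is.character(ref)) ref <- read_track(ref, b)
    sweep_res <- sweep_delays(bw_reg, ref, chip_by_chrom[[reg$chrom]],
                              tau_range = sw$tau_range %||% c(1L, 50L),
                              w = w, standardize = standardize)
    delays <- sweep_res$best_pair
  }

  tracks <- list()
  matrices <- list()
  metrics <- list()
  model <- set_delays(default_model(), delays)
  for (ch in chroms) {
    bw <- walks_by_chrom[[ch]]
    if (length(bw$walks) < 2L) {
      warning("chromosome ", ch, " has <2 usable bins; skipped")
      next
    }
    D <- build_dda_matrix(bw, model, w = w, standardize = standardize)
    Dn <- postprocess_dda(D)
    chp <- if (!is.null(chip_by_chrom)) chip_by_chrom[[ch]]
           else rep(NA_real_, nrow(Dn$values))
    track <- call_compartments(Dn, chp, mode = "dda",
                               pc_index = config$pc_index)
    prov <- attr(track, "provenance")
    prov$delays <- delays
    prov$chrom <- ch
    attr(track, "provenance") <- prov
    tracks[[ch]] <- track
    matrices[[ch]] <- Dn
    if (!is.null(config$reference) && !is.null(config$reference[[ch]]))
      metrics[[ch]] <- track_metrics(track, config$reference[[ch]])
  }

  out <- list(tracks = tracks, matrices = matrices, delays = delays,
              sweep = sweep_res,
              metrics = if (length(metrics)) metrics else NULL,
              bins = walks_by_chrom, config = config)
  if (!is.null(config$out_dir)) write_outputs(out, config$out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(res$tracks)) {
    write_matrix(res$matrices[[ch]],
                 file.path(dir, paste0(ch, "_dda.tsv")), format = "tsv")
    write_track(res$tracks[[ch]], res$bins[[ch]]$bins,
                file.path(dir, paste0(ch, "_compartments")))
  }
  prov <- list(delays = as.integer(res$delays),
               config = res$config[setdiff(names(res$config),
                                           c("fasta", "reference"))],
               chromosomes = names(res$tracks))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Consolidated per-chromosome metric report
#'
#' Aggregates per-chromosome `metric_report`s into a table plus the mean
#' and variance of every metric across chromosomes.
#'
#' @param metrics named list of `metric_report`s (e.g.
#'   `run_predict()$metrics`).
#' @param path optional JSON output path.
#' @return list with `table` (data.frame, one row per chromosome),
#'   `mean` and `var` (named numeric over `r_pc`, `auc`, `acc`, `f1`).
#' @export
run_report <- function(metrics, path = NULL) {
  cols <- c("r_pc", "auc", "acc", "f1")
  if (!length(metrics)) {
    out <- list(table = data.frame(), mean = stats::setNames(
      rep(NA_real_, 4), cols), var = stats::setNames(rep(NA_real_, 4),
                                                     cols))
  } else {
    tab <- do.call(rbind, lapply(names(metrics), function(ch) {
      m <- metrics[[ch]]
      data.frame(chrom = ch, r_pc = m$r_pc, auc = m$auc, acc = m$acc,
                 f1 = m$f1, n_bins = m$n_bins)
    }))
    out <- list(table = tab,
                mean = vapply(cols, function(cl)
                  mean(tab[[cl]], na.rm = TRUE), numeric(1)),
                var = vapply(cols, function(cl)
                  stats::var(tab[[cl]], na.rm = TRUE), numeric(1)))
  }
  if (!is.null(path))
    jsonlite::write_json(list(
      table = out$table, mean = as.list(out$mean),
      var = as.list(out$var)), path, auto_unbox = TRUE, dataframe = "rows",
      pretty = TRUE, digits = NA, na = "null")
  out
}
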