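#' Synthetic fixture specification
#'
#' A self-contained description of a synthetic data set with planted
#' ground truth: block-structured sequences whose base-composition
#' dynamics differ between the two planted compartment classes, a plaid
#' contact map with optional distance decay and multiplicative noise,
#' and class-biased peak calls. Generation is a pure function of the
#' spec (seed included).
#'
#' Defaults are sized for desk-scale runs: 200 bins of 10 kb (a 1:10
#' scale model of a 20 Mb training region at 100 kb resolution), class
#' blocks of 25 bins, class GC levels 0.60 (A) / 0.40 (B), plaid means
#' 2 (intra) / 0.5 (inter) with no decay and no noise unless requested,
#' and peak rates 3 (A) / 0.3 (B) per bin.
#'
#' @param n_bins number of bins (default 200).
#' @param bin_size bin width in nucleotides (default 10000).
#' @param labels planted `"A"`/`"B"` label per bin; default alternating
#'   blocks of `block` bins starting with A.
#' @param block block length in bins for the default labels (default 25).
#' @param seed integer seed governing all fixture randomness.
#' @param chrom sequence name (default `"chrSim"`).
#' @param gc_a,gc_b class GC targets.
#' @param persistence probability that a base keeps its S/W group from
#'   the previous position (first-order Markov composition; 0 = iid).
#' @param period_a,period_b optional lag (nt) of a sinusoidal GC
#'   modulation per class (`NULL` = none).
#' @param amp amplitude of the periodic GC modulation.
#' @param intra_mean,inter_mean plaid contact levels for same/different
#'   class pairs.
#' @param decay distance-decay exponent `alpha` in `(1+|i-j|)^-alpha`
#'   (0 = off).
#' @param noise multiplicative log-normal noise dispersion (sdlog; 0 =
#'   noiseless).
#' @param rate_a,rate_b Poisson peak rates per bin and class.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_bins = 200L, bin_size = 10000L, labels = NULL,
                         block = 25L, seed = 1L, chrom = "chrSim",
                         gc_a = 0.60, gc_b = 0.40, persistence = 0,
                         period_a = NULL, period_b = NULL, amp = 0.15,
                         intra_mean = 2, inter_mean = 0.5, decay = 0,
                         noise = 0, rate_a = 3, rate_b = 0.3) {
  if (is.null(labels)) {
    labels <- rep(rep(c("A", "B"), each = block),
                  length.out = n_bins)
  }
  if (length(labels) != n_bins) stop("labels length must equal n_bins")
  if (!all(labels %in% c("A", "B"))) stop("labels must be 'A' or 'B'")
  stopifnot(intra_mean > 0, inter_mean > 0, rate_a >= 0, rate_b >= 0,
            gc_a > 0, gc_a < 1, gc_b > 0, gc_b < 1,
            persistence >= 0, persistence < 1)
  structure(list(n_bins = as.integer(n_bins),
                 bin_size = as.integer(bin_size), labels = labels,
                 seed = as.integer(seed), chrom = chrom,
                 gc = c(A = gc_a, B = gc_b), persistence = persistence,
                 period = list(A = period_a, B = period_b), amp = amp,
                 intra_mean = intra_mean, inter_mean = inter_mean,
                 decay = decay, noise = noise,
                 rate = c(A = rate_a, B = rate_b)),
            class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf(
    "fixture_spec: %d x %d nt bins, GC A/B = %.2f/%.2f, plaid %g/%g, seed %d\n",
    x$n_bins, x$bin_size, x$gc[["A"]], x$gc[["B"]],
    x$intra_mean, x$inter_mean, x$seed))
  invisible(x)
}

with_fixture_seed <- function(spec, offset, expr) {
  # localized RNG so generators are pure functions of (spec, seed) and
  # leave the caller's RNG state untouched
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed + offset)
  expr
}

#' Generate block-structured synthetic sequences
#'
#' One sequence (chromosome) made of `n_bins` bins; each bin's bases are
#' drawn from its class's composition process: a first-order strong/weak
#' (S = C/G, W = A/T) chain with stationary GC level `gc`, optional
#' persistence, and an optional sinusoidal GC modulation of period
#' `period` nucleotides (which plants lag-`period` autocorrelation in
#' the implied DNA walk increments). Within a group C/G (resp. A/T) are
#' chosen uniformly.
#'
#' @param spec a `fixture_spec`.
#' @return list with `seqs` (a `Biostrings::DNAStringSet` of one
#'   record), `labels`, `bins` (a `genomic_bins`).
#' @export
gen_sequences <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec, 101L, {
    bases_strong <- c("C", "G")
    bases_weak <- c("A", "T")
    bin_seqs <- character(spec$n_bins)
    for (i in seq_len(spec$n_bins)) {
      cls <- spec$labels[i]
      g <- spec$gc[[cls]]
      t <- seq_len(spec$bin_size)
      p <- rep(g, spec$bin_size)
      per <- spec$period[[cls]]
      if (!is.null(per))
        p <- pmin(0.95, pmax(0.05, g + spec$amp * sin(2 * pi * t / per)))
      fresh <- stats::runif(spec$bin_size) < p
      strong <- fresh
      if (spec$persistence > 0) {
        keep <- stats::runif(spec$bin_size) < spec$persistence
        for (tt in 2:spec$bin_size)
          if (keep[tt]) strong[tt] <- strong[tt - 1L]
      }
      pick <- ifelse(stats::runif(spec$bin_size) < 0.5, 1L, 2L)
      chars <- ifelse(strong, bases_strong[pick], bases_weak[pick])
      bin_seqs[i] <- paste(chars, collapse = "")
    }
    seqs <- Biostrings::DNAStringSet(
      stats::setNames(paste(bin_seqs, collapse = ""), spec$chrom))
    bins <- make_bins(stats::setNames(spec$n_bins * spec$bin_size,
                                      spec$chrom),
                      bin_size = spec$bin_size)
    list(seqs = seqs, labels = spec$labels, bins = bins)
  })
}

#' Generate a plaid synthetic Hi-C contact map
#'
#' Entry `(i, j)` is `intra_mean` (same planted label) or `inter_mean`
#' (different), times a distance-decay factor `(1 + |i-j|)^-decay`,
#' times multiplicative log-normal noise `exp(N(0, noise^2))` drawn once
#' per unordered pair. Symmetric and strictly positive by construction.
#'
#' @param spec a `fixture_spec`.
#' @return list with `H` (a `contact_matrix` of kind `"hic"`) and
#'   `labels`.
#' @export
gen_plaid_hic <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec, 202L, {
    n <- spec$n_bins
    same <- outer(spec$labels, spec$labels, `==`)
    base <- ifelse(same, spec$intra_mean, spec$inter_mean)
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    v <- base * (1 + d)^(-spec$decay)
    if (spec$noise > 0) {
      eps <- matrix(0, n, n)
      ut <- upper.tri(eps, diag = TRUE)
      eps[ut] <- stats::rnorm(sum(ut), sd = spec$noise)
      eps <- eps + t(eps) - diag(diag(eps))
      v <- v * exp(eps)
    }
    bins <- make_bins(stats::setNames(n * spec$bin_size, spec$chrom),
                      bin_size = spec$bin_size)
    list(H = contact_matrix(v, bins = bins, kind = "hic"),
         labels = spec$labels)
  })
}

#' Generate class-biased synthetic peak calls
#'
#' Per-bin peak counts are Poisson with the class rate (`rate_a` for A,
#' emulating an open-chromatin mark such as H3K4me1); peak positions are
#' uniform within the bin, width 200 nt (clipped to the bin).
#'
#' @param spec a `fixture_spec`.
#' @param labels planted labels (default the spec's).
#' @return data.frame in BED layout (`chrom`, `start`, `end`, 0-based
#'   half-open), possibly empty.
#' @export
gen_peaks <- function(spec, labels = spec$labels) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec, 303L, {
    counts <- stats::rpois(spec$n_bins, spec$rate[labels])
    rows <- which(counts > 0)
    if (!length(rows))
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    starts <- unlist(lapply(rows, function(i) {
      off <- floor(stats::runif(counts[i], 0, spec$bin_size - 200))
      (i - 1L) * spec$bin_size + off
    }))
    data.frame(chrom = spec$chrom, start = as.integer(starts),
               end = as.integer(starts + 200L))
  })
}

#' Materialize a fixture on disk
#'
#' Writes the FASTA, contact matrix (dense TSV), peak BED and planted
#' labels TSV for a spec into a directory.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created).
#' @return invisibly, a named list of the written paths.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sq <- gen_sequences(spec)
  hi <- gen_plaid_hic(spec)
  pk <- gen_peaks(spec)
  paths <- list(
    fasta = file.path(dir, "fixture.fa"),
    matrix = file.path(dir, "fixture_hic.tsv"),
    peaks = file.path(dir, "fixture_peaks.bed"),
    labels = file.path(dir, "fixture_labels.tsv"))
  Biostrings::writeXStringSet(sq$seqs, paths$fasta)
  write_matrix(hi$H, paths$matrix, format = "tsv")
  write_bed(pk, paths$peaks)
  utils::write.table(
    data.frame(bin = bin_labels(sq$bins), label = spec$labels),
    paths$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
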