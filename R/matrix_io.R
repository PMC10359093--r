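#' Read / write contact matrices
#'
#' Supported formats: `"homer"` (interaction-matrix text with a header
#' row and column of `chrom-start` bin labels), `"tsv"` (dense
#' tab-separated values with a label header row), and `"cool"` (a
#' single-resolution cooler HDF5 container, handled through a bundled
#' Python/h5py helper). Masked entries are serialized as `NA` (text
#' formats) or carried via NaN bin weights (cooler) and restored as
#' masked. Round trips preserve values to 1e-9 and labels exactly.
#'
#' @param M a `contact_matrix`.
#' @param path file path.
#' @param format one of `"homer"`, `"tsv"`, `"cool"`; default guessed
#'   from the file extension (`.cool` / `.tsv`; anything else `homer`).
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns
#'   a `contact_matrix`.
#' @export
write_matrix <- function(M, path, format = NULL) {
  stopifnot(inherits(M, "contact_matrix"))
  format <- guess_format(path, format)
  labels <- matrix_labels(M)
  switch(format,
    homer = write_homer(M$values, labels, path),
    tsv = write_dense_tsv(M$values, labels, path),
    cool = write_cool(M, labels, path),
    stop("unsupported format: ", format))
  invisible(path)
}

#' @rdname write_matrix
#' @param kind the `kind` to stamp on the matrix read back.
#' @export
read_matrix <- function(path, format = NULL, kind = "hic") {
  format <- guess_format(path, format)
  parsed <- switch(format,
    homer = read_homer(path),
    tsv = read_dense_tsv(path),
    cool = read_cool(path),
    stop("unsupported format: ", format))
  v <- parsed$values
  mask <- apply(v, 1L, function(r) all(is.na(r)))
  dimnames(v) <- rep(list(parsed$labels), 2)
  m <- contact_matrix(v, mask = mask, kind = kind)
  dimnames(m$values) <- rep(list(parsed$labels), 2)
  m
}

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("homer", "tsv", "cool")))
  ext <- tolower(tools::file_ext(path))
  if (ext == "cool") "cool" else if (ext == "tsv") "tsv" else "homer"
}

matrix_labels <- function(M) {
  if (!is.null(M$bins)) return(bin_labels(M$bins))
  if (!is.null(dimnames(M$values)[[1]])) return(dimnames(M$values)[[1]])
  paste0("bin-", seq_len(nrow(M$values)))
}

fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

write_homer <- function(v, labels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("bin", labels), collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(labels[i], fmt_num(v[i, ])), collapse = "\t"), con)
}

read_homer <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  labels <- header[-1]
  n <- length(labels)
  if (length(lines) - 1L != n)
    stop(sprintf("HOMER header declares %d bins but file has %d rows",
                 n, length(lines) - 1L))
  v <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n + 1L)
      stop(sprintf("HOMER row %d has %d fields, expected %d (line %d)",
                   i, length(fields), n + 1L, i + 1L))
    if (fields[1] != labels[i])
      stop(sprintf("HOMER row label %s does not match header label %s",
                   fields[1], labels[i]))
    v[i, ] <- suppressWarnings(as.numeric(fields[-1]))
  }
  list(values = v, labels = labels)
}

write_dense_tsv <- function(v, labels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(fmt_num(v[i, ]), collapse = "\t"), con)
}

read_dense_tsv <- function(path) {
  lines <- readLines(path)
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(labels)
  if (length(lines) - 1L != n)
    stop(sprintf("dense TSV declares %d bins but has %d data rows",
                 n, length(lines) - 1L))
  v <- do.call(rbind, lapply(lines[-1], function(l)
    suppressWarnings(as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))))
  if (ncol(v) != n) stop("dense TSV row width does not match header")
  list(values = v, labels = labels)
}

# --- cooler container via the bundled Python helper ---------------------

cooler_helper <- function() {
  p <- system.file("python", "cooler_io.py", package = "dnadda")
  if (!nzchar(p)) stop("bundled cooler helper not found")
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("python interpreter not on PATH; cooler IO needs h5py")
  list(python = py, script = p)
}

write_cool <- function(M, labels, path) {
  h <- cooler_helper()
  td <- tempfile("coolio")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  bt <- cool_bins_table(M, labels)
  bins_tsv <- file.path(td, "bins.tsv")
  utils::write.table(bt, bins_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  # all unmasked upper-triangle entries (zeros included, to round-trip)
  ok <- which(!M$mask)
  pix <- NULL
  ut <- which(upper.tri(M$values, diag = TRUE), arr.ind = TRUE)
  keep <- !M$mask[ut[, 1]] & !M$mask[ut[, 2]]
  ut <- ut[keep, , drop = FALSE]
  pix <- data.frame(bin1_id = ut[, 1] - 1L, bin2_id = ut[, 2] - 1L,
                    count = sprintf("%.17g", M$values[ut]))
  pixels_tsv <- file.path(td, "pixels.tsv")
  utils::write.table(pix, pixels_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  status <- system2(h$python, c(h$script, "write", shQuote(path),
                                shQuote(bins_tsv), shQuote(pixels_tsv)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("cooler write failed: ", paste(status, collapse = "\n"))
  invisible(path)
}

cool_bins_table <- function(M, labels) {
  if (!is.null(M$bins)) {
    data.frame(chrom = M$bins$chrom, start = M$bins$start,
               end = M$bins$end,
               weight = ifelse(M$mask, "nan", "1"))
  } else {
    parts <- regmatches(labels, regexec("^(.*)-([0-9]+)$", labels))
    okp <- all(lengths(parts) == 3L)
    chrom <- if (okp) vapply(parts, `[`, character(1), 2) else labels
    start <- if (okp) as.numeric(vapply(parts, `[`, character(1), 3))
             else seq_along(labels) - 1
    width <- if (length(start) > 1) stats::median(diff(sort(start))) else 1
    data.frame(chrom = chrom, start = start, end = start + width,
               weight = ifelse(M$mask, "nan", "1"))
  }
}

read_cool <- function(path) {
  h <- cooler_helper()
  td <- tempfile("coolio")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  bins_tsv <- file.path(td, "bins.tsv")
  pixels_tsv <- file.path(td, "pixels.tsv")
  status <- system2(h$python, c(h$script, "read", shQuote(path),
                                shQuote(bins_tsv), shQuote(pixels_tsv)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("cooler read failed: ", paste(status, collapse = "\n"))
  bt <- utils::read.table(bins_tsv, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  px <- utils::read.table(pixels_tsv, header = TRUE, sep = "\t")
  n <- nrow(bt)
  v <- matrix(NA_real_, n, n)
  mask <- !is.finite(suppressWarnings(as.numeric(bt$weight)))
  ok <- !mask
  v[ok, ok] <- 0
  if (nrow(px) > 0) {
    i <- px$bin1_id + 1L
    j <- px$bin2_id + 1L
    v[cbind(i, j)] <- px$count
    v[cbind(j, i)] <- px$count
  }
  list(values = v, labels = paste(bt$chrom, bt$start, sep = "-"))
}
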