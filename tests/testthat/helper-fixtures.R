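# shared in-code fixtures; everything is generated at test time

random_dna <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  p <- if (length(alphabet) == 4L)
    c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  else rep(1 / length(alphabet), length(alphabet))
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

random_walk_series <- function(n) cumsum(sample(c(-1, 1), n, replace = TRUE))

# brute-force minimum-norm least squares via pseudoinverse (independent
# of the package's SVD fit path)
pinv_lsq <- function(M, y, tol = 1e-12) {
  sv <- svd(M)
  keep <- sv$d > tol * sv$d[1]
  as.vector(sv$v[, keep, drop = FALSE] %*%
            diag(1 / sv$d[keep], sum(keep)) %*%
            t(sv$u[, keep, drop = FALSE]) %*% y)
}

oracle_rho <- function(M, y, a) sqrt(mean((y - M %*% a)^2))

# signed +/-1 reference track from planted labels
label_track <- function(labels) ifelse(labels == "A", 1, -1)

# brute-force AUC: count concordant (A, B) score pairs, ties half
brute_auc <- function(score, labels) {
  pos <- score[labels]
  neg <- score[!labels]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

expect_masked_na <- function(M) {
  for (i in which(M$mask)) {
    expect_true(all(is.na(M$values[i, ])))
    expect_true(all(is.na(M$values[, i])))
  }
}
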