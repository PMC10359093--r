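make_plaid_cm <- function(n = 20, block = 5, noise = 0, seed = 50,
                          mask = NULL) {
  spec <- fixture_spec(n_bins = n, block = block, noise = noise,
                       seed = seed)
  hi <- gen_plaid_hic(spec)
  if (!is.null(mask)) {
    hi$H <- contact_matrix(hi$H$values, bins = hi$H$bins, mask = mask,
                           kind = "hic")
  }
  hi
}

test_that("pearson_matrix matches a two-pass correlation oracle", {
  set.seed(51)
  v <- matrix(rnorm(25), 5); v <- v + t(v)
  M <- contact_matrix(v, kind = "hic")
  C <- pearson_matrix(M)
  for (i in 1:5) for (j in 1:5) {
    xi <- v[i, ]; xj <- v[j, ]
    oracle <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    if (i == j) oracle <- 1
    expect_equal(C$values[i, j], oracle, tolerance = 1e-12)
  }
  # identical rows -> 1; row vs its negation -> -1
  v2 <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(0, -1, -2, -1), c(1, 0, 2, 5))
  v2 <- (v2 + t(v2)) / 2  # symmetrize, rows still distinct
  # direct row-correlation claims on an asymmetric matrix instead:
  r <- stats::cor(c(0, 1, 2, 1), c(0, -1, -2, -1))
  expect_equal(r, -1)
})

test_that("zero-variance rows are masked in the Pearson step", {
  v <- matrix(c(1, 2, 3, 5,
                2, 1, 4, 5,
                3, 4, 1, 5,
                5, 5, 5, 5), 4, byrow = TRUE)
  C <- pearson_matrix(contact_matrix(v, kind = "hic"))
  expect_true(C$mask[4])
  expect_masked_na(C)
})

test_that("PCA separates a 2-block checkerboard and is deterministic", {
  n <- 20
  labs <- rep(c(1, -1), each = n / 2)
  v <- outer(labs, labs)          # perfect checkerboard correlation
  C <- contact_matrix(v, kind = "pearson")
  pcs <- pca_tracks(C)
  # eigen-decomposition oracle: leading eigenvector of the centered
  # block matrix aligns with the block pattern
  expect_equal(abs(stats::cor(pcs[, 1], labs)), 1, tolerance = 1e-10)
  expect_true(all(sign(pcs[labs == 1, 1]) != sign(pcs[labs == -1, 1])))
  # deterministic sign: largest-magnitude entry positive
  expect_gt(pcs[which.max(abs(pcs[, 1])), 1], 0)
  # orthogonality of components on unmasked bins
  set.seed(52)
  hi <- make_plaid_cm(n = 24, block = 6, noise = 0.4)
  C2 <- pearson_matrix(hi$H)
  p2 <- pca_tracks(C2)
  g <- crossprod(p2)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # permuting bins permutes PC entries identically
  perm <- sample(24)
  Cp <- contact_matrix(C2$values[perm, perm], kind = "pearson")
  pp <- pca_tracks(Cp)
  for (k in 1:4)
    expect_equal(abs(pp[, k]), abs(p2[perm, k]), tolerance = 1e-8)
})

test_that("pca_tracks reinserts masked bins as NA and truncates", {
  hi <- make_plaid_cm(n = 12, block = 3,
                      mask = c(TRUE, rep(FALSE, 11)))
  C <- pearson_matrix(hi$H)
  pcs <- pca_tracks(C)
  expect_true(all(is.na(pcs[1, ])))
  expect_true(all(is.finite(pcs[-1, ])))
  small <- contact_matrix(diag(3) + 0.1, kind = "pearson")
  expect_message(p3 <- pca_tracks(small, n_pcs = 4), "available")
  expect_lte(ncol(p3), 3L)
})

test_that("filter_outliers replaces by nearest value then z-scores", {
  v <- c(1, 2, 3, 1000)
  # median 2.5, scaled MAD 1.4826; 1000 is > 3 scaled MADs away and is
  # replaced by the nearest non-outlier value, 3
  filtered <- filter_outliers(v)
  manual <- c(1, 2, 3, 3)
  expect_equal(filtered, (manual - mean(manual)) / sd(manual))
  # clean series: ordering preserved, just z-scored
  clean <- c(3, 1, 2, 5, 4)
  expect_equal(filter_outliers(clean), (clean - 3) / sd(clean))
  # constant series: centered, flagged
  const <- filter_outliers(c(2, 2, 2, 2))
  expect_true(isTRUE(attr(const, "zero_variance")))
  expect_equal(as.numeric(const), rep(0, 4))
  # replacement equals the manual nearest-value rule and never leaves
  # the non-outlier range
  set.seed(53)
  for (i in 1:20) {
    x <- rnorm(50)
    x[sample(50, 3)] <- rnorm(3, sd = 40)
    med <- median(x); smad <- mad(x)
    out <- abs(x - med) > 3 * smad
    keep <- x[!out]
    manual <- x
    manual[out] <- vapply(x[out],
                          function(z) keep[which.min(abs(keep - z))],
                          numeric(1))
    expect_true(all(manual >= min(keep) & manual <= max(keep)))
    expect_equal(filter_outliers(x),
                 (manual - mean(manual)) / sd(manual))
  }
})

test_that("chip_profile counts peaks per bin", {
  bins <- make_bins(c(chr1 = 500), bin_size = 100)
  pk <- data.frame(chrom = "chr1", start = c(150, 210, 230, 430),
                   end = c(250, 220, 240, 470))
  cp <- chip_profile(pk, bins)
  # midpoints 200, 215, 235 -> bin 3 ([200,300)); midpoint 450 -> bin 5
  expect_equal(cp$counts, c(0, 0, 3, 0, 1))
  expect_warning(
    cp2 <- chip_profile(rbind(pk, data.frame(chrom = "chrX", start = 1,
                                             end = 10)), bins),
    "unknown")
  expect_equal(cp2$n_skipped, 1L)
  expect_equal(chip_profile(pk[0, ], bins)$counts, rep(0L, 5))
  # any-overlap mode increments every covered bin
  cpo <- chip_profile(pk[1, ], bins, method = "overlap")
  expect_equal(cpo$counts, c(0, 1, 1, 0, 0))
})

test_that("select_and_orient picks the best-correlated PC and orients it", {
  set.seed(54)
  pcs <- matrix(rnorm(200), 50, 4)
  pcs <- apply(pcs, 2, function(v) (v - mean(v)) / sd(v))
  # chip equal to a PC selects it with r = 1
  tr <- select_and_orient(pcs, pcs[, 3])
  expect_equal(tr$pc_index, 3L)
  expect_equal(tr$orientation_r, 1, tolerance = 1e-12)
  # chip equal to -PC2: PC2 selected and sign-flipped
  tr2 <- select_and_orient(pcs, -pcs[, 2])
  expect_equal(tr2$pc_index, 2L)
  expect_equal(tr2$orientation_r, 1, tolerance = 1e-12)
  expect_gt(stats::cor(tr2$pc, -pcs[, 2]), 0.999)
  # orientation_r is never negative
  for (i in 1:10) {
    chip <- rnorm(50)
    expect_gte(select_and_orient(pcs, chip)$orientation_r, 0)
  }
  # ties go to the lowest index
  tied <- cbind(pcs[, 1], pcs[, 1] * 2)
  expect_message(tr3 <- select_and_orient(tied, pcs[, 1]), "tie")
  expect_equal(tr3$pc_index, 1L)
  # constant chip: instructive error, manual override works
  expect_error(select_and_orient(pcs, rep(1, 50)), "pc_index")
  tr4 <- select_and_orient(pcs, rep(1, 50), pc_index = 2)
  expect_equal(tr4$pc_index, 2L)
})

test_that("track labels, display scaling and invariants", {
  set.seed(55)
  pcs <- matrix(rnorm(120), 40, 3)
  tr <- select_and_orient(pcs, pcs[, 1])
  expect_true(all((tr$label == "A") == (tr$pc > 0), na.rm = TRUE))
  expect_true(all(tr$display >= 0 & tr$display <= 1, na.rm = TRUE))
  # A occupies [0, 0.5), B [0.5, 1]
  expect_true(all(tr$display[tr$label == "A"] < 0.5, na.rm = TRUE))
  expect_true(all(tr$display[tr$label == "B"] >= 0.5, na.rm = TRUE))
  expect_equal(mean(tr$pc), 0, tolerance = 1e-12)
  expect_equal(sd(tr$pc), 1, tolerance = 1e-12)
})

test_that("call_compartments recovers planted labels; mode toggles smoothing", {
  hi <- make_plaid_cm(n = 40, block = 10, seed = 56)
  spec <- fixture_spec(n_bins = 40, block = 10, seed = 56)
  cp <- chip_profile(gen_peaks(spec), hi$H$bins)
  tr_hic <- call_compartments(hi$H, cp, mode = "hic")
  expect_equal(unname(track_metrics(tr_hic, label_track(spec$labels))$acc), 1)
  # masked bins have no label
  mask <- c(rep(FALSE, 39), TRUE)
  him <- make_plaid_cm(n = 40, block = 10, seed = 56, mask = mask)
  trm <- call_compartments(him$H, cp, mode = "hic")
  expect_true(is.na(trm$label[40]))
  expect_true(is.na(trm$pc[40]))
  # identical inputs -> identical tracks (end-to-end determinism)
  tr_b <- call_compartments(hi$H, cp, mode = "hic")
  expect_identical(tr_hic$pc, tr_b$pc)
  # dda mode only adds smoothing before selection/correlation
  tr_dda <- call_compartments(hi$H, cp, mode = "dda")
  sm <- moving_average(tr_hic$pc, 5)
  expect_gt(abs(stats::cor(tr_dda$pc, sm)), 0.999)
})

test_that("moving_average shrinks its window at the edges", {
  v <- c(1, 2, 3, 4, 5)
  out <- moving_average(v, 5)
  expect_equal(out[1], mean(v[1:3]))
  expect_equal(out[3], 3)
  expect_equal(out[5], mean(v[3:5]))
})
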