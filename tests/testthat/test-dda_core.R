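test_that("model enumeration is canonical and complete", {
  models <- enumerate_models()
  # 9 admissible monomials (total degree 1..3 over two delays) in
  # subsets of size 1..3: 9 + 36 + 84 models
  expect_length(models, 9 + 36 + 84)
  # the default symmetric quadratic model is present and addressable
  def <- default_model()
  expect_true(def$id %in% names(models))
  expect_equal(models[[def$id]]$terms, def$terms)
  # no duplicate monomial multisets (brute-force set comparison)
  keys <- vapply(models, function(m)
    paste(sort(vapply(m$terms, paste, character(1), collapse = ",")),
          collapse = ";"), character(1))
  expect_false(anyDuplicated(keys) > 0)
  # minimal request: exactly one model xdot = a1 x_tau1
  expect_length(enumerate_models(1, 1, 1), 1L)
  expect_equal(enumerate_models(1, 1, 1)[[1]]$terms, list(1L))
})

test_that("dda_model validates its invariants", {
  expect_error(dda_model(list(c(4L, 0L))), "degree")
  expect_error(dda_model(list(c(0L, 0L))), "degree")
  expect_error(dda_model(list(c(1L, 0L), c(1L, 0L))), "duplicate")
  expect_error(default_model(5, 5), "tau1 < tau2")
  expect_error(dda_model(list(c(1L, 1L)), delays = c(0, 3)), "positive")
})

test_that("center derivative is exact on low-degree polynomials", {
  t <- 1:20
  expect_equal(center_derivative(t), rep(1, 18))
  expect_equal(center_derivative(rep(3.5, 10)), rep(0, 8))
  expect_equal(center_derivative(t^2), 2 * t[2:19])
  expect_equal(center_derivative(t, w = 3), rep(1, 14))
  expect_error(center_derivative(c(1, 2), w = 1), "short")
})

test_that("build_design lays out monomial columns over the fit window", {
  m <- default_model(2, 5)
  x <- random_walk_series(60)
  d <- build_design(x, m, standardize = FALSE)
  expect_equal(ncol(d$M), 3L)
  expect_equal(d$n, 60 - 5 - 2)          # L - max(tau) - 2w
  t <- (5 + 2):(60 - 1)
  expect_equal(d$M[, 1], x[t - 2])
  expect_equal(d$M[, 2], x[t - 5])
  expect_equal(d$M[, 3], x[t - 2] * x[t - 5])
  expect_equal(d$xdot, (x[t + 1] - x[t - 1]) / 2)
  # constant series without standardization: columns c, c, c^2
  dc <- build_design(rep(2, 30), m, standardize = FALSE)
  expect_true(all(dc$M[, 1] == 2) && all(dc$M[, 3] == 4))
  # window errors name the delays
  expect_error(build_design(1:8, default_model(3, 9)), "empty fit window")
})

test_that("ST fit matches the pseudoinverse oracle", {
  set.seed(7)
  for (i in 1:20) {
    x <- random_walk_series(300)
    taus <- sort(sample(1:30, 2))
    m <- default_model(taus[1], taus[2])
    d <- build_design(x, m)
    f <- fit_st(x, m)
    a_or <- pinv_lsq(d$M, d$xdot)
    expect_lt(max(abs(f$a - a_or) / pmax(abs(a_or), 1e-12)), 1e-8)
    expect_equal(f$rho, oracle_rho(d$M, d$xdot, a_or), tolerance = 1e-10)
    expect_equal(f$n_points, d$n)
  }
  # constant series: zero derivative fit exactly by zero coefficients
  fc <- fit_st(rep(5, 50), default_model(2, 4), standardize = FALSE)
  expect_equal(fc$a, rep(0, 3))
  expect_equal(fc$rho, 0)
  # sign flip of the input verified against the oracle, not asserted
  x <- random_walk_series(200)
  m <- default_model(3, 8)
  dneg <- build_design(-x, m)
  fneg <- fit_st(-x, m)
  expect_equal(fneg$a, pinv_lsq(dneg$M, dneg$xdot), tolerance = 1e-9)
})

test_that("CT fit solves the row-stacked system", {
  set.seed(8)
  m <- default_model(4, 11)
  xi <- random_walk_series(250)
  xj <- random_walk_series(250)
  di <- build_design(xi, m)
  dj <- build_design(xj, m)
  Ms <- rbind(di$M, dj$M)
  ys <- c(di$xdot, dj$xdot)
  f <- fit_ct(xi, xj, m)
  a_or <- pinv_lsq(Ms, ys)
  expect_lt(max(abs(f$a - a_or) / pmax(abs(a_or), 1e-12)), 1e-8)
  expect_equal(f$rho, oracle_rho(Ms, ys, a_or), tolerance = 1e-10)
  expect_equal(f$n_points, di$n + dj$n)
  # duplicated rows preserve solution and RMS residual
  fii <- fit_ct(xi, xi, m)
  fst <- fit_st(xi, m)
  expect_equal(fii$a, fst$a, tolerance = 1e-10)
  expect_equal(fii$rho, fst$rho, tolerance = 1e-12)
})

test_that("rho is invariant to row order within the design", {
  set.seed(9)
  m <- default_model(2, 6)
  x <- random_walk_series(80)
  d <- build_design(x, m)
  for (i in 1:5) {
    perm <- sample(d$n)
    a <- pinv_lsq(d$M[perm, ], d$xdot[perm])
    expect_equal(oracle_rho(d$M[perm, ], d$xdot[perm], a),
                 fit_st(x, m)$rho, tolerance = 1e-10)
  }
})

test_that("ergodicity arithmetic, identity and symmetry", {
  expect_equal(ergodicity(1, 1, 1), 0)
  expect_equal(ergodicity(2, 4, 3), 0)
  expect_equal(ergodicity(1, 3, 4), 0.5)
  expect_equal(ergodicity(3, 1, 4), ergodicity(1, 3, 4))
  expect_true(is.na(ergodicity(1, 1, 0)))
  expect_equal(ergodicity(0, 0, 0), 0)
  set.seed(10)
  m <- default_model(3, 7)
  for (i in 1:10) {
    x <- random_walk_series(150)
    f <- fit_st(x, m)
    fc <- fit_ct(x, x, m)
    expect_equal(ergodicity(f$rho, f$rho, fc$rho), 0, tolerance = 1e-12)
  }
})

test_that("bins from same vs different composition processes separate", {
  spec <- fixture_spec(n_bins = 12, bin_size = 3000, block = 6, seed = 21)
  sq <- gen_sequences(spec)
  bw <- bin_walks(sq$seqs, sq$bins)
  m <- default_model(5, 12)
  E <- build_dda_matrix(bw, m)$values
  same <- outer(sq$labels, sq$labels, "==")
  diag(same) <- NA
  expect_lt(mean(E[same & !is.na(same)]),
            mean(E[!same & !is.na(same)]))
})
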