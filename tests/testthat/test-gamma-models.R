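test_that("gg_set_marginal matches its conjugate closed form", {
  p1 <- gamma_params(1, 1, 1)
  expect_equal(exp(gg_set_marginal(0, p1)), 1)        # 1/(1+y)^2 at 0
  expect_equal(exp(gg_set_marginal(1, p1)), 0.25)
  expect_equal(exp(gg_set_marginal(c(1, 1), p1)), 2 / 27)
  expect_error(gg_set_marginal(-1, p1), "negative")
  expect_error(gg_set_marginal(0, gamma_params(0.5, 1, 1)), "zero")
})

test_that("gg_set_marginal agrees with numerical rate integration", {
  set.seed(7)
  for (i in 1:15) {
    K <- sample(1:4, 1)
    y <- runif(K, 0.2, 8)
    pr <- gamma_params(runif(1, 0.5, 12), runif(1, 0.5, 6), runif(1, 0.5, 10))
    lf <- function(t) sum(stats::dgamma(y, pr$a, rate = t, log = TRUE)) +
      stats::dgamma(t, pr$a0, rate = pr$nu, log = TRUE)
    mid <- (K * pr$a + pr$a0) / (sum(y) + pr$nu)   # rate posterior mean
    lm <- lf(mid)                                  # scale factor only
    f <- function(th) vapply(th, function(t) exp(lf(t) - lm), numeric(1))
    oracle <- lm + log(stats::integrate(f, 0, mid, rel.tol = 1e-12)$value +
                         stats::integrate(f, mid, Inf, rel.tol = 1e-12)$value)
    expect_equal(gg_set_marginal(y, pr), oracle, tolerance = 1e-8)
  }
})

test_that("gg marginals integrate to one and survive extreme scales", {
  pr <- gamma_params(2, 1.5, 3)
  mass <- stats::integrate(function(y)
    vapply(y, function(yy) exp(gg_set_marginal(yy, pr)), numeric(1)),
    0, 1e6, rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-4)
  # no overflow in log space: y up to 1e6, K up to 10
  expect_true(is.finite(gg_set_marginal(rep(1e6, 10), gamma_params(20, 0.6, 20))))
})

test_that("gg_h0_h1 pools under H0 and factorizes under HA", {
  p1 <- gamma_params(1, 1, 1)
  r <- gg_h0_h1(2, 2, p1)
  expect_equal(exp(r[["log_p0"]]), 2 / 125)
  expect_equal(exp(r[["log_pA"]]), (1 / 9)^2)
  sep <- gg_h0_h1(100, 0.01, p1)
  expect_gt(sep[["log_pA"]], sep[["log_p0"]])
})

test_that("tn_gamma_channel_marginal obeys support and limits", {
  expect_identical(tn_gamma_channel_marginal(c(2, -1), c(0, 0), 1, 0.5, 3),
                   -Inf)
  # tau2 -> 0 with a single observation collapses to the gamma density
  y <- 150
  got <- tn_gamma_channel_marginal(y, 0, 1e-8, 0.1, 20)
  expect_equal(got, stats::dgamma(y, 20, rate = 0.1, log = TRUE),
               tolerance = 1e-4)
})

test_that("tn_gamma_channel_marginal matches a dense-grid oracle", {
  # trapezoid oracle accumulated in log space (the integrand underflows
  # doubles when the replicate set is wider than the replicate SD)
  log_trapz_oracle <- function(y, v, tau2, a, th) {
    eta <- seq(1e-6, 500, length.out = 1e5)
    lf <- stats::dgamma(eta, a, rate = th, log = TRUE)
    for (k in seq_along(y)) {
      sk <- sqrt(v[k] + tau2)
      lf <- lf + stats::dnorm(y[k], eta, sk, log = TRUE) -
        stats::pnorm(eta / sk, log.p = TRUE)
    }
    m <- max(lf)
    m + log(sum(exp(lf - m)) * (eta[2] - eta[1]))
  }
  y <- c(180, 210, 195); a <- 20; th <- 0.1; tau2 <- 0.25
  got <- tn_gamma_channel_marginal(y, rep(0, 3), tau2, th, a)
  oracle <- log_trapz_oracle(y, rep(0, 3), tau2, a, th)
  expect_equal(got, oracle, tolerance = 1e-6)
  # known pixel-level variances enter additively
  v <- c(4, 9, 1)
  expect_equal(tn_gamma_channel_marginal(y, v, tau2, th, a),
               log_trapz_oracle(y, v, tau2, a, th), tolerance = 1e-6)
})

test_that("bngg_h0_h1 is finite, direction-sensitive and oracle-consistent", {
  pr <- gamma_params(20, 3, 20)
  same <- bngg_h0_h1(c(150, 170), c(150, 170), c(0, 0), c(0, 0), 100, pr)
  expect_true(all(is.finite(same)))
  expect_lt(abs(same[["log_pA"]] - same[["log_p0"]]), log(1e6))

  apart <- bngg_h0_h1(c(5, 6), c(500, 480), c(0, 0), c(0, 0), 1, pr)
  expect_gt(apart[["log_pA"]], apart[["log_p0"]])

  got <- bngg_h0_h1(c(150, 170), c(160, 140), c(0, 0), c(0, 0), 100, pr)
  oracle <- bngg_grid_oracle(c(150, 170), c(160, 140), c(0, 0), c(0, 0),
                             100, 20, 3, 20)
  expect_equal(got[["log_p0"]], oracle[["log_p0"]], tolerance = 1e-5)
  expect_equal(got[["log_pA"]], oracle[["log_pA"]], tolerance = 1e-5)
})

test_that("marginals are permutation invariant in the replicate sets", {
  pr <- gamma_params(8, 2, 5)
  y <- c(30, 45, 38, 51)
  expect_identical(gg_set_marginal(y, pr), gg_set_marginal(rev(y), pr))
  a <- bngg_h0_h1(c(30, 45), c(40, 35), c(1, 2), c(2, 1), 4, pr)
  b <- bngg_h0_h1(c(45, 30), c(35, 40), c(2, 1), c(1, 2), 4, pr)
  expect_identical(a, b)
})

test_that("the fixed-node fit path agrees with the adaptive scalar path", {
  set.seed(11)
  n <- 10
  Yr <- matrix(exp(rnorm(n * 2, 5, 0.7)), n, 2)
  Yg <- matrix(exp(rnorm(n * 2, 5, 0.7)), n, 2)
  tau2 <- runif(n, 50, 500)
  pr <- gamma_params(20, 0.6, 20)
  ds <- meth_dataset(Yr, Yg, scale = "linear")
  fast <- dmhmix:::compute_marginals(ds, "BNGG", pr, tau2, quadrature_spec())
  for (i in seq_len(n)) {
    slow <- bngg_h0_h1(Yr[i, ], Yg[i, ], c(0, 0), c(0, 0), tau2[i], pr,
                       quadrature_spec(32, accuracy = 1e-8))
    expect_equal(fast$log_p0[i], slow[["log_p0"]], tolerance = 1e-4)
    expect_equal(fast$log_pA[i], slow[["log_pA"]], tolerance = 1e-4)
  }
})
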