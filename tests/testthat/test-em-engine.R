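test_that("e_step computes the posterior stably", {
  expect_equal(e_step(log(0.3), log(0.3), 0.5), 0.5)
  expect_equal(e_step(log(0.1), log(0.2), 0.2), 1 / 3)   # pA = 2 p0
  expect_lt(e_step(log(0.3), log(0.3), 1e-12), 1e-11)    # p -> 0 limit
  expect_equal(e_step(-Inf, -Inf, 0.3), 0.3)             # double underflow
  expect_equal(e_step(-Inf, log(0.2), 0.3), 1)
  expect_equal(e_step(log(0.2), -Inf, 0.3), 0)
  # extreme log magnitudes do not overflow
  expect_equal(e_step(-5000, -4990, 0.5), 1 / (1 + exp(-10)))
})

test_that("m_step_p applies the regularized update", {
  Z <- rep(10 / 96, 96)
  expect_equal(m_step_p(Z), 0.12)
  expect_equal(m_step_p(rep(1, 4)), 0.75)
  expect_gt(m_step_p(rep(0, 50)), 0)
  expect_equal(m_step_p(rep(0, 50)), 2 / 54)
  expect_equal(m_step_p(numeric(0)), 0.5)
})

test_that("total_log_likelihood collapses, adds and matches brute force", {
  d <- log(0.37)
  expect_equal(total_log_likelihood(d, d, 0.2), d)
  expect_equal(total_log_likelihood(d, d, 0.9), d)
  set.seed(5)
  l0 <- rnorm(40, -20, 5); lA <- rnorm(40, -20, 5); p <- 0.17
  expect_equal(total_log_likelihood(l0, lA, p),
               total_log_likelihood(l0[1:15], lA[1:15], p) +
                 total_log_likelihood(l0[16:40], lA[16:40], p))
  brute <- sum(log(p * exp(lA) + (1 - p) * exp(l0)))
  expect_equal(total_log_likelihood(l0, lA, p), brute, tolerance = 1e-12)
})

test_that("the global M-step never descends and recovers a known mean", {
  sim <- simulate_blnnn(n_probes = 400, seed = 31)
  ds <- sim$dataset
  tau2 <- rep(0.09, 400)
  Z <- rep(0.3, 400)
  pr0 <- ln_params(6.5, 3)
  enter <- {
    m <- dmhmix:::compute_marginals(ds, "BLNNN", pr0, tau2, NULL)
    sum(Z * m$log_pA + (1 - Z) * m$log_p0)
  }
  res <- m_step_global(ds, "BLNNN", Z, pr0, tau2)
  expect_gte(res$objective, enter)

  # parameter recovery at n = 5000
  sim2 <- simulate_blnnn(n_probes = 5000, seed = 32)
  fit <- fit_model(sim2$dataset, model_spec("BLNN"))
  expect_lt(abs(fit$params$mu - 7.8), 0.1)
})

test_that("the tau hill-climb matches a dense 1-D grid and hits the floor", {
  pr <- ln_params(7.8, 1.8)
  yr <- c(8.6, 8.2); yg <- c(7.1, 7.4); z <- 0.9
  ds <- meth_dataset(matrix(yr, 1), matrix(yg, 1), scale = "log")
  obj1 <- function(t2) {
    r <- ln_h0_h1(yr, yg, rep(t2, 2), rep(t2, 2), pr)
    z * r[["log_pA"]] + (1 - z) * r[["log_p0"]]
  }
  grid <- exp(seq(log(1e-6), log(1e4), length.out = 4000))
  best <- max(vapply(grid, obj1, numeric(1)))
  got <- m_step_tau_hillclimb(ds, "BLNN", z, pr, 0.09)
  expect_gte(obj1(got), obj1(0.09))             # ascent
  expect_equal(obj1(got), best, tolerance = 0.02 * abs(best))

  # degenerate zero-variance data (identical replicates, all posterior
  # weight on the channel-specific branch) drives tau2 to the lower bound
  ds0 <- meth_dataset(matrix(c(8, 8), 1), matrix(c(7, 7), 1), scale = "log")
  got0 <- m_step_tau_hillclimb(ds0, "BLNN", 1, pr, 1e-4)
  expect_equal(got0, 1e-6)
})

test_that("fit_model recovers the mixing weight on its own data", {
  sim <- simulate_blnnn(n_probes = 2000, seed = 33)
  fit <- fit_model(sim$dataset, model_spec("BLNNN"))
  expect_true(fit$converged)
  expect_lt(abs(fit$p - 0.10), 0.03)
  expect_true(all(fit$Z >= 0 & fit$Z <= 1))
  expect_true(fit$p > 0 && fit$p < 1)
})

test_that("fits are deterministic and the trace is monotone", {
  sim <- simulate_blnnn(n_probes = 300, seed = 34)
  f1 <- fit_model(sim$dataset, model_spec("BLNNN"))
  f2 <- fit_model(sim$dataset, model_spec("BLNNN"))
  expect_identical(f1$Z, f2$Z)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  expect_identical(unclass(f1$params), unclass(f2$params))
  slack <- 1e-6 * abs(f1$loglik_trace[-1])
  expect_true(all(diff(f1$loglik_trace) >= -slack))
})

test_that("default initial values follow the published settings", {
  sg <- model_spec("BGG")
  expect_equal(c(sg$init$a, sg$init$a0, sg$init$nu, sg$init_p),
               c(20, 0.6, 20, 0.2))
  sl <- model_spec("BLNN")
  expect_equal(c(sl$init$mu, sl$init$phi2, sl$init_p), c(7.8, 1.8, 0.5))
  expect_equal(sl$tol, 1e-4)
})

test_that("scale mismatches and impossible probes are caught", {
  sim <- simulate_blnnn(n_probes = 60, seed = 35)
  expect_error(fit_model(sim$dataset, model_spec("BGG")), "linear")
  lin <- linearize_dataset(sim$dataset)
  expect_error(fit_model(lin, model_spec("BLNNN")), "log")
  # zero signal under BGG (a = 20) has zero density under both hypotheses
  lin0 <- lin
  lin0$treated[3, 1] <- 0
  expect_error(fit_model(lin0, model_spec("BGG")), "probe_3")
})

test_that("write_fit emits readable JSON and TSV", {
  sim <- simulate_blnnn(n_probes = 50, seed = 36)
  fit <- fit_model(sim$dataset, model_spec("BLNNN", max_iter = 20))
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_fit(fit, jp, tp)
  j <- jsonlite::read_json(jp)
  expect_equal(j$model, "BLNNN")
  tab <- utils::read.delim(tp)
  expect_equal(nrow(tab), 50)
  expect_true(all(c("probe_id", "Z", "tau2") %in% names(tab)))
})
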