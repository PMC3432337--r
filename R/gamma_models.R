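#' Gamma hierarchy hyperparameters
#'
#' Shape--rate parameterization throughout: replicate signals (BGG) or
#' latent channel means (BNGG/BNNGG) follow Gamma(shape \code{a}, rate
#' \eqn{\theta_i}), and the probe-level rate follows
#' \eqn{\theta_i \sim} Gamma(shape \code{a0}, rate \code{nu}).
#'
#' @param a observation/channel-mean shape (> 0).
#' @param a0 prior shape (> 0).
#' @param nu prior rate (> 0).
#' @return an object of class \code{gamma_params}.
#' @export
gamma_params <- function(a, a0, nu) {
  vals <- c(a = a, a0 = a0, nu = nu)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("gamma_params: a, a0 and nu must be strictly positive and finite")
  structure(list(a = a, a0 = a0, nu = nu), class = "gamma_params")
}

#' Quadrature settings for the truncated-normal/gamma marginals
#'
#' @param nodes Gauss--Legendre nodes per axis (>= 16).
#' @param accuracy relative accuracy target for the adaptive scalar
#'   marginals, in (0, 1e-2].
#' @param max_doublings maximum node-doubling rounds before the adaptive
#'   marginals give up.
#' @return an object of class \code{quadrature_spec}.
#' @export
quadrature_spec <- function(nodes = 64L, accuracy = 1e-6,
                            max_doublings = 6L) {
  if (nodes < 16) stop("quadrature_spec: need >= 16 nodes per axis")
  if (accuracy <= 0 || accuracy > 1e-2)
    stop("quadrature_spec: accuracy target must be in (0, 1e-2]")
  structure(list(nodes = as.integer(nodes), accuracy = accuracy,
                 max_doublings = as.integer(max_doublings)),
            class = "quadrature_spec")
}

# --- numerics helpers ------------------------------------------------------

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

row_logsumexp <- function(M) {
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  ok <- is.finite(m)
  out <- m
  if (any(ok)) {
    out[ok] <- m[ok] + log(rowSums(exp(M[ok, , drop = FALSE] - m[ok])))
  }
  out
}

.gl_cache <- new.env(parent = emptyenv())

gl_unit <- function(n) {
  key <- as.character(n)
  got <- .gl_cache[[key]]
  if (is.null(got)) {
    got <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- got
  }
  got
}

# --- BGG closed form -------------------------------------------------------

gg_log_marginal_terms <- function(sum_log_y, sum_y, K, params) {
  a <- params$a; a0 <- params$a0; nu <- params$nu
  (a - 1) * sum_log_y + a0 * log(nu) + lgamma(K * a + a0) -
    K * lgamma(a) - lgamma(a0) - (K * a + a0) * log(sum_y + nu)
}

check_gg_domain <- function(y, a) {
  if (any(y < 0)) stop("gg_set_marginal: negative observations are outside the gamma support")
  if (any(y == 0) && a < 1)
    stop("gg_set_marginal: zero observations need shape a >= 1")
}

#' Conjugate gamma-gamma set marginal (BGG)
#'
#' Log marginal density of a set of replicate signals sharing one latent
#' rate: \eqn{\int \prod_k \Gamma(y_k; a, \theta)\,\Gamma(\theta; a_0, \nu)
#' \, d\theta}, in shape--rate parameterization, evaluated in closed form
#' entirely in log space.
#'
#' @param y numeric vector of nonnegative signals (zero allowed only when
#'   \code{a >= 1}).
#' @param params a \code{\link{gamma_params}} object.
#' @return log marginal density (scalar).
#' @examples
#' gg_set_marginal(1, gamma_params(1, 1, 1))    # log(1/4)
#' @export
gg_set_marginal <- function(y, params) {
  stopifnot(inherits(params, "gamma_params"), length(y) >= 1)
  check_gg_domain(y, params$a)
  slog <- if (params$a == 1) 0 else sum(log(y))
  gg_log_marginal_terms(slog, sum(y), length(y), params)
}

#' BGG null and alternative marginals for one probe
#'
#' Under H0 both channels share one latent rate (the pooled set marginal);
#' under HA each channel has its own rate drawn from the same prior, so the
#' log marginals add.
#'
#' @param y_treated,y_control numeric vectors of replicate signals.
#' @param params a \code{\link{gamma_params}}.
#' @return named numeric vector \code{c(log_p0, log_pA)}.
#' @export
gg_h0_h1 <- function(y_treated, y_control, params) {
  if (length(y_treated) == 0 || length(y_control) == 0)
    stop("gg_h0_h1: both channels must be nonempty")
  c(log_p0 = gg_set_marginal(c(y_treated, y_control), params),
    log_pA = gg_set_marginal(y_treated, params) +
      gg_set_marginal(y_control, params))
}

# Row-wise BGG marginal for an n x K matrix of positive signals.
gg_marginal_rows <- function(Y, params) {
  check_gg_domain(Y, params$a)
  slog <- if (params$a == 1) rep(0, nrow(Y)) else rowSums(log(Y))
  gg_log_marginal_terms(slog, rowSums(Y), ncol(Y), params)
}

# --- truncated-normal/gamma quadrature core --------------------------------

# Per-probe eta-integration window: the truncated-normal replicate factors
# confine the integrand to the data window (they decay like a Gaussian, the
# gamma prior only polynomially/exponentially), so the window follows the
# data regardless of theta.
row_max <- function(M) M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]

eta_window <- function(Y, S) {
  smax <- row_max(S)
  lo <- pmax(-row_max(-Y) - 12 * smax, 1e-12)
  hi <- row_max(Y) + 12 * smax
  hi <- pmax(hi, lo * (1 + 1e-8) + 1e-8)
  list(lo = lo, hi = hi)
}

# log f_i(eta_e) = sum_k log TN(y_ik; eta_e, s_ik) on per-probe eta grids.
# Returns list(eta = n x E matrix, logw = n x E, f = n x E).
tn_loglik_grid <- function(Y, S, n_nodes) {
  win <- eta_window(Y, S)
  gl <- gl_unit(n_nodes)
  half <- (win$hi - win$lo) / 2
  eta <- outer(half, gl$x) + (win$lo + win$hi) / 2     # n x E
  logw <- log(outer(half, gl$w))
  f <- matrix(0, nrow(Y), n_nodes)
  for (k in seq_len(ncol(Y))) {
    f <- f + stats::dnorm(Y[, k], mean = eta, sd = S[, k], log = TRUE) -
      stats::pnorm(eta / S[, k], log.p = TRUE)
  }
  f[rowSums(Y < 0) > 0, ] <- -Inf   # outside the truncated support
  list(eta = eta, logw = logw, f = f)
}

# Inner channel marginals I_i(theta_t) on an n x T grid of rates:
# log I_i(t) = log sum_e w_e TN-lik_i(eta_e) Gamma(eta_e; a, theta_t).
# The gamma kernel is expanded by hand and its theta-dependent norming
# constant pulled outside the log-sum-exp.
tn_gamma_inner <- function(grid, a, theta) {
  n <- nrow(grid$eta); Tn <- ncol(theta)
  out <- matrix(NA_real_, n, Tn)
  base <- grid$f + grid$logw + (a - 1) * log(grid$eta)
  lconst <- a * log(theta) - lgamma(a)       # n x T
  for (t in seq_len(Tn)) {
    out[, t] <- row_logsumexp(base - theta[, t] * grid$eta) + lconst[, t]
  }
  out
}

# Outer log-rate grid per probe. The theta posterior behaves like
# Gamma(a0 + m*a, nu + sum of channel means), m = number of latent channel
# means integrated; window is that surrogate widened by a factor 8 each way,
# merged across the H0/HA integrals so one grid serves all three.
theta_grid <- function(params, ybar_r, ybar_g, n_nodes) {
  a <- params$a; a0 <- params$a0; nu <- params$nu
  q <- function(shape, rate) {
    cbind(stats::qgamma(1e-10, shape, rate = rate) / 8,
          stats::qgamma(1 - 1e-10, shape, rate = rate) * 8)
  }
  w0 <- q(a0 + 2 * a, nu + ybar_r + ybar_g)
  wr <- q(a0 + a, nu + ybar_r)
  wg <- q(a0 + a, nu + ybar_g)
  lo <- pmax(pmin(w0[, 1], wr[, 1], wg[, 1]), 1e-300)
  hi <- pmax(w0[, 2], wr[, 2], wg[, 2])
  gl <- gl_unit(n_nodes)
  llo <- log(lo); lhi <- log(hi)
  half <- (lhi - llo) / 2
  ltheta <- outer(half, gl$x) + (llo + lhi) / 2
  theta <- exp(ltheta)
  logw <- log(outer(half, gl$w)) + ltheta   # Jacobian of the log transform
  list(theta = theta, logw = logw)
}

# Vectorized BNGG/BNNGG marginals for a whole dataset.
# Yr, Yg: n x K signal matrices; Vr, Vg: known per-replicate variances
# (zeros for BNGG); tau2: per-probe variance vector.
tn_gamma_marginals_rows <- function(Yr, Yg, Vr, Vg, tau2, params,
                                    n_eta, n_theta) {
  Sr <- sqrt(Vr + tau2)
  Sg <- sqrt(Vg + tau2)
  gr <- tn_loglik_grid(Yr, Sr, n_eta)
  gg <- tn_loglik_grid(Yg, Sg, n_eta)
  tg <- theta_grid(params, rowMeans(pmax(Yr, 0)), rowMeans(pmax(Yg, 0)),
                   n_theta)
  Ir <- tn_gamma_inner(gr, params$a, tg$theta)
  Ig <- tn_gamma_inner(gg, params$a, tg$theta)
  lprior <- stats::dgamma(tg$theta, shape = params$a0, rate = params$nu,
                          log = TRUE) + tg$logw
  log_p0 <- row_logsumexp(Ir + Ig + lprior)
  log_pA <- row_logsumexp(Ir + lprior) + row_logsumexp(Ig + lprior)
  list(log_p0 = log_p0, log_pA = log_pA)
}

quadrature_error <- function(message, estimate) {
  stop(structure(class = c("dmhmix_quadrature_error", "error", "condition"),
                 list(message = message, call = sys.call(-1),
                      estimate = estimate)))
}

#' Truncated-normal/gamma channel marginal (BNGG, BNNGG)
#'
#' Log density of one channel's replicate set given the probe rate
#' \eqn{\theta}: \eqn{\int_0^\infty \prod_k TN(y_k; \eta, v_k + \tau^2)
#' \,\Gamma(\eta; a, \theta)\, d\eta}, with TN the normal truncated to
#' \eqn{[0, \infty)}. Evaluated by Gauss--Legendre quadrature with node
#' doubling until the requested relative accuracy is met.
#'
#' @param y numeric vector of replicate signals (any real; negative values
#'   give density zero).
#' @param known_var per-replicate known variances (all zero for BNGG).
#' @param tau2 between-replicate variance (>= 0).
#' @param theta latent gamma rate (> 0).
#' @param a gamma shape (> 0).
#' @param quad a \code{\link{quadrature_spec}}.
#' @return log density (scalar; \code{-Inf} if any \code{y < 0}).
#' @export
tn_gamma_channel_marginal <- function(y, known_var, tau2, theta, a,
                                      quad = quadrature_spec()) {
  stopifnot(length(known_var) == length(y), tau2 >= 0, theta > 0, a > 0)
  if (any(known_var < 0)) stop("known_var entries must be >= 0")
  if (any(known_var + tau2 <= 0))
    stop("each replicate needs positive total variance (known_var + tau2)")
  if (any(y < 0)) return(-Inf)
  Y <- matrix(y, 1); V <- matrix(known_var, 1)
  one <- function(n) {
    grid <- tn_loglik_grid(Y, sqrt(V + tau2), n)
    tn_gamma_inner(grid, a, matrix(theta, 1, 1))[1, 1]
  }
  n <- quad$nodes
  prev <- one(n)
  for (d in seq_len(quad$max_doublings)) {
    n <- n * 2L
    cur <- one(n)
    if (!is.finite(cur) && !is.finite(prev)) return(cur)
    if (abs(expm1(cur - prev)) <= quad$accuracy) return(cur)
    prev <- cur
  }
  quadrature_error(
    sprintf("eta quadrature did not reach relative accuracy %g", quad$accuracy),
    prev)
}

#' BNGG/BNNGG null and alternative marginals for one probe
#'
#' H0 integrates the product of the two channel marginals over a shared
#' rate \eqn{\theta \sim \Gamma(a_0, \nu)}; HA integrates each channel over
#' its own rate. BNGG passes zero known variances, BNNGG the per-replicate
#' \eqn{\sigma^2}.
#'
#' @param y_treated,y_control replicate signal vectors.
#' @param known_var_treated,known_var_control per-replicate known
#'   variances (zeros for BNGG).
#' @param tau2 between-replicate variance.
#' @param params a \code{\link{gamma_params}}.
#' @param quad a \code{\link{quadrature_spec}}.
#' @return named numeric vector \code{c(log_p0, log_pA)}.
#' @export
bngg_h0_h1 <- function(y_treated, y_control, known_var_treated,
                       known_var_control, tau2, params,
                       quad = quadrature_spec()) {
  stopifnot(inherits(params, "gamma_params"))
  if (length(y_treated) == 0 || length(y_control) == 0)
    stop("bngg_h0_h1: both channels must be nonempty")
  one <- function(n_eta, n_theta) {
    res <- tn_gamma_marginals_rows(
      matrix(y_treated, 1), matrix(y_control, 1),
      matrix(known_var_treated, 1), matrix(known_var_control, 1),
      tau2, params, n_eta, n_theta)
    c(log_p0 = res$log_p0, log_pA = res$log_pA)
  }
  ne <- quad$nodes; nt <- quad$nodes
  prev <- one(ne, nt)
  for (d in seq_len(quad$max_doublings)) {
    ne <- ne * 2L; nt <- nt * 2L
    cur <- one(ne, nt)
    if (all(!is.finite(cur) & !is.finite(prev))) return(cur)
    if (max(abs(expm1(cur - prev))) <= quad$accuracy) return(cur)
    prev <- cur
  }
  quadrature_error(
    sprintf("theta/eta quadrature did not reach relative accuracy %g",
            quad$accuracy), prev)
}
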