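with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Normal truncated to [0, Inf) by rejection; mean/sd are full-length vectors.
rtnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Simulate log-scale data under the BLNNN generative model
#'
#' Draws per-probe differential indicators \eqn{z_i \sim} Bernoulli(p);
#' null probes share one latent log mean \eqn{\eta_i \sim N(\mu,
#' \varphi^2)} while differential probes draw independent channel means
#' from the same prior; every replicate adds between-replicate noise
#' \eqn{N(0, \tau^2)} and pixel-level noise \eqn{N(0, \sigma'^2)}, and the
#' pixel-level SE \eqn{\sigma'} is recorded as known.
#'
#' @param mu,phi2 latent prior mean and variance (log units).
#' @param tau2 between-replicate variance (default \eqn{0.3^2}).
#' @param sigma_rel pixel-level SE \eqn{\sigma'} (default 0.1), constant
#'   across replicates unless \code{sigma_rel_range} is given.
#' @param p differential fraction in [0, 1].
#' @param n_probes number of probes.
#' @param reps_per_channel technical replicates per channel.
#' @param seed integer seed (deterministic output).
#' @param sigma_rel_range optional length-2 range; per-replicate
#'   \eqn{\sigma'} drawn log-uniformly from it to emulate heterogeneous
#'   pixel noise.
#' @return list with \code{dataset} (log-scale \code{meth_dataset} with
#'   known SEs) and \code{truth} (data frame: \code{probe_id},
#'   \code{differential}, \code{eta_r}, \code{eta_g}, \code{tau2}).
#' @export
simulate_blnnn <- function(mu = 7.8, phi2 = 1.8, tau2 = 0.09,
                           sigma_rel = 0.1, p = 0.1, n_probes = 10000,
                           reps_per_channel = 3, seed = 1,
                           sigma_rel_range = NULL) {
  if (phi2 <= 0 || tau2 < 0 || sigma_rel < 0 || p < 0 || p > 1 ||
      reps_per_channel < 1 || n_probes < 1)
    stop("simulate_blnnn: invalid parameter ranges")
  with_seed(seed, {
    n <- n_probes; K <- reps_per_channel
    z <- stats::runif(n) < p
    eta_r <- stats::rnorm(n, mu, sqrt(phi2))
    eta_g <- ifelse(z, stats::rnorm(n, mu, sqrt(phi2)), eta_r)
    draw_se <- function() {
      if (is.null(sigma_rel_range)) {
        matrix(sigma_rel, n, K)
      } else {
        matrix(exp(stats::runif(n * K, log(sigma_rel_range[1]),
                                log(sigma_rel_range[2]))), n, K)
      }
    }
    se_r <- draw_se(); se_g <- draw_se()
    noise <- function(se) {
      matrix(stats::rnorm(n * K, 0, sqrt(tau2)), n, K) +
        matrix(stats::rnorm(n * K), n, K) * se
    }
    Yr <- eta_r + noise(se_r)
    Yg <- eta_g + noise(se_g)
    ids <- paste0("probe_", seq_len(n))
    list(
      dataset = meth_dataset(Yr, Yg, se_r, se_g, scale = "log",
                             probe_ids = ids,
                             generation_label = "simulated"),
      truth = data.frame(probe_id = ids, differential = z,
                         eta_r = eta_r, eta_g = eta_g, tau2 = tau2,
                         stringsAsFactors = FALSE))
  })
}

#' Simulate linear-scale data under a gamma hierarchy
#'
#' BGG draws replicate signals directly from Gamma(shape a, rate
#' \eqn{\theta}); BNGG and BNNGG draw latent channel means
#' \eqn{\eta \sim} Gamma(a, \eqn{\theta}) and add truncated-normal
#' replicate noise on \eqn{[0, \infty)} (rejection sampling). Probe rates
#' \eqn{\theta} are shared across channels for null probes and drawn
#' independently for differential ones. For BNNGG the known per-replicate
#' SD is \code{sigma_rel} times the channel latent mean.
#'
#' @param model \code{"BGG"}, \code{"BNGG"} or \code{"BNNGG"}.
#' @param params a \code{\link{gamma_params}}.
#' @param tau2 between-replicate variance (ignored for BGG).
#' @param sigma_rel relative pixel-level SE (BNNGG only).
#' @param p differential fraction.
#' @param n_probes,reps dimensions.
#' @param seed integer seed.
#' @return list with \code{dataset} (linear-scale \code{meth_dataset})
#'   and \code{truth}.
#' @export
simulate_gamma_family <- function(model = c("BGG", "BNGG", "BNNGG"),
                                  params = gamma_params(20, 3, 20),
                                  tau2 = 1, sigma_rel = 0, p = 0.1,
                                  n_probes = 1000, reps = 3, seed = 1) {
  model <- match.arg(model)
  stopifnot(inherits(params, "gamma_params"))
  if (tau2 < 0 || sigma_rel < 0 || p < 0 || p > 1) stop("invalid parameter ranges")
  with_seed(seed, {
    n <- n_probes; K <- reps
    a <- params$a; a0 <- params$a0; nu <- params$nu
    z <- stats::runif(n) < p
    th_r <- stats::rgamma(n, shape = a0, rate = nu)
    th_g <- ifelse(z, stats::rgamma(n, shape = a0, rate = nu), th_r)
    ids <- paste0("probe_", seq_len(n))
    if (model == "BGG") {
      Yr <- matrix(stats::rgamma(n * K, shape = a, rate = th_r), n, K)
      Yg <- matrix(stats::rgamma(n * K, shape = a, rate = th_g), n, K)
      truth <- data.frame(probe_id = ids, differential = z,
                          theta_r = th_r, theta_g = th_g,
                          stringsAsFactors = FALSE)
      return(list(dataset = meth_dataset(Yr, Yg, scale = "linear",
                                         probe_ids = ids,
                                         generation_label = "simulated"),
                  truth = truth))
    }
    eta_r <- stats::rgamma(n, shape = a, rate = th_r)
    eta_g <- stats::rgamma(n, shape = a, rate = th_g)
    se_r <- se_g <- NULL
    v_r <- v_g <- matrix(0, n, K)
    if (model == "BNNGG") {
      se_r <- matrix(sigma_rel * eta_r, n, K)
      se_g <- matrix(sigma_rel * eta_g, n, K)
      v_r <- se_r^2; v_g <- se_g^2
    }
    Yr <- matrix(rtnorm_pos(n * K, rep(eta_r, K), sqrt(tau2 + as.vector(v_r))),
                 n, K)
    Yg <- matrix(rtnorm_pos(n * K, rep(eta_g, K), sqrt(tau2 + as.vector(v_g))),
                 n, K)
    truth <- data.frame(probe_id = ids, differential = z,
                        theta_r = th_r, theta_g = th_g,
                        eta_r = eta_r, eta_g = eta_g, tau2 = tau2,
                        stringsAsFactors = FALSE)
    list(dataset = meth_dataset(Yr, Yg, se_r, se_g, scale = "linear",
                                probe_ids = ids,
                                generation_label = "simulated"),
         truth = truth)
  })
}

#' True/false positive rates of posterior calls against truth
#'
#' @param Z posterior probabilities.
#' @param truth logical vector of true differential status.
#' @param threshold posterior calling threshold in (0, 1).
#' @return named numeric vector \code{c(TPR, FPR)} (\code{NA} when a
#'   denominator is empty).
#' @export
confusion_rates <- function(Z, truth, threshold = 0.8) {
  if (length(Z) != length(truth))
    stop("confusion_rates: Z and truth must have the same length")
  stopifnot(threshold > 0, threshold < 1)
  call <- Z >= threshold
  tpr <- if (any(truth)) sum(call & truth) / sum(truth) else NA_real_
  fpr <- if (any(!truth)) sum(call & !truth) / sum(!truth) else NA_real_
  c(TPR = tpr, FPR = fpr)
}

#' BLNNN self-simulation study: averaged TPR and FPR
#'
#' Repeats \code{\link{simulate_blnnn}} (seed \code{base_seed + i} for
#' iteration i), fits BLNNN by EM from its standard initial values, calls
#' probes differential at \eqn{Z_i \ge} \code{threshold}, and averages
#' true and false positive rates over iterations.
#'
#' @param mu,phi2,tau2,sigma_rel,p generative parameters
#'   (see \code{\link{simulate_blnnn}}).
#' @param n_probes probes per iteration.
#' @param reps_per_channel replicates per channel.
#' @param n_iterations number of simulated datasets.
#' @param threshold posterior calling threshold (default 0.8).
#' @param base_seed seed offset; iteration i uses \code{base_seed + i}.
#' @param tol,max_iter EM convergence control passed to
#'   \code{\link{model_spec}}.
#' @return list of class \code{study_result}: \code{per_iteration} data
#'   frame (seed, TPR, FPR, converged, n_iter), averaged \code{tpr} and
#'   \code{fpr}, \code{threshold}, \code{n_iterations}.
#' @export
run_simulation_study <- function(mu = 7.8, phi2 = 1.8, tau2 = 0.09,
                                 sigma_rel = 0.1, p = 0.1,
                                 n_probes = 2000, reps_per_channel = 3,
                                 n_iterations = 50, threshold = 0.8,
                                 base_seed = 1, tol = 1e-4,
                                 max_iter = 200) {
  stopifnot(n_iterations >= 1)
  rows <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    seed_i <- base_seed + i
    sim <- simulate_blnnn(mu, phi2, tau2, sigma_rel, p, n_probes,
                          reps_per_channel, seed = seed_i)
    fit <- fit_model(sim$dataset,
                     model_spec("BLNNN", tol = tol, max_iter = max_iter))
    cr <- confusion_rates(fit$Z, sim$truth$differential, threshold)
    rows[[i]] <- data.frame(iteration = i, seed = seed_i,
                            TPR = cr[["TPR"]], FPR = cr[["FPR"]],
                            converged = fit$converged,
                            n_iter = fit$n_iter)
  }
  per_iter <- do.call(rbind, rows)
  structure(list(per_iteration = per_iter,
                 tpr = mean(per_iter$TPR, na.rm = TRUE),
                 fpr = mean(per_iter$FPR, na.rm = TRUE),
                 threshold = threshold, n_iterations = n_iterations,
                 base_seed = base_seed),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "study_result: %d iterations, threshold %.2f\n  averaged TPR %.2f%%, FPR %.2f%%\n",
    x$n_iterations, x$threshold, 100 * x$tpr, 100 * x$fpr))
  invisible(x)
}
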