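MODEL_NAMES <- c("BGG", "BNGG", "BNNGG", "BLNN", "BLNNN")

#' Specify a mixture model fit
#'
#' Bundles the model family, initial values, quadrature settings and
#' convergence control for \code{\link{fit_model}}. Default initial values
#' are \code{(a, a0, nu, p) = (20, 0.6, 20, 0.2)} for the gamma family and
#' \code{(mu, phi2, p) = (7.8, 1.8, 0.5)} for the log-normal family; both
#' were chosen for rapid, uniform convergence across models.
#'
#' @param model one of \code{"BGG"}, \code{"BNGG"}, \code{"BNNGG"},
#'   \code{"BLNN"}, \code{"BLNNN"}.
#' @param init initial global parameters (\code{\link{gamma_params}} or
#'   \code{\link{ln_params}}); defaults as above.
#' @param init_p initial mixing weight in (0, 1).
#' @param quad \code{\link{quadrature_spec}} for the gamma hierarchies.
#' @param tol relative log-likelihood convergence tolerance (the default
#'   1e-4 stops when the change is no more than 0.01 percent).
#' @param max_iter maximum EM iterations.
#' @param tau2_bounds per-probe variance search bounds.
#' @param mstep_evals objective-evaluation budget per global M-step.
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(model = MODEL_NAMES, init = NULL, init_p = NULL,
                       quad = quadrature_spec(), tol = 1e-4,
                       max_iter = 500L, tau2_bounds = c(1e-6, 1e4),
                       mstep_evals = 60L) {
  model <- match.arg(model)
  gamma_family <- model %in% c("BGG", "BNGG", "BNNGG")
  if (is.null(init)) {
    init <- if (gamma_family) gamma_params(20, 0.6, 20) else ln_params(7.8, 1.8)
  }
  if (gamma_family && !inherits(init, "gamma_params"))
    stop("gamma-family models need gamma_params initial values")
  if (!gamma_family && !inherits(init, "ln_params"))
    stop("log-normal models need ln_params initial values")
  if (is.null(init_p)) init_p <- if (gamma_family) 0.2 else 0.5
  if (init_p <= 0 || init_p >= 1) stop("init_p must be in (0, 1)")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(model = model, init = init, init_p = init_p, quad = quad,
                 tol = tol, max_iter = as.integer(max_iter),
                 tau2_bounds = tau2_bounds,
                 mstep_evals = as.integer(mstep_evals)),
            class = "model_spec")
}

# Marginal H0/HA log densities for every probe under the given state.
compute_marginals <- function(dataset, model, params, tau2, quad) {
  Yr <- dataset$treated; Yg <- dataset$control
  switch(model,
    BGG = list(
      log_p0 = gg_marginal_rows(cbind(Yr, Yg), params),
      log_pA = gg_marginal_rows(Yr, params) + gg_marginal_rows(Yg, params)),
    BNGG = tn_gamma_marginals_rows(Yr, Yg, Yr * 0, Yg * 0, tau2, params,
                                   quad$nodes, quad$nodes),
    BNNGG = tn_gamma_marginals_rows(Yr, Yg, dataset$se_treated^2,
                                    dataset$se_control^2, tau2, params,
                                    quad$nodes, quad$nodes),
    BLNN = ln_marginals_rows(Yr, Yg, Yr * 0 + tau2, Yg * 0 + tau2,
                             params$mu, params$phi2),
    BLNNN = ln_marginals_rows(Yr, Yg, dataset$se_treated^2 + tau2,
                              dataset$se_control^2 + tau2,
                              params$mu, params$phi2))
}

#' EM E-step: posterior probability of differential methylation
#'
#' \eqn{\hat z_i = p\, p_A(i) / (p\, p_A(i) + (1-p)\, p_0(i))}, computed
#' stably from log inputs. When both marginals underflow to \code{-Inf}
#' the data carry no information and \eqn{\hat z_i = p}.
#'
#' @param log_p0,log_pA per-probe log marginals under H0 and HA.
#' @param p mixing weight in (0, 1).
#' @return vector of posterior probabilities in [0, 1].
#' @export
e_step <- function(log_p0, log_pA, p) {
  stopifnot(length(log_p0) == length(log_pA), p > 0, p < 1)
  d <- (log1p(-p) + log_p0) - (log(p) + log_pA)
  Z <- 1 / (1 + exp(d))
  Z[is.nan(d)] <- p
  pmin(pmax(Z, 0), 1)
}

#' EM M-step for the mixing weight
#'
#' Regularized update \eqn{\hat p = (2 + \sum_i \hat z_i) / (4 + n)},
#' which keeps \eqn{p} strictly inside (0, 1) for any posterior vector.
#'
#' @param Z posterior probabilities in [0, 1].
#' @return updated mixing weight.
#' @export
m_step_p <- function(Z) {
  if (length(Z) == 0) return(0.5)
  stopifnot(all(Z >= 0 & Z <= 1))
  (2 + sum(Z)) / (2 * 2 + length(Z))
}

#' Total mixture log-likelihood
#'
#' \eqn{\sum_i \log\{p\, p_A(i) + (1-p)\, p_0(i)\}} via log-sum-exp.
#'
#' @param log_p0,log_pA per-probe log marginals.
#' @param p mixing weight.
#' @return scalar total log-likelihood.
#' @export
total_log_likelihood <- function(log_p0, log_pA, p) {
  la <- log(p) + log_pA
  l0 <- log1p(-p) + log_p0
  m <- pmax(la, l0)
  per <- ifelse(is.finite(m), m + log(exp(la - m) + exp(l0 - m)), m)
  sum(per)
}

weighted_objective <- function(marg, Z) {
  v <- Z * marg$log_pA + (1 - Z) * marg$log_p0
  # a weight of exactly 0 silences a -Inf marginal on the unused branch
  v[Z == 0 & !is.finite(marg$log_pA)] <-
    ((1 - Z) * marg$log_p0)[Z == 0 & !is.finite(marg$log_pA)]
  v[Z == 1 & !is.finite(marg$log_p0)] <-
    (Z * marg$log_pA)[Z == 1 & !is.finite(marg$log_p0)]
  sum(v)
}

params_to_par <- function(params) {
  if (inherits(params, "gamma_params")) {
    log(c(params$a, params$a0, params$nu))
  } else c(params$mu, log(params$phi2))
}

par_to_params <- function(par, gamma_family) {
  if (gamma_family) {
    ex <- exp(par)
    gamma_params(ex[1], ex[2], ex[3])
  } else ln_params(par[1], exp(par[2]))
}

#' EM M-step for the global hyperparameters
#'
#' Maximizes the posterior-weighted observed-data log-likelihood
#' \eqn{\sum_i [\hat z_i \log p_A(i) + (1 - \hat z_i) \log p_0(i)]} over
#' the global parameters with \code{\link[stats]{nlminb}} on
#' log-transformed (positivity-constrained) coordinates. If the search
#' fails, up to three deterministically jittered restarts are tried; if the
#' returned objective would be worse than the entering one, the previous
#' parameters are kept, so the step never descends.
#'
#' @param dataset a \code{meth_dataset}.
#' @param model model name.
#' @param Z posterior probabilities.
#' @param params current global parameters.
#' @param tau2 per-probe variance vector.
#' @param quad \code{\link{quadrature_spec}}.
#' @param eval_budget objective-evaluation cap for the search.
#' @return list with updated \code{params}, the achieved \code{objective}
#'   and a logical \code{improved}.
#' @export
m_step_global <- function(dataset, model, Z, params, tau2,
                          quad = quadrature_spec(), eval_budget = 60L) {
  gamma_family <- inherits(params, "gamma_params")
  obj_fn <- function(par) {
    pp <- try(par_to_params(par, gamma_family), silent = TRUE)
    if (inherits(pp, "try-error")) return(1e300)
    marg <- compute_marginals(dataset, model, pp, tau2, quad)
    val <- weighted_objective(marg, Z)
    if (!is.finite(val)) return(1e300)
    -val
  }
  par0 <- params_to_par(params)
  enter <- -obj_fn(par0)
  jitters <- list(0, 0.05, -0.05, 0.1)
  best_par <- par0; best_val <- enter
  for (j in jitters) {
    start <- par0 + j
    res <- try(stats::nlminb(start, obj_fn,
                             control = list(eval.max = eval_budget,
                                            iter.max = eval_budget)),
               silent = TRUE)
    if (!inherits(res, "try-error") && is.finite(res$objective) &&
        -res$objective > best_val) {
      best_par <- res$par; best_val <- -res$objective
    }
    if (best_val > enter) break  # ascent achieved; no restart needed
  }
  if (best_val < enter) {        # defensive; cannot happen given the above
    best_par <- par0; best_val <- enter
  }
  list(params = par_to_params(best_par, gamma_family),
       objective = best_val, improved = best_val > enter)
}

#' Per-probe variance update by hill climbing
#'
#' Coordinate search over each \eqn{\tau_i^2} maximizing that probe's
#' posterior-weighted log-likelihood contribution: multiplicative steps
#' (x1.5 / /1.5), step shrinkage x0.5 when neither direction improves,
#' stopping when the step factor is within 1 percent of 1 or after 50
#' moves. Values are clamped to \code{bounds}. The per-probe objective
#' never decreases.
#'
#' @param dataset a \code{meth_dataset}.
#' @param model model name (\code{"BGG"} has no variance layer).
#' @param Z posterior probabilities.
#' @param params global parameters.
#' @param tau2 entering per-probe variances.
#' @param quad \code{\link{quadrature_spec}}.
#' @param bounds lower/upper clamp for \eqn{\tau_i^2}.
#' @return updated \code{tau2} vector.
#' @export
m_step_tau_hillclimb <- function(dataset, model, Z, params, tau2,
                                 quad = quadrature_spec(),
                                 bounds = c(1e-6, 1e4)) {
  if (model == "BGG") return(tau2)
  n <- n_probes(dataset)
  stopifnot(length(tau2) == n, length(Z) == n)
  probe_obj <- function(ds, z, t2) {
    marg <- compute_marginals(ds, model, params, t2, quad)
    v <- z * marg$log_pA + (1 - z) * marg$log_p0
    v[z == 0] <- (marg$log_p0)[z == 0]
    v[z == 1] <- (marg$log_pA)[z == 1]
    v
  }
  obj <- probe_obj(dataset, Z, tau2)
  step <- rep(1.5, n)
  active <- rep(TRUE, n)
  for (move in seq_len(50)) {
    if (!any(active)) break
    idx <- which(active)
    ds <- subset_dataset(dataset, idx)
    za <- Z[idx]; ta <- tau2[idx]; sa <- step[idx]
    up <- pmin(ta * sa, bounds[2])
    dn <- pmax(ta / sa, bounds[1])
    o_up <- probe_obj(ds, za, up)
    o_dn <- probe_obj(ds, za, dn)
    eps <- 1e-9 * abs(obj[idx]) + 1e-12
    take_up <- o_up >= o_dn & o_up > obj[idx] + eps
    take_dn <- !take_up & o_dn > obj[idx] + eps
    tau2[idx[take_up]] <- up[take_up]
    obj[idx[take_up]] <- o_up[take_up]
    tau2[idx[take_dn]] <- dn[take_dn]
    obj[idx[take_dn]] <- o_dn[take_dn]
    stuck <- !(take_up | take_dn)
    step[idx[stuck]] <- 1 + (sa[stuck] - 1) * 0.5
    active[idx] <- (step[idx] - 1) >= 0.01
  }
  tau2
}

init_tau2 <- function(dataset, floor_at = 1e-6) {
  row_var <- function(M) {
    if (ncol(M) < 2) return(rep(NA_real_, nrow(M)))
    rowSums((M - rowMeans(M))^2) / (ncol(M) - 1)
  }
  vt <- row_var(dataset$treated)
  vg <- row_var(dataset$control)
  dft <- max(ncol(dataset$treated) - 1, 0)
  dfg <- max(ncol(dataset$control) - 1, 0)
  pooled <- if (dft + dfg > 0) {
    (ifelse(is.na(vt), 0, vt) * dft + ifelse(is.na(vg), 0, vg) * dfg) /
      (dft + dfg)
  } else rep(floor_at, n_probes(dataset))
  pmax(pooled, floor_at)
}

#' Fit an empirical Bayes mixture model by EM
#'
#' Alternates the E-step (\code{\link{e_step}}), the regularized mixing
#' weight update (\code{\link{m_step_p}}), the numerical global parameter
#' search (\code{\link{m_step_global}}) and one per-probe variance
#' hill-climb sweep (\code{\link{m_step_tau_hillclimb}}; not for BGG,
#' which has no variance layer) until the total log-likelihood changes by
#' no more than \code{tol} in relative terms, or \code{max_iter} is hit.
#'
#' @param dataset a \code{meth_dataset}; linear scale for BGG/BNGG/BNNGG,
#'   log scale for BLNN/BLNNN. BNNGG and BLNNN require known SEs.
#' @param spec a \code{\link{model_spec}}.
#' @return an object of class \code{mixture_fit}: model name, fitted
#'   global \code{params}, \code{tau2}, mixing weight \code{p}, posterior
#'   vector \code{Z}, \code{delta} (mean log signal, treated minus
#'   control), \code{loglik_trace}, \code{converged}, \code{n_iter}.
#' @export
fit_model <- function(dataset, spec) {
  stopifnot(inherits(dataset, "meth_dataset"), inherits(spec, "model_spec"))
  model <- spec$model
  gamma_family <- model %in% c("BGG", "BNGG", "BNNGG")
  want_scale <- if (gamma_family) "linear" else "log"
  if (dataset$scale != want_scale)
    stop(model, " requires a ", want_scale, "-scale dataset")
  if (model %in% c("BNNGG", "BLNNN") &&
      (is.null(dataset$se_treated) || is.null(dataset$se_control)))
    stop(model, " requires known per-replicate SEs in the dataset")

  params <- spec$init
  p <- spec$init_p
  tau2 <- if (model == "BGG") NULL else
    init_tau2(dataset, floor_at = spec$tau2_bounds[1])
  quad <- spec$quad

  marg <- compute_marginals(dataset, model, params, tau2, quad)
  dead <- !is.finite(marg$log_p0) & !is.finite(marg$log_pA)
  if (any(dead)) {
    stop("non-finite likelihood at initialization for probe(s): ",
         paste(utils::head(dataset$probe_ids[dead], 10), collapse = ", "))
  }
  ll <- total_log_likelihood(marg$log_p0, marg$log_pA, p)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < spec$max_iter) {
    iter <- iter + 1L
    Z <- e_step(marg$log_p0, marg$log_pA, p)
    p <- m_step_p(Z)
    gm <- m_step_global(dataset, model, Z, params, tau2, quad,
                        eval_budget = spec$mstep_evals)
    params <- gm$params
    if (!is.null(tau2)) {
      tau2 <- m_step_tau_hillclimb(dataset, model, Z, params, tau2, quad,
                                   bounds = spec$tau2_bounds)
    }
    marg <- compute_marginals(dataset, model, params, tau2, quad)
    ll_new <- total_log_likelihood(marg$log_p0, marg$log_pA, p)
    trace <- c(trace, ll_new)
    tol_abs <- if (abs(ll) > 1e-8) spec$tol * abs(ll) else 1e-8
    if (abs(ll_new - ll) <= tol_abs) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  Z <- e_step(marg$log_p0, marg$log_pA, p)

  mean_log <- function(M) {
    if (dataset$scale == "log") rowMeans(M) else rowMeans(log(pmax(M, 1e-300)))
  }
  structure(list(
    model = model, params = params, tau2 = tau2, p = p, Z = Z,
    delta = mean_log(dataset$treated) - mean_log(dataset$control),
    mean_log_treated = mean_log(dataset$treated),
    mean_log_control = mean_log(dataset$control),
    probe_ids = dataset$probe_ids,
    log_p0 = marg$log_p0, log_pA = marg$log_pA,
    loglik_trace = trace, loglik = ll,
    converged = converged, n_iter = iter
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: %s, %d probes, %d EM iterations (%s)\n",
              x$model, length(x$Z), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  log-likelihood %.4f, p = %.4f\n", x$loglik, x$p))
  if (inherits(x$params, "gamma_params")) {
    cat(sprintf("  a = %.4g, a0 = %.4g, nu = %.4g\n",
                x$params$a, x$params$a0, x$params$nu))
  } else {
    cat(sprintf("  mu = %.4g, phi2 = %.4g\n", x$params$mu, x$params$phi2))
  }
  invisible(x)
}

#' Serialize a fit to JSON (globals) and TSV (per-probe results)
#'
#' @param fit a \code{mixture_fit}.
#' @param json_path path for the global-parameter JSON, or \code{NULL}.
#' @param tsv_path path for the per-probe TSV
#'   (\code{probe_id Z tau2 mean_log_treated mean_log_control}), or
#'   \code{NULL}.
#' @return \code{fit}, invisibly.
#' @export
write_fit <- function(fit, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!is.null(json_path)) {
    glob <- unclass(fit$params)
    jsonlite::write_json(
      list(model = fit$model, params = glob, p = fit$p,
           n_iter = fit$n_iter, converged = fit$converged,
           loglik = fit$loglik),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(
      data.frame(probe_id = fit$probe_ids, Z = fit$Z,
                 tau2 = if (is.null(fit$tau2)) NA_real_ else fit$tau2,
                 mean_log_treated = fit$mean_log_treated,
                 mean_log_control = fit$mean_log_control),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fit)
}
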