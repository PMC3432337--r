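# Fixture builders used across the suite; everything is generated in code.

make_raw_records <- function(n_probes = 20, reps = 3, seed = 1,
                             treated_factor = 1, background = 100) {
  set.seed(seed)
  ids <- sprintf("p%03d", seq_len(n_probes))
  grid <- expand.grid(probe_id = ids, channel = c("treated", "control"),
                      replicate = seq_len(reps), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  base <- exp(stats::rnorm(n_probes, 7.5, 1))
  y <- base[match(grid$probe_id, ids)] *
    exp(stats::rnorm(nrow(grid), 0, 0.2)) *
    ifelse(grid$channel == "treated", treated_factor, 1)
  data.frame(grid,
             F = background + y,
             B = background,
             SD_F = 0.05 * y + 1,
             SD_B = 2,
             Pix_F = 25L,
             Pix_B = 25L,
             stringsAsFactors = FALSE)
}

write_probe_fixture <- function(records, path = tempfile(fileext = ".tsv")) {
  write_probe_table(records, path)
  path
}

# Deterministic linear two-channel dataset with a controlled ratio.
make_linear_dataset <- function(n_probes = 300, reps = 2, seed = 1,
                                ratio = 1) {
  set.seed(seed)
  base <- exp(stats::rnorm(n_probes, 8, 1.2))
  ctrl <- base * exp(matrix(stats::rnorm(n_probes * reps, 0, 0.1),
                            n_probes, reps))
  trt <- ratio * base * exp(matrix(stats::rnorm(n_probes * reps, 0, 0.1),
                                   n_probes, reps))
  meth_dataset(trt, ctrl, se_treated = 0.05 * trt, se_control = 0.05 * ctrl,
               scale = "linear")
}

# Log-scale dataset exponentiated onto the linear scale, with the relative
# SEs converted to absolute SDs, so gamma and log-normal fits see the same
# probes.
linearize_dataset <- function(ds_log) {
  trt <- exp(ds_log$treated)
  ctrl <- exp(ds_log$control)
  meth_dataset(trt, ctrl,
               se_treated = ds_log$se_treated * trt,
               se_control = ds_log$se_control * ctrl,
               scale = "linear", probe_ids = ds_log$probe_ids)
}

# Independent dense-grid oracle for the BNGG/BNNGG marginals (trapezoid on
# an explicit 2-D grid; no shared code with the package's quadrature).
bngg_grid_oracle <- function(yr, yg, vr, vg, tau2, a, a0, nu,
                             eta_n = 20000, th_n = 2000, eta_hi = NULL,
                             th_hi = NULL) {
  if (is.null(eta_hi)) eta_hi <- max(yr, yg) + 20 * sqrt(tau2 + max(vr, vg))
  if (is.null(th_hi)) th_hi <- stats::qgamma(1 - 1e-9, a0, rate = nu) * 4
  eta <- seq(1e-9, eta_hi, length.out = eta_n); deta <- eta[2] - eta[1]
  thg <- seq(1e-7, th_hi, length.out = th_n); dth <- thg[2] - thg[1]
  tnprod <- function(ys, vs) {
    out <- rep(1, length(eta))
    for (k in seq_along(ys)) {
      s <- sqrt(vs[k] + tau2)
      out <- out * stats::dnorm(ys[k], eta, s) / stats::pnorm(eta / s)
    }
    out
  }
  fr <- tnprod(yr, vr); fg <- tnprod(yg, vg)
  Ir <- vapply(thg, function(t) sum(fr * stats::dgamma(eta, a, rate = t)) * deta,
               numeric(1))
  Ig <- vapply(thg, function(t) sum(fg * stats::dgamma(eta, a, rate = t)) * deta,
               numeric(1))
  pri <- stats::dgamma(thg, a0, rate = nu)
  c(log_p0 = log(sum(Ir * Ig * pri) * dth),
    log_pA = log(sum(Ir * pri) * dth) + log(sum(Ig * pri) * dth))
}

# Exact one-sided hypergeometric tail by explicit enumeration of tables at
# least as enriched, via binomial coefficients only.
fisher_enum_oracle <- function(k_cat, n_cat, k_bg, n_bg) {
  k_tot <- k_cat + k_bg
  xs <- max(0, k_tot - n_bg):min(n_cat, k_tot)
  total <- sum(choose(n_cat, xs) * choose(n_bg, k_tot - xs))
  tail <- xs[xs >= k_cat]
  sum(choose(n_cat, tail) * choose(n_bg, k_tot - tail)) / total
}
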