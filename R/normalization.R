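# Lowess fit evaluated at the input points. The curve is clamped to its
# value at the 1st/99th intensity percentiles: local linear fits at sparse
# intensity extremes are high-variance, and constant extension there keeps
# repeated normalization stable.
lowess_curve <- function(x, y, span) {
  fit <- stats::lowess(x, y, f = span)
  qs <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  keep <- fit$x >= qs[1] & fit$x <= qs[2]
  if (sum(keep) < 2) keep <- rep(TRUE, length(fit$x))
  stats::approx(fit$x[keep], fit$y[keep], xout = x, rule = 2, ties = mean)$y
}

#' Within-array lowess M-A normalization
#'
#' Removes intensity-dependent dye bias from a linear-scale two-color
#' dataset. For each treated/control replicate pairing, probes with
#' positive signal in both channels are placed on the M-A plane
#' (\eqn{M = \log_2(t/c)}, \eqn{A = \frac{1}{2}\log_2(t c)}), a lowess
#' curve \eqn{\hat M(A)} is fit, and the correction is redistributed
#' symmetrically: treated signals are divided by \eqn{2^{\hat M/2}} and
#' control signals multiplied by \eqn{2^{\hat M/2}}. Each probe's standard
#' error is rescaled by the same multiplicative factor as its signal, so
#' the relative SE \eqn{\sigma' = \sigma/y} is unchanged by normalization.
#'
#' @param dataset linear-scale \code{meth_dataset} with both channels.
#' @param span lowess smoother span (fraction of probes), in (0, 1].
#' @param min_probes minimum number of usable probes required per pairing.
#' @return a list of class \code{normalization_result}: \code{dataset}
#'   (corrected), \code{correction_treated}/\code{correction_control}
#'   (multiplicative factors, probes x replicates), \code{span},
#'   \code{stage}.
#' @export
normalize_within_array <- function(dataset, span = 0.4, min_probes = 50) {
  stopifnot(inherits(dataset, "meth_dataset"))
  if (dataset$scale != "linear")
    stop("within-array normalization requires a linear-scale dataset")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  kt <- ncol(dataset$treated); kc <- ncol(dataset$control)
  corr_t <- matrix(1, nrow(dataset$treated), kt)
  corr_c <- matrix(1, nrow(dataset$control), kc)
  for (k in seq_len(max(kt, kc))) {
    it <- min(k, kt); ic <- min(k, kc)
    tk <- dataset$treated[, it]; ck <- dataset$control[, ic]
    usable <- tk > 0 & ck > 0
    if (sum(usable) < min_probes) {
      stop("within-array normalization: only ", sum(usable),
           " usable probes in pairing ", k, " (need >= ", min_probes, ")")
    }
    M <- log2(tk[usable] / ck[usable])
    A <- 0.5 * log2(tk[usable] * ck[usable])
    Mhat <- lowess_curve(A, M, span)
    half <- 2^(Mhat / 2)
    corr_t[usable, it] <- corr_t[usable, it] / half
    corr_c[usable, ic] <- corr_c[usable, ic] * half
  }
  out <- dataset
  out$treated <- dataset$treated * corr_t
  out$control <- dataset$control * corr_c
  if (!is.null(dataset$se_treated)) out$se_treated <- dataset$se_treated * corr_t
  if (!is.null(dataset$se_control)) out$se_control <- dataset$se_control * corr_c
  structure(list(dataset = out,
                 correction_treated = corr_t,
                 correction_control = corr_c,
                 span = span, stage = "within_array"),
            class = "normalization_result")
}

#' Between-array lowess normalization
#'
#' Aligns two or more arrays (datasets over a shared probe universe;
#' the intersection of probe ids is used) to a probe-wise median
#' pseudo-array. For each array, the per-probe mean log2 signal (over both
#' channels and all replicates) is compared with the reference, the
#' difference is lowess-smoothed against mean intensity, and every signal
#' and SE of the array is divided by the smoothed factor, leaving relative
#' SEs unchanged.
#'
#' @param datasets list of >= 2 linear-scale \code{meth_dataset} objects.
#' @param span lowess span.
#' @return list of \code{normalization_result}, one per input dataset, each
#'   restricted to the common probe universe.
#' @export
normalize_between_arrays <- function(datasets, span = 0.4) {
  if (!is.list(datasets) || length(datasets) < 2)
    stop("between-array normalization needs a list of >= 2 datasets")
  for (d in datasets) {
    stopifnot(inherits(d, "meth_dataset"))
    if (d$scale != "linear") stop("between-array normalization requires linear-scale datasets")
  }
  common <- Reduce(intersect, lapply(datasets, function(d) d$probe_ids))
  if (length(common) == 0) stop("empty probe intersection across arrays")
  datasets <- lapply(datasets, subset_dataset, idx = common)

  mean_log2 <- function(d) {
    m <- cbind(d$treated, d$control)
    m[m <= 0] <- NA
    rowMeans(log2(m), na.rm = TRUE)
  }
  logs <- vapply(datasets, mean_log2, numeric(length(common)))
  ref <- apply(logs, 1, stats::median, na.rm = TRUE)

  lapply(seq_along(datasets), function(j) {
    d <- datasets[[j]]
    D <- logs[, j] - ref
    A <- (logs[, j] + ref) / 2
    ok <- is.finite(D) & is.finite(A)
    Dhat <- rep(0, length(common))
    if (sum(ok) >= 2) Dhat[ok] <- lowess_curve(A[ok], D[ok], span)
    fac <- 2^(-Dhat)
    out <- d
    out$treated <- d$treated * fac
    out$control <- d$control * fac
    if (!is.null(d$se_treated)) out$se_treated <- d$se_treated * fac
    if (!is.null(d$se_control)) out$se_control <- d$se_control * fac
    structure(list(dataset = out,
                   correction_treated = matrix(fac, length(common), ncol(d$treated)),
                   correction_control = matrix(fac, length(common), ncol(d$control)),
                   span = span, stage = "between_array"),
              class = "normalization_result")
  })
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("normalization_result (%s): %d probes, span %.2f\n",
              x$stage, length(x$dataset$probe_ids), x$span))
  cat(sprintf("  correction range (log2): [%.4f, %.4f]\n",
              min(log2(x$correction_treated), log2(x$correction_control)),
              max(log2(x$correction_treated), log2(x$correction_control))))
  invisible(x)
}
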