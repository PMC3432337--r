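---
title: "Empirical Bayes mixture models for two-color DMH arrays: methods and design notes"
author: "dmhmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dmhmix methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Differential methylation hybridization (DMH) interrogates thousands of
CpG-rich promoter fragments on a two-color oligonucleotide array:
methylation-sensitive restriction digestion enriches methylated fragments,
the treated sample is labeled Cy5 and the untreated parental sample Cy3,
and the per-probe channel contrast reflects a methylation difference.
The statistical task is to decide, probe by probe, whether the treated and
control channels share one underlying methylation level or two.

`dmhmix` frames this as an empirical Bayes two-component mixture. Each
probe $i$ carries a latent indicator $z_i \sim \mathrm{Bernoulli}(p)$.
Under the null component the two channels share a single latent level
drawn from a prior; under the alternative each channel draws its own
latent level independently from the same prior. Replicate-level noise is
layered on top. All hyperparameters — the prior, the mixing weight $p$,
and per-probe replicate variances $\tau_i^2$ — are estimated from the
data by EM, and the E-step posterior
$$\hat z_i \;=\; \frac{p\,p_A(y_i)}{p\,p_A(y_i) + (1-p)\,p_0(y_i)}$$
is the probe-level probability of differential methylation.

# Signals and standard errors

From a scanned probe record the linear signal and its standard error are
$$y = |F - B|, \qquad
  \sigma = \sqrt{SD_F^2/Pix_F + SD_B^2/Pix_B}, \qquad
  \sigma' = \sigma / y,$$
with $F, B$ the foreground/background intensities of one dye and
$SD$, $Pix$ the pixel-level standard deviations and pixel counts.
$\sigma'$ is both the relative SE of $y$ and, by the delta method, the
SD of $\log y$; the log-scale models consume it as a known per-replicate
noise component. Probes with $y = 0$ cannot be placed on the log scale
and are excluded from log-scale datasets (with a recorded count) rather
than floored — flooring would fabricate an arbitrary $-\infty$
neighborhood. The log base is natural by default (configurable to 2);
nothing downstream depends on the choice beyond a scale factor, and the
base is recorded in the dataset.

# The five hierarchies

All five models share the mixture structure and differ in the noise
hierarchy:

* **BGG** (gamma–gamma): replicate signals
  $y \sim \Gamma(a, \theta_i)$ with probe rate
  $\theta_i \sim \Gamma(a_0, \nu)$. The marginals are conjugate closed
  forms.
* **BNGG**: truncated-normal replicate noise
  $y \sim TN(\eta_{ij}, \tau_i^2)$ on $[0, \infty)$ around latent channel
  means $\eta_{ij} \sim \Gamma(a, \theta_i)$.
* **BNNGG**: as BNGG with the known pixel-level variance added,
  $y \sim TN(\eta_{ij}, \sigma_{ijk}^2 + \tau_i^2)$.
* **BLNN** (log-normal–normal): log signals
  $y' \sim N(\eta_{ij}, \tau_i^2)$ with $\eta_{ij} \sim N(\mu, \varphi^2)$.
* **BLNNN**: as BLNN with the known pixel-level variance added,
  $y' \sim N(\eta_{ij}, \sigma'^2_{ijk} + \tau_i^2)$.

Two parameterization choices are deliberately pinned down because the
notation $\Gamma(a, \theta)$ alone does not fix them:

* **Shape–rate throughout.** $y \sim \Gamma(\text{shape } a,
  \text{rate } \theta)$ and $\theta \sim \Gamma(\text{shape } a_0,
  \text{rate } \nu)$, which yields the classic conjugate marginal
  $$p(y_{1..K}) = \frac{\prod_k y_k^{a-1}\; \nu^{a_0}\,
     \Gamma(Ka + a_0)}{\Gamma(a)^K\, \Gamma(a_0)\,
     (\textstyle\sum_k y_k + \nu)^{Ka+a_0}}.$$
  With the standard initial $a_0 = 0.6 < 1$ the marginal mean of $y$ is
  infinite; the density remains proper and the EM is unaffected.
* **Truncated-normal support $[0, \infty)$**: intensities are
  nonnegative; the density is
  $\phi((y-\eta)/s) / (s\,\Phi(\eta/s))$ for $y \ge 0$.

For the log-normal models the set marginal is the $K$-variate normal
with mean $\mu\mathbf{1}$ and covariance
$\mathrm{diag}(v) + \varphi^2 J$. It is evaluated by the rank-one
(precision-weighted shrinkage) identity
$$\log m(y) = \sum_k \log N(y_k; \mu, v_k)
  - \tfrac12 \log(1 + \varphi^2 W)
  + \tfrac12 \frac{\varphi^2 b^2}{1 + \varphi^2 W},
  \quad W = \sum_k v_k^{-1},\;\; b = \sum_k \frac{y_k - \mu}{v_k},$$
which costs $O(K)$ per probe and — because it is written around the
independence baseline — remains exact in floating point as
$\varphi^2 \to 0$. Equivalence to the explicit-covariance multivariate
normal density is enforced by a test, not assumed.

# Quadrature for the truncated-normal/gamma marginals

BNGG/BNNGG marginals have no closed form. The inner integral over a
channel's latent mean $\eta$ and the outer integral over the probe rate
$\theta$ are evaluated by Gauss–Legendre quadrature in log space
(log-sum-exp everywhere; a true zero is carried as a $-\infty$ sentinel
that the E-step maps to $\hat z_i \in \{0, 1, p\}$ correctly).

Window placement is the part that matters:

* The $\eta$ window follows the data: the truncated-normal replicate
  factors decay like a Gaussian while the gamma prior varies
  polynomially–exponentially, so the product integrand is confined to
  $[\min_k y_k - 12 s_{\max},\; \max_k y_k + 12 s_{\max}]$ (clipped to
  positive), independent of $\theta$.
* The $\theta$ window follows a conjugate surrogate posterior
  $\Gamma(a_0 + m\,a,\; \nu + \sum \bar y)$ ($m$ = number of latent
  channel means integrated), widened by a factor of 8 each way and
  merged across the three integrals (pooled, treated, control) so one
  grid serves all of them; nodes are placed in $\log\theta$.

The EM fit path uses fixed node counts (64 per axis by default; 16 is
the accepted minimum) — fixed grids keep the likelihood surface smooth
across iterations, which the monotonicity guarantee relies on. The
exported scalar marginals additionally double the node counts until
successive estimates agree to a relative accuracy target (default
$10^{-6}$), and a test pins the fixed-node path to the adaptive path.
With 64 nodes the fixed path agrees with fully converged quadrature to
about $4\times10^{-4}$ on the log scale in stress cases (large
$\tau_i^2$, wide windows), far below anything that could affect a
posterior call.

# EM estimation

Each iteration performs:

1. **E-step**: $\hat z_i$ from the current marginals, computed from log
   quantities.
2. **Mixing weight**: the regularized update
   $\hat p = (2 + \sum_i \hat z_i)/(4 + n)$, which keeps $p$ strictly
   inside $(0, 1)$ even when every posterior collapses.
3. **Global parameters**: `nlminb` maximizes the posterior-weighted
   observed-data log-likelihood
   $\sum_i [\hat z_i \log p_A + (1 - \hat z_i)\log p_0]$ over
   log-transformed coordinates (positivity for $a, a_0, \nu, \varphi^2$).
   If the search fails, three deterministically jittered restarts are
   tried; if the best candidate would still be worse than the entering
   point, the previous parameters are kept. The step therefore never
   descends, which is all the EM ascent argument needs — a partial
   (generalized-EM) maximization is accepted deliberately, and the
   per-step evaluation budget (default 60) bounds the cost of the
   numerically expensive gamma hierarchies.
4. **Per-probe variances**: one hill-climb sweep per probe over
   $\tau_i^2$ — multiplicative steps ($\times 1.5$, $\div 1.5$), step
   shrinkage by half when neither direction improves, termination when
   the step factor is within 1% of 1 or after 50 moves, values clamped
   to $[10^{-6}, 10^{4}]$. The sweep is vectorized over the active probe
   set, and the per-probe objective never decreases.

Convergence is declared when the total log-likelihood
$\sum_i \log\{p\,p_A + (1-p)\,p_0\}$ changes by no more than 0.01%
(relative tolerance $10^{-4}$; absolute fallback $10^{-8}$ near zero),
up to 500 iterations. The trace is returned and tested to be
non-decreasing within a slack of $10^{-6}|LL|$ per step. The whole fit
is deterministic: refitting the same dataset reproduces the trace and
posteriors bit for bit.

Initial values are $(a, a_0, \nu, p) = (20, 0.6, 20, 0.2)$ for the
gamma family and $(\mu, \varphi^2, p) = (7.8, 1.8, 0.5)$ for the
log-normal family — settings chosen for uniform, rapid convergence
across models (the listed order resolves 1.8 as the prior *variance*
$\varphi^2$, not its SD). BLNNN uses the BLNN initials.
$\tau_i^2$ starts at the pooled within-channel sample variance, floored
at the search lower bound $10^{-6}$. The floor sits at the bound rather
than some larger constant on purpose: with near-noiseless replicates a
larger floor would overstate the replicate noise at the first E-step and
can lock probes with small real channel differences into the null
branch; flooring at the bound is a no-op whenever the sample variance is
measurable.

# Normalization

Within-array lowess M–A normalization removes intensity-dependent dye
bias: per replicate pairing, $M = \log_2(t/c)$ and
$A = \frac12\log_2(tc)$ over probes positive in both channels, a lowess
curve $\hat M(A)$ (span 0.4 by default), and symmetric redistribution —
treated divided by $2^{\hat M/2}$, control multiplied by $2^{\hat M/2}$.
Between-array normalization aligns each array's per-probe mean log
signal to the probe-wise median pseudo-array (robust and independent of
array order) with the same machinery. Two implementation notes:

* Each probe's $\sigma$ is rescaled by the same multiplicative factor
  as its signal, making $\sigma'$ normalization-invariant — consistent
  with $\sigma'$ being the quantity the log-scale models consume. (An
  additive rescaling would break that invariance; the multiplicative
  reading is the one under which the pipeline is self-consistent.)
* The fitted curve is clamped to its value at the 1st/99th percentile
  of $A$ and extended constantly beyond. Local linear fits at sparse
  intensity extremes are high-variance, and the clamp is what makes
  repeated normalization stable (a second pass changes $M$ by less
  than 0.02 at realistic probe counts).

Print-tip/block-wise lowess, alternative background corrections and
quantile normalization are out of scope.

# Posterior classification and heritability patterns

A probe is called differentially methylated when $\hat z_i \ge 0.8$,
not differentially methylated when $\hat z_i \le 0.2$, and undetermined
in between. For generation-resolved analyses each generation comparison
yields a direction call: **Up** if $\hat z_i \ge 0.8$ and the mean log
signal difference (treated − control) is positive, **Down** if
negative, **Even** otherwise — the threshold is a strict $\ge$, so
$\hat z_i = 0.79$ is Even no matter how large the signal difference.
The difference of replicate means of normalized log signals is used as
the direction statistic because it is the one quantity available from
every model family.

Triples of calls over generations 1, 3, 5 map to heritability
categories: three monotone-decreasing triples (DDD, EDD, EED) are
*stochastic hypomethylation*, their Up mirror images *stochastic
hypermethylation*, ten listed non-monotone triples are *random
differential methylation*, and the remaining 11 of the 27 possible
triples are reported as *unclassified* — the published table is read as
exhaustive for its three categories, and unlisted triples are not
forced into the random class.

# TFBS enrichment

Probe sequences in each heritability category are scanned with
TRANSFAC-style position weight matrices on both strands using the
information-weighted matrix similarity score
$(S - S_{\min})/(S_{\max} - S_{\min})$, where position $p$ contributes
$I(p)\,f_{p,b}$ with $I(p) = \sum_b f_{pb}\log(4 f_{pb})$; windows
scoring at or above the threshold (default 0.85) are hits. This is a
simplified scanner: the core-similarity pre-filter of the MATCH tool
and its per-matrix threshold profiles are deliberately not reproduced,
so scores are comparable in spirit but not identical.

Enrichment against background is tested per matrix with a one-sided
(greater) Fisher exact test on sequence-level presence/absence — the
standard reading of "frequencies" for category-versus-background
tables; raw site counts are also emitted. The background is 10000
random sequences, each copying the length of a category sequence
(cycling through the category) with bases drawn i.i.d. at that
sequence's GC fraction. Significance uses a Bonferroni threshold
$\alpha / (n_{tf} \cdot n_{categories})$; the divisor defaults to the
actual numbers tested, with an override (e.g. 459 matrices × 3
categories, giving $3.63\times10^{-5}$ at $\alpha = 0.05$) to mirror
the published correction exactly.

# The simulation study

`simulate_blnnn()` generates data from the BLNNN hierarchy itself:
$z_i \sim \mathrm{Bernoulli}(p)$; null probes share
$\eta_i \sim N(\mu, \varphi^2)$, differential probes draw independent
channel means from the same prior; each replicate adds
$N(0, \tau^2)$ between-replicate noise and $N(0, \sigma'^2)$
pixel-level noise, with $\sigma'$ recorded as known. Defaults are
$\mu = 7.8$, $\varphi^2 = 1.8$, $p = 0.1$, three replicates per
channel, $\tau = 0.3$ and $\sigma' = 0.1$. The noise magnitudes stand
in for array-typical values (the within-replicate coefficient of
variation of such arrays is on the order of tens of percent, i.e.
$\tau \approx 0.3$ on the natural-log scale, with pixel-level SEs a few
times smaller); they are explicit arguments everywhere so a study
states its conditions. $\sigma'$ is constant across replicates by
default; `sigma_rel_range` draws per-replicate values log-uniformly to
emulate heterogeneous spot quality.

`run_simulation_study()` repeats simulate → fit → call
($\hat z_i \ge 0.8$, matching the posterior classification threshold)
→ TPR/FPR, with iteration $i$ seeded `base_seed + i` so any prefix of
a study is reproducible independently of its length.

What the generator does *not* emulate: dye bias and spatial artifacts
(the data are born normalized), probe-sequence effects, correlation
between neighboring probes, outlier spots, and heavy-tailed noise.
Passing recovery and TPR/FPR checks on this generator therefore
demonstrates correctness of the estimation machinery under the model's
own assumptions — not robustness to the full messiness of scanned
arrays.

An intrinsic property of this design worth knowing: differential
probes' channel means differ by $N(0, 2\varphi^2)$, which places an
atom of probes arbitrarily close to "no difference". At
$\varphi^2 = 1.8$, $\tau = 0.3$, $\sigma' = 0.1$ and three replicates,
around 12% of truly differential probes have a channel gap below 0.3
log units — under the channel-mean noise SD of
$\sqrt{(\tau^2 + \sigma'^2)/3} \approx 0.18$ — and even the posterior
computed with the *true* generative parameters cannot call them at
$\hat z \ge 0.8$. The achievable true positive rate under these
conditions is therefore bounded in the mid-60s percent; reported
sensitivities substantially above that imply quieter noise settings or
a wider latent prior.

# Problem sizes and test design

The test suite exercises every closed form against an independent
oracle (numerical rate integration for the gamma marginal, an
explicit-covariance multivariate normal density for the log-normal
marginal, dense 2-D trapezoid grids for the truncated-normal/gamma
marginals, hypergeometric enumeration for Fisher p-values) and checks
EM ascent, convergence, determinism and parameter recovery on
simulated data. Simulation sizes were chosen to keep estimates stable
while remaining desk-scale: the self-simulation study runs 50
iterations of 2000 probes; parameter recovery uses 10 seeds of 10000
probes; the model-comparison fit of all five hierarchies uses 500
probes with 32 quadrature nodes (the gamma quadrature dominating the
cost); EM property checks use 60–80 probes. `scripts/acceptance.R`
re-runs the self-simulation study from scratch and writes the averaged
TPR and FPR (as percentages) to JSON.

# Known limitations

* The gamma-hierarchy marginals are quadrature-based; pathological
  inputs (shape $a < 1$ with an integrand singularity at the origin
  inside the window, or replicate sets spanning several orders of
  magnitude within one probe) can degrade the fixed-grid accuracy.
  The adaptive scalar marginals report non-convergence explicitly,
  carrying their best estimate in the error condition.
* The mixing-weight update is the regularized form above, equivalent
  to a mild symmetric prior on $p$; on pure-null data $p$ converges to
  $2/(4+n)$, not 0.
* Per-probe $\tau_i^2$ estimation from a handful of replicates is
  noisy, and the joint $(\hat z_i, \tau_i^2)$ update has a known local
  optimum in which a real channel difference is absorbed into an
  inflated $\tau_i^2$; the initialization policy above removes the
  main trigger but cannot rule the optimum out.
* The PWM scanner is a simplified stand-in for MATCH; enrichment
  conclusions are comparative, not matrix-calibrated.
* Replicates are treated as exchangeable technical replicates within a
  channel; no replicate pairing across channels is modeled.
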