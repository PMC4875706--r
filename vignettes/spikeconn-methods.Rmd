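---
title: "Methods: regularized spike-response GLMs and empirical Bayesian connectivity testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized spike-response GLMs and empirical Bayesian connectivity testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spikeconn)
```

## The model

`spikeconn` infers directed functional connectivity between neurons from
binned binary spike trains. For each target (postsynaptic) neuron $i$, the
probability of a spike in bin $t$ is

$$p_i(t) = f(\lambda_i(t)), \qquad
\lambda_i(t) = R_{i0} + \sum_{l=1}^{L} R^E_{il} E_l(t)
 + \sum_{c=1}^{C} \sum_{s=1}^{M} R_{ic}(s)\, N_c(t-s),$$

where $N_c(t) \in \{0, 1\}$ are the binned spike indicators, $E_l(t)$ are
real-valued external-input channels, and $f$ is the logistic link
$1/(1+e^{-x})$ (default) or the complementary log–log link
$1 - \exp(-e^x)$, which makes the Bernoulli-per-bin model approximate a
Poisson spike process at small bin width. The *spike response function*
(SRF) $R_{ic}(s)$ is the increment that a spike of source neuron $c$ adds
to $i$'s propensity $s$ bins later; the history sum runs over all neurons
including $i$ itself (the self-history row), which is fitted like any other
but excluded from connectivity reporting.

Each SRF is a linear combination of $K$ smooth Gamma-density bases,
$R_{ic}(s) = \sum_k A_{ick} B_k(s)$ with $B_k(s) = \mathrm{Ga}(s;\,
m_k, v_k)$ and $m_k = v_k = k^2/2$ bins. Small $k$ gives a sharp,
short-latency filter; large $k$ a broad, slow one. A practical default is
$K = \lfloor\sqrt{2M}\rfloor$, the largest index whose mean lag stays
inside the window; `make_gamma_basis()` uses it when `K` is omitted. An
identity ("raw-lag") basis with $K = M$ is available for the classical
likelihood-ratio chi-square test.

Fitting maximizes the regularized log-likelihood
$\sum_t L^i_t - \eta\,\mathrm{Reg}^i$ per target neuron, where
$\mathrm{Reg}^i$ is the L2 penalty $\tfrac12 \sum A_{ick}^2$
(non-sparse), the L1 penalty $\sum |A_{ick}|$, or the group lasso
$\sum_c \lVert A_{ic\cdot} \rVert_2$ (group-sparse over source neurons).
The baseline and external-input coefficients are never penalized. The sum
over $t$ starts at $t = M+1$ so that every evaluated bin has a full
history window; this sacrifices $M$ bins but avoids edge bias.

## Optimization and numerical choices

* The smooth (L2) objective is maximized by damped Newton iterations with
  step halving; convergence is declared at a relative objective change
  below $10^{-8}$ together with a vanishing gradient. The problem is
  concave for both links, so the optimum is unique.
* The nonsmooth penalties use FISTA (proximal gradient with Nesterov
  momentum), backtracking line search and adaptive restart. Along a
  hyperparameter path, fits are warm-started from the neighbouring
  $\eta$, which cuts iteration counts several-fold.
* Likelihood-ratio null refits (one per directed pair, with the source's
  loadings forced to zero) are warm-started from the alternative optimum
  and solved by a fixed-metric Newton method that reuses the alternative
  fit's information matrix, with a full-Newton fallback; refits agree
  with from-scratch optimization to $10^{-6}$ on the LR scale.
* Per-parameter asymptotic standard deviations come from the inverse
  observed information of the smooth part of the objective at the
  optimum (the Wald construction behind confidence intervals and the
  MaxZ statistic). For the raw-lag basis, the rule MaxZ $> 1.96$ is
  exactly the "some 95% CI excludes zero" rule; for smooth bases MaxZ
  mixes the per-weight Z-scores through the (nonnegative) basis profiles.
* The total response is clamped to $[-30, 12]$ before the link, and
  log-probabilities are evaluated with `log1p`/`expm1` forms.

## Statistics and significance procedures

For each ordered pair the package computes the likelihood ratio
$\mathrm{LR} = -2(\ln L_0 - \ln L)$ (unpenalized log-likelihoods at the
penalized optima; small negatives from finite tolerances are floored at
zero), and the shape statistics Surface $\sum_s |R(s)|$, Peak
$\max_s |R(s)|$, Delay $\arg\max_s |R(s)|$ (ties to the smallest lag;
descriptive, not a test statistic), the metric-weighted norm MD with the
ridge-regularized inverse covariance of known-null loading vectors
(ridge fraction 0.05 of the mean eigenvalue), and MaxZ.

`run_test_suite()` exposes five significance procedures. CHI2 refers the
LR to a chi-square with degrees of freedom equal to the number of
constrained parameters — $K$, which equals $M$ for the raw-lag basis; it
needs no surrogates. DOF refits the degrees of freedom to surrogate-null
LR statistics by the method of moments (the chi-square mean identity),
with maximum likelihood as an option. The empirical Bayesian procedures
(EB-LR, EB-regularized-LR, and EB on any shape statistic) estimate
q-values directly from surrogate null samples.

Surrogate neurons are circular time shifts of real spike trains by
uniformly drawn offsets in $[2M, T - 2M]$ — large enough that the copy is
independent of every real neuron at model lags, and wrap-around preserves
length and spike count. Surrogates are appended to the population and
participate in the fits exactly like real neurons (as sources; they are
not fitted as targets). The number of surrogates targets about 300 null
pairs; pairs whose surrogate is a shifted copy of the destination itself
are excluded from the null set to avoid autocorrelation contamination.

The direct q-value estimator is a two-group tail ratio: with
$\hat F_0(s) = (1 + \#\{\mathrm{null} \ge s\})/(n_0 + 1)$ (add-one
correction, so no q is exactly zero) and
$\hat F(s) = \#\{\mathrm{real} \ge s\}/n$,
$q(s) = \min(1, \hat\pi_0 \hat F_0(s) / \hat F(s))$, made monotone by the
running minimum over all weaker thresholds. $\hat\pi_0$ is the median,
over a grid of lower null quantiles, of the observed-to-null mass ratio
below the cutoff, capped at 1; it can be overridden by a constant. Local
false discovery rates use Gaussian kernel densities with a shared
Silverman bandwidth. Because only tail counts enter, the q-values are
invariant under strictly monotone transforms of the statistic.

## External-input estimation

Shared slow drive is estimated by smoothing each observed neuron's train
with a moving average (default window 20 bins), eigen-decomposing the
$C \times C$ covariance of the smoothed densities over time, and taking
the leading component scores as candidate channels, sign-aligned with the
mean population density and z-scored. The channels fed to the GLM are
built from *trailing* (causal) windows — the current and future bins of a
neuron never enter the regressors that predict it. With a centered window
the target's own spike appears inside its regressor and the apparent
likelihood gain of every channel is inflated by orders of magnitude; the
exported `smooth_spikes()` keeps the centered default for descriptive
use and offers `align = "trailing"`. The number of channels is chosen by
AIC in the "log-likelihood minus number of free parameters" convention
(larger is better), fitting the population GLM with $0, 1, \ldots,
L_{\max}$ leading channels; channels are estimated once and held fixed.

## The simulators and their calibration

`simulate_network()` draws Bernoulli spikes sequentially through the
generating link (complementary log–log by default), accumulating
presynaptic kernels, per-neuron private Poisson-input events and shared
signals into the total response. The 15-neuron benchmark
(`build_experiment1_network()`) wires three groups of five in a loop —
ten excitatory connections placed at random among the 25 ordered pairs
from G1 to G2, ten more from G2 to G3, and ten inhibitory from G3 to G1 —
with independent 50–150 Hz private Poisson inputs and 200 Hz sampling.

The generating kernel is a unit-peak Gamma(shape 2, rate 0.4) profile
over 20 lags (peak near 10 ms, tail to 100 ms), so a connection weight
equals its SRF peak. The calibration fixes $w_\mathrm{exc} = +3$,
$w_\mathrm{inh} = -8$ and per-group firing-rate targets of
(1.65, 1.1, 1.6) spikes/s, enforced by a damped fixed-point adjustment of
the baselines against simulated rates averaged over replicate runs (12
iterations of two 50,000-bin simulations with fixed internal seeds;
averaging matches the arithmetic-mean rate, where adjusting against single
noisy realizations would match the geometric mean and leave bursty neurons
above target); realized per-neuron rates over five-minute stretches fall
in the 0.6–2 spikes/s band. The slow kernel tail and the top-of-band rates for the
inhibition's sources and targets are what make suppressive connections
statistically visible: inhibition is only informative where the target
would otherwise fire. Under these conditions the best-hyperparameter
Surface-statistic AUC is ≈1.0 at $T = 10{,}000$ for both L2 and group
lasso, and ≈0.83 (L2) versus ≈0.80 (group lasso) at $T = 2000$, with L2
much flatter across $\eta$ — the qualitative regime of interest, reached
from the published firing-rate band rather than from generating weights,
which are not public.

The partial-observation scenario (`build_experiment3_scenario()`) adds
one slow Ornstein–Uhlenbeck shared signal (time constant 1000 bins = 5 s)
with positive couplings drawn from $U(0.8, 1.0)$, recalibrates baselines
with the drive active, marks 7 of the 15 neurons unobserved, and labels
each ordered observed pair by the shortest generating path whose
intermediate nodes are all unobserved (direct, one interneuron, two or
more, or none).

The generators emulate binary binned spiking with known ground truth,
stationary rates, linear superposition of kernel effects and
conditionally independent bins. They do not emulate refractoriness or
bursting, nonstationary excitability, measurement artifacts (imaging
noise, spike-detection jitter), or non-GLM dynamics, so green tests here
speak to statistical behaviour under the model class, not to robustness
against those features.

## Problem sizes used by the test suite

The test suite runs the full pipeline at reduced replicate counts chosen
to keep the default run short: perfect-detection checks on 3 seeds at
$T = 50{,}000$; best-AUC checks on 4 seeds at $T = 10{,}000$ and 20 seeds
at $T = 2000$; FDP conservativeness on 8 replicates at $T = 2000$ and 5
at $T = 10{,}000$; chi-square calibration pooled over 3 simulations at
$T = 20{,}000$; and one partial-observation analysis at $T = 100{,}000$
(scaled down from a 400,000-bin design). The acceptance script re-runs
the headline quantities at the same sizes with seeds derived from its
`--seed` argument.

## Known limitations

* **Surrogate exchangeability under strong coupling.** The empirical
  Bayesian q-values are conservative exactly when unconnected real pairs
  are exchangeable with time-shifted surrogate pairs. In a small, densely
  and strongly coupled recurrent network, unconnected pairs (reverses of
  true edges, two-step paths, within-group pairs sharing drivers) retain
  weak genuine dependence whenever the fitted kernels are biased — by
  heavy shrinkage (large $\eta$) or by basis truncation — and their LR
  tail is then heavier than the surrogate null's, so realized FDP can
  exceed the q threshold. With a full-capacity basis and mild
  regularization the control is exact in our simulations; with
  $\eta = 3$ on the calibrated benchmark it degrades. The same mechanism
  makes the DOF correction unsafe at very short $T$.
* **Chi-square asymptotics under sparse firing.** The chi-square law for
  the LR requires lag-coincidence counts well away from the discrete
  regime. At 0.6–2 spikes/s and $T = 20{,}000$, raw-lag coincidence
  counts average ~1–2 and the LR distribution is visibly lumpy; smooth
  bases pool across lags and come much closer, and the distance shrinks
  with $T$, but a Kolmogorov–Smirnov distance below 0.05 is not reached
  at that length. The DOF procedure exists precisely to absorb the
  residual mean miscalibration.
* **AIC with hidden strong drivers.** With seven unobserved, strongly
  coupled neurons, their collective activity is a real multi-channel
  common input, and AIC correctly prefers more than one estimated
  channel on the benchmark-derived scenario; the single-channel answer
  is recovered in the linear-coupling regime (weak modulation), as the
  unit suite demonstrates on an independent-neuron scenario.
* Circular shifting assumes no prominent periodicity at the shift scale;
  the moving-average/PCA channel estimator assumes the drive is slow
  relative to the smoothing window and enters the log-rate roughly
  linearly.
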