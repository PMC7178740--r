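---
title: "Bayesian posterior indices for the two-sample t-test: model, panel, and Monte-Carlo design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian posterior indices for the two-sample t-test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btindices)
```

## The model

`btindices` analyses a two-group comparison under the
Jeffreys–Zellner–Siow (JZS) model of the Bayesian t-test. Both groups are
normal with a common variance, $Y_{1i} \sim N(\mu + \sigma\delta/2,
\sigma^2)$ and $Y_{2j} \sim N(\mu - \sigma\delta/2, \sigma^2)$, where
$\delta = (\mu_1 - \mu_2)/\sigma$ is the standardized effect size. The
nuisance parameters get the objective priors $p(\mu) \propto 1$ and
$p(\sigma^2) \propto 1/\sigma^2$; the effect size gets a zero-centred
Cauchy prior $\delta \sim C(0, r)$ with one of the conventional scales
$r = \sqrt2/2$ (*medium*), $1$ (*wide*) or $\sqrt2$ (*ultrawide*).

Everything the model says about $\delta$ flows through a sufficiency
reduction: with the pooled two-sample statistic $t$, degrees of freedom
$\nu = n_1 + n_2 - 2$ and effective sample size
$n_\mathrm{eff} = n_1 n_2 / (n_1 + n_2)$, the sampling distribution of $t$
given $\delta$ is noncentral t with noncentrality
$\delta\sqrt{n_\mathrm{eff}}$. Two consequences:

* the Bayes factor is a ratio of one-dimensional integrals,
  $\mathrm{BF}_{10} = \int f_{\nu,\delta\sqrt{n_\mathrm{eff}}}(t)\,
  C(\delta; 0, r)\, d\delta \,/\, f_{\nu,0}(t)$, which `jzs_bf10()`
  evaluates by adaptive quadrature in three segments centred on the
  likelihood peak (so a mode far from zero cannot be stepped over);
* the posterior of $\delta$ is proportional to
  $f_{\nu,\delta\sqrt{n_\mathrm{eff}}}(t) \cdot C(\delta; 0, r)$, which
  `delta_posterior()` represents as a normalized density on a uniform
  grid.

The grid representation is a deliberate departure from MCMC-based
tooling: it removes chain noise entirely, so Monte-Carlo rate estimates at
a fixed seed are bit-reproducible and index computations are deterministic
functionals of the density. `posterior_draws()` exists only to emulate
draw-based decision rules (inverse-CDF sampling from the grid), not to
carry the inference.

The noncentral-t density itself is evaluated from the scale-mixture
representation $T = (Z + \lambda)/W$ with $W = \sqrt{\chi^2_\nu/\nu}$, by
48-node Gauss–Legendre quadrature over the central $1 - 2\times10^{-12}$
quantile range of $W$. This kernel is vectorized over the noncentrality —
one evaluation per grid point costs about a hundred flops — and is
validated against `stats::dt(ncp = )` in the test suite (absolute error
near 1e-11; relative error at the density peak ~2e-6, the accuracy floor
of the reference itself). Its absolute-error character means extreme tail
ordinates below ~1e-12 of the peak are not resolved relatively; all uses
here (normalized posteriors, marginal-likelihood integrals) are
insensitive to that.

## The index panel

For one dataset pair, `index_panel()` returns eight quantities:

| column | meaning | significance rule |
|---|---|---|
| `bf10` | JZS Bayes factor for $\delta \ne 0$ | $\ge 3$ |
| `rope95` | share of the 95% HPD interval's mass inside the ROPE $[-0.1, 0.1]$ | $\le$ tolerance |
| `rope_full` | posterior mass inside the ROPE | $\le$ tolerance |
| `pd` | probability of direction, $\max(q, 1-q)$ with $q = P(\delta > 0 \mid x)$ | minority mass $\le$ tolerance |
| `p_map` | posterior density at 0 over density at the MAP | $< 0.05$ |
| `ev_bar_flat` | FBST e-value against $H_0$, flat reference | $> 0.95$ |
| `ev_bar_cauchy` | FBST e-value, Cauchy-prior reference | $> 0.95$ |
| `p_welch` | Welch's two-sided p-value (frequentist reference) | $< 0.05$ |

Numerical choices that matter:

* **HPD interval.** A waterline bisection on the grid density: the
  smallest density threshold whose super-level set holds the requested
  mass. The posteriors of this model are unimodal, so the set is one
  interval; a multimodal input raises an error rather than silently
  returning a disconnected set's hull. Endpoints are interpolated across
  the waterline, so the $\pm 1.96$ benchmark of a standard normal shape is
  met to well under grid resolution.
* **"Completely outside the ROPE".** A Cauchy-tailed grid density never
  has literally zero mass in $[-0.1, 0.1]$, and "PD exactly 1" is likewise
  unattainable under a continuous density. Both rules are therefore
  operationalized with `outside_tolerance` (default `2.5e-4`, i.e. less
  than one draw in 4000 of the draw-based rule they emulate). The
  tolerance is a field of `significance_rules()` and can be set to 0 to
  recover the literal rule.
* **95% ROPE denominator.** `rope_fraction_95()` divides the
  HPD-intersect-ROPE mass by the nominal level 0.95 (the convention of
  draw-based ROPE tooling); `denominator = "captured"` switches to the
  mass the interval actually captured. The two differ by under one part in
  $10^4$ on these posteriors.
* **Tangential set.** The FBST surprise function uses a strict
  inequality, $s(\delta) > s(0)$; ties sit on a measure-zero boundary. Set
  boundaries are located by linear interpolation inside the crossing grid
  cell, which keeps the Gaussian closed-form benchmarks (`ev_bar`
  $= 2\Phi(2)-1$ for an $N(1, 0.5^2)$ shape, and the rest) to within
  1e-3 at the default grid.
* **MAP location.** Grid argmax refined by a three-point quadratic fit;
  `p_map` and `pd` move by less than 1e-4 when the grid is doubled.
* **Degenerate data.** Two groups that are constant and equal take the
  $t = 0$ path (the panel is well defined); constant but unequal groups
  raise a "degenerate variance" error, as no scale is identifiable.

The grid is auto-sized: centred on the sample effect
$t/\sqrt{n_\mathrm{eff}}$, widened until the boundary densities fall below
$10^{-8}$ of the peak (at least the central $1 - 10^{-6}$ of mass
covered), and failing loudly after five widenings. Single-dataset analyses
default to 4001 points; the simulation engine uses 2001 (the minimum the
posterior operations are specified for), which halves the per-replicate
cost and changes desk-scale rates by far less than their binomial error.

## What the generator emulates — and what it does not

`builtin_settings()` encodes the four study conditions: a null
(both groups standard normal, $\delta = 0$) and three heteroscedastic
effects with $\delta \approx -0.357$ (small: $N(2.89, 1.84^2)$ vs
$N(3.5, 1.56^2)$), $\delta \approx -0.646$ (medium: $N(254.08, 2.36^2)$ vs
$N(255.84, 3.04^2)$) and $\delta \approx -1.03$ (large: $N(15.01, 3.4^2)$
vs $N(19.91, 5.8^2)$). The standardizer is the root mean square of the two
group SDs; the second parameter of every $N(a, b)$ is read as a standard
deviation, including the noise term $N(0, \varepsilon)$ — that reading
makes the printed effect-size arithmetic of the settings come out exactly,
so it is applied uniformly. Group 1 always has the smaller mean, hence the
negative signs; `read_two_group_csv()` maps the first-appearing group
level to group 1 and reports the mapping, since the sign convention is the
user's to flip.

Note an intentional mismatch: the generating settings are
*heteroscedastic*, while the JZS model assumes a common variance (the
frequentist reference is Welch's test, which does not). The panel is thus
evaluated exactly where practitioners use it — mildly misspecified — and
the type-I/sensitivity rates measure the indices as used, not the model at
its best. What the generator does **not** emulate: non-Gaussian data,
unequal group sizes, correlated noise, or real-trial features such as
dropout and measurement floors. Passing rates here say nothing about those
regimes.

Noise is additive and independent per observation, so it leaves mean
differences unchanged and shrinks the standardized effect to
$\delta / \sqrt{1 + 2\varepsilon^2/(\sigma_1^2 + \sigma_2^2)}$ — the
mechanism behind every index's sensitivity loss in the noise arm.

## The Monte-Carlo engine

`run_grid()` crosses the settings with a sample-size grid
($n = 10, \dots, 100$ by 10, noise-free) and separately with a noise grid
($\varepsilon = 0.5, \dots, 5$ by 0.5 at $n = 30$), under each prior, with
10,000 replicates per cell by default. Per replicate: generate the pair,
reduce to $t$, compute the Bayes factor and the grid posterior, evaluate
the panel, apply the rules. The estimated rate is the share of significant
calls, reported with its binomial standard error
$\sqrt{\hat p(1-\hat p)/\mathrm{reps}}$.

Reproducibility is structural rather than procedural: replicate $k$ of a
cell is seeded by a deterministic 31-bit hash of (base seed, setting, $n$,
$\varepsilon$, prior label, $k$), so any replicate can be regenerated in
isolation, cells can run in any order or in parallel with identical
output, and a YAML manifest written next to every rate CSV suffices to
reproduce the table exactly. A replicate that fails numerically is redrawn
once with an offset-seed hash and counted; the run aborts if failures
exceed 0.1% (none occur under the built-in settings).

Desk-scale defaults in this repository: the analysis drivers use 500
replicates over $n \in \{10, 30, 50, 100\}$, the acceptance machinery
2000 replicates per checked cell and 300 for monotonicity sweeps — sizes
at which every qualitative conclusion of the full study is already stable
against 3-SE bands, while a full cell at 10,000 replicates runs in a few
minutes. The draw-count default of 4000 for `posterior_draws()` is a
convention (the draw-based tooling being emulated does not publish one)
and only enters through the `outside_tolerance` rationale.

## Design choices that were genuinely open

* **Reference implementation vs re-implementation.** The JZS integral
  could be delegated to an existing Bayes-factor package; it is instead
  authored here (it is the package's core) and verified against a
  brute-force two-dimensional quadrature over $(\delta, \log\sigma^2)$ of
  the full likelihood — an oracle that never touches the sufficiency
  reduction. Agreement is enforced at 1e-3 relative on random small
  datasets; observed agreement is ~1e-6.
* **95%-ROPE significance criterion.** Draw-based tooling can call
  "significant" either when the HPD interval is disjoint from the ROPE or
  when no retained draw lands in it. The HPD-disjointness version (via
  `rope95 <= outside_tolerance`) is the default here; the draws path is
  available through `posterior_draws()` for cross-checks.
* **Noise parameter.** $\varepsilon$ is an SD, not a variance (see above).
* **Prior-label coupling.** `prior_spec()` refuses a scale that
  contradicts its label, and infers the label from a bare scale, so rate
  tables can never carry a mislabelled prior.

## Limitations

* The panel is two-sided and point-null only: no one-sided Bayes factors,
  interval-null Bayes factors, paired designs, or the hybrid
  "Bayes factor versus ROPE" index.
* Published 10,000-replicate rates are reproduced within Monte-Carlo
  error only; the original study's RNG stream is not public, so bitwise
  reproduction of its tables (or of its single-dataset illustration
  values) is not possible in principle.
* The e-value here is the evidence *against* the null; asymptotic
  critical values for the FBST are not implemented (the study design
  uses the fixed 0.95 threshold instead).
* At extreme effects the informativeness ordering of the priors reverses
  (a wider prior holds more density at a distant mode); statements about
  the medium prior "accumulating evidence faster" are scoped to the
  study's effect range, $|\delta| \lesssim 1$.
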