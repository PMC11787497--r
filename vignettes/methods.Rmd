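---
title: "Models and methods behind tvadual"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tvadual}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvadual)
```

`tvadual` analyses masked single-target report experiments in which an
observer reports the location and/or the letter identity of a briefly
presented target. This vignette documents the models, the numerical
choices, and the boundaries of what the simulated cohorts can and cannot
establish.

## The psychometric model

Accuracy at exposure duration $t$ (seconds) follows a TVA-style encoding
race with a guessing floor:

$$
p(t) \;=\;
\begin{cases}
c, & t < t_0\\[2pt]
\bigl(1 - e^{-v (t - t_0)}\bigr) + e^{-v (t - t_0)}\, c, & t \ge t_0
\end{cases}
$$

with temporal threshold $t_0 \ge 0$ (s), processing speed $v > 0$
(objects/s), and guessing probability $c$ (1/12 here: twelve locations,
twelve letters, uniform guessing). The function is continuous at $t = t_0$,
nondecreasing in $t$ and $v$, nonincreasing in $t_0$, and confined to
$[c, 1)$. The model assumes a single target (no between-object
competition), no lapse parameter, and feature-unspecific guessing; these
are deliberate non-goals, matching the single-letter paradigm.

### Estimation

The fit minimises the binomial negative log-likelihood of per-duration
counts $(n_d, k_d)$ — trial order carries no information under the model,
so counts are the sufficient statistic. The tail probability is evaluated
in log space ($\log(1-p) = -v(t - t_0) + \log(1 - c)$), so the objective
stays finite even when $v\,(t - t_0)$ is large.

Numerical choices:

* **Search box** $t_0 \in [0, 0.150]$ s, $v \in [0.5, 500]$ /s. The upper
  $t_0$ bound sits above the second-longest canonical duration (129 ms) but
  below the asymptotic region, where the threshold would no longer be
  identifiable from an 11-point design; the $v$ box spans everything from
  near-flat to effectively instantaneous curves.
* **Multi-start grid** $t_0 \in \{0, 10, \dots, 120\}$ ms $\times$
  $v \in \{5, 10, 20, 40, 80, 160\}$ /s, with the best three starts refined.
  The likelihood is continuous but has a kink in $t_0$ wherever the
  threshold crosses a sampled duration, so refinement uses a Nelder–Mead
  simplex (derivative-free) on $(t_0, \log v)$, with excursions outside the
  box pulled back by a quadratic penalty. $t_0$ is continuous, not
  restricted to sampled durations.
* **Ties** between refined candidates break by lower NLL, then lower $t_0$.
* **Degenerate data** (accuracy at chance everywhere) drive $v$ into its
  lower bound; the fit is returned with `converged = FALSE` and the bound
  flagged instead of raising, so one flat observer cannot halt a cohort
  analysis.
* `chance` is fixed, never estimated: it is a design constant of the
  paradigm, and estimating it from 11-point data would trade bias for
  variance where the model already pins the floor.

The dual-report analysis fits each observer $\times$ feature $\times$
report-order cell separately (25 trials per duration per cell, required by
the 2$\times$2 ANOVA) and also pooled over order (for the headline feature
contrast); blocked data are fitted per observer $\times$ feature. Sessions
are pooled before fitting: the model treats them as homogeneous, and the
per-order cell already isolates the only order effect the design defines.
The "aggregate observer" curve is purely descriptive: the arithmetic mean
of the individually fitted parameters.

## Stochastic independence of the two reports

Per observer and duration, the four joint outcomes (location
correct/wrong $\times$ identity correct/wrong) give observed probabilities
$(p_{cc}, p_{cw}, p_{wc}, p_{ww})$. With marginals $a = p_{cc}+p_{cw}$ and
$b = p_{cc}+p_{wc}$, independence predicts $(ab, a(1-b), (1-a)b,
(1-a)(1-b))$ — marginals preserved exactly, cells summing to 1. Agreement
is summarised per observer as the Pearson correlation over the stacked
duration $\times$ cell vector, and the correlations are tested against zero
with a one-sample t test, Cohen's $d_z$ and the JZS Bayes factor.

Choices worth recording:

* All four cells enter the correlation vector by default; a two-cell
  variant (both-correct and both-wrong only) is available via
  `cells = "diagonal"` for sensitivity analysis. The four-cell vector is
  the more stringent summary since the off-diagonal cells are where
  coupling first shows.
* No Fisher z-transform before the group test: the test is reported on raw
  correlations, as is conventional for this descriptor; with near-1
  correlations a z-transform would only inflate the statistic.
* Duration cells with zero trials are dropped, not imputed; an observer
  whose probability vector has zero variance gets an `NA` correlation and
  is excluded from the group test with a warning.
* When probing the comonotone regime, "informative" durations are those
  whose marginals lie in $(0.2, 0.95)$: coupling acts on *encoding* events,
  and at chance-level or ceiling marginals the joint cell is dominated by
  independent guessing (or saturated), so no excess is detectable there
  even in expectation.

## Group-level statistics

* **t tests and $d_z$.** Paired tests run on differences; $d_z =
  \bar d / s_d = t/\sqrt n$ exactly. Zero-variance differences yield a
  degenerate flag, not an infinite statistic. All p values are two-sided.
* **JZS Bayes factor.** The default Bayes factor for a one-sample/paired
  $t$ under a Cauchy$(0, r)$ prior on the standardized effect, $r = 0.707$
  by default. It is computed as the Zellner–Siow mixture-of-$g$ integral,
  with the point-null likelihood folded into the integrand so only
  likelihood *ratios* are exponentiated, on the $\log g$ scale with a
  max-shift, via adaptive quadrature (relative tolerance $10^{-8}$). This
  keeps the computation stable for $|t|$ well beyond 250, where the BF
  exceeds $10^{12}$. BF01 is the reciprocal.
* **2$\times$2 repeated-measures ANOVA.** Own sums-of-squares
  decomposition (each effect tested against its subject-interaction error,
  df 1 and $n-1$; sphericity is moot at two levels). Generalized eta
  squared uses the fully-within convention: all subject-related variance
  components in the denominator. The convention matters — partial
  $\eta^2$ values from the same table can be several times larger — so it
  is fixed and documented. A literally zero effect sum of squares reports
  $F = 0$ even if the error stratum is also empty.
* **Holm follow-ups.** The follow-up family is the four
  location-vs-identity cell comparisons of the 2$\times$2 (both same-order
  and crossed-order pairs), adjusted together per parameter via the
  standard step-down rule (`stats::p.adjust`).
* **Within-subject CIs.** Cousineau normalization (remove each observer's
  mean, restore the grand mean) followed by the Morey correction
  ($M/(M-1)$ on the normalized variance), half-width $t_{n-1}$ critical
  value times the corrected SE. For $M = 2$ this makes each condition's
  half-width equal the paired-difference CI half-width divided by
  $\sqrt 2$ — the normalization halves the difference variance, the Morey
  factor doubles it back once. The intervals are invariant to adding any
  per-observer constant. A plain between-subject CI is available behind
  `method = "between"` for comparison.

## The synthetic-data generator

The generator emulates the two masked-report designs: eleven durations
(12–224 ms), twelve locations and twelve letters (`ABFGHJLMRSTX`), dual
report with counterbalanced order (25 trials per duration per order per
session, 550/session) or blocked report (50 per duration per session).
Targets are uniform; each feature's encoding event is Bernoulli with the
psychometric encoding probability; an encoded feature is reported
correctly, a non-encoded one guessed uniformly over all twelve
alternatives, so accuracy given no encoding is exactly $1/12$.

* **Dependence coupling.** `dependence_rho` mixes independent uniforms
  (probability $1-\rho$) with a single shared uniform compared against both
  encoding probabilities (probability $\rho$). Marginals are exact for
  every $\rho$; $\rho = 0$ is the independence regime the analysis assumes
  and $\rho = 1$ the comonotone extreme (joint success
  $\min(p_1, p_2)$). This device exists only to exercise the independence
  analysis; it models no known perceptual mechanism.
* **Random streams.** One master seed; each observer gets a substream
  derived deterministically from seed and observer index, so enlarging a
  cohort never perturbs earlier observers' trials.
* **Cohort defaults.** The analysis drivers simulate nine observers with
  location thresholds 10–25 ms versus identity 25–40 ms and location speeds
  25–40 /s versus identity 10–25 /s, independent encoding, four dual-report
  sessions (2,200 trials/observer) or two blocked sessions per feature
  (1,100 trials/feature). These sit in the plausible range for masked
  letter report with practiced adult observers and build in the
  location-advantage orderings at comfortably detectable magnitude.
* **What is not modelled:** perceptual confusability structure among
  letters or neighbouring locations, mask-similarity effects, eccentricity,
  eye movements, response times, lapses, and session-level learning or
  fatigue (sessions are homogeneous; the model pools them). Real location
  reports collected by mouse click are emitted here as discrete indices,
  sidestepping the scoring question entirely. Consequently, passing tests
  show that the estimation and inference machinery is correct under the
  model's own assumptions — not that real data satisfy those assumptions.

## Problem sizes and tolerances

The test suite works at deliberately chosen sizes: coupling marginals at
$10^5$ draws, accuracy-vs-curve checks at 2,500–5,000 trials per duration
(3-SD binomial bands), recovery at the blocked design's 50 trials per
duration per feature, the exhaustive grid oracle at 1 ms $\times$ 0.5 /s
resolution, ANOVA agreement to $10^{-9}$, quadrature cross-checks to
$10^{-5}$. These keep the full suite under a minute of compute while
leaving each check statistically sharp.

## Known limitations

* The threshold kink makes profile confidence intervals for $t_0$
  awkward; the package reports point estimates and group-level CIs only.
* With 11 durations and 25 trials per cell, $t_0$ and $v$ estimates are
  mildly correlated; per-order fits are noticeably noisier than pooled
  fits, which is visible in the ANOVA's error terms.
* The JZS Bayes factor is for one-sample/paired designs only; no Bayesian
  ANOVA is provided.
* The independence summary is a correlation, not a contingency test; a
  chi-square/log-linear alternative is deliberately out of scope.
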