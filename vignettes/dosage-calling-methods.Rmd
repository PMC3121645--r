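---
title: "Dosage calling for tetraploids: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage calling for tetraploids: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradose)
```

## The problem

Bi-allelic genotyping assays (GoldenGate, Infinium, KASP and similar) report
two intensities per marker and sample, one per allele. In a tetraploid, a
marker genotype is one of five allele dosages — nulliplex to quadruplex
(0 to 4 copies of allele a) — and the allele signal ratio
$f = s_a/(s_a + s_b)$ moves from 0 towards 1 as the dosage of a rises.
Because the two channels differ in background and sensitivity, the five
dosage classes do not sit at $0, \tfrac14, \ldots, 1$; they form five
marker-specific clusters. `tetradose` assigns dosages by fitting a
five-component normal mixture to the transformed ratios and only keeps
markers and samples whose assignment is statistically confident.

## The mixture model

Ratios are arcsine-square-root transformed, $y = \arcsin\sqrt{f}$, which
stabilises the variance that otherwise shrinks near 0 and 1. On the
transformed scale we model

$$ y \sim \sum_{j=0}^{4} \pi_j \, N(\mu_j, \sigma^2), $$

with a common standard deviation $\sigma$. The component means are not free:
they follow a parametric dosage-response. Writing $x$ for the dosage of
allele a, the expected channel signals are linear (optionally quadratic) in
the dosage, and the expected fraction reduces to

$$ \mu_x = \mathrm{asr}\!\left(
   \frac{c_1 + x + d x^2}
        {c_1 + x + d x^2 + c_2 + r(4-x) + r d (4-x)^2}\right), $$

with $c_1, c_2 \ge 0$ the channel backgrounds relative to the a-channel
sensitivity, $r > 0$ the b:a sensitivity ratio and $d \ge 0$ a relative
curvature shared by both channels (each channel's quadratic term is scaled
by its own sensitivity — the one genuinely open reading of the quadratic
extension; we use the shared-relative-curvature form and keep it isolated in
`mean_model()`). Four nested variants are fitted: model 1 ($c_1, c_2, r$),
model 2 ($c_1 = c_2 = c$), model 3 (adds $d$), model 4 ($c$ and $d$).

The mixing proportions are either free (four parameters) or constrained to
Hardy-Weinberg ratios $\binom{4}{x} p_a^x (1-p_a)^{4-x}$ with a single
allele frequency. Internally the HWE parameter `p` is the b-allele
frequency, so the nulliplex-a class has probability $p^4$; tables also
report $p_a = 1 - p$. Each of the 4 mean models is combined with both
proportion models: 8 variants per marker, compared by
$\mathrm{BIC} = -2\,\mathrm{LL} + k \ln n$.

## Fitting: EM with a weighted nonlinear least-squares M-step

The E-step computes posterior class memberships in log space (log-sum-exp).
The M-step updates proportions in closed form — column means when free; under
HWE the dosage-weighted binomial MLE
$\hat p = \sum_{ij} w_{ij}(4 - x_j)/(4n)$, which is the exact maximiser for
this constraint — and then re-estimates $(c_1, c_2, r, d)$ by weighted
nonlinear least squares. The weighted residual sum of squares separates into
a parameter-free within-component term plus a five-point problem in the
posterior masses and posterior-weighted class means, so the optimiser
(bounded quasi-Newton, warm-started from the current parameters) only ever
sees five residuals. $\sigma^2$ is the weighted RSS over $n$.

Numerical choices, all of which matter for reproducibility:

* **Convergence**: stop when the log-likelihood changes by less than `1e-6`,
  cap at 500 iterations. The M-step is guarded never to increase the
  objective, so the likelihood trace is non-decreasing up to that tolerance.
* **Start configurations**: (i) complete-linkage hierarchical clustering of
  $y$ cut at five groups (degenerate cuts padded by midpoint insertion);
  (ii) five equidistant means from 0.142 to 1.429, the transforms of ratios
  0.02 and 0.98. Start means seed the constrained model by unweighted
  least-squares projection onto the dosage-response family.
* **$\sigma$ floor** of `1e-4` (transformed scale) against spike components;
  $\sigma$ is initialised from the pooled within-group spread of the
  nearest-start-mean assignment.
* **Degeneracy guard**: a converged solution whose adjacent means lie closer
  than one fitted $\sigma$ has collapsed components — they are mutually
  unresolvable, no observation can reach a decisive posterior anywhere near
  them, and they arise as boundary drift of $r$ towards 0 or $\infty$ on
  low-information (near-monomorphic) markers. Such solutions are treated as
  numerical failures of that one fit, exactly like a $\sigma$ collapse.
* **Determinism**: no random numbers are used anywhere in fitting; both
  starts are deterministic functions of the data, so identical input yields
  bit-identical results.

## Marker selection

Per marker: (1) observations with total intensity
$\sqrt{s_a^2 + s_b^2} < 3200$ are dropped (a GoldenGate-specific default,
exposed as an option and skipped for ratio-only input); the marker is
abandoned if fewer than 60% of samples survive, or fewer than 10 samples
remain. (2) The 8 variants are fitted from both starts; the minimum-BIC fit
is provisionally selected. (3) If its simplex or triplex component has a
lower mixing proportion *or* fewer provisionally assigned samples than the
components on both sides — the signature of a component parked in the wide
gap that opens when $r$ is far from 1 — a third, "rescue" start is built by
shifting the component means one class across the gap (triplex checked
first; the simplex-side recipe mirrors the construction towards $\pi/2$;
one rescue round only) and the 8 variants are refitted from it. (4) Fits in
which an interior class has fewer assigned samples than some class on each
side (a "valley", impossible in a cross or HWE population) are discarded,
unless that would discard everything or the check is disabled. (5) The
minimum-BIC survivor is selected (ties broken by model id, HWE before free,
then start order). (6) Samples are assigned the maximum-posterior dosage
only above the 0.99 threshold. (7) The marker is rejected if fewer than 60%
of used samples were assigned, if $\sigma > 0.1$, or if more than 85% of
the *assigned* samples share one class. Each rejection carries exactly one
reason code, in that order of precedence.

## The simulator

`sim_config()`/`simulate_marker()` generate two-channel records with known
truth: dosages are drawn from HWE (or explicit) proportions, transformed
ratios from $N(\mu_x, \sigma)$ (default noise on the transformed scale,
which matches the fitted model exactly and keeps parameter-recovery tests
sharp), and each record gets a log-normal total intensity (median 10000,
CV 0.3) split across the channels at the drawn ratio. A raw-signal noise
mode (multiplicative log-normal noise per channel) exists to probe the two
approximations the transformed-scale model makes — the expectation of a
ratio is not the ratio of expectations, and the expectation of a transform
is not the transform of the expectation. Defaults describe a well-behaved
assay: $\sigma = 0.04$, model 2 with $c = 0.05$, $r = 1$, 224 samples.

Planted failure modes emulate the pathologies seen on real arrays:

* `monomorphic` — one dosage class only; rejected by the peak-dominance
  filter.
* `diffuse` — $\sigma = 0.25$, far above the dispersion cap; rejected for
  dispersion or call fraction.
* `wide_gap` — $r = 5$, so the quadruplex peak sits near $\pi/2$ far from
  the crowded lower peaks; the b-allele frequency is set to 0.1, leaving
  the nulliplex- and simplex-a classes — the ones beyond the crowded side —
  essentially empty; $\sigma$ is 0.035, a well-performing assay. The gap
  misfit is a start-configuration pathology, and these are the conditions
  under which it actually occurs: with no samples anchoring the lowest
  components, both generic starts settle in the shifted optimum whose
  triplex component sits in the empty gap, and only the rescue start
  recovers the correct fit. With populated tail classes, or diffuse peaks,
  the generic starts already find the right optimum and the rescue step is
  a no-op — on real arrays the misfit likewise affected only a minority of
  markers.

What the simulator does **not** reproduce: null alleles (extra off-class
clusters), batch or plate effects, between-sample intensity correlation, and
diploid contamination. Passing tests on synthetic panels therefore show the
algorithm recovers its own model class and applies the documented filters —
they cannot certify behaviour on artefacts outside that model.

## Problem sizes in the tests and acceptance script

The test-suite fits use 100-500 samples per marker and a handful of markers
per panel; the acceptance script uses 25 replicates per model variant at
n = 500 for parameter recovery, ten 224-sample clean markers for call
accuracy, five wide-gap/monomorphic/diffuse fixtures each, and a 24-marker,
224-sample panel for run-level statistics. These sizes give stable
statistics for the properties checked while keeping a full run to minutes on
one core.

## Known limitations

* The five-component structure is tetraploid-specific; other ploidies need
  a different component count and dosage map.
* A marker whose true $r$ is extreme (beyond roughly 20) has lower-dosage
  classes compressed within the noise and will usually fail the call-rate
  filter — correctly, but the rejection reason is then about calls, not
  about $r$.
* The HWE-constrained fit assumes a panel of unrelated individuals; in a
  structured cross the free-proportion variants carry the load, at a BIC
  penalty.
* Null alleles are not modelled and not flagged.
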