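---
title: "Modelling microbiome recovery after antibiotics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microbiome recovery after antibiotics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbimpulse)
```

## The model

A short antibiotic course is one of the strongest perturbations the human
microbiome experiences.  `mbimpulse` treats the community as a unit mass
resting in a *stability landscape* parameterized by a single state
variable — diversity — and models a course of duration $\tau$ much shorter
than the study length $T$ as an instantaneous impulse.  Near a stable
equilibrium any smooth potential is locally harmonic, so displacement
$x(t)$ from the baseline equilibrium obeys a damped oscillator

$$\ddot x + b\,\dot x + k\,x = D\,\delta(t),$$

with damping $b$, restoring strength $k$ and impulse magnitude $D$.  We
assume $b^2 > 4k$ (overdamped): no oscillatory recovery has ever been
observed in these communities.  Substituting
$b = e^{\phi_1} + e^{\phi_2}$, $k = e^{\phi_1 + \phi_2}$ makes both rate
parameters unconstrained *and* enforces overdamping by construction, since
$b^2 - 4k = (e^{\phi_1} - e^{\phi_2})^2 \ge 0$.  The recovery-only
solution ("Model 1") is

$$x_1(t) = \frac{D e^{\phi_1} e^{\phi_2}}{e^{\phi_2}-e^{\phi_1}}
  \left(e^{-e^{\phi_1}t} - e^{-e^{\phi_2}t}\right),$$

and the state-transition variant ("Model 2") adds a single asymptote
parameter,

$$x_2(t) = x_1(t) + A\,(1 - e^{-e^{\phi_1}t}),$$

so that $x_2 \to A$: the community settles in an *alternative stable
state* displaced by $A$ from baseline.  Sign convention: displacement is
positive when diversity is **below** baseline, so $A > 0$ is a transition
to a persistently lower-diversity (gut-dysbiosis-like) state and $A < 0$
to a higher-diversity state (the disease-associated direction in the oral
cavity).

Two numerical notes.  First, the amplitude prefactor in $x_1$ is the
product form with $e^{\phi_1}e^{\phi_2} = k$ in the numerator; this is the
parameterization in which all priors and reported posteriors are defined,
and it corresponds to the initial velocity $\dot x(0) = D\,k$ rather than
$D$.  The package deliberately implements this form verbatim — the ODE
test oracle therefore uses $\dot x(0) = D k$ — because "fixing" the
scaling would silently change the meaning of every fitted $D$.  Second,
$x_1$ is a 0/0 form at $\phi_1 = \phi_2$; whenever
$|\phi_1 - \phi_2| < 10^{-8}$ we switch to the analytic critical-damping
limit $D k t e^{-\sqrt{k}\,t}$, keeping the likelihood continuous for the
sampler.

The damping ratio $\zeta = b/(2\sqrt k) = \cosh((\phi_1-\phi_2)/2) \ge 1$
is an inherent property of the landscape and should be consistent across
perturbations of the same ecosystem; `summarize()` reports it from the
per-draw values.

```{r model-shapes}
p <- impulse_params(D = 8.45, phi1 = 0, phi2 = 0.56, A = 0.84)
t <- c(0.33, 1.33, 2.33, 4.33, 12.33)
rbind(model1 = model1_displacement(p, t),
      model2 = model2_displacement(p, t))
p$zeta
```

## From reads to displacement

Diversity is summarized as Faith's phylogenetic diversity (PD): the total
branch length of the subtree spanning the observed taxa (path to the root
included by default; `include_root = FALSE` gives the crown-only
convention).  To make PD comparable across unequal sequencing depths,
`bootstrap_pd()` rarefies each sample — subsampling reads *without
replacement* to a fixed depth — and averages PD over bootstraps (default
100, matching the study convention; default depth 1000 reads, chosen to
sit at the retention threshold).  Only subjects with a complete series of
6 samples, each with strictly more than 1,000 reads, are retained
(`filter_complete()`).

Displacement is defined per subject relative to the mean baseline PD:
$x(t) = \mathrm{PD}_{\text{baseline}} - \mathrm{PD}(t)$.  The baseline
point itself is excluded from fitting — its displacement is zero by
construction and would anchor the likelihood with an artificial
zero-residual observation.  Timepoint labels are mapped to months as
baseline $\to 0$, end of the 10-day course $\to 0.33$, then 1.33, 2.33,
4.33 and 12.33 months from treatment start; the study never states
numeric coordinates, so this mapping is configurable.

## Bayesian fitting

Each treatment group $\times$ body site is fitted by pooling all subjects'
displacements with one shared parameter vector and i.i.d. Gaussian noise,
$x_{ij} \sim \mathcal N(x_m(t_j;\theta), \sigma)$.  The original analysis
does not print its likelihood; this is the simplest form consistent with
pooled group fits, and per-subject random effects are explicitly left as
future work.  Priors are the non-informative boxes
$D \sim U(0,10)$, $\phi_1 \sim U(-1.99, 1.99)$, $\phi_2 \sim U(-2,2)$,
$A \sim U(-2,2)$, plus a weakly informative $\sigma \sim$ half-normal(0, 2)
(the original $\sigma$ prior is unpublished; this choice is flat over the
plausible 0–1 range of residual SDs and was fixed before any testing).

No Stan is available in the target environment, so `fit_group()` uses a
bespoke sampler on the unconstrained scale (logit for box parameters, log
for $\sigma$, with Jacobians kept so the posterior normalizer *is* the
marginal likelihood):

* an adaptive random-walk Metropolis kernel (Haario-style running
  covariance, Robbins–Monro scale tuning to 0.234 acceptance,
  diminishing adaptation continuing through sampling);
* a 20% mixture of independence proposals from the running
  moment-matched normal, which decorrelates slowly-mixing chains;
* an occasional $\phi_1 \leftrightarrow \phi_2$ swap move (a deterministic
  involution accepted at the constrained-scale posterior ratio).  Model 1
  is exactly exchange-symmetric in $(\phi_1, \phi_2)$, so its posterior is
  bimodal by construction; the swap move makes chains hop between the
  mirrored modes instead of stalling in one, and marginal summaries of
  $\phi_1,\phi_2$ should be read up to that label exchange.  Model 2
  breaks the symmetry only weakly through the $A$ term.

The protocol is the study's: 4 chains, 1000 burn-in, 9000 retained
iterations (each retained iteration composes several internal
sub-updates, a kernel choice, not a change of protocol).  A fit is flagged
`converged` only if every parameter has split-$\hat R \le 1.01$ and
effective sample size $> 1000$ (Geyer initial-monotone estimator on split
chains).  A fit that misses the contract is rerun up to twice with
deterministically derived seeds — the standard analyst response to a
failed set of chains, kept reproducible — and a fit that still fails is
reported as non-converged and refused by model selection rather than
silently used.

## Model selection

Evidence for a state transition is the Bayes factor
$BF = p(y \mid \text{Model 2}) / p(y \mid \text{Model 1})$, with $BF > 3$
read as positive evidence (Kass–Raftery).  Marginal likelihoods are
estimated by bridge sampling implemented from the Meng–Wong optimal-bridge
recursion: posterior draws are split in half, the first half fits a
moment-matched multivariate-normal proposal on the unconstrained scale,
and the fixed-point iteration (relative tolerance $10^{-10}$) runs on the
second half plus fresh proposal draws.  The Monte-Carlo SE comes from
bootstrap resamples of both weight vectors.  The estimator is validated
two independent ways in the test suite: against the closed-form
normal–normal conjugate evidence, and against adaptive 2-D quadrature of
prior $\times$ likelihood on a two-parameter toy (1% on the log scale).

## The synthetic world

`generate_dataset()` emulates the study design: 5 treatment groups
(placebo, ciprofloxacin, clindamycin, minocycline, amoxicillin) at 2 body
sites with the published group sizes (9–22 subjects), 6 timepoints, and
per-group generating parameters defaulting to the published
state-transition-model posterior medians.  Defaults chosen where no value
is stated, fixed once and not revisited:

* observation noise $\sigma = 0.4$ diversity units (visual residual
  spread of the published group fits);
* baseline PD across subjects: gut $\mathcal N(20, 2)$, oral
  $\mathcal N(15, 2)$ — typical Faith's PD magnitudes for 16S data at
  this depth, large relative to the biggest displacement ($D \approx 8$);
* read depths uniform on [1100, 20000], so defaults survive the
  $>1000$-read filter; a `dropout` option creates sub-threshold samples
  for filter tests.

`generate_otu_dataset()` additionally realizes each target diversity as
an actual OTU table: a random tree is drawn, and each sample's reads are
multinomial over the smallest nested taxon set whose PD best matches the
target.  What the generator does **not** emulate: taxon-level ecology,
compositional autocorrelation, or any longitudinal correlation beyond the
mean curve — so a green recovery test establishes that the estimator
recovers parameters under the model's own assumptions, not that the model
is true of real communities.

## The Lotka–Volterra connection

The two-state landscape assumes a perturbation can move the community to
a *different-diversity* stable state.  `sweep_glv()` asks how often small
generalized Lotka–Volterra systems
($\dot x_i = x_i(r_i + \sum_j a_{ij} x_j)$, $n = 3$) license that
assumption.  Fixed points are found exactly by support enumeration (solve
$A_{SS} x_S = -r_S$ on each of the $2^n$ supports), classified by the
Jacobian's leading eigenvalue (strictly negative $\Rightarrow$ stable;
$|\mathrm{Re}\,\lambda|_{\max} < 10^{-8}$ is "marginal" and excluded).  A
system is *two-state* iff it has $\ge 2$ stable non-negative equilibria
whose Shannon diversities differ, **and** an abundance-reducing
instantaneous perturbation from the highest-diversity stable state can
reach another stable state's basin (checked by RK4 integration from a
library of uniform scalings and species knockdowns).  Abundance scaling
preserves exact zeros — GLV cannot resurrect an extinct species — so in
practice a two-state system needs a stable state whose support is nested
in the high-diversity state's support, e.g. stable three-species
coexistence plus a stable single-species state.

Free parameters are the 3 growth rates and 6 off-diagonal interactions
(matching a $5^9$ full grid) with $a_{ii} = -1$; the default per-parameter
values $\{-1,-0.5,0,0.5,1\}$ are a declared assumption, since the original
grid and criterion are in unpublished supplementary material.  Under this
default the two-state fraction is *much rarer* than the published
$\approx 0.079\%$: the 10,000-cell subsamples measured by the acceptance
test typically contain no two-state cell at all (multistability of any
kind is already rare on this grid).  The published number should
therefore be treated as attainable only under the original (unknown)
grid/criterion; the acceptance test asserts subsample self-consistency
and an order-of-magnitude bound rather than the printed value.  Genuine two-state systems do exist off-grid (the test suite
freezes one found by random search over competitive parameter ranges).

## Numerical choices and degenerate inputs

* Critical-damping switch at $|\phi_1-\phi_2| < 10^{-8}$ (above).
* Negative times are rejected: the impulse defines $t = 0$.
* Rarefaction at full depth without replacement returns the whole sample,
  so the bootstrap SD is exactly 0 — used as a test invariant.
* Bridge sampling: proposal covariance is ridge-stabilized by $10^{-10}$;
  a proposal that never lands in the posterior's support fails loudly
  instead of returning a number.
* Fixed-point duplicates are merged at $10^{-9}$; singular support
  subsystems (no isolated equilibrium) are skipped.
* GLV integration uses fixed-step RK4 ($h = 0.02$) with a $10^6$ blow-up
  guard; diverging systems are flagged unbounded and classified
  not-two-state.
* All randomness flows from explicit integer seeds; the pipeline derives
  one sub-seed per group $\times$ site $\times$ model from its root seed,
  so re-running a configuration is byte-identical.

## Known limitations

Single shared $\theta$ per group (no subject-level random effects);
Gaussian noise without the bootstrap-SD measurement-error weights;
diversity as a one-dimensional state variable; underdamped dynamics
excluded by construction; the GLV sweep's grid/criterion are assumptions,
not reproductions.  These mirror the boundaries of the modelling framework
itself rather than shortcuts in the implementation.
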