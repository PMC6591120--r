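# mbimpulse

Stability-landscape impulse-response models of microbiome recovery after
antibiotics.

A short antibiotic course knocks the gut and oral microbiomes out of
their baseline state; diversity crashes and then slowly recovers — or
settles somewhere new.  `mbimpulse` makes the familiar
"ball-in-a-landscape" cartoon quantitative: the community is a unit mass
in a potential well parameterized by diversity, the course is an impulse
at `t = 0`, and the displacement `x(t)` from baseline follows an
overdamped harmonic oscillator

    x¨ + b x˙ + k x = D δ(t),    b = e^φ1 + e^φ2,  k = e^(φ1+φ2)

giving the closed-form recovery model

    x1(t) = D e^φ1 e^φ2 / (e^φ2 − e^φ1) · (e^(−e^φ1 t) − e^(−e^φ2 t))

and a state-transition variant `x2(t) = x1(t) + A(1 − e^(−e^φ1 t))`
whose asymptote `A` is a transition to an alternative stable state.
Fitting both per treatment group and comparing them with a Bayes factor
(BF > 3 = positive evidence, Kass–Raftery) turns "did the microbiome come
back?" into a model-selection question.

The package is aimed at microbiome researchers with sparse longitudinal
diversity data (a handful of timepoints over a year): it provides

* the closed-form models, their damping ratio
  `ζ = b/(2√k) = cosh((φ1−φ2)/2)`, and a numerical ODE oracle;
* Faith's phylogenetic diversity with bootstrap rarefaction from OTU
  table + newick tree, the study's completeness filter
  (6 samples, each > 1,000 reads), and baseline-relative displacement;
* Bayesian fitting by adaptive MCMC (4 chains, 1000 burn-in, 9000
  iterations; split-R̂ ≤ 1.01 and n_eff > 1000 required for convergence);
* marginal likelihoods by bespoke bridge sampling and Bayes-factor
  tables;
* a synthetic-data generator with the study's design and known ground
  truth;
* a generalized Lotka–Volterra scan estimating how often small
  (3-species) systems license the two-state assumption.

## Worked example

Simulate a clindamycin-like gut arm with a known state transition plus a
placebo arm, run the full pipeline, and read off the Bayes factor:

```r
library(mbimpulse)

groups <- data.frame(
  group = c("placebo", "clindamycin"), site = "gut", n = c(4L, 6L),
  D = c(0, 8.45), A = c(0, 0.84), phi1 = c(0, 0), phi2 = c(0.5, 0.56))
div <- generate_dataset(study_design(groups = groups, sigma = 0.4,
                                     seed = 21))$diversity
res <- run_analysis(run_config(mode = "diversity", out_dir = "results",
                               seed = 5), diversity = div)
res$bf_table
#>         group site    logml1    logml2       bf             label
#> 1 clindamycin  gut -35.87659 -23.51244 234252.4 positive evidence

subset(res$params, model == 2 & parameter %in% c("D", "A", "zeta"),
       select = c(parameter, median, lower, upper))
#>    parameter    median     lower     upper
#> 6          D 8.4538889 7.4404024 9.5859097
#> 9          A 0.7287615 0.4950452 0.9617334
#> 11      zeta 1.0134755 1.0000280 1.1353573
```

The simulated transition (`A = 0.84`) is recovered with an overwhelming
Bayes factor, the placebo arm is fitted with the recovery-only model
only, and the damping ratio sits just above critical damping — the regime
reported for real gut data.  `results/` then contains
`params_summary.csv`, `bf_table.csv`, `diagnostics.json` and `run.log`.

A command-line front end with the same functionality ships in
`inst/exec/mbimpulse` (subcommands `simulate`, `diversity`, `fit`,
`compare`, `glv-sweep`, `run-all`).

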