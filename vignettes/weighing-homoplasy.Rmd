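---
title: "Weighing trait-optimum homoplasy with multi-regime OU models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighing trait-optimum homoplasy with multi-regime OU models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ouhomoplasy)
```

## The question

When two clades independently acquire the same lifestyle — here the
motivating system is two squirrel clades (Marmotini and Xerini) that each
evolved fossoriality from arboreal ancestors — do their functional traits
evolve toward the *same* selective optimum?  Sharing an optimum
(trait-optimum homoplasy) is a different and stronger claim than having
similar trait values, which can arise from shared ancestry alone.
`ouhomoplasy` frames the question as a model-comparison problem on a
time-calibrated phylogeny and adds two safeguards that raw information
criterion scores lack: a specimen-resampling sensitivity filter and a
parametric-bootstrap power analysis (phylogenetic Monte Carlo).

## The model

Trait residuals evolve along the tree either by Brownian motion,

$$dX_t = \sigma\,dB_t,$$

or by an Ornstein–Uhlenbeck process pulled toward the optimum of the
selective regime painted on each branch segment,

$$dX_t = \alpha\,(\theta_{r(t)} - X_t)\,dt + \sigma\,dB_t .$$

With the root state fixed (the non-stationary formulation used throughout),
the tip expectations and covariances are

$$E[X_i] = X_0 e^{-\alpha T_i} + \sum_{\text{seg}} \theta_{\text{seg}}
  \left(e^{-\alpha (T_i - t_{\text{end}})} -
        e^{-\alpha (T_i - t_{\text{start}})}\right),$$

$$V_{ij} = \frac{\sigma^2}{2\alpha}
  \, e^{-\alpha (T_i + T_j - 2 t_a)} \left(1 - e^{-2\alpha t_a}\right),$$

where $T_i$ is the depth of tip $i$, $t_a$ the height of the pair's most
recent common ancestor above the root, and the sum runs over the regime
segments of lineage $i$.  The tips are jointly Gaussian, so the
log-likelihood is the usual multivariate-normal expression.  The rate of
adaptation is reported as the phylogenetic half-life
$t_{1/2} = \ln 2 / \alpha$, the time for a lineage entering a new regime to
cover half the distance to its new optimum.

### The six hypotheses

With a background regime and two derived-regime clades (A, the larger;
B, the smaller), six models span the biologically distinct scenarios:

| model | optima | interpretation |
|---|---|---|
| `BM1` | — | non-adaptive drift, single rate |
| `OU1` | 1 | every lineage tracks the ancestral optimum |
| `OU2_shared` | 2 | A and B share one novel optimum — **homoplasy** |
| `OU2_onlyB` | 2 | A retains the background optimum, B departs |
| `OU2_onlyA` | 2 | B retains the background optimum, A departs |
| `OU3` | 3 | A and B each evolve their own optimum |

Regime shifts are painted at the root of each derived clade's *stem*
branch (configurable per clade via `include_stem`), so the derived regime
begins when the lineage split from its sister group, not at the crown.
Every branch not claimed by a named clade — including any isolated lineage
that shares the derived lifestyle but is too small to support its own
optimum estimate — carries the background regime; monotypic clades are
paintable (`regime_clade("one_tip", ...)`) when a different choice is
wanted.

### Parameter counts and the root state

SIC $= -2\ln L + p\ln n$ needs an explicit parameter count.  By default
the root state equals the optimum of the background (root) regime, giving
$p = 2 + k$ for an OU model with $k$ optima ($\alpha$, $\sigma^2$,
$\theta_1..\theta_k$) and $p = 2$ for BM1 ($X_0$, $\sigma^2$).  A free-$X_0$
policy is available (`root_policy = "free"`), but note that on an
ultrametric tree the root weight $e^{-\alpha T}$ is the same for every tip,
so $X_0$ is confounded with a constant shift of the optima: the likelihood
maximum is unchanged and the extra parameter only pays an SIC penalty.  The
free policy is intended for non-ultrametric inputs (which the package
tolerates with a warning, using per-tip depths throughout).

## Fitting

At a fixed $\alpha$, the covariance is $\sigma^2 W(\alpha)$ and the
expectation is linear in the optima, so both nuisance blocks have
closed-form maximizers: the optima by generalized least squares,
$\hat\sigma^2 = Q/n$ from the GLS residual quadratic form.  Fitting an OU
model therefore reduces to a one-dimensional search over $\log\alpha$,
which we run from seven deterministic starts log-spaced over half-lives
from $0.01\,T$ to $10\,T$ ($T$ = tree depth) followed by Brent refinement
between the bracketing starts.  This profiled search finds the same maximum
as a joint optimization over $(\log\alpha, \log\sigma^2, \theta)$ — the
test suite asserts the equivalence — with far fewer likelihood
evaluations.  BM1 has a closed-form ML fit.  Numerical guards worth
knowing:

* $\alpha$ is searched within $[\ln 2/(100T),\ 10^4/T]$; an estimate at a
  bound is flagged in the fit's convergence status, never silently kept.
* $1 - e^{-2\alpha t_a}$ is evaluated with `expm1`; the naive form loses
  eight digits at small $\alpha$ and visibly corrupts the BM limit on
  trees with near-identical tips.
* SIC ties (within $10^{-9}$) break toward fewer parameters, then toward
  the fixed model order of the table above, so rankings are deterministic.
* Everything is ML, not REML, so SIC values are comparable between BM and
  OU families.

The likelihood core is compiled (RcppArmadillo); batch fitting shares one
Cholesky factorization per $\alpha$ start across all datasets of a
parametric-bootstrap batch, which is what makes the 5,000-dataset
comparisons of the full procedure tractable.

## The pipeline

`run_study()` executes the stages in their methodological order:

1. **Allometric residuals** — each ln-trait is regressed on ln body mass
   by OLS over the *full* species table (no phylogenetic correction;
   species means when several specimens exist).  Residuals are taken from
   the OLS fit; an optional residual-randomization permutation test
   reports significance without affecting the residuals.  Only afterwards
   are residuals pruned to the study tree — the regression-then-prune
   order matters and is asserted by a test.
2. **SIC scoring** of all six models per trait.
3. **Sensitivity filter** — to mimic single-specimen sampling, each of
   `n_replicates` (default 1,000) resampled datasets draws one value per
   species from Normal(observed residual, SD); all six models are
   re-scored and the SIC winner tallied.  The trait passes when the modal
   winner equals the empirical winner.  The SD defaults to one pooled
   ln-scale value estimated from species with two or more specimens (a
   ln-scale specimen SD transfers unchanged to the residual scale because
   the regression only shifts species means); per-species SDs are
   accepted.  The allometric regression is *not* re-run inside replicates
   — noise is added to residuals directly, a documented simplification.
4. **Advance rule** — the homoplasy model proceeds to pairwise comparison
   only if the sensitivity filter passed and it ranked first by SIC, or
   second behind `OU3` (the only more complex model).
5. **Phylogenetic Monte Carlo** — for each advanced trait and each
   alternative model: fit both models ($\delta_{\mathrm{emp}} =
   2(\ln L_{\text{focal}} - \ln L_{\text{alt}})$; the factor 2 is a
   convention and cancels in interval membership), simulate `n_sim`
   (default 5,000) datasets under each fitted model, refit both models to
   every dataset, and classify $\delta_{\mathrm{emp}}$ against the two
   95% percentile intervals: inside the focal interval only
   (`focal_favored`, "+"), inside both (`both_plausible`, "="), inside
   neither (`both_implausible`, "/"), or inside the alternative interval
   only (`alternative_favored`, "−").  The fourth case is included for
   completeness even though it is rarely seen in practice.  Refits of
   each model to its own simulations also yield percentile bootstrap CIs
   for every fitted parameter and a per-parameter reliability flag.

Intervals are two-sided percentile intervals with boundary values counted
as inside (`ci_type = "upper"` switches to a one-sided construction).

## The synthetic-study generator

`synthetic_study()` builds a complete, fully seeded analogue of the
motivating study design: a pure-birth background tree of 76 species with
two grafted monophyletic derived clades of 43 and 6 species (125 total),
depth 70 My, stem shifts at 24.5 and 31.3 My before present and crown ages
at 0.7 of the stem age; ln body mass evolving as BM
($\sigma^2 = 0.02$/My from a root at $\ln 400\,\mathrm{g}$) plus a +1
ln-unit offset for the large derived clade, so groups differ in mass range;
and traits built as allometric line (slope 1/3 on the ln scale, the
isometric expectation for linear skeletal measurements) plus an OU or BM
residual with known parameters, plus Normal specimen noise.  The default
trait is strongly informative: half-life 2 My, stationary SD 0.1, derived
optima 0.4 ln-units (4 stationary SDs) below the background.  An optional
block of extra background species is present in the trait tables but
absent from the study tree, exercising the regress-then-prune path.

What the generator deliberately does not emulate: measurement error
correlated across traits, fossil (non-ultrametric) tips, mass-dependent
slope differences between groups (interaction effects are excluded from
the design by construction), and character-dependent diversification.
Passing tests on synthetic studies therefore validate the inference
machinery, not the biological realism of any particular empirical dataset.

## Validation harnesses and problem sizes

The acceptance suite (and `scripts/acceptance.R`, which recomputes the
same quantities from scratch) runs at these sizes, chosen to give stable
Monte-Carlo estimates at desk scale:

* **Likelihood oracle** — 200 random instances of up to 6 tips; package
  lnL against expectations and covariances built by numerical integration
  of the OU kernel along root-to-tip paths, agreement to $10^{-8}$.
* **BM limit** — $|\ln L_{\mathrm{OU}}(\alpha = 10^{-9}) -
  \ln L_{\mathrm{BM}}| < 10^{-4}$ on 50 random instances.
* **Parameter recovery** — 100 replicates on the 125-tip default study:
  median absolute bias of the derived optimum below 10% of the separation,
  and 95% bootstrap CI coverage (100 refits each) within [88%, 99%].
* **Selection consistency** — 200 replicates under each of the six
  generators: the generating model is SIC-best in at least 70% (observed:
  well above 90% for all six); and on 50 BM-generated datasets the
  homoplasy model is never (≤ 5% of runs) `focal_favored` against BM1 at
  `n_sim = 500`.
* **PMC calibration** — 300 runs on a 48-tip study (a deliberate
  scale-down; interval calibration does not depend on tip count) with
  `n_sim = 500`: $\delta_{\mathrm{emp}}$ falls inside the focal 95%
  interval in 95% ± 3% of runs.  The reference distribution here is built
  at the *generating* parameters, the well-defined nominal-coverage
  target.  Intervals built from fitted parameters — what
  `pmc_compare()` does on empirical data, where truth is unavailable —
  are conservative: the bootstrap recentres on each dataset's own fit
  (we measure correlation ≈ 0.8 between $\delta_{\mathrm{emp}}$ and the
  refit centre), so their empirical coverage approaches 100%.  For the
  discrimination question this errs on the safe side: it makes
  `focal_favored` harder, not easier, to obtain.
* **Sensitivity filter** — zero specimen SD must give a 100% modal
  frequency; and a deliberately fragile trait (small clade's optimum
  halfway between the background and the large clade's optimum, specimen
  SD at 0.75× the main separation) must be dismissed because the modal
  resampled winner differs from the empirical winner.  This reproduces,
  mechanistically rather than by seed choice, the situation where
  single-specimen sampling noise overturns an SIC ranking: added white
  noise inflates the effective $\sigma^2$ and makes the extra optimum of
  the empirical winner no longer worth its SIC penalty.

## A worked miniature

```{r example, eval = FALSE}
library(ouhomoplasy)

st <- synthetic_study(
  n_bg = 28, n_cladeA = 14, n_cladeB = 6, seed = 101,
  configs = list(
    trait_config("homoplastic", model = "OU2_shared"),
    trait_config("conserved",   model = "OU1",
                 theta = c(background = 0, cladeA = 0, cladeB = 0)),
    trait_config("drifting",    model = "BM1")))

report <- run_study(st$tree, st$traits, st$mass, st$painting,
                    n_replicates = 200, n_sim = 500, specimen_sd = 0.05,
                    seed = 9)
report$scores          # 18 rows: 3 traits x 6 models, SIC-ranked
report$advance         # which traits reach the pairwise stage
pmc_symbol_table(report)   # the +/=/ / matrix for advanced traits
```

On this configuration the homoplastic trait is the only one that advances,
and its pairwise row typically reads `+` against BM1 and OU1 (the data can
discriminate) and `=` against OU3 (which nests the focal model and can
mimic it — exactly the ambiguity the power analysis is designed to
expose).

## Known limitations

* Single-trait models only; no trait-correlated (multivariate) OU, no
  multiple-rate BM, no per-regime $\alpha$ or $\sigma^2$.
* The regime history is taken as given (painted); the package does not
  reconstruct ancestral lifestyles or sample stochastic maps, though it
  exports SIMMAP-format paintings for interoperability.
* Percentile bootstrap CIs from self-simulations centre on the point
  estimate by construction; they quantify estimation spread, and the
  reliability flag catches pathologies (boundary estimates, skewed
  distributions), but they are not bias-corrected intervals.
* The sensitivity filter's "hypothetical populations" are Normal around
  the observed species value with a shared SD by default — the simplest
  reading of a single-specimen sampling model; per-species SDs can be
  supplied when replicate specimens exist.
* Replicate-level work runs serially; reproducibility comes from a single
  seeded stream per batch, recorded in every output.
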