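# ouhomoplasy

Macroevolutionary model comparison for **trait-optimum homoplasy**: did two
clades that independently acquired the same lifestyle evolve toward the
*same* selective optimum, or do alternative scenarios explain the data as
well?  The package was built around the classic two-fossorial-clade design
(a large and a small burrowing clade nested in an arboreal background, one
continuous size-corrected trait at a time) but is generic over any
two-derived-clade painting.

It is aimed at researchers doing phylogenetic comparative analyses of
continuous traits who want more than a single information-criterion table:
the pipeline couples likelihood scoring with a specimen-resampling
sensitivity check and a parametric-bootstrap power analysis, so "the
homoplasy model won" is only reported when the data and tree could actually
have discriminated it.

## The method in brief

Size-corrected trait residuals (OLS of ln trait on ln body mass over the
full species table, no phylogenetic correction, pruned to the study tree
*after* the regression) are modelled on a regime-painted time tree either
as Brownian motion or as an Ornstein–Uhlenbeck process

dX = α (θ_r(t) − X) dt + σ dB,

with the selective regime r(t) painted on each branch segment and shifts
placed at the root of each derived clade's stem lineage.  Six hypotheses
are fitted per trait — BM1, OU1 (one optimum), OU2_shared (both derived
clades share a novel optimum: the homoplasy model), OU2_onlyB, OU2_onlyA
(only one clade departs), OU3 (three optima) — and ranked by the Schwarz
information criterion, SIC = −2 lnL + p ln n.  The pull α is reported as
the phylogenetic half-life t½ = ln2/α.  Traits whose ranking survives the
sensitivity filter and place the homoplasy model first (or second behind
OU3) advance to pairwise phylogenetic Monte Carlo: simulate 5,000 datasets
under each of the two fitted models, refit both to every dataset, and
classify the empirical likelihood ratio δ_emp = 2(lnL_focal − lnL_alt)
against the two 95% bootstrap intervals (`+` focal favored, `=` both
plausible, `/` both implausible, `−` alternative favored).  The same
refits yield percentile bootstrap CIs for every fitted parameter.

A fully seeded synthetic-study generator (125-tip clade-structured tree,
body masses, specimen-level traits with known generating parameters)
makes every stage testable end to end without any external data.

## Worked example

```r
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
report
#> study_report: 3 trait(s) scored on 48 species (seed 9)
#>   advanced to pairwise comparison: homoplastic
#>   pairwise classifications:
#> # A tibble: 1 × 6
#>   trait       BM1   OU1   OU2_onlyB OU2_onlyA OU3
#> 1 homoplastic +     +     +         +         =
```

The trait generated with a shared derived optimum is the only one that
advances, and its SIC panel shows why:

```r
dplyr::filter(report$scores, trait == "homoplastic")
#>   model          p logLik   SIC  t_half  rank
#> 1 BM1            2   8.94 -10.1 NA          6
#> 2 OU1            3  15.0  -18.3 15.0        5
#> 3 OU2_shared     4  34.2  -52.9  1.22       1
#> 4 OU2_onlyB      4  20.8  -26.0 10.3        3
#> 5 OU2_onlyA      4  18.0  -20.4 10.7        4
#> 6 OU3            5  36.1  -52.8  0.0142     2
```

`OU2_shared` is SIC-best with a fitted half-life of 1.2 My (truth: 2 My on
this generator) and fitted optima 0.15 (background) vs −0.22 (derived;
truth: separation −0.4 around the regression-centred scale).  The
pairwise row reads `+` against BM1, OU1 and both single-departure models —
the data can discriminate those — and `=` against OU3, which nests the
homoplasy model and cannot be told apart at this signal strength: exactly
the ambiguity the power analysis exists to expose.  The drift-generated
trait is dismissed by the sensitivity filter; the conserved trait never
ranks the homoplasy model high enough.

Individual stages are available as plain functions (`fit_allometry()`,
`score_models()`, `sampling_sensitivity()`, `advance_rule()`,
`pmc_compare()`, `parameter_cis()`, `simulate_traits()`), and
`autoplot()` on a `pmc_result` draws the two ratio histograms with δ_emp
marked.

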