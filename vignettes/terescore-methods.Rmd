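---
title: "Scoring isoflavone mixtures relative to estradiol: the TERE model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring isoflavone mixtures relative to estradiol: the TERE model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terescore)
```

## The problem

Clinical trials of phytoestrogen supplements — soy or red-clover extracts
taken for post-menopausal complaints — use formulations that differ wildly in
which isoflavones they contain and in what amounts. Two trials can both
administer "100 mg of isoflavones" yet deliver potencies an order of
magnitude apart, because the individual compounds differ enormously in how
strongly they bind the estrogen receptors. Comparing such trials by total
milligrams is meaningless. `terescore` puts every formulation on a single
potency scale anchored to estradiol.

## The model

Each compound $i$ in a formulation has a daily intake $d_i$ (mg/day, as
aglycone equivalents) and a relative binding affinity $\mathrm{RBA}^{\alpha}_i$
and $\mathrm{RBA}^{\beta}_i$ at the alpha and beta estrogen receptors,
expressed as a percentage of estradiol's binding (estradiol = 100). The
per-compound contribution at one receptor is

$$ c^{r}_i = d_i \cdot \mathrm{RBA}^{r}_i / 100, \qquad r \in \{\alpha, \beta\}, $$

a theoretical, unitless quantity on the scale where 1 mg of estradiol
contributes 1 per receptor. The **Theoretical Efficacy** is the additive
total

$$ \mathrm{TE} = \sum_i c^{\alpha}_i + \sum_i c^{\beta}_i
   \quad (\text{combined mode}), \qquad
   \mathrm{TE}_\beta = \sum_i c^{\beta}_i \quad (\text{beta-only mode}), $$

and the **Theoretical Efficacy Related to Estradiol** expresses it as a
fraction of the estradiol reference activity of 100:

$$ \mathrm{TERE} = \mathrm{TE}/100 = 1/x, \qquad x = 100/\mathrm{TE}. $$

The reference 100 is definitional — it does not depend on an estradiol row
being present in the affinity table.

Because alpha-receptor activation is the channel of concern for
hormone-dependent tumour proliferation while beta-receptor activation
carries the intended benefits (bone, cardiovascular, CNS), the combined
total is also partitioned:

$$ \mathrm{risk\%} = 100 \frac{\sum_i c^{\alpha}_i}
     {\sum_i c^{\alpha}_i + \sum_i c^{\beta}_i}, \qquad
   \mathrm{benefit\%} = 100 - \mathrm{risk\%}, $$

and the absolute alpha total $\sum_i c^{\alpha}_i$ is reported as the
**alpha load**. The percentages answer "what share of the bound activity
sits on the risky receptor"; the load answers "how much absolute
alpha-channel activity does the dose carry" — two formulations with the
same ~2% risk share can differ three-fold in load, which is why both are
always reported and the load is deliberately left unclassified (no
defensible toxicological cutoff exists for it).

### Assumptions

The model is strictly additive: contributions scale linearly in dose and
sum across compounds. It therefore applies only where no synergistic or
antagonistic interaction between components is expected, and it ignores
pharmacokinetics entirely — absorption, entero-hepatic recirculation,
gut-flora conversion (e.g. of daidzein to the more potent equol in the
30–50% of people who carry the converting flora), sulfation and
glucuronidation. It is a screening and comparison statistic, not a
pharmacodynamic prediction.

## Tunable parameters

* **Affinity table** (`default_affinity_table()`): per-compound RBA
  percentages at both receptors. The packaged table carries the
  Fokialakis competitive-binding values for estradiol and the five major
  isoflavone aglycones, plus a proxy mapping glycitein onto daidzein
  (glycitein's affinities are not tabulated; its gut metabolism parallels
  daidzein's and its contributions are minor, so daidzein's values stand
  in). Any alternative published set can be supplied via
  `read_affinity_table()`; proxies must resolve in one hop so a
  substituted value can never propagate through a chain. Affinities are
  stored exactly on the printed percentage scale (0.860 means 0.860%);
  the division by 100 happens once, inside `receptor_contribution()`, so
  stored numbers stay digit-identical to their source. Estradiol's
  beta-receptor entry, published as "at most 100", is stored as 100 so
  the reference score is exactly defined.

* **Mode** (`combined`, the default, or `beta_only`): the published
  worked examples themselves use both conventions — tabulated mixture
  scores sum both channels, while the pure-genistein dose-threshold
  argument is consistent only with the beta channel alone. Both are
  therefore first-class; `combined` is the default because it is the
  convention of every tabulated mixture.

* **Relevance cutoff** (`threshold_denominator`, default 15.2):
  formulations whose TERE falls too far below estradiol's activity are
  unlikely to show measurable clinical bioactivity. The empirical anchor
  is the genistein dose–response for hot-flush reduction: 10 mg/day
  (TERE $1/22.8$, beta-only) showed no relevant effect, while 15 mg/day
  (TERE $1/15.2$) is the lowest dose with a significant effect. The
  published accounts are not self-consistent about the exact boundary —
  the rule of thumb is quoted as "at or below $1/15$ is too low", yet the
  minimum effective dose itself scores $1/15.2$, which is below $1/15$.
  We resolve this in favour of the concrete dose datum: the default
  cutoff denominator is 15.2, and the boundary is inclusive on the
  relevant side (`LOW` iff $x > 15.2$), so the minimum effective dose
  classifies as `POTENTIALLY_RELEVANT` and the ineffective 10 mg dose as
  `LOW`. The cutoff is a plain argument, so users preferring the literal
  round-number rule can pass `threshold_denominator = 15`. The
  classification is agnostic to mode: it sees only the denominator it is
  given.

* **Compound registry** (`default_compound_registry()`): molecular
  formulas for the five aglycones and their natural conjugates — the
  7-O-glucosides genistin, daidzin and glycitin and their 6''-O-malonyl
  (+C3H2O3) and 6''-O-acetyl (+C2H2O) esters. Intakes reported as
  conjugates are converted to aglycone-equivalent milligrams by the
  molar-mass ratio parent/conjugate (always in (0,1)); molar masses are
  computed from the formulas with 4-decimal standard atomic masses, never
  tabulated, so the formula is the single source of truth. Trial reports
  conventionally already state aglycone equivalents, so the per-component
  `is_aglycone_equivalent` flag defaults to `TRUE` and conversion is
  opt-in.

## Numerical choices

* The TERE denominator is always computed from the **unrounded** TE.
  Published renditions occasionally divide 100 by a pre-rounded total
  (e.g. $100/11.2 = 8.93$ where the unrounded total gives 8.91), which is
  why reproduction tests use a 1% relative tolerance rather than digit
  equality; unrounded is the only self-consistent rule.
* Zero-potency formulations (all affinities zero) score an explicit
  infinite denominator, `LOW` relevance and an undefined risk/benefit
  partition, rather than erroring at report level; `risk_benefit()`
  called directly on such a score raises a typed degenerate-formulation
  error.
* Compound names are canonicalized (lower case, hyphens/underscores and
  whitespace runs collapsed to single spaces), so `"Biochanin-A"` and
  `"biochanin a"` are one record; duplicate components merge by intake
  summation, which together with exact additivity makes scores invariant
  to component order and to splitting a dose across rows.
* Comparison reports rank by descending TE (larger TE = closer to
  estradiol), ties broken by label ascending; `sort = FALSE` preserves
  input order for row-by-row mirroring of a published table.
* Decimal parsing accepts only the period separator, deliberately
  locale-independent.
* Report rendering: contributions at 6 significant digits, percentages at
  1 decimal, alpha loads at 3 significant digits, TERE fractions as
  `1/x` with `x` at 2 decimals.

## What the fixtures emulate

`generate_fixtures()` regenerates, as plain CSV/YAML, every worked
example the method was demonstrated on: the two complementary 100 mg
daidzein/genistein assays, a 60 mg/day soy OTC extract, a red-clover
extract, a 60 g soy-germ preparation, nine clinical-trial mixtures with
their reported outcomes carried as opaque annotation strings, and the
10/15 mg pure-genistein dose pair. These are *inputs as published* —
intakes already in aglycone equivalents — so the fixtures exercise the
scoring path, the proxy rule and the reporting layout, but not the
conjugate-conversion path (covered separately by unit tests) and none of
the biology the model abstracts away. Passing the reproduction suite
shows the arithmetic matches the published worked examples; it says
nothing about how well additive receptor-weighted intake predicts
clinical outcomes. One caveat is inherited from the source material: the
red-clover score table as published is internally inconsistent (its
printed receptor totals are not the sums of its own printed per-compound
cells), so that fixture is held to the model's invariants, not to
printed digits. Likewise one printed alpha load (0.43 for the 48/24/8 mg
genistein/daidzein/glycitein mix) is reproducible only by rounding each
per-compound contribution to two decimals before summing; the package
does not do that, and reports 0.423.

Problem sizes are desk-scale throughout — formulations of one to six
compounds, tables of five records — so the full test suite and the
acceptance script each run in seconds; randomized invariant checks use a
few dozen generated formulations with intakes spanning 0.1–1500 mg/day,
the range seen across supplement trials.

## Known limitations

* Additivity is an assumption, not a finding; mixtures with plausible
  component interaction are outside the model's domain.
* Affinity values are supplied data. Published RBA sets disagree between
  assays and laboratories; no reconciliation is attempted — users choose
  a table and the report records its label.
* Aglycone conversion is mass-ratio based (mg to mg); molar (µmol)
  dosing conventions are not supported.
* The relevance cutoff derives from a single endpoint (hot-flush
  reduction) and a single compound's dose series; treating it as a
  general bioactivity boundary is an extrapolation, which is why the
  flag is named `POTENTIALLY_RELEVANT` rather than anything stronger.
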