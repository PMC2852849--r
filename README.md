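# terescore

Potency scoring for mixtures of estrogen-mimicking compounds.

Clinical trials of phytoestrogen supplements — soy or red-clover isoflavone
extracts taken for hot flushes, bone density or vascular endpoints — use
formulations that differ both in which compounds they contain and in what
amounts, and the compounds differ enormously in receptor binding (genistein
binds the beta estrogen receptor ~2000× more strongly than daidzein does).
Total milligrams is therefore a meaningless basis of comparison. `terescore`
puts any such formulation on a single potency scale anchored to estradiol,
for anyone designing, reviewing or comparing such trials or assessing
over-the-counter supplement compositions.

## The model

For compounds with daily intakes $d_i$ (mg/day, aglycone equivalents) and
relative binding affinities $\mathrm{RBA}^{\alpha}_i, \mathrm{RBA}^{\beta}_i$
(percent of estradiol's binding at the alpha/beta estrogen receptor):

- per-compound contribution: $c^{r}_i = d_i \cdot \mathrm{RBA}^{r}_i / 100$
- **Theoretical Efficacy**: $\mathrm{TE} = \sum_i (c^{\alpha}_i + c^{\beta}_i)$
  (or the beta channel alone in `beta_only` mode)
- **TERE** (Theoretical Efficacy Related to Estradiol):
  $\mathrm{TE}/100$, written $1/x$ with $x = 100/\mathrm{TE}$
- **risk / benefit**: the alpha and beta shares of the combined total, in
  percent (alpha binding is the tumour-proliferation concern, beta binding
  the intended benefit channel)
- **alpha load**: the absolute alpha total $\sum_i c^{\alpha}_i$
- **relevance**: scores at or above TERE $1/15.2$ (the score of the lowest
  genistein dose with a significant clinical effect) flag as
  `POTENTIALLY_RELEVANT`, lower scores as `LOW`.

The model is strictly additive — valid only where no synergy or antagonism
between components is expected — and deliberately ignores pharmacokinetics.
See the methods vignette (`vignettes/terescore-methods.Rmd`) for the full
account, including how conjugated intakes (genistin, daidzin, glycitin and
their malonyl/acetyl esters) are converted to aglycone equivalents by
molar-mass ratio.

## Worked example

A 100 mg/day mix of 25 mg daidzein + 75 mg genistein, scored against the
packaged affinity table:

```r
library(terescore)
f <- formulation("assay-1", data.frame(
  compound = c("daidzein", "genistein"),
  intake_mg = c(25, 75)))
score_formulation(f)
```

```
<tere_score> assay-1
  mode: combined
  compound intake_mg rba_alpha rba_beta alpha_contribution beta_contribution
  daidzein        25     0.031     0.02            0.00775             0.005
 genistein        75     0.860    43.90            0.64500            32.925
  TE: 33.58   TERE: 1/2.98 (denominator 2.978)
  risk: 1.9%   benefit: 98.1%   alpha load: 0.653
  relevance: POTENTIALLY_RELEVANT
```

Reading: the mix carries about a third (1/2.98) of the theoretical activity
of the estradiol reference, 98.1% of it on the beneficial beta channel.
Inverting the proportions (75 mg daidzein + 25 mg genistein) drops TE to
11.23 — TERE 1/8.91 — a three-fold potency difference between two trials
that would both be reported as "100 mg of isoflavones".

The same machinery works on files and from the shell
(`inst/cli/terescore`):

```sh
Rscript inst/cli/terescore fixtures /tmp/fx
Rscript inst/cli/terescore compare /tmp/fx/clinical_trials.csv --format text
Rscript inst/cli/terescore score /tmp/fx/genistein_doses.csv --mode beta_only
```

`fixtures` regenerates input files for all the published worked examples
(two complementary 100 mg assays, three trial extracts, nine clinical-trial
mixtures, the 10/15 mg genistein dose pair, and the default affinity table).

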