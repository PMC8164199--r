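---
title: "Grey relational characterization of multireceptor toxicity and derivative screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey relational characterization of multireceptor toxicity and derivative screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greytox)
```

## The model

`greytox` condenses a compound-by-receptor panel of acute aquatic toxicity
values (EC50/LC50 in mg/L, all strictly positive) into one comprehensive
characterization value per compound by grey relational analysis (GRA).
Unlike the common factor-ranking use of GRA — which averages grey
coefficients *vertically* to rank the influence of factors on an indicator —
this application averages *horizontally*: each compound is an indicator,
each receptor organism a factor, and the compound's degree summarizes how
close its whole toxicity profile lies to a fixed reference.

The reference sequence is the constant series at the acute-toxicity
classification boundary, $x_0 = 1.0$ mg/L (EC50/LC50 below 1.0 mg/L is the
"acutely toxic" classification). Because every column carries the same
units, no dimensionless pre-normalization is applied — and deliberately no
hook for one is provided; the statistic is defined on the raw
concentrations. For compound $k$ and receptor $i$:

$$\Delta_i(k) = |x_0 - x_i(k)|, \qquad
\xi_i(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                {\Delta_i(k) + \rho\,\Delta_{\max}}, \qquad
y_{0k} = \sum_i w_i\,\xi_i(k).$$

Each coefficient lies in $(0, 1]$ and equals 1 exactly when its difference
attains the governing minimum; degrees inherit $(0, 1]$. A degree of 1
therefore identifies the compound whose concentrations are closest to the
boundary — the least comprehensively toxic profile in the panel. The
statistic is a *within-panel* comparison: degrees are only comparable
between compounds scored in the same run.

## Parameters

* `reference` (mg/L, default 1.0): the classification boundary. Changing it
  re-anchors the whole analysis; values other than the 1.0 mg/L standard
  are supported but leave the "classification" interpretation behind.
* `rho` (dimensionless, default 0.5): the resolution coefficient in
  $(0,1)$ damping the maximum-difference term. 0.5 is the near-universal
  convention; smaller values stretch the coefficient range downward.
* `normalization` (default `per_sequence`): where $\Delta_{\min}$ and
  $\Delta_{\max}$ come from. See below.
* `weights` (default equal): receptor weights summing to 1. Equal weights
  make the degree the plain horizontal mean over the $n$ receptors.

### The normalization choice

The textbook grey coefficient uses double extremes,
$\min_i \min_k \Delta$ and $\max_i \max_k \Delta$, over the entire
difference matrix (`normalization = "global"`). The worked reference
tables bundled with the package, however, are only reproducible when each
comparison sequence uses its *own* extremes over compounds
(`per_sequence`): for the DEHP/fish cell the per-sequence form gives
0.7268 while the literal global form gives 0.6027. Which convention the
original analysts intended cannot be determined from their printed
equation alone, so the package defaults to `per_sequence` — the convention
that reproduces the published numbers — and keeps `global` as an explicit
mode; the acceptance suite asserts both the agreement of the former and
the divergence of the latter rather than resolving the ambiguity.

## Derivative screening

All screens reuse one statistic, `change_rate(old, new)` =
$(new - old)/old \times 100$, computed at full precision; the 2-decimal
display convention of the reports is a separate step (`round_half_up()`,
half-away-from-zero, matching the reference tables).

* **Stage 1** (`screen_activity_increase()`): a derivative passes when its
  estimated comprehensive characterization value exceeds the parent's by
  *strictly more than* the threshold (default 10 %); a tie at exactly the
  threshold fails, reading "more than" literally.
* **Stage 2** (`screen_multireceptor_reduction()`): computed on
  pEC50/pLC50 values ($-\log_{10}$ mg/L), so "toxicity reduced" means the
  p-value decreased, i.e. the effective concentration increased. The flag
  requires a strictly negative rate on *every* receptor.
* **Proportionality**: "the decline is close to 1:1:1:1" is quantified as
  the ratio of the largest to the smallest absolute per-receptor rate. No
  published cutoff exists, so the flag threshold (default 2.5, chosen so
  the least uniform decline the reference screen still treats as
  near-proportional, ratio about 2.35, passes) is advisory and always
  reported alongside the raw ratio. Mixed-sign or zero rates make the
  diagnostic not applicable rather than silently flagging.

## Property and model verdicts

* **Stability**: a total-energy change rate $\le 0$ passes outright; a
  positive rate passes only while strictly below 5 %, encoding the
  "improved or remained unchanged (small increase below 5 %)" reading.
  Note the sign subtlety: total energies are negative, so a derivative
  with a *higher* (less negative) energy shows a *negative* change rate.
  The verdict applies the change-rate arithmetic as the reference reports
  do.
* **Insulation**: the HOMO–LUMO gap change is reported, never thresholded —
  no published cutoff exists.
* **Existence**: lowest vibrational frequency $> 0$ (a real minimum).
* **POPs**: persistence is derivative half-life in air strictly above 48 h
  (two days). Percent changes of log Kow and log Koa are percent changes
  *of the logarithms* — unconventional (a ratio of logs, not of the
  underlying partition coefficients), but exactly the arithmetic of the
  reference tables; every verdict carries a note saying so.
* **Docking**: lower score = weaker binding; `all_weaker` requires every
  protein's rate strictly negative.
* **Reaction barriers**: $\Delta E = E_{TS} - \sum E_{reactant}$ with
  caller-declared units; no hartree/kJ·mol conversion is attempted.
* **Pharmacophore-model validation**: configuration cost $\le 17$
  (non-strict, "should not be greater than 17"), correlation $> 0.7$
  (strict), every per-compound $|error| < 2$. The total-minus-fixed cost
  gap is reported without a threshold. The per-compound error metric is
  not defined by a formula anywhere in the reference material; the signed
  max/min ratio — $+\,\hat a/a$ when the estimate $\hat a$ is at or above
  the observed activity $a$, else $-(a/\hat a)$ — was reconstructed from
  the printed fit tables. It reproduces the sign of all 14 printed errors
  and their magnitudes to within about 0.01; five rows differ by one unit
  in the second decimal because the source computed errors from unrounded
  estimates and printed the estimates rounded to two decimals (the two
  rows whose unrounded estimates are recoverable from the activity table
  confirm this). The strict two-decimal comparison is kept in the
  acceptance suite as an honest record of that display-rounding limit.

## Numerical choices

* No rounding anywhere mid-pipeline; the 6- and 4-decimal layouts of the
  written CSV reports are display formatting only.
* Fixture comparisons use absolute tolerance $10^{-3}$ for 4-decimal
  reference values and $5\times10^{-7}$ for 6-decimal ones. Reported
  change-rate cells are compared at the printed precision of each cell
  plus 0.01 percentage points, the slack induced by display-rounded
  inputs.
* A panel in which every value equals the reference has an all-zero
  difference matrix; the coefficient is undefined there and the package
  raises a degenerate-panel error rather than returning NaN.
* Matrices are keyed by receptor *id* throughout, never by column
  position; the bundled reference tables use a different column order than
  the panel file, and id-keying makes all comparisons order-proof.
* Panel invariants (positivity, uniqueness, no missing cells) are
  enforced at construction; `validate_tox_panel()` returns structured
  findings for auditing files without raising.

## The synthetic generator

`generate_panel()` emulates the numeric regime the pipeline assumes:
concentrations $10^{p_k + s_i + \varepsilon}$ with compound potencies
uniform on $[-5, -0.2]$ log10 mg/L, fixed receptor offsets, and normal
log10 noise (sd 0.15), clipped strictly below the 1.0 mg/L boundary. The
default offsets (green algae 0, daphnid +0.80, mysid −0.60, fish +0.78)
were set once from the median receptor ratios of the bundled panel, so
synthetic panels reproduce its sensitivity ordering — mysid most
sensitive — and stress the same per-column-extreme structure that
distinguishes the two normalizations. Clipping keeps the
monotone-remission property well-posed (a uniformly less-toxic derivative
can never leave the panel's domain); `clip = FALSE` allows unclipped
generation for robustness testing. One seeded stream drives each run, and
the generator restores the caller's RNG state.

What the generator does *not* model: any structure–activity relationship
(shifts are imposed, not predicted from chemistry), correlated noise
between receptors beyond the shared potency term, censoring or
non-detects, and measurement error structure of real ECOSAR predictions.
Passing property tests on synthetic panels therefore demonstrate the
*arithmetic and invariances* of the pipeline — bounds, scale invariance,
permutation equivariance, monotone remission, seed determinism — not
predictive validity on real chemistry.

Test and acceptance runs use deliberately small problem sizes (panels of
4–14 compounds, 3–4 receptors, a handful of seeds per property), which
this statistic comfortably supports: the estimator is deterministic, so
the property checks probe structure, not sampling error.

## Limitations

* The degree is relative to the panel and the reference; it is not an
  absolute toxicity scale, and adding or removing compounds changes the
  extremes and hence every coefficient.
* The comprehensive characterization inherits whatever bias the upstream
  EC50/LC50 predictions carry; the package consumes the values as given
  and performs no toxicity prediction of its own.
* The stage-1 screen compares pharmacophore-estimated characterization
  values whose printed precision varies between source tables; each stage
  takes its own table at face value, so small cross-table inconsistencies
  (e.g. a parent estimated at 0.7171 in one table and 0.72 in another)
  propagate as-is.
* Percent changes of logarithmic descriptors and of negative total
  energies are faithful to the reference arithmetic but need care in
  interpretation; the report notes flag the former.
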