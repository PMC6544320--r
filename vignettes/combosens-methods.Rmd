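---
title: "Scoring drug-combination sensitivity and synergy with combosens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug-combination sensitivity and synergy with combosens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combosens)
```

## The problem

High-throughput drug-combination screens usually test a drug pair on a full
factorial dose matrix and summarise the result as a *synergy* score — the
deviation of the observed effect from a null model of non-interaction. Two
things make that practice fragile. First, the full matrix is expensive in
cells, which rules it out for scarce patient-derived material. Second, synergy
alone is a biased selection criterion: a pair can deviate strongly from its
null model while never reaching a therapeutically useful level of inhibition.
Sensitivity (how much the combination actually inhibits) and synergy (how much
of that exceeds expectation) are different axes and should be scored together,
ideally on the same scale.

combosens implements a cross-design analysis that addresses both points. Only
one row and one column of the dose matrix are required — each drug titrated
over the partner fixed at its IC50 — and both a sensitivity score (CSS) and a
family of synergy scores (S) are computed from those two vectors, all in
percent-inhibition units. The full-matrix reference models (HSA, Bliss, Loewe,
ZIP) are also implemented, both to score factorial data directly and to define
a consensus ground truth against which the cross-design scores can be
validated.

## Dose-response model

Every curve is fit on log10 concentration $x' = \log_{10}(x)$. Combination
(foreground-over-background) curves use the four-parameter log-logistic

$$y = y_{min} + \frac{y_{max} - y_{min}}{1 + 10^{\lambda (m - x')}},$$

with fractional inhibition asymptotes $0 \le y_{min} \le y_{max} \le 1$,
midpoint $m = \log_{10}(\mathrm{IC}_{50})$ and slope $\lambda$. Monotherapy
curves use the same family with the bottom pinned at zero,
$y = a / (1 + 10^{b(c - x')})$. Responses arrive as percent inhibition
(viability tables are converted as $100 - \text{viability}$, without
clipping); they are rescaled to fractions and clipped to $[0,1]$ only at
fitting time, so raw out-of-range observations survive for QC.

The area under a fitted curve over the tested range $[c_1, c_2]$ has the
closed form

$$\mathrm{AUC} = y_{min}(c_2 - c_1) + (y_{max} - y_{min})\,
\frac{1}{\lambda}\log_{10}\!\frac{1 + 10^{\lambda (c_2 - m)}}
{1 + 10^{\lambda (c_1 - m)}},$$

and analogously for the monotherapy form. Both are validated against adaptive
quadrature to $10^{-8}$ relative error across the whole parameter box (the
acceptance suite draws 1,000 random parameter sets).

### Numerical choices

* **Optimiser.** Bounded least squares via L-BFGS-B with analytic gradients
  and five starts (midpoint at the three log-range quartiles plus the
  observation nearest the response midpoint, slopes 0.5/1/2, sign taken from
  the response-concentration covariance); the lowest-RSS start wins. No
  fitting procedure is prescribed by the scoring definitions themselves, so
  this is a package choice tuned for small (4–8 point) vectors.
* **Slope sign.** The box is $|\lambda| \le 20$ with the sign free; a
  decreasing monotherapy fit ($b < 0$) is kept and reported with a warning
  rather than forced monotone.
* **Degenerate data.** All-identical responses return an exact flat curve;
  fewer than two distinct positive concentrations is an error. If every
  optimisation start fails, the curve is flagged and its area falls back to
  trapezoidal integration of the observed points so a score is still defined
  for pathological blocks.
* **Stability.** $\log_{10}(1 + 10^u)$ is evaluated in log-space, and the
  monotherapy area uses a rearrangement that avoids catastrophic cancellation
  when the curve is essentially zero over the tested range. Below
  $|\lambda| < 10^{-6}$ the analytic slope-to-zero limit (half-span
  rectangle) is used; both guards are quadrature-checked.

## CSS: the combination sensitivity score

From a full matrix, `extract_cross()` keeps the row and column whose fixed
dose is closest to each drug's IC50 *on the log scale* (dose ladders are
logarithmic; an exact tie goes to the lower dose, with a warning). Each arm is
fit, integrated, and normalized as the proportion of its maximal possible
inhibition after discounting a noise floor:

$$\mathrm{AUC}' = \frac{\mathrm{AUC} - inh_{min}(c_2 - c_1)}
{(1 - inh_{min})(c_2 - c_1)}, \qquad \mathrm{CSS}_i = 100\,\mathrm{AUC}'.$$

`inh_min` defaults to 0.10: inhibition below 10% is treated as experimental
noise. A curve entirely below the floor would give a negative score; the
package clips the normalized area to $[0,1]$ (with a message), on the view
that sub-noise inhibition is a true zero. The two arms give CSS1 and CSS2 —
two estimates of the same quantity — and CSS is their mean. Their absolute
difference is a built-in consistency QC: `qc_filter()` fails blocks whose
difference *strictly exceeds* the threshold (default 10 CSS units), so a
difference of exactly 10 passes.

## S synergy scores and the reference models

Because CSS and the normalized monotherapy areas share the percent-inhibition
scale, synergy is a subtraction:

$$S_{sum} = \mathrm{CSS} - (\mathrm{AUC}_1 + \mathrm{AUC}_2),\quad
S_{max} = \mathrm{CSS} - \max_i \mathrm{AUC}_i,\quad
S_{mean} = \mathrm{CSS} - \tfrac12\textstyle\sum_i \mathrm{AUC}_i,$$

with $\mathrm{AUC}_i$ the monotherapy area normalized exactly like the CSS
(same `inh_min`, same scale) — the definitions do not spell out that
normalization, but without it the terms would not be commensurate.
$S_{sum} \le S_{max} \le S_{mean}$ always; $S_{sum}$ is the most conservative
and is the default for prioritization.

The four full-matrix references score each combination cell
$(x_1 > 0, x_2 > 0)$ and average over the matrix (margins excluded — their
scores are identically near zero for HSA/Bliss and would only dilute the
average), times 100:

* **HSA** $y_c - \max(y_1, y_2)$ and **Bliss** $y_c - (y_1 + y_2 - y_1 y_2)$
  use the observed (replicate-averaged) monotherapy margins.
* **Loewe** here is the dose-additivity form "a drug combined with itself":
  the expected effect is the fitted monotherapy response to the summed dose,
  $y_e = \tfrac12[f_1(x_1 + x_2) + f_2(x_1 + x_2)]$. The two evaluations
  coincide when the curves are identical, which is the model's premise; the
  mean keeps the score symmetric in drug labels. The classical implicit
  Loewe equation is deliberately not implemented.
* **ZIP** compares smoothed values: $y'_1, y'_2$ from the monotherapy fits,
  and $y'_c$ the mean of a row-wise and a column-wise four-parameter
  log-logistic fit through the full matrix, evaluated at the cell. The
  four-parameter form matters: along a row the partner's fixed dose lifts the
  bottom asymptote off zero, and a three-parameter fit could not represent
  even a perfectly non-interacting (Bliss-built) matrix, which must score
  zero. If one directional fit fails the other is used; if both fail the
  observed value is used and flagged.

A combination is consensus-**synergistic** when all four averages strictly
exceed +5, consensus-**antagonistic** when all four are strictly below −5,
and non-interactive otherwise. The ±5 band reflects replicate-level noise in
percent inhibition; it is exposed as an argument because published wordings of
the rule differ in sign and strictness, and the strict ±5 reading is adopted
here. `evaluate_s_scores()` then measures how well each S variant separates
the two consensus classes (rank-based AUROC with tie-averaged ranks; average
precision with tied scores processed as blocks), and `ss_prioritize()` flags
hits at or above the 75th percentile (linear-interpolation quantile) on both
the CSS and S axes.

## What the simulator emulates — and what it does not

`sim_spec()` describes a stated world chosen once to resemble a matrix-stage
confirmation screen of cytotoxic-like agents:

| parameter | default | why |
|---|---|---|
| monotherapy tops $a$ | 0.90 / 0.85 | high- but sub-maximal efficacy |
| slopes $b$ | 2 / 2 | steep, cytotoxic-like Hill slopes |
| IC50s | 1 and 2 (conc. units) | arbitrary scale anchors |
| dose grids | 4×4, half-log steps at offsets −1, −0.5, 0, +0.5 around each IC50, plus zero margins | IC50 is itself a tested dose, as in an IC50-anchored design; also avoids the log-equidistant anchor tie a grid symmetric around the IC50 would hit on every extraction |
| `noise_sd` | 0.066 | reported mean replicate sd of percent inhibition in large published screens, as a fraction |
| `n_replicates` | 4 | matrix-stage replicate count of such screens |

Combination cells follow the chosen reference model (Bliss, HSA or the
mean-evaluation Loewe — generator and scorer share one convention) plus an
injectable interaction `delta`; expectations are clipped to $[0,1]$ *before*
noise, and noisy replicates are not clipped, mirroring how raw screens report
out-of-range values. Everything is deterministic under `seed`.

The simulator does not emulate plate effects, drug-specific noise,
heteroscedasticity, or pharmacokinetics. A green stochastic test therefore
establishes that the scoring pipeline recovers known interactions under
Gaussian replicate noise on an IC50-anchored grid — not that it is robust to
systematic experimental artefacts. Note also that under the Bliss generator
the *absolute* $S_{sum}$ of a non-interacting block is not zero (the
background drug's contribution makes CSS exceed neither-monotherapy
additivity by a curve-dependent offset), so the stochastic checks are about
ordering and sign recovery relative to the injected effect, which is the way
the S scores are meant to be used.

## Feature harness

Drug combinations are featurised as the bitwise OR of their drugs' binary
target/fingerprint profiles; similarity-ensemble target predictions can be
pre-filtered with the strict published thresholds (Z > 20, Tanimoto > 0.4,
P < 0.01). `cv_harness()` reproduces the evaluation protocol: per repeat, a
random 70/30 split of combinations, 10-fold CV on the training side to pick
the learner configuration with lowest RMSE, then RMSE / R² / Pearson r / MAE
on the held-out side, summarised as mean ± sd over 20 repeats. Learners are
injected through a small fit/predict/grid contract — the published analyses
used off-the-shelf Elastic Net, random forests and SVMs, which this package
intentionally does not re-implement; the bundled closed-form ridge keeps the
tests dependency-light. R² is reported as 0 when the test responses are
constant.

## Known limitations

* The cross design measures sensitivity at the IC50 anchors; combinations
  whose interaction appears only at extreme dose ratios can be missed by
  construction.
* The Loewe score is the direct dose-additivity evaluation, not the implicit
  interaction-index solution; for drugs with very different efficacies the
  two diverge.
* The QC filter catches inconsistency between the two cross arms, not
  systematic bias affecting both arms equally.
* `cv_harness()` validates within one cell line; no molecular features of the
  cell lines are modelled.

```{r example}
spec <- sim_spec(model = "bliss", delta = 0.15, seed = 42)
mat <- build_matrix(simulate_matrix(spec))
syn <- matrix_synergy(mat)
rec <- extract_cross(mat, 10^spec$mono1$c, 10^spec$mono2$c)
cssr <- css_from_cross(rec)
s <- s_scores(cssr$css, syn$mono1, syn$mono2)
cssr
syn
unlist(s[c("s_sum", "s_max", "s_mean")])
```
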