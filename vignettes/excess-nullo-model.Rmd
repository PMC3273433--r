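---
title: "Modelling X-chromosome mis-segregation in a SPO11 bioassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling X-chromosome mis-segregation in a SPO11 bioassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullox)
```

## The generative model

A SPO11-deficient *Drosophila* female makes no meiotic DSBs, hence no
crossovers and no chiasmata, and her X chromosomes mis-segregate. We model
each oocyte as taking exactly one of three mutually exclusive fates:

* **normal** (probability `1 - d - l`): the four meiotic products all carry
  one X;
* **meiosis-I nondisjunction** (probability `d`): both homologs travel to
  one pole; the products carry X dosages (2, 2, 0, 0);
* **unrepaired-DSB loss** (probability `l`): one X is destroyed; random
  segregation gives products with dosages (0, 1, 1, 1).

The functional egg pronucleus is a uniform draw among the four products.
This single assumption reproduces the defining arithmetic of the assay: a
nondisjunctional oocyte yields nullo-X and diplo-X eggs at 1/2 each, a
loss-affected oocyte yields nullo-X at 1/4 and diplo-X never. Hence

$$p_\text{nullo} = \tfrac{d}{2} + \tfrac{l}{4}, \qquad
  p_\text{diplo} = \tfrac{d}{2}, \qquad
  p_\text{normal} = 1 - d - \tfrac{l}{4},$$

and for any $l > 0$, $p_\text{nullo} > p_\text{diplo}$: an excess of
nullo-X eggs is the signature of chromosome loss, which is what the assay
scores.

Fertilization by X or Y sperm (1:1) and zygote viability map eggs to six
zygote classes. With the default viability model — X0 sons and XXY
daughters fully viable, XXX and Y0 zygotes dead, normal XX/XY viable — the
survival-conditional scored classes are

$$P(\text{X0 son}) = \frac{d/4 + l/8}{Z}, \quad
  P(\text{XXY daughter}) = \frac{d/4}{Z}, \quad
  Z = 1 - \tfrac{d}{2} - \tfrac{l}{8}.$$

Treating fates as exclusive ignores oocytes that both nondisjoin and lose a
broken X; at the rates observed in the assay such joint events are
second-order and the three-class data could not identify them anyway.
Chromosomes other than the X are not modelled because the assay scores only
X classes.

One subtlety is worth recording: the *fertilization weight* of XXY
daughters, $d/4$, does not depend on $l$, but the *conditional frequency*
$\,(d/4)/Z$ rises slightly with $l$ because losses shrink the viable pool
$Z$. The property tests assert the invariant in its correct (weight) form.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `d` | P(meiosis-I X nondisjunction) per oocyte | — | estimated |
| `l` | P(unrepaired-DSB X loss) per oocyte | — | estimated |
| `p_x` | P(fertilizing sperm carries X) | 0.5 | Mendelian male segregation |
| `v_x0, v_xxy` | viability of exceptional zygotes | 1 | they are scored as adults |
| `v_xxx, v_y0` | viability of XXX / Y0 zygotes | 0 | classical inviability |
| `v_normal` | viability of XX/XY zygotes | 1 | reference class |

The assay never states whether X0/XXY survival is complete; full viability
matches the scoring scheme (only these two classes are counted as
exceptional) and is left configurable for sensitivity analysis. Viability
and sperm parameters are *not* co-estimated — with three observed classes
they are unidentifiable — so fitting holds them at these defaults.

## Estimation

Counts `(n_x0, n_xxy, n_other)` are multinomial. Because the model can
match the two observed frequencies exactly whenever `f0 >= f2`, the MLE is
closed-form:

$$\hat d = \frac{4 f_2}{1 + f_0 + f_2}, \qquad
  \hat l = \frac{8 (f_0 - f_2)}{1 + f_0 + f_2}.$$

When `f0 < f2` the loss rate is clamped to zero, flagged, and `d` is
re-estimated on the constrained edge (also closed-form, via the pooled
exceptional frequency); a numeric optimizer re-checks both cases and must
agree within 1e-8 in the interior. Counts implying `d + l > 1` are rejected
as inconsistent rather than silently projected.

Confidence intervals:

* **profile likelihood** (default, deterministic): invert the
  $\chi^2_1$ deviance cutoff on each rate, profiling the other by 1-D
  optimization; boundary-clamped rates get one-sided intervals with lower
  bound exactly 0;
* **parametric bootstrap**: multinomial resamples from the fitted model,
  percentile intervals, explicit seed required.

`compare_to_control()` reports two nested likelihood-ratio tests: separate
`(d, l)` per cross versus fully shared (2 df), and — because the scientific
question is specifically whether the *loss* rate increased — shared `d`
with separate `l` versus fully shared (1 df). The 1-df nesting was chosen
over the alternative reading (separate rates vs shared-`d`) because it
directly answers that question.

## Relation to the published chi-square test

The assay's tables test the excess count with a Pearson chi-square on the
2x2 table `[[excess, rest], [excess_control, rest_control]]`, without
continuity correction. That construction — the only one we found that
reproduces all four published P values to two significant figures — treats
`n_x0 - n_xxy` as if it were a binomial count out of `N`. The variance of a
difference of two multinomial counts is, however, of order
`n_x0 + n_xxy`, not of order `excess`, so the published test is markedly
anticonservative: for the strongest contrast in the packaged fixtures it
prints P ~ 7e-07 where the likelihood-ratio test gives P ~ 0.01. The
package deliberately provides both: `chi_square_excess()` reproduces the
published statistic exactly, `compare_to_control()` gives the model-based
assessment. The tier boundaries follow the published star convention, with
values exactly on a boundary assigned to the weaker tier.

Rounding of every reported percentage is half-up (ties away from zero),
one decimal for cross tables and whole percent for fertility — base R's
round-half-even would disagree on ties. Two published cytology percentages
(7.4% for 16/220 and 1.3% for 2/177) are inconsistent with their own
fractions; they are documented exclusions, and the self-consistent ones
(91%, 70%, 100%, 100%) are reproduced exactly.

## What the simulators emulate — and what they do not

`simulate_cross()` draws fertilized eggs per mother (Poisson, or
negative-binomial if a dispersion is supplied — mother-level heterogeneity
exists but is unreported, so Poisson is the default), classifies each egg
through egg fate, then sperm, then viability, and discards dead zygotes
before counting, mirroring the fact that only eclosing progeny are scored.
`simulate_fecundity()` applies the model's viable fraction `Z` times a
baseline egg-to-pupa survival (default 0.88, calibrating the
no-mis-segregation case to the fertility scale of the SPO11-proficient
control). `simulate_cytology()` is binomial per ovary with optional
beta-binomial overdispersion.

Defaults state the world of the real assay: ~100 mothers per cross with
~13 scored progeny each, cytology rate 0.074 over 2 ovaries of ~110
nuclei. Whether 13 progeny/mother reflects laying rate or scoring window is
unknowable from the source, so it is an explicit free parameter.

The generators do **not** emulate: larval-stage mortality structure (the
baseline survival is a single number), autosomal mis-segregation, DSB
timing or repair-pathway choice, clutch effects on class probabilities, or
scorer error. A green simulation-based test therefore establishes that the
estimator inverts *this* model at realistic sample sizes — not that the
model captures every feature of real fly data.

## Numerical choices

* Likelihood kernel treats `0 * log(0)` as 0 and returns `-Inf` for
  impossible observations (nonzero count in a zero-probability class).
* Interior re-maximization uses a softmax parametrization of the open
  simplex with Nelder-Mead at `reltol 1e-14`; the shared-`d` model uses
  L-BFGS-B on `(d, t1, t2)` with `l_i = t_i (1 - d)` so the box covers the
  constraint `d + l <= 1`.
* Chi-square tables with a zero margin get statistic 0 and P = 1 rather
  than 0/0; expected cells below 5 trigger a warning and a Fisher exact P
  reported alongside, never silently substituted.
* Negative excess counts are reported signed with a warning, and truncated
  at 0 only inside the contingency table, where a negative cell would be
  meaningless.
* LRT statistics are floored at 0 to absorb optimizer noise at the null.
* All simulators take one mandatory seed and use a single PRNG stream;
  `derive_seeds()` spawns child seeds (all below 2^31) for replicated
  designs.

## Limitations

* The two rates are identified only under the default sperm/viability
  assumptions; partial XXX viability, for instance, would bias `l̂`
  downward (some diplo-X eggs would surface as XXX daughters).
* Profile intervals rely on the asymptotic $\chi^2$ cutoff; at boundary
  fits they are one-sided by construction rather than mixture-calibrated.
* The type-I error of the 2-df likelihood-ratio test is validated by
  simulation at interior rates typical of the assay; very small `l` with
  frequent boundary clamping would need the mixture reference.
* Fecundity differences between genotypes beyond the aneuploidy load (e.g.
  transgene toxicity) are absorbed into the configurable baseline survival
  and not modelled mechanistically.
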