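---
title: "Composition-activity PLS modeling of protein hydrolysates"
author: "aapls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-activity PLS modeling of protein hydrolysates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aapls)
```

## The modeling problem

Enzymatic food protein hydrolysates are complex peptide mixtures whose
antioxidant potency is determined largely by their bulk amino-acid makeup
rather than by individual peptide sequences. `aapls` models antioxidant
activities (radical-scavenging percentages, ferric reducing power) as a
function of the percent amino-acid composition of such mixtures, using
partial least squares (PLS) regression — the standard chemometric tool when
descriptors outnumber observations and are strongly collinear.

Three descriptor families are supported, alone or combined into one
26-column block:

* **AA** — the 18 individual amino-acid percentages. Acid hydrolysis cannot
  distinguish Asn from Asp or Gln from Glu, so these are pooled as Asx and
  Glx.
* **gAA** — five physicochemical group sums: sulfur-containing
  (SCAA = Cys + Met), positively charged (PCAA = Arg + Lys + His),
  hydrophobic (HAA, ten residues), acidic (AcAA = Asx + Glx) and aromatic
  (AAA = Phe + Tyr + Trp).
* **z** — composition-weighted sums of the Hellberg 3-z amino-acid scales,
  `sum_zi = sum over amino acids of zi(X) * c_X`, where `c_X` is the
  percent composition. The weights `c_X` are used in percent units exactly
  as reported, not converted to fractions: the bundled reference group sums
  reproduce only from the unnormalised percentages, and a common factor of
  100 is absorbed by autoscaling anyway. The z1 score measures
  hydrophilicity, z2 steric bulk, z3 electronic properties; the pooled Asx
  and Glx records are arithmetic means of their constituent residues.

A bundled 16-sample panel of hempseed and pea protein hydrolysates and
fractions provides a realistic composition matrix; activity values are not
redistributable and can be attached from a user-supplied CSV via
`with_activities()`.

## Autoscaling

All descriptors and the response are centred and scaled to unit variance
before modeling (`autoscale()`), so every variable enters with equal a
priori weight. The sample standard deviation uses the `n - 1` denominator
(the chemometrics convention); since the same factor applies to every
column this affects no scale-free statistic (R-squared, VIP,
classification). A constant column is a hard error naming the column, not a
silent drop: descriptor blocks have fixed widths (18/5/3/26) and silent
drops would corrupt coefficient and VIP bookkeeping.

## NIPALS PLS1

`fit_pls1()` implements the NIPALS algorithm for a single response. Per
component the unit-norm weight vector is the normalised covariance between
the current X residual and the current y residual — for one response this
step is exact, not iterative, so no convergence tolerance exists. Scores,
loadings and y-loadings follow, and X (and y) are deflated by the rank-one
component fit. Coefficients on scaled data are `b = W (P'W)^-1 c`.

Two conventions are fixed for reproducibility:

* **Sign indeterminacy.** Each weight vector is flipped so its
  largest-magnitude element is positive. Latent directions are only defined
  up to sign; fixing the sign makes coefficients and VIP values identical
  across platforms and BLAS builds.
* **R-squared.** `R2(a) = 1 - SS_res(a) / SS_tot` on the scaled response,
  cumulative over components and non-decreasing by construction.

At full rank the PLS fit equals the least-squares projection; the test
suite verifies this equivalence against `lm.fit` on random instances, along
with score orthogonality and weight normalisation.

## Cross-validation and component selection

`cross_validate()` defaults to 7 exclusion groups assigned round-robin in
sample order ("venetian blinds"), with leave-one-out available. The
original software behind this family of models uses seven groups by
default; since the publication does not state the scheme, both are offered
and the default is documented here. Within each fold, centring and scaling
are recomputed on the training part only, so no information leaks from
held-out samples.

Per component, `Q2_a = 1 - PRESS_a / SS_(a-1)`, where `PRESS_a` is the
predictive residual sum of squares using `a` components (in full-data
scaled-response units) and `SS_(a-1)` the fitted residual sum of squares of
the previous component count. The cumulative statistic uses the product
rule `Q2cum = 1 - prod_a (PRESS_a / SS_(a-1))`, matching the conventions of
the standard chemometrics software family. `select_components()` keeps the
largest `A` whose every component clears a per-component limit (default
0.05); `A = 0` is a legitimate verdict meaning "no valid model".

## Permutation validity testing

`permutation_test()` refits the model on randomly permuted responses
(descriptors unaltered, same component count, same cross-validation
scheme). Straight lines are fitted by ordinary least squares through the
points (|correlation with the original response|, statistic) — including
the unpermuted model at correlation 1 — separately for the cumulative
R-squared and Q2. The intercepts at zero correlation estimate chance-level
fit and predictive ability; a model is valid when the R-squared intercept
is below 0.4 and the Q2 intercept below 0.05. Twenty permutations are the
default, the identity permutation is rejected, and a fixed seed makes every
draw reproducible. Whether the Q2 entering the permutation line is
cumulative or per-component is not fixed by convention; the cumulative form
is the default, switchable via `q2_type`.

## VIP and contributor classification

`vip()` computes, per descriptor,
`VIP_j = sqrt( p * sum_a SSY_a (w_ja)^2 / sum_a SSY_a )` with
`SSY_a = c_a^2 t_a' t_a` the response variance explained by component `a` —
the standard decomposition from scores and y-loadings on scaled data.
Squared VIPs average to 1 by construction, so 1 marks average importance.
Classification uses the conventional thresholds: strong above 1.0, weak
from 0.5 to 1.0, unimportant below 0.5. Boundary values (exactly 1.0 or
0.5) are assigned to the weaker class — the conservative choice where the
thresholds are quoted as open intervals. Contribution direction is the sign
of the scaled coefficient; a coefficient of exactly zero is reported as
sign "none". Within each class the cross-activity summary orders variables
by descending VIP, ties broken by the fixed descriptor column order (AA in
panel order, then the five groups, then the three z sums).

## The synthetic benchmark

`generate_compositions()` draws composition rows from a Dirichlet
distribution (gamma-ratio construction) scaled to exactly 100%. The
concentration weights default to the bundled panel's mean composition times
0.30, a total concentration of about 30, which at `n = 1000` spreads each
residue's range beyond the observed range of the real panel. The closure
constraint — and the collinearity it induces among amino-acid columns — is
deliberately preserved, because real composition panels obey it.

`generate_activity()` builds responses as linear functions of descriptor
values computed by the production descriptor code (never a duplicated
formula), plus Gaussian noise. Noise can be given as a standard deviation
or solved from a target explained fraction, so experiments can state a
planted R-squared of 0.7 directly.

`make_benchmark()` mirrors the shape of the real study: 16 samples, four
activities, one activity restricted to an 11-sample subset (an assay not
run on every sample). Each default truth plants one dominant and one
secondary group effect at a combined planted R-squared of 0.7, with the
dominant effect about twice the standardised magnitude of the secondary.
This ratio is a deliberate design choice for the recovery benchmark: with
16 samples, a 50/50 split of the explainable variance leaves both VIPs
straddling the 1.0 threshold by sampling noise alone, so neither planted
effect would be an unambiguous "strong contributor"; a dominant effect is
recovered as strong with the correct sign in ≈99% of replicate datasets,
and the secondary effect's sign in ≈97%.

### What the generator does not emulate

Real hydrolysate panels derive from a small number of parent proteins and
fractionation protocols, so their compositions vary along a few latent
directions (for example the strong antagonism between positively charged
and hydrophobic group sums, correlation about −0.76 in the bundled panel).
Dirichlet draws are nearly independent across residues apart from closure,
giving the synthetic X a higher effective rank. One visible consequence:
chance-level one-component R-squared for a permuted response is about 0.27
on the real 26-column block but about 0.55 on the synthetic one, so
wide-block synthetic models fail the R-squared-intercept criterion more
often than real ones. Statistical checks of the permutation machinery
therefore use the 5-column group block, where the two panels behave
comparably. Passing tests demonstrate the machinery's calibration under the
generator's assumptions, not the validity of any particular real-data
model. Assay chemistry (dose-response, absorbance kinetics) is not
simulated at all.

## Numerical choices and degenerate inputs

* Component extraction stops with an error if the remaining covariance
  norm falls below 1e-12 (rank exhausted) or if the requested component
  count exceeds the rank of the scaled X.
* Cross-validation caps the component count at what every training fold
  can support (fold size and rank), and refuses folds leaving fewer than
  three training samples — the minimum for autoscaling.
* A constant response, a constant descriptor column within a training
  fold, and mismatched descriptor labels are all named, immediate errors.
* Row sums of composition tables are checked against [95, 105]; the check
  warns by default and is promotable to an error, since partial panels may
  legitimately omit residues.
* Reports serialize to JSON with 17 significant digits, so round-trips
  reproduce every double bit-exactly.

## Problem sizes used in the shipped checks

The statistical checks in the test suite use the study's natural scale:
16-sample panels, 200 pure-noise replicates for the null behaviour of Q2
and component selection, 50 replicate benchmarks for permutation-test
calibration, and 100 for contributor recovery — enough for the rates being
asserted (bounds at 90-95%) to have standard errors of 1-3 percentage
points. The full suite runs in well under a minute.

## Known limitations

* Sequence information is out of scope by design: two hydrolysates with
  identical composition but different peptide sequences are
  indistinguishable to these models.
* Only single-response (PLS1) models are fitted; the four assays are
  modeled separately, as in the source study, and no multi-response or
  orthogonalised PLS variant is provided.
* The bundled panel carries no activity values; numeric replication of the
  original model statistics requires the user to supply the original
  activity measurements, for which `with_activities()` documents the
  expected layout. Fit R-squared is scheme-independent and can be compared
  directly; Q2 and permutation intercepts depend on the cross-validation
  scheme and permutation draws and should be compared at the level of the
  validity verdict.
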