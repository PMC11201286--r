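---
title: "NMS-E scoring, rank-correlation analysis, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NMS-E scoring, rank-correlation analysis, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmse)
```

## The scoring model

The Numerical Multi-Scoring System of Endometriosis (NMS-E) is a
preoperative, non-invasive severity assessment built from transvaginal
ultrasonography and pelvic examination. It is organised in three layers: a
*Physical Finding Map* (three 3x3 grids holding the raw findings), a compact
one-line *summary*, and the *E-score*, a single severity number. The E-score
is the sum of five component scores:

* **Cyst score** (0-10 ovarian, plus 0-6 tubal). Each ovary's endometrioma
  is measured by maximum diameter in cm to one decimal place (total of the
  maximum diameters when multi-cystic); the per-side score is the diameter
  rounded *up* to a whole centimetre, capped at 5 points, so
  $s = \min(5, \lceil d \rceil)$. A right 6.5 cm / left 2.4 cm pair rounds
  to 7/3 and scores 5 + 3 = 8. Non-endometrioma cysts are recorded with a
  one-letter initial but never scored. Each side with a visible tubal lesion
  (hydrosalpinx, pyosalpinx) adds 3 points.
* **Adhesion score** (0-10). The number of sliding-sign-positive sites among
  ten canonical locations (five cross-sectional: ovary-side wall,
  ovary-uterus and inter-ovarian spaces; five longitudinal: anterior and
  posterior uterine surfaces).
* **Pain score** (0-10). The maximum Numeric Rating Scale value over seven
  pelvic regions palpated around the cervix (numbered I-VII; region V is the
  pouch of Douglas).
* **Uterine score** (0-9 under the flat scheme). Retroversion (R),
  adenomyosis (A) and endometriotic nodules (E; deep hypoechogenic lesions
  at least 1 cm in diameter) each contribute 3 points. Myomas (M) are noted
  but never scored.
* **Rare score** (0 or 10). A flat 10 points when any rare-site disease
  (intestinal, bladder, ureteral, vaginal, cutaneous, umbilical, inguinal)
  is present.

Because tubal lesions and rare sites add points beyond the four core
components, the total has no fixed upper bound; the core components alone
span 0-39.

```{r}
e_score(worked_example_exam())
```

### Design choices in the scoring rules

Several details of the verbal scoring rules admit more than one reading;
this package fixes them as follows and treats the choices as part of its
contract.

* **Flat nodule term.** Under the flat (`"flat3"`) scheme, nodules score 3
  points *once* if any are present, regardless of their number. This keeps
  the uterine score within its stated 0-9 range (3 points per lesion
  *type*); the size-graded scheme is the one that scores nodules
  individually.
* **Size-graded bands.** The graded (`"sized"`) scheme scores each nodule
  by diameter band with half-open intervals $[1,2) \to 3$, $[2,3) \to 6$,
  $[3,\infty) \to 10$, cumulatively over nodules. Verbal descriptions of
  the band edges vary ("over 2 cm but under 3 cm" vs "between 2 cm and
  3 cm"); half-open bands give every diameter exactly one band, and the 2.6
  cm teaching-case nodule is unaffected.
* **Rare score is flat.** Multiple rare sites still score 10; a per-site
  cumulative mode is deliberately not offered, keeping one canonical score.
* **Cap order for multi-cystic ovaries.** Per side, raw diameters are
  summed first, then rounded up, then capped at 5. The per-side cap makes
  the combined 10-point ovarian cap automatic.
* **Rounding on ingest.** Diameters are stored to one decimal place
  (half-up). Pain values must be whole numbers; decimals are rejected
  rather than rounded.
* **Retroversion source.** A retroverted uterus scores 3 points whether
  detected on ultrasound or pelvic examination; the package does not
  distinguish the source.

## The summary notation

The one-line summary (grammar `nmse-summary/1`, this package's own dialect)
condenses an exam into:

```
Cy R6.5/L2.4 | Ad7/10 | P8@V | Ut A,E2.6 | Rare - | E=29
```

Cyst sizes appear per side (`-` when absent; a one-letter initial prefixes
non-endometrioma cysts; tubal lesions follow in parentheses, e.g.
`L-(h.s)`); then the adhesion count, the maximal pain with its region
numeral, the uterine lesion codes, rare sites, and the flat-scheme total.
The parser recomputes the total from the other fields and refuses
inconsistent strings, so a tampered `E=` cannot slip through. An optional
bracketed version tag (`[nmse-summary/1] `) is accepted and any other
version rejected, leaving room for future grammar revisions. The summary is
an aggregate: the identity of adherent sites and the full pain map are not
carried, and parsed objects say so via `complete = FALSE`.

## Rank-correlation analysis

Validation analyses for scores of this kind are rank-based. `spearman_corr`
ranks both vectors and takes the Pearson correlation of the ranks, with two
tie dialects:

* `"average"` (default): ties receive the mean of the ranks they occupy —
  the statistically standard treatment.
* `"rank_eq"`: all tied values receive the minimum (first) rank in
  ascending order, reproducing the spreadsheet idiom of ranking with a
  minimum-rank function and then applying the product-moment correlation to
  the rank vectors. Both vectors are ranked this way.

Integer scores tie heavily, so the dialects can differ; the `analyze`
command computes both and prints the second whenever any cell differs by
more than 0.001. P-values use the large-sample t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$ degrees of freedom; no
multiple-testing correction is applied.

`correlation_table` assembles the usual validation layout — one row per
score variant (full E-score, each component alone, and the recorded r-ASRM
score when present), one column per outcome (r-ASRM score, surgical
duration, blood loss). Estimates are kept at full precision and only
rounded to 3 decimals for printing.

### The duration model

Surgical duration is predicted by an affine model $y = \beta_1 x + \beta_0$
with $x$ the E-score; `fit_duration_model` is ordinary least squares
(through `stats::lm`) and `duration_model()` carries the canonical
published coefficients $\beta_1 = 6.2995$ min/point, $\beta_0 = 49.459$
min. Note that evaluating the canonical model at $x = 19$ gives
$169.1495$ min; a commonly quoted round figure of "about 175 min" for that
E-score is not consistent with the coefficients, and this package always
evaluates the equation.

### r-ASRM comparison

For comparison with the intraoperative standard, `rasrm_total` sums the
revised ASRM component points (peritoneal up to 6, endometriomas up to 40,
posterior cul-de-sac obliteration up to 40, tubal adhesions up to 32, and
per-ovary adhesion categories none / < 1/3 / 1/3-2/3 / > 2/3 mapped to
0/4/8/16 points), capped at 150. Stages partition 1-150 as I (1-5),
II (6-15), III (16-40), IV (41+). Published bin labels ("16-40", "> 41")
leave the value 41 unassigned; it is placed in stage IV here, matching the
conventional "> 40" cut. The full r-ASRM worksheet (filmy vs dense
adhesions, per-lesion sizes) is out of scope; only the component-point
granularity is implemented.

## The synthetic cohort model

Patient-level data behind scores of this kind are generally not shareable,
so the package ships a seeded simulator whose defaults emulate the
reference cohort's published summary statistics, making the whole analysis
pipeline testable end to end.

### Score-level simulation with findings back-filled

Components are simulated at the *score* level and concrete findings are
back-filled afterwards, rather than simulating findings directly. This
guarantees exact score round-trips (re-scoring a generated exam reproduces
the sampled component scores, a property the tests check exhaustively) and
makes rank-correlation targeting tractable. The cost is that the
within-component fine structure (which sites are adherent, where pain
localises, per-side cyst splits) is synthetic: plausible but not fitted to
any real joint distribution. Passing tests therefore demonstrate the
pipeline's correctness on data with realistic margins and rank structure,
not clinical realism of the fine structure.

Joint component scores come from a Gaussian copula: a latent multivariate
normal $Z$ with correlation matrix $r_{ij} = 2\sin(\pi\rho_{ij}/6)$ — the
identity linking a bivariate normal's Pearson correlation to the Spearman
correlation of its margins — is mapped coordinate-wise through each
marginal's quantile function. Target matrices that the transform leaves
non-positive-semidefinite are repaired to the nearest correlation matrix
(`Matrix::nearPD`) with a warning. Because the reference tables publish
score-versus-outcome correlations but not within-cohort component pairs,
unpublished pairs default to a weak positive 0.3 and stay configurable.

### Default marginals

| component | support | mean | shape |
|---|---|---|---|
| cyst | 0-12 | 6.32 | discretized normal, sd 3.0 |
| adhesion | 0-9 | 3.96 | discretized normal, sd 2.6 |
| pain | 1-10 | 6.07 | discretized normal, sd 2.5 |
| uterine | {0,3,6,9} | 3.48 | implied by lesion prevalences E 52.2%, R 39.6%, A 24.3% |

The discretized-normal marginals take a normal density on the integer
support and solve for the location (by `uniroot`) so that the pmf mean hits
the target exactly; the spreads are chosen once so the distributions fill
the observed ranges. The uterine marginal is the distribution of
$3 \times (\text{number of lesion types present})$ under independent
presence at the stated prevalences (mean 3.48, close to the observed 3.51).
Rare-site disease is an independent Bernoulli at 4.5%; myomas (never
scored) at 16.2%.

Back-filling inverts the scoring rules: a per-side score $s \in [1,5)$
draws a diameter on the one-decimal grid in $(s-1, s]$ (a capped score of 5
draws from $(4, 9]$), so the ceiling rule reproduces $s$ exactly after
ingest rounding; combined scores above 10 are absorbed by tubal lesions in
3-point steps; the adhesion score selects a uniformly random site subset of
that size; the pain score is placed in one region — the pouch of Douglas
preferred when posterior adhesion sites are positive, echoing the clinical
association between cul-de-sac disease and pain there — with other regions
drawn at or below it; the uterine score selects score/3 lesion types
weighted by prevalence, nodule diameters drawn from $[1, 4)$.

### Outcomes and calibration

Duration and blood loss are affine in the flat-scheme E-score plus Gaussian
noise, truncated (clamped) to the published observed ranges (51-421 min,
0-500 mL); the r-ASRM outcome is affine in the *latent severity* (the
standardized sum of the four copula coordinates) plus noise, clamped to
[10, 150] and rounded. Clamping after noise slightly biases the outcome
means; this is accepted and the configured coefficients absorb it.

Two noise levels are calibrated constants, fixed once in the defaults and
recorded in `inst/extdata/default_cohort_spec.yaml`: `duration_noise_sd =
41` min and `rasrm_link$noise_sd = 24` points. With the default marginals
these reproduce rank correlations of about 0.724 (E-score vs duration) and
0.758 (E-score vs r-ASRM) at $n = 5000$; the blood-loss coefficients
(slope 4 mL/point, noise sd 60) give about 0.40. The calibration was done
with the closed-form copula identity as the starting point (for an affine
signal $aX$ plus noise of sd $\sigma$, the latent Pearson correlation is
$a\sigma_X/\sqrt{a^2\sigma_X^2+\sigma^2}$) and refined by simulation.

### Determinism and degenerate inputs

Identical spec + seed give byte-identical cohorts (`generate_cohort` seeds
the RNG stream once and draws everything from it). `n = 0` returns an empty
cohort. A uterine score that is not a multiple of 3 is a spec error. With
`duration_noise_sd = 0` and unbounded truncation, duration is a strictly
increasing function of the E-score and its Spearman correlation is exactly
1 — a useful boundary test.

## Problem sizes and numerical tolerances

The test suite exercises the closed forms on a 0.1 cm grid over (0, 50);
compares average-rank Spearman with a brute-force counting oracle to 1e-12
over 1000 random tied vectors; verifies OLS recovery of the canonical
duration coefficients to 1e-9 on noise-free points; checks the simulator's
correlation and mean fidelity on cohorts of $n = 5000$ (tolerances ±0.05 on
Spearman targets, ±0.15 on component means — sampling error at that size is
roughly 0.014 on $\rho$ and 0.04 on the means); and round-trips the summary
notation and CSV schema over 500 randomly generated exams. These sizes are
the package's own choices, large enough that failures signal defects rather
than noise.

## Known limitations

* The summary grammar is this package's own; other implementations of the
  scoring sheet may abbreviate differently, and a translator would be
  needed to interchange with them.
* The simulator targets rank structure and marginal means; it does not
  model symptom scales, treatment history, or the joint clinical
  distribution of findings beyond the copula.
* The intraoperative variant of the score (confirming the same elements
  during surgery) is not implemented.
* Correlation output deliberately omits confidence intervals; with heavy
  ties the two tie dialects are the more informative sensitivity check.
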