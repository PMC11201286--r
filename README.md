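# nmse — Numerical Multi-Scoring System of Endometriosis

`nmse` implements the NMS-E, a preoperative severity assessment for
endometriosis that combines transvaginal ultrasonography and pelvic
examination. Endometriosis severity has traditionally been staged
intraoperatively (the revised ASRM classification); the NMS-E makes a
comparable severity number — the **E-score** — available *before* surgery,
which is what operating-room planning, triage to specialised surgeons, and
patient counselling actually need.

The package is for gynaecologists and clinical researchers who want to

* score examinations and render the Physical Finding Map,
* exchange findings as a compact TNM-like summary line or a cohort CSV,
* validate scores against surgical outcomes with rank correlations,
* predict surgical duration from the E-score, and
* simulate realistic synthetic cohorts when patient data cannot be shared.

## The score

The E-score is the sum of five components:

| component | range | rule |
|---|---|---|
| Cyst | 0-10 (+0-6 tubal) | per ovary min(5, ⌈diameter cm⌉), endometriomas only; 3 per side with a tubal lesion |
| Adhesion | 0-10 | count of sliding-sign-positive sites among 10 canonical locations |
| Pain | 0-10 | maximum palpation NRS over 7 pelvic regions |
| Uterine | 0-9 (flat) | 3 points each for retroversion, adenomyosis, nodules ≥ 1 cm |
| Rare | 0 / 10 | flat 10 for any rare-site disease |

An alternative size-graded nodule scheme (`"sized"`) scores each
endometriotic nodule 3/6/10 points for diameters in [1,2)/[2,3)/[3,∞) cm —
deep lesions dominate surgical complexity, and grading them by size
improves the correlation with operating time. Surgical duration is
predicted by the canonical affine model *y* = 6.2995·*x* + 49.459 min,
with *x* the E-score.

## Worked example

The teaching case: right endometrioma 6.5 cm, left 2.4 cm, seven positive
adhesion sites, pain peaking at NRS 8 in the pouch of Douglas, adenomyosis
plus a 2.6 cm endometriotic nodule.

```r
library(nmse)
ex <- worked_example_exam()
e_score(ex)
#> <nmse_score> scheme = flat3
#>   Cyst      8  (right 5 + left 3 + tubal 0)
#>   Adhesion  7 / 10
#>   Pain      8 / 10
#>   Uterine   6
#>   Rare      0
#>   E-score  29
```

The 6.5 cm cyst rounds up to 7 but is capped at 5; 2.4 cm rounds up to 3;
adenomyosis and the nodule give 3 + 3 = 6; the total severity is 29. Under
the size-graded scheme the 2.6 cm nodule scores 6 instead of 3, so
`e_score(ex, "sized")$e_score` is 32. The one-line summary and the
predicted operating time:

```r
serialize_summary(ex)
#> [1] "Cy R6.5/L2.4 | Ad7/10 | P8@V | Ut A,E2.6 | Rare - | E=29"
predict_duration(duration_model(), 29)
#> [1] 232.1445
```

A synthetic cohort with the default (reference-cohort) marginals, scored
and analysed:

```r
co <- generate_cohort(cohort_spec(n = 5000, seed = 1))
e   <- sapply(co$exams, function(x) e_score(x)$e_score)
dur <- sapply(co$exams, function(x) x$outcomes$duration_min)
spearman_corr(e, dur)
#> Spearman rho = 0.722 (n = 5000, tie mode = average, p = 0)
```

The simulated E-score–duration rank correlation lands on the configured
target of about 0.72; `cohort_descriptives(co)` reproduces the configured
component means (cyst 6.32, adhesion 3.96, pain 6.07, uterine 3.48).

## Command line

A thin launcher is installed at `inst/cli/nmse`:

```sh
nmse score    --in exams.csv --scheme flat3 --out scores.csv
nmse summarize --in exams.csv
nmse predict  --escore 19
nmse simulate --n 111 --seed 1 --config spec.yaml --out cohort.csv
nmse analyze  --in cohort.csv --tie-mode average --out corr.csv
```

`analyze` reports Spearman correlations under the standard average-rank tie
treatment and, whenever it differs materially, also under the spreadsheet
minimum-rank dialect (`rank_eq`).

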