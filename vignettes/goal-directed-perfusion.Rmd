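---
title: "Goal-directed perfusion analytics: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal-directed perfusion analytics: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdperf)
```

## The physiological model

On cardiopulmonary bypass the pump flow replaces cardiac output, so the
cardiac index is `CI = flow / BSA` and the oxygen delivery index is

$$\mathrm{DO_2i} = 10 \cdot CI \cdot \left(1.36 \cdot Hb \cdot SaO_2 +
0.003 \cdot PaO_2\right) \quad [\mathrm{mL\,O_2/min/m^2}]$$

with haemoglobin in g/dL and saturations as fractions. Two unit conventions
deserve a note, because monitor documentation is often sloppy about them:

* **The factor 10.** Arterial oxygen content is conventionally stated per
  decilitre of blood while flow is in litres per minute; the decilitre-to-
  litre factor of 10 is mandatory. Without it the standard GDP threshold of
  280 mL/min/m² would be unreachable at any clinical flow (CI 2.2 at Hb 10
  would "deliver" 29.9), so `gdperf` always includes it.
* **Fractions, not percent.** All saturations are stored as fractions in
  \[0, 1\]. The raw-file dialect carries percent columns (`sao2_pct`,
  `svo2_pct`), because that is what monitors export, and `ingest_records()`
  converts on the way in. Haemoglobin "g%" is read as g/dL.

The oxygen extraction ratio is `(SaO2 - SvO2) / SaO2` and oxygen consumption
follows the Fick principle, `VO2i = 10 · CI · (CaO2 - CvO2)`. Carbon dioxide
production and DO2i/VCO2i ratios are out of scope: intra-operative CO2
insufflation makes exported capnography unusable for that purpose.

**Reference conditions.** Iso-delivery reference curves and flow
recommendations default to `sao2 = 1`, `pao2 = 0` (full saturation, dissolved
oxygen neglected). This is a documented convention, not a physiological
claim: it is the convention under which the familiar bedside numbers come out
(CI 2.574 → 2.6 at Hb 8 for the 280 goal), it is conservative (dissolved
oxygen only adds delivery), and nothing prevents passing measured `sao2` and
`pao2` instead.

## The GDP filters

`apply_gdp_constraints()` retains rows with `do2i >= 280`, `svo2 > 0.68` and
`map > 60`. The DO2i comparison is inclusive ("at least 280") while the
saturation and pressure cuts are strict — the asymmetry is deliberate and is
pinned by a unit test, since rows exactly on the delivery threshold are
legitimate goal-compliant observations. Removal counts are attributed to the
first failing criterion in the fixed order incomplete → DO2i → SvO2 → MAP;
the retained set itself is order-independent (a pure intersection), which is
also what makes the filter idempotent.

`density_filter()` then removes rows lying in sparsely measured cardiac-index
regions: CI is binned at 0.1 L/min/m² (left-closed, right-open) and bins with
fewer than 100 valid haemoglobin measurements are dropped. Two choices were
genuinely open:

* **Bin width 0.1.** "A CI value" has no canonical aggregation; 0.1 L/min/m²
  is the resolution at which clinical CI ranges are quoted (1.3–2.8), and the
  width is configurable in `gdp_thresholds()`.
* **Single pass.** Removing sparse bins changes no other bin's count under
  fixed-width binning, so iterating to a fixed point is equivalent here; a
  single counting pass is simpler and is the documented semantics.
* The filters run constraints-first, density-second, matching the narrative
  order in which such analyses are described; with the default settings the
  result barely depends on the order because the density filter acts on CI
  alone.

A numerical detail: the bin index adds `1e-9` before flooring, so a CI that
is mathematically on a bin edge but lands a few ulps low (e.g. `2.8` after
division by `0.1`) still bins right-of-edge, keeping edge behaviour
predictable.

## Iso-DO2i bands and the weighted quadratic

`extract_iso_band()` selects rows with `|do2i - L| <= tol` (default
`tol = 10` mL/min/m²) and weights them with a triangular kernel
`w = 1 - |do2i - L| / tol`. The kernel encodes exactly one idea — proximity
to the iso-level — with no shape parameters to tune; the band tolerance is
configurable because monitored cohorts differ in density. Rows exactly on
the band edge would get weight 0, which would silently drop them from a
weighted fit; they are instead floored at `1e-8` so band membership and the
fit see the same rows (a measure-zero case that matters only in constructed
data). With `tol = 0` the kernel degenerates to weight 1 on exact matches.

`fit_iso_quadratic()` fits `ci = a0 + a1·hb + a2·hb²` by weighted least
squares (`stats::lm`). The regression is CI-on-Hb, not Hb-on-CI, because the
clinical read-out goes that way: given the patient's haemoglobin, what flow
is needed. A quadratic in Hb approximates the true hyperbola
`L / (13.6·Hb)` extremely well over clinical haemoglobin spans — over
Hb ∈ \[8, 12\] the best quadratic deviates from the 280-hyperbola by well
under 0.01 L/min/m², which is why the noise-free oracle tests can demand
agreement within 0.05. Guard rails: at least 10 distinct haemoglobin values,
a rank check for degenerate bands, and **no extrapolation** — `predict()`
returns `NA` outside the band's observed Hb support, and plotted curves are
clipped to their own domains.

`recommend_flow()` inverts the delivery equation in closed form; it reports
both full-precision and one-decimal values because pump flows are set at
0.1 L/min resolution.

## What the synthetic generator emulates

`simulate_cohort()` stands in for a non-deposited clinical dataset, so its
defaults are chosen once, on physiological grounds, and define the study
conditions for every test:

| parameter | default | rationale |
|---|---|---|
| patients | 272 | cohort scale being emulated |
| sampling interval | 5 s | in-line monitor rate; with 90–150 min cases gives ~1,100–1,800 rows/case, ~390k rows/cohort |
| CI set point | N(2.3, 0.15), noise 0.06 | conventional 2.2–2.4 L/min/m² flow management |
| Hb | start N(10.8, 0.85), reflecting walk in \[7, 14\] | post-dilution anaemia, slow drift, core mass 9–12 g/dL |
| low-flow episodes | 2/h, 30–180 s, ~35% depth | transient surgical flow reductions — the dominant source of sub-280 DO2i |
| latent VO2i | N(75, 10) mL/min/m² | adult consumption on normothermic bypass |
| SvO2 | inverse Fick from latent VO2i | see below |
| MAP | 20 + 22·CI + N(0, 6) | pressure driven chiefly by flow; mean ≈ 70 mmHg at CI 2.3 |
| BSA, age, sex, BMI | 1.95 ± 0.21 m², 62.5 ± 12.4 y, 73.6% male, 28.4 ± 4.8 | demographic structure of the emulated cohort |
| corruption | 1% duplicate rows, 0.5% empty rows, 1% missing cells | spreadsheet-export artefacts |

Two generator decisions are structural rather than cosmetic:

* **SvO2 from latent consumption.** Venous saturation is derived as
  `SvO2 = SaO2 - VO2i / (10·CI·1.36·Hb)` rather than sampled independently,
  so that a flow reduction depresses DO2i and SvO2 *together*. That coupling
  is what makes the GDP filters behave as they do on real data, and it is
  what lets the filter tests use the generator's ground-truth low-DO2i tags
  as an oracle.
* **Sampling interval.** Only the aggregate cohort row count (~10³ rows per
  case) constrains the monitor rate; 5 s with 90–150 minute cases matches
  both that scale and realistic bypass durations simultaneously, and both
  knobs are configurable.

What the generator does **not** emulate: surgical phases (cooling, clamping,
weaning), temperature effects on the dissociation curve, vasoactive drug
boluses, sensor drift/recalibration steps, and between-variable artefact
correlation (cells go missing independently). Passing tests therefore show
that the pipeline's *mechanics* — accounting, filtering, band extraction,
fit recovery — are correct under physiologically shaped data; they do not
certify performance on any particular clinical cohort.

## Cleaning and interpolation choices

* **Duplicates** are byte-identical rows (after timestamp normalisation to
  UTC); near-duplicates are kept because no similarity rule would be
  defensible without device knowledge. Remaining ties on (patient,
  timestamp) keep the first occurrence.
* **Interpolation** is linear in time, within patient only, and only bridges
  gaps whose flanking measured samples lie within `max_gap = 120` s — the
  most conservative reading of "interpolated from nearby points". Leading
  and trailing gaps are never invented; rows that stay incomplete are
  excluded by the constraint filter (and counted as such). Filled cells
  carry `"interpolated"` provenance that survives re-running the step, so
  interpolation is idempotent.
* **Row conservation** is an invariant, not a log line: ingested = cleaned +
  duplicates removed + empties removed, checked in tests against the
  generator's corruption ledger exactly.

## Problem sizes and determinism

Unit tests run on seeded cohorts of 2–12 patients with 20–45 minute cases
(hundreds to a few thousand rows), where brute-force oracles (row-by-row
predicate scans, closed-form curves) are feasible; the end-to-end structure
check runs the full default 272-patient cohort (~390k rows) once, in about a
minute. All randomness flows through a single integer seed
(`withr::with_seed` inside the generator), and the pipeline manifest records
the configuration hash and per-stage row counts, so a seed + config pair
reproduces every coefficient bit-for-bit.

## Known limitations

* The quadratic is a local description over the band's haemoglobin support;
  it has no physiological validity outside it (hence the hard no-extrapolation
  rule) and will curve upward far outside any data.
* Constant 1.36 mL/g Huefner number and a temperature-independent dissolved
  term; acid–base and temperature corrections are out of scope.
* No uncertainty bands on the fitted curves — the weighted RSS and
  coefficient standard errors are reported, but bootstrap confidence bands
  for monitored time series (with their within-patient autocorrelation)
  would need block resampling and are left out deliberately.
* Patient-level exclusion rules and formal outlier tests are not modelled;
  the density filter is the only outlier control, as in the analysis style
  this package reproduces.
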