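---
title: "Methods: screening glucose-conjugated gibberellins from isotope-labeled LC-MS/MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening glucose-conjugated gibberellins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glcga)
```

# The measurement model

A glucose-conjugated gibberellin (Glc-GA) carries one free carboxyl group
(unless it is a glucosyl ester, in which case the carboxyl is blocked and
the compound is invisible to this assay). Amide derivatization with
*N*,*N*-dimethylethylenediamine (DMED) transforms the neutral molecule by
`+C4H12N2 − H2O`; the deuterated reagent (d4-DMED) adds the same atoms with
four deuteriums in place of four hydrogens. Everything downstream follows
from exact monoisotopic arithmetic over these transforms:

* native conjugate = free GA `+C6H10O5` (glucose condensation);
* derivatized neutral = native `+C4H12N2 − H2O`;
* light channel = derivatized mass `+ 1.007276` (`[M+H]+`);
* heavy channel = light `+ 4 × (m(D) − m(H)) = +4.0251` Da;
* fragment cations written as formulas are charged species: mass minus one
  electron.

Element masses are IUPAC monoisotopic values hard-coded to six decimals
(`elementMassTable()`); deuterium is the distinct symbol `D`. One
deliberate modeling choice deserves mention: published tabulations of
derivatized conjugate formulas sometimes carry two extra hydrogens relative
to amide stoichiometry, but only `+C4H12N2 − H2O` reproduces the observed
`[M+H]+` values (e.g. 563.2963 for the C25H32O10 conjugate class), so the
amide stoichiometry is used throughout. Likewise the formic-acid loss is
implemented at its monoisotopic mass 46.0055 Da (CH2O2).

# Screening stages and their assumptions

**Channel construction.** Every registry GA with `carboxyls > 0` yields one
candidate per the arithmetic above; candidates within 0.001 Th merge into
one isobaric channel. 0.001 Th effectively means "identical molecular
formula" — positional isomers are intentionally not separated, mirroring
the physical ambiguity of the measurement.

**Pair matching.** Peak pairs are accepted when
`rt(light) − rt(heavy) ∈ [0, 0.013]` min and the light/heavy apex-height
ratio lies in `[0.76, 1.50]`. The sign convention encodes the deuterium
isotope effect on reversed-phase retention: the heavy form never elutes
later than the light form. Intensity means apex height, not area; with a
1:1 mix of the two labels the ratio centers on 1. Assignment is greedy 1:1
by smallest `|ΔRT|` with ties broken by the ratio closest to 1 — with peaks
that satisfy the narrow RT window, an optimal assignment and the greedy one
coincide in practice, and greediness keeps the result order-invariant.

**Five-class MS2 rules.** Neutral-loss ladders are walked breadth-first
from two seeds — the precursor and the `[M − glucose − (CH3)2NH]+` anchor —
chaining only through fragments actually observed, to depth 4. Class 4
(carbon skeleton) matches hydrocarbon cations CxHy+ with `5 ≤ x ≤ 18`, odd
`y` and m/z in 80–230; "odd-numbered" is read as an odd hydrogen count,
i.e. even-electron cations of odd nominal mass, which is the only reading
under which the classic tropylium-type series (91.0542, 105.0699, ...)
qualifies. The default pass policy demands classes 5 (glucose), 1
(reagent) and 2 (A-ring) plus at least one of classes 3 or 4; the
published candidate narratives all show exactly this pattern, and the
policy is a configurable argument for chemistries that differ.

**A-ring inference.** Below the anchor fragment the molecule has lost its
glucose and reagent parts, so H2O / HCOOH / CO2 losses report on the A-ring:
each sequential H2O marks a hydroxyl, an HCOOH marks the lactone, and a
combined `CO2 + 2H2O` loss (80.0110 Da) contributes two hydroxyls — the
pattern seen in di-hydroxylated conjugates where the second water leaves
only together with the ring-opening CO2. Hydroxyl count is the maximum
over all observed ladder paths, which makes the inference a lower bound on
the true hydroxylation and motivates the step-2 rule: candidates are kept
when their annotated count is *at least* the inferred count and the lactone
flags agree exactly.

**QSRR retention filter.** Retention indices come from piecewise-linear
interpolation of an (RT, RI) anchor table. The anchor series shipped with
the package was reverse-engineered so that the worked examples' (RT, RI)
pairs are reproduced exactly; users calibrating their own gradients supply
a two-column CSV. The QSRR model itself is a pluggable ordinary
least-squares fit (`fitQsrr()`, `loocvRmse()`); predicted RIs for
candidates are consumed from a table rather than recomputed, because the
descriptor set behind the published predictions is not reproducible from
formulas alone. The filter is one-sided with threshold 69.5832 RI units
(the cross-validated RMSE of the underlying 13-standard model): glucose
conjugation always weakens retention, so an experimental RI far *above*
the parent prediction is disqualifying while arbitrarily large negative
deviations of the prediction are not. Candidates lacking a prediction are
retained with a warning — the filter only eliminates on positive evidence.

**Standard comparison.** Square-root-intensity cosine over greedily
tolerance-matched fragments. The reject (< 0.5) and support (> 0.8)
thresholds are package defaults, not published constants; they sit far
apart deliberately so that borderline scores change nothing.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `groupTol` | 0.001 | Th | isobaric = same formula |
| match `tolPpm` (MS1 and MS2) | 10 | ppm | Orbitrap at R = 30,000–120,000 |
| pair RT delta | [0, 0.013] | min | deuterium retention effect |
| pair intensity ratio | [0.76, 1.50] | — | 1:1 label mixing |
| `minSnr` | 3 | — | (apex − baseline)/MAD |
| `minPoints` | 5 | scans | suppresses single-scan artifacts |
| ladder depth | 4 | steps | deepest published ladder |
| `riThreshold` | 69.5832 | RI | QSRR cross-validated RMSE |
| `rejectBelow` / `acceptAbove` | 0.5 / 0.8 | cosine | conservative, configurable |

# Numerical choices

Peak picking smooths with a 5-scan moving average, takes local maxima above
`baseline + minSnr × noise` (baseline = median, noise = MAD with an SD
fallback for sparse traces), walks bounds to the surrounding valleys, and
refines the apex by three-point parabolic interpolation — which resolves
retention differences an order of magnitude below the scan period, as the
0.013-min pairing window requires. XIC windows are half-open `(lo, hi]`
so that disjoint windows tile the total ion current exactly. Formula
deltas refuse to drive any element count negative. Linear fits require at
least `p + 2` samples and a full-rank design; leave-one-out RMSE uses the
closed-form hat-matrix identity and is verified in the tests against an
explicit refit loop.

# What the simulator emulates — and what it does not

`simulateRun()` generates MS1 full scans over m/z 300–700 between 7.2 and
13.2 min at 2 Hz (the retention window covered by the RI calibration
anchors), Gaussian elution profiles (σ = 0.035 min, apex height 20,000)
for each light/heavy pair with a 0.006-min light-heavy offset and 1:1
ratio, Poisson counting noise, ten random noise centroids per scan (mean
intensity 100, exponential), and one DDA MS2 per analyte built from its
neutral-loss ladder with a decreasing geometric intensity profile and
ground-truth class labels per fragment. Decoys probe one criterion each:
ratio-violating pairs (3:1 or 0.3:1), RT-violating pairs (±0.05 min), and
well-behaved pairs whose MS2 lacks the glucose loss.

The simulator does *not* model chromatographic tailing, ion suppression,
isotope envelopes, multiply charged species, in-source fragmentation, or
chimeric MS2 spectra. Passing the round-trip test (100% spike recall, 0%
decoy acceptance across seeded runs) therefore demonstrates the internal
consistency of the pipeline — that every stage preserves a detectable
analyte and every designed failure mode is caught — not its performance on
real extracts, where co-elution and matrix effects will reduce recall.

Problem sizes used by the validation suite: 721-scan runs, 3 spikes + 5
decoys per run, 50 seeded runs in the acceptance checks (20 where a
smaller replicate count estimates the same proportion), 13 × 4 designs
with 100 replicates for the regression recovery checks.

# Open design decisions taken

* The registry's `lactone`/`hydroxyls` columns are *A-ring* annotations
  (the only features the anchor ladder can see), curated for the channel
  members relevant to the worked examples; they are user-replaceable CSV
  input, and the curation is honest about being a structural reading, not
  a computed property.
* Reference-standard MS2 spectra are not publicly deposited, so the
  shipped GA7/GA34 standards are synthetic constructions (named
  accordingly) built from the fragmentation arithmetic: GA34 shares its
  conjugate's post-glucose-loss ladder, GA7 is deliberately disjoint.
  They exercise the step-4 logic; they are not measured spectra.
* The predicted-RI table contains only the published predictions for the
  563.2963-channel parents plus GA3; other candidates fall through the
  missing-prediction path by design.

# Known limitations

* Single derivatization is assumed even for GAs with multiple carboxyls;
  multiply labeled channels are out of scope.
* Only `[M+H]+` adducts in positive mode are modeled.
* Positional isomers of the glucose attachment are never separated — final
  candidate sets are isobaric equivalence classes, exactly as reported.
* Retention indices are usable only relative to a user-supplied calibration;
  the anchor scale itself is not derivable from first principles.
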