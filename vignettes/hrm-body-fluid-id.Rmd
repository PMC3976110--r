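---
title: "Identifying body fluids from high-resolution melt curves: methods and design"
author: "meltID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying body fluids from high-resolution melt curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltID)
```

## The problem

Forensic casework routinely needs to establish *which* body fluid a
stain contains, not just whose DNA it carries. Messenger-RNA markers
are fluid-specific — ALAS2 for blood, TGM4 for semen, HTN3 for saliva,
IL19 for vaginal secretions, MMP10 for menstrual blood, IL1F7 or CCL27
for skin — and a reverse-transcribed marker amplicon can be recognized
in a closed tube by its melting temperature (Tm). In a high-resolution
melt (HRM) assay the instrument records fluorescence of a saturating
intercalating dye while temperature rises in 0.1 °C steps; as each
double-stranded amplicon denatures, fluorescence drops, and the
negative derivative −dF/dT shows one peak per amplicon with the peak
maximum at its Tm. A multiplex panel is interpretable exactly when its
markers' Tm windows do not overlap.

`meltID` implements the analysis side of such assays end to end:

1. **panel registry** — the published marker panels (three duplexes, an
   epithelial triplex, an "all body fluids" hexaplex and the six
   singleplexes), each marker with its mean Tm and the mean ± 3SD
   window inside which a peak counts as detected, plus a validator for
   pairwise window resolvability;
2. **synthetic melt curves** — a generative model of single-source and
   admixed donors used for fixtures, calibration checks and power
   exploration;
3. **signal processing** — baseline normalization and the
   Savitzky–Golay −dF/dT transform;
4. **peak calling** — thresholded local-maxima detection with
   sub-grid Tm refinement, width measurement and broad-artifact
   rejection;
5. **marker classification** — window assignment, body-fluid calls,
   and quality flags (genomic-DNA contamination, artifact humps,
   possible menstrual blood, mixtures);
6. **reporting** — donor-cohort specificity tables with the published
   shading bands, CSV interfaces and a command-line wrapper.

## Marker panels and Tm windows

Published tables report each marker's mean amplicon Tm and a
"± 3SD" range; SDs are not printed, so the registry derives
`sd = (high − low) / 6` — the exact inverse of the convention. Windows
are treated as closed intervals and membership is tested on the
reported Tm after rounding to 0.1 °C, the precision at which both the
windows and instrument software report temperatures. A peak exactly on
a printed boundary is therefore *inside*.

The original-design MMP10 reaction yields two products (the
primer pair co-amplifies MMP3), with windows 81.8–82.7 °C and
83.0–84.0 °C. Because the second product is not always amplified, and
because a genomic-DNA product at 83.1 °C falls inside the secondary
window, only the *primary* window is `required` for a positive MMP10
call; the secondary window records a supporting match but can never by
itself produce one.

`validatePanel()` checks every pair of windows belonging to different
markers (the genomic-DNA window included) and reports overlaps, or
gaps smaller than a configurable `margin`. The default margin is 0
(strict disjointness): the hexaplex's tightest accepted separation is
the 0.1 °C gap between MMP10 (81.5–82.3) and TGM4 (82.4–83.0), so any
positive default margin would reject the published panel. The
validator shows that the hexaplex resolves all six markers, and that
pooling the six original-design markers into one hypothetical panel
fails (TGM4's window sits inside MMP10's primary window; IL1F7
overlaps the secondary one) — which is why the hexaplex needed
redesigned primers and a replacement skin marker (CCL27).

One printed inconsistency is worth noting: the figure text for the
MMP10 singleplex reports products at 81.8/83.2 °C while the table
prints means 82.2/83.5 °C. The built-ins follow the table.

## The generative melt model

Each double-stranded product is a **melt component** contributing a
falling two-state logistic to the raw trace:

$$f(T) = \frac{A}{1 + e^{(T - T_m)/w}}$$

with amplitude $A$, midpoint $T_m$ and width scale $w$ (°C). The
derivative peak then has height $A/(4w)$ and full width at half
maximum $2\ln(3 + 2\sqrt{2})\,w \approx 3.5255\,w$ — the two closed
forms used as analytic oracles throughout the test suite. Defaults:

| parameter | default | meaning |
|---|---|---|
| `width_scale` (specific product) | 0.35 °C | derivative FWHM ≈ 1.23 °C, a sharp specific melt |
| `width_scale` (dimer hump) | 1.5–2.5 °C | the "abnormally broad" low-temperature artifacts |
| baseline | `2.0 − 0.01·T` | slow background fluorescence decay |
| `noise_sd` | 0.003 | i.i.d. Gaussian per 0.1 °C step, relative to unit amplitudes |
| amplitude law | log-normal(0, 0.4) | strictly positive, right-skewed intensities |

A **donor model** states, per body fluid, the probability that each
marker's template is present; the defaults are the published detection
frequencies of the donor cohorts (for example a menstrual-blood donor
on the blood/menstrual duplex carries MMP10 always, ALAS2 with
probability 4/5 and vaginal IL19 with probability 3/5; on the
hexaplex, vaginal donors carry MMP10 with probability 3/9). Each
included marker draws one amplitude, and a Tm for every product:
normal around the published mean with the window-implied SD, truncated
to the window so simulated cohorts are consistent with the ± 3SD
semantics.

Products of one marker share a single *standardized* Tm shift (one
z-draw scaled by each window's SD) rather than independent draws. Both
amplicons of a dual-product reaction melt under identical salt, dye
and ramp conditions, so their Tms co-vary; independent draws would
collapse the MMP10 pair below the ~1.1 °C resolution limit of the
derivative plot in roughly an eighth of donors, which contradicts the
observed 5/5 detection of both-product MMP10 melts. Artifacts are
optional extra components: broad dimer humps below 78 °C (by default
attached with probability 0.5 to the fluids whose primers produced
them on the original duplexes — semen on saliva/semen, vaginal on
vaginal/skin), and genomic-DNA products at the known Tms (80.6 °C from
the hexaplex IL19 primers; 78.5/83.1 °C from the original MMP10
primers).

What the generator deliberately does **not** emulate: PCR efficiency
and plateau effects, sequence thermodynamics (Tms are table constants,
not predicted), inter-run calibration drift, temperature-dependent dye
quenching, and any correlation between template quantity and Tm.
Passing tests therefore demonstrate that the *analysis* recovers what
this signal model encodes — they are not evidence about instrument
behaviour beyond it.

## Signal processing

**Normalization.** Instrument export conventions vary, so the package
declares one: straight lines are fitted to the first and last 10 % of
the grid and each curve is rescaled pointwise so the pre-melt baseline
maps to 1 and the post-melt baseline to 0. This is affine per curve —
it cannot move a derivative peak — and it standardizes amplitudes so
one absolute peak threshold is meaningful across samples. Curves whose
pre/post baseline separation is below 10× the baseline-fit residual
noise (blanks, no-template controls) cannot be meaningfully rescaled —
division by a near-zero range would only amplify noise into spurious
peaks — so they are returned unscaled and flagged `flat`.

**Derivative.** Smoothing and differentiation are one linear operator:
the analytic first-derivative weights of a Savitzky–Golay local
polynomial fit, applied by convolution, with half a window trimmed at
each end of the grid (no built-in marker window comes near the grid
ends; the closest approach is HTN3's lower bound 75.9 °C against grid
starts of 65 or 73 °C). The default is a 7-point (0.7 °C) window of
degree 2. The degree choice is a real trade-off, measured during
development: the quadratic filter attenuates the height of a sharp
specific peak by ≈ 4.5 % but amplifies grid noise modestly (derivative
noise SD ≈ 0.0057 per unit amplitude), whereas the cubic filter
preserves heights and widths to a few tenths of a percent but
amplifies noise 2.7×, which under the default noise/threshold stack
floods cohorts with spurious low peaks. Since Tm location — the
quantity classification depends on — is unbiased under either degree,
the noise-robust quadratic is the default and the cubic is available
(`smooth_degree = 3`) when absolute peak heights or widths matter on
clean curves; the analytic-oracle checks in the test suite use it.

## Peak calling

Local maxima of −dF/dT are kept if they reach the analysis threshold —
an absolute value (default 0.05 on normalized curves, where a
unit-amplitude specific product peaks at ≈ 0.7) or a fraction of the
curve maximum. The fraction mode reproduces the operator tactic of
raising the threshold line under a strong specific peak so that weak
broad artifacts fall below it. Temperature intervals can be excluded
outright (`x_exclusions`), the published remedy for dimer humps at
known positions; an excluded peak never reaches classification.

Each retained maximum gets a sub-grid Tm by parabolic interpolation
through the three grid points at the maximum (reported rounded to
0.1 °C), a prominence, and a width: the full width at
`height − prominence/2`, with the crossing search bounded by the
saddles toward neighbouring retained peaks. When a saddle sits above
the half-prominence level (two close peaks of similar height), the
resolved side's half-width is mirrored — melt peaks are near-symmetric
— instead of letting the search run across the neighbour and
misreport the pair's envelope as one huge width. Isolated peaks are
unaffected. Peaks wider than `max_fwhm` (default 2.0 °C, comfortably
above the ≈ 1.23 °C of specific products and far below the ≥ 5 °C
humps) are flagged broad: they stay in the peak table but never
assign to markers. Maxima closer than `min_separation` (default
0.5 °C) merge, keeping the taller; exact ties keep the lower
temperature, a deterministic convention.

Two behaviours of summed logistic components are worth knowing. First,
overlapping flanks attract: the dual MMP10 products at 82.2/83.5 °C
(1.3 °C apart at $w$ = 0.35) have their true summed-curve maxima at
82.28/83.42 °C, so the pipeline faithfully reports 82.3/83.4 — a
property of the signal model, not an estimator bias. Second, a broad
hump closer than ~3 °C to a strong specific peak becomes a shoulder
with no local maximum of its own and cannot be called separately;
x-axis exclusion is the right tool there, as on the real instrument.

## Classification and reporting

Per sample: non-broad peaks are tested against every marker window
(closed, rounded-Tm membership; the panel must pass validation at
margin 0, otherwise assignment would be ambiguous and the call is
refused). A marker is detected iff a peak lies in its required window;
the tallest in-window peak supplies the observed Tm. A peak in the
genomic-DNA window raises `dna_contamination` — an RNA-quality alert,
never a fluid call. Remaining peaks are listed unassigned, so per
sample `assigned + unassigned + broad = called`.

Fluid calls are exactly the fluids of detected markers. Two or more
distinct fluids raise `mixture`; MMP10 and ALAS2 together raise
`possible_menstrual`, because menstrual blood is expected to carry
peripheral blood — the package reports both markers and the flag, and
deliberately does not suppress the separate blood/vaginal calls:
whether a menstrual interpretation should subsume them is a
policy question for the analyst, and all the evidence needed either
way is in the output. No quantitative mixture proportions are
estimated: peak intensity was reported not to track mixture
composition, so none is claimed.

`aggregateSpecificity()` assembles the fluid × marker detection matrix
of a cohort, with denominators counted per panel run (mirroring donor
studies where each duplex tests a different subset), and shades cells
white (no detection), light, or dark at ≥ 60 % (duplex scheme) or
≥ 75 % (hexaplex scheme) — following the table captions exactly; the
dark threshold is compared with `≥`.

## Numerical conventions and degenerate inputs

* Temperatures are carried at full precision; rounding to 0.1 °C
  happens at reporting, and window membership uses the rounded value
  with a 1e−9 guard against floating-point representation.
* The temperature grid must be ascending and uniform to 1e−6 °C;
  curves shorter than 20 points are rejected by the container's
  validity method.
* Empty cohorts, blank curves, zero-component simulations and
  zero-count cohorts all return well-formed empty or flagged objects
  rather than errors; a grid/panel mismatch produces per-sample error
  records instead of aborting a cohort.
* All randomness flows through explicit seeds; identical seeds give
  bit-identical curve tables and byte-identical interpretation CSVs.

## Problem sizes used by the test suite

The suite exercises parameter recovery at sizes chosen to make the
binomial bands meaningful while keeping a laptop run comfortable:
5 000 menstrual donors for the ALAS2 co-detection recovery (3 SE band
± 0.017 around 0.8), 2 000 donors for truth-level inclusion rates,
800 donors for pipeline-level co-detection, and 150 samples per fluid
(× 6 fluids, × noise on/off) for end-to-end recovery. End-to-end
recovery is asserted as detection of the true fluid — the semantics of
the published specificity tables — at 100 % noise-free and ≥ 99 %
under default noise; measured residuals are misses of ≈ 0.3 %
(dominated by CCL27, whose published window is a single 0.1 °C step
wide, so estimation noise of ± 0.05 °C can round a true peak out of
it) and spurious extras of ≈ 0.9 % in the weakest-amplitude donors.

## Known limitations

* Tm windows are the published constants; the package does not predict
  Tm from sequence, and primer sequences are carried as metadata only.
* Overlapping peaks are resolved by windows only — no multi-component
  deconvolution — so products closer than ~1.1 °C merge, and the
  reported Tm of moderately overlapping pairs inherits the flank
  attraction described above.
* The amplitude law is a stated convention, not a fit; no quantitative
  conclusion in the package depends on it.
* Specificity aggregation needs truth labels; on real casework it
  summarizes concordance with presumed provenance, not ground truth.
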