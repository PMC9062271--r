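---
title: "Estimating woody biomass and disturbance losses with woodyAGB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating woody biomass and disturbance losses with woodyAGB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In savannas under chronic disturbance — elephant browsing, recurrent
fire, other browsers, woodcutting, abiotic dieback — woody plants are
routinely broken, burnt, topkilled and resprouting. Standard forest
biomass protocols fail here twice over: stem diameter at breast height
(DBH) is often unmeasurable (stems branch, snap or burn below 130 cm),
and a damaged tree's height no longer follows the allometric
relationships the models were fitted on. At the same time, the damage
itself is scientifically valuable: the difference between what a plant
*would* carry and what it *does* carry, attributed per disturbance
agent, is a direct measurement of disturbance impact.

`woodyAGB` implements an individual-based protocol that quantifies both
sides: standing aboveground biomass (AGB) and per-agent AGB losses, per
individual, per plot, and per stratum.

## Growth classes and estimation workflows

Every individual is classified (`classify_growth_class()`) from three
observables: whether it carries living and/or dead *adult-sized* stems
(basal circumference strictly greater than 15 cm — a stem of exactly
15 cm is not adult-sized), its total visually estimated biomass loss
(the "gulliver" threshold of 30% separates lightly from heavily damaged
plants), and its height relative to a juvenile/sapling boundary.

| class | situation | workflow |
|-------|-----------|----------|
| JU/SA | no adult stems, light damage | canopy model; output is *post*-disturbance; pre-value by reverse damage assessment |
| GJ/GS | as above, loss ≥ 30% | same workflow, heavier damage |
| AA | living adult stems, loss < 30% | stem model per stem (shared height); output is *pre*-disturbance; losses deducted |
| AG1 | living adult stems, loss ≥ 30% | as AA, with pre-disturbance height reconstructed from DBH |
| AG2a | living + dead adult stems, living crowns < 30% | living stems as AA; dead stems valued separately |
| AG2b | living + dead adult stems, living crowns ≥ 30% | living stems as AG1; dead stems valued separately |
| AG3 | only dead adult stems; shrub-like resprout | canopy model for regrowth + dead-stem valuation |

Two asymmetries are central and easy to get wrong:

* the canopy model measures the **damaged** crown, so its output is
  standing AGB and the pre-disturbance value follows by
  `reverse_damage()` (`agb_pre = agb_post / (1 − pct/100)`); the stem
  model measures the **persistent** stem, so its output is
  pre-disturbance AGB and losses are deducted;
* visual loss percentages refer to the **living part only**. Dead
  adult-sized stems are excluded from that estimate and valued
  independently (`dead_stem_agb()`), because their former biomass often
  exceeds the living regrowth by orders of magnitude and would otherwise
  crush the percentage scale. Their reconstructed biomass is attributed
  to the recorded topkill agent(s), split equally when two joint agents
  are listed (the protocol records up to two without weights; custom
  weights are accepted).

The central invariant, checked per individual and re-checked after every
aggregation step, is conservation:
`agb_ex = agb_standing + Σ losses` (relative tolerance 1e-9).

## Proxy reconstruction and its calibration

Three regressions recover destroyed proxies, refitted locally
(`calibrate_models()`) from the healthy reference subset — class AA with
total loss below 30% and no dead stems. The 30% cutoff reuses the
gulliver threshold; "adult non-gulliver" alone would admit trees with
just-sub-threshold damage, and a single threshold keeps the class system
and the calibration subset consistent.

* `h_est = exp(a + b·ln DBH)` — OLS of ln h on ln DBH, fitted on each
  tree's *dominant* (largest-diameter) stem only. A tree's height is set
  by its dominant stem; secondary stems of multi-stem trees would pair
  the same height with smaller DBHs and bias the fit downwards. Where
  the estimate falls below the field reading, the reading is kept
  (`max` rule), so height "correction" never shrinks a tree.
* `DBH_est = s·basal_circ/π` — least squares through the origin on
  basal *diameter*; the printed form is a pure proportionality, so the
  intercept defaults off (an option exists). R² is the uncentered,
  through-origin definition, computed on the DBH-vs-basal-diameter scale.
* `basal_circ = 130·circ(hx)/(130 − t·hx)` — only the final formula is
  standard, so we linearize: `y = 130 − 130·circ(hx)/basal_circ`
  regressed on `hx` through the origin, making `t` a one-parameter least
  squares problem consistent with the functional form. Readings with
  `hx ≥ 130/t` are outside the model's validity and reported.

When no reference trees are available, `default_calibration()` supplies
coefficients fitted to a semi-arid African savanna community
(a = 4.72595, b = 0.63385, s = 0.7968, t = 0.2032), flagged
`"reference"` in every output so provenance is never silent. The model
families are fixed to these forms; other families may fit other
communities better and are deliberately out of scope.

## Parameters that matter

| parameter | default | units | why |
|-----------|---------|-------|-----|
| adult-size threshold | 15 (strict) | cm basal circumference | defines "adult-sized stem"; basal, not breast-height, because stem bases survive disturbance |
| gulliver threshold | 30 | % total loss | separates the light-damage workflows from gulliver workflows |
| juvenile/sapling boundary | 150 | cm height | site-specific; not asserted as universal, review per community |
| damage cap | 99 | % | total topkill still leaves a live root system; keeps reverse damage assessment finite |
| `default_swd` | none | g cm⁻³ | optional last-resort wood density after the species → genus fallback |

Specific wood density is dry mass over fresh cylinder volume, the five
caliper readings averaged first (`sample_volume()`); the protocol does
not specify averaging five per-segment volumes instead, and the
mean-then-volume reading is the simplest consistent one (a regression
test pins it). Species means are looked up with a species → genus →
default chain, each value flagged with its provenance; genus is the
first whitespace-separated token of the binomial. Densities at or above
1.5 g cm⁻³ are rejected as data-entry errors.

## Upscaling

The nested design records each growth class on its own subplot, so an
individual in class *c* on plot *p* is weighted by
`10000 / realized_area(c, p)` and by its `edge_fraction` (the fraction
of the plant inside the plot). Plot summaries are field-wise sums;
stratum summaries report means, standard deviations and plot counts —
inferential statistics are out of scope. `agb_pot`, the potential AGB
per vegetation type, is the arithmetic mean (median by option) of
pre-disturbance AGB over the least-disturbed reference stratum; no
automatic outlier exclusion is implemented because no defensible
criterion exists — exclusion is an explicit user-supplied plot list.

## The synthetic study

`simulate_inventory()` generates a full study with known ground truth:
60 plots by default, per-class counts Poisson(density × subplot area),
adult DBH lognormal (median 12 cm, log-sd 0.45, truncated at 5 cm),
heights on the height–DBH power law with lognormal biological scatter
(σ = 0.15), crowns linked to height by `CD = 0.45·(h/100)^0.85`, and
measurement noise (σ = 0.05, lognormal) applied to every emitted height,
circumference and crown diameter. The disturbance regime draws per-agent
Beta losses with stratum-specific attack probabilities and means,
injecting the gradient the package is meant to detect: fire losses
decline, and elephant losses and topkill probability rise, from low to
high elephant density; woodcutting concentrates at the low-density
(communal) sites. Totals are rescaled to respect the 99% cap. Stem
densities and damage magnitudes are realism-motivated choices, not
reproductions of any particular landscape.

Ground truth is computed by evaluating the estimation workflows on the
noise-free observables with the generating coefficients and true wood
densities. This is a deliberate, prominent limitation: **the generator
offers no biomass truth independent of the allometric models**, so
end-to-end tests verify protocol logic — classification, reconstruction,
partitioning, conservation, upscaling — not allometric accuracy. Real
data add observer variance in the visual loss percentages, species-level
allometric deviations, and spatial clumping, none of which the generator
emulates (plot-level density variation only). A passing suite therefore
says the arithmetic of the protocol is right, not that the two
published models fit any particular community.

Reproducibility: one seed fixes the whole stream; each plot runs on a
sub-stream derived deterministically from the seed and plot index, so
regenerating a subset of plots reproduces them exactly.

## Numerical choices

* Conservation and identity tolerances are 1e-9 relative; the zero-noise
  end-to-end run achieves ~1e-14.
* The cap rescaling shrinks totals marginally below 99 so floating-point
  summation can never push a recorded total past the cap; validation and
  `reverse_damage()` accept 99 + 1e-9 for the same reason.
* Degenerate fits raise errors rather than returning NaN: all-equal DBH
  (height fit), all readings at the base (taper fit), fewer than three
  usable stems (any fit, naming the fit). `run_pipeline()` can fall back
  per-component to the reference coefficients (`partial = TRUE`),
  flagging the calibration `"mixed"`.
* Ties in `reconstruct_height()` (estimate equals observation) return
  the shared value; extrapolated heights are not truncated — extreme
  DBH produces extreme heights, left to validation warnings rather than
  silently clipped.
* CSV serialization uses shortest-round-trip doubles, so
  write-then-read is the exact identity on all numeric fields.

Problem sizes in the test suite (a 60-plot default study for
conservation and identity checks, 50 × 500 replicates for
calibration-recovery statistics, 10⁴ draws for the damage cap) were
chosen to make the Monte-Carlo assertions stable at the stated
tolerances.

## Known limitations

* Visual loss percentages are taken at face value; no observer-error
  model, no uncertainty propagation to AGB.
* The "educated guess" reconstruction of a partially missing stem base
  is a field procedure, not a computation: such stems must arrive with a
  reconstructed basal value or an alternative reading, else estimation
  errors out naming the missing proxy.
* Single pooled calibration: no species- or site-stratified fits.
* No belowground biomass or carbon-fraction conversion.
* The deposited-workbook reader is a best-effort adapter requiring an
  explicit column mapping; the canonical CSV schema is normative.
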