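---
title: "Modeling and analysing regulatory RNA arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analysing regulatory RNA arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starkit)
```

## The system

A small transcription activating RNA (STAR) switch consists of a *target
RNA* — a leader sequence that by default folds into an intrinsic terminator,
keeping the downstream gene off — and a trans-acting STAR that prevents
terminator formation and turns the gene on. A **regulatory RNA array** puts
1–8 tandem STAR copies on a single transcript, separated by cleavable
insulators (a Csy4 endoribonuclease hairpin, optionally stabilised by a
strong upstream hairpin, or a self-cleaving ribozyme). Cleavage converts one
transcription event into several independently acting activators, so the
output gain of the controlled gene can be tuned simply by choosing the copy
number — no promoter library required.

## The kinetic model

`starkit` models one array transcription unit with three species — the
intact array transcript $A$, the free STAR pool $S$, and the output RNA $G$:

$$A' = u - (k_c + d_A)\,A$$
$$S' = \varepsilon\, n\, k_c\, A - d_S\, S$$
$$G' = a_T\big(\lambda + (1-\lambda)\,\theta(S)\big) - d_G\, G,
\qquad \theta(S) = \frac{S}{K+S}$$

with closed-form fixed point
$A^* = u/(k_c+d_A)$, $S^* = \varepsilon n k_c A^*/d_S$,
$G^* = (a_T/d_G)\,(\lambda + (1-\lambda)\,\theta(S^*))$.

Assumptions worth stating explicitly:

* **Saturating activation.** $\theta(S) = S/(K+S)$ is the fraction of
  target transcription events that are anti-terminated. This form is the
  simplest one that is linear at low $S$ (the copy-number-tuning regime)
  *and* saturates at high input — first-order mass action alone cannot
  reproduce output saturation.
* **Lumped cleavage.** Csy4 processing is first-order with rate $k_c$ and
  releases $\varepsilon n$ STARs per transcript. Per-site sequential
  intermediates collapse to the same steady state, and the data the model
  addresses vary only a scalar cleaving efficiency, so the lumped form
  loses nothing at steady state. Enzyme (Csy4) saturation is not modelled.
* **Arbitrary units.** All concentrations and rates are in arbitrary units.
  The default set (`u = 0.5, k_c = 1, d_A = 0.1, d_S = d_G = a_T = 1,
  K = 10, eps = 0.9, lam = 0.02`) places the 1–8-copy series at the
  reference input 0.5 in the sub-saturating regime; these are estimates
  fixed in configuration, not measured values.
* **Real-valued `n`.** Interfaces treat the copy number as an integer in
  0–8, but the arithmetic accepts any non-negative real; this is what makes
  the exchangeability identity $S^*(\varepsilon, n) = S^*(\varepsilon n)$
  testable exactly.

Three consequences the tests pin down exactly:

* **Leak shift.** $G^*(\lambda) = (1-\lambda)G^*(0) + \lambda a_T/d_G$ is an
  algebraic identity: leak shifts every copy-number curve upward by the same
  additive amount and leaves the slope's copy dependence untouched.
* **Gain tuning.** Leak-subtracted output is proportional to
  $\theta(S^*)$; as $u \to 0$ the activation linearises and the
  8-copy/1-copy output ratio tends to exactly 8 (`limiting_gain_ratio()`).
* **Efficiency vs linearity.** Lowering $\varepsilon$ scales $S^*$ and
  therefore lowers the slope of output vs copies without degrading the
  linear relation.

### Linearity bands

The relative curvature of $\theta$ grows quadratically in $S/K$. At
$S^*(n{=}8) \approx 0.05\,K$ the copy series deviates from its
least-squares line by well under 1%; at $S^*(n{=}8) \approx 0.1\,K$ the
maximum deviation is about 1.15%. The Pearson correlation is much less
sensitive: $r > 0.99$ holds across the whole sub-saturating range and the
package's acceptance checks use that statistic.

### Numerics

No general ODE solver is available in the dependency set, so the package
ships a small adaptive Dormand–Prince 5(4) integrator (absolute tolerance
$10^{-9}$, relative $10^{-6}$, steps land exactly on output times,
non-finite states abort with diagnostics). The model is non-stiff for valid
parameters — the linear part's eigenvalues are the negated degradation
rates — so an explicit embedded pair is appropriate. Steady states are
**always** computed from the closed forms, never detected heuristically
from a trajectory; the integrator exists to verify the closed forms
(module invariant: $|G(t_{end}) - G^*|/G^* < 10^{-3}$ over random draws)
and to serve as the joint-ODE oracle for circuits.

The limiting gain ratio is evaluated over a decreasing input sequence until
successive decades agree; because the leak subtraction works in a
neighbourhood of $\lambda a_T/d_G$, floating point caps the achievable
accuracy near $10^{-7}$ relative, which the convergence tolerance respects.

## Circuits

Transcription units compose through two kinds of directed edges:

* **u-driver** — a unit's transcription input is a constant, an inducible
  on/off level, or the upstream unit's activated target transcription rate
  $a_T(\lambda + (1-\lambda)\theta)$. The *receiving* unit's plasmid
  copy-number multiplier scales the handoff (the target promoter DNA lives
  on the receiving unit's plasmid); the driver's own multiplier affects only
  its own input and output gene. This resolves an ambiguity in how a shared
  multiplier could be applied — applying both would double-count the
  plasmid copy number.
* **s-source** — which free-STAR pool activates the unit's target: its own
  single-variant pool (default), another unit's pool (multiplex reporters),
  or none (an array unit that exists only to release STARs).

`build_amplifier()` (one unit; identical to the core model),
`build_cascade()` (inducible STAR50 stage → STAR10 array amplifier →
reporter, on plasmids with default multipliers 10/5/1) and
`build_multiplex()` (one array releasing STAR10 and STAR50 pools that
independently drive GFP and RFP) construct the three studied topologies.
`simulate_circuit()` chains closed forms in topological order;
`simulate_circuit_ode()` integrates all species jointly and is used as the
independent oracle (agreement to $10^{-3}$ relative on random circuits).

Because the multiplex branches share only the transcript, the model has no
retroactivity or resource competition: GFP depends on $n$ only and RFP on
$m$ only, to machine precision. This is a modelling choice that matches the
argument for why output ratios are set by copy numbers; real cells can
violate it through shared RNAP or degradation machinery.

A consequence of the reconstruction worth knowing: the cascade's *off*
state is amplified by array copies too (leak transcription of the stage-1
target feeds the array), so x4 > x1 holds in both on and off states. The
model's fold activation (on/off ratio) for x4 exceeds x1 at the defaults,
whereas measured 3-plasmid cascades show comparable or slightly reversed
folds; the reconstruction does not pin down where leak amplification
saturates, so only the level orderings are asserted.

## The plate-reader pipeline

`correct_plate()` implements the standard three-step arithmetic in a fixed
order: subtract media-blank means from OD and FL; form FL/OD per well;
subtract the blank-cells (autofluorescence) mean FL/OD. Wells whose
corrected OD is at or below `od_floor = 0.01` would amplify blank noise
without bound, so their ratios are set to `NA` and flagged. Negative
autofluorescence-subtracted values are retained, not clipped — clipping
would bias replicate means upward near the detection floor.

`build_standard_curve()` converts inducer concentration to *relative
promoter activity* via the same plate's inducible-GFP control: knot means,
isotonic-adjusted if non-monotone (with a warning), piecewise-linear
interpolation by default (a Hill fit is available behind `rule = "hill"`),
normalised so the highest-induction knot is 1.0. The normalisation anchor
is configurable in the sense that any rescaling is a post-hoc multiplication;
the package fixes the top knot because the fully induced control is the
only condition every dose series shares. Extrapolation above the top knot
is refused; queries below the lowest knot return the basal activity.

`copy_correlation()` uses replicate-level points, so 5 copy levels × 4
replicates give df = 18. `welch_ttest()` reports the exact fractional
Welch–Satterthwaite df (used for the p-value) *and* the pooled convention
`n1 + n2 - 2` that balanced n = 4 designs commonly quote as df = 6.
`anova_tukey()` wraps `aov()`/`TukeyHSD()` with significance annotations at
.05/.01/.001; a design with zero between-group signal (F = 0/0) is reported
as p = 1.

## Synthetic data: the stated world

`generate_copy_sweep()` emulates a copy-number characterisation: copies
{1, 2, 4, 6, 8} × an inducer dose series × 4 biological replicates, plus
inducible-GFP standard-curve wells, media blanks and blank cells. The
measurement model is:

* **lognormal biological noise** (unit mean, CV `cv_bio = 0.1`) per
  replicate on the true expression `gain * G_star` — multiplicative noise
  keeps FL strictly positive with roughly constant replicate CV across the
  dynamic range, which is what s.d. error bars across conditions look like;
* **additive Gaussian read noise** (`sd_read = 20` raw FL units);
* OD above blank lognormal (mean 0.5, CV 0.05); raw FL =
  `(expression + autofluorescence) * OD_above_blank + media baseline`.

Calibration gain ($10^4$ FL/OD per model a.u.), autofluorescence (200
FL/OD) and the media baselines (OD 0.04, FL 100) are arbitrary but fixed.
The dose → input ground truth is a Hill response (h = 1.5, c50 = 0.06 %
arabinose or 40 µM cumate, basal 0.02) normalised so full induction equals
the reference input 0.5 — the input at which copy-number gain is read out.
Noise defaults are plausible stand-ins, not fits to the study's replicate
distributions, which are not available here.

What a green test does and does not establish: with zero noise the pipeline
returns the generating model's FL/OD exactly (a round-trip identity, i.e. a
test of the pipeline's arithmetic, not of the biology); with default noise
the copy-number Pearson r is ≥ 0.95 for ~95% of seeds, matching the
experimentally observed linearity regime. The generator does not emulate
growth differences between species, time-resolved reads, plate position
effects, or saturation of the detector, so agreement here says nothing
about those failure modes.

`recover_parameters()` fits the closed form to condition means by bounded
least squares (L-BFGS-B). `eps` and `gain` enter as a product wherever
$\theta$ is linear, so they are only jointly identifiable across several
copy levels; the degenerate request (both free, one copy level) is refused
rather than returned with an enormous interval. At default noise the median
relative error of a free `{eps, lam}` fit over 50 seeds is below 10%, and
the bias vanishes as `cv_bio → 0`.

## Sequence assembly

`assemble_array()` interleaves STAR and insulator parts per the
Golden-Gate-style scheme: every part carries 4-nt fusion overhangs at both
ends, adjacent parts must agree on the junction overhang, and the assembled
sequence keeps one copy of each shared scar (length = Σ part lengths − 4 ×
junctions). The per-junction checks, a forbidden-site scan (BsaI by
default, both strands, 0-based half-open coordinates, palindromic hits
deduplicated per locus) and direct-repeat statistics are reported together.
`repeat_risk()` finds the longest exactly repeated substring by suffix
sorting (verified against a quadratic brute force) — tandem arrays are
repetitive by design, and the score (length × copies) quantifies the
recombination-prone sequence an assembly carries. The shipped part
sequences are synthetic placeholders with the right structure (the real
parts and overhangs live in the study's supplementary tables); replace
`inst/extdata/synthetic_parts.fa` with real parts for design work.
Insulator quality enters the kinetics only through `eps` (defaults:
shcsy4hp 0.90, csy4hp 0.75, PlmJ 0.05 — ordering per the observed x4/x1
performance, values estimates); no RNA folding is predicted.

## Known limitations

* The kinetic constants are reconstructions with arbitrary units; absolute
  outputs are not comparable to fluorescence counts except through the
  synthetic calibration gain.
* No stochastic (SSA) simulation, no growth-coupled dilution beyond
  first-order degradation, no time-varying inducer protocols.
* Circuit coupling is instantaneous in the driver's activated fraction;
  transcription/maturation delays are not modelled.
* The multiplex independence property is exact only because resource
  competition is deliberately excluded.
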