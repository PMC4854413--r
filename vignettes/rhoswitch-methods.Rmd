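---
title: "Methods: Boolean modelling of the Rac1/RhoA switch and leading-edge FRET quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Boolean modelling of the Rac1/RhoA switch and leading-edge FRET quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhoswitch)
```

## The model

`rhoswitch` models EGFR1 signalling at the front of an invasively
migrating cell as a Boolean network: each of the 41 species is ON (1) or
OFF (0), every reaction takes one time increment, and each non-clamped
node updates by a rule built from AND, OR and NOT over its regulators.
The network has one clamped input (EGF, held ON to represent sustained
stimulation during RCP-driven receptor recycling), two nominated outputs
(Rac1 and RhoA) and 38 intermediates. Five nodes start ON — PDK1, mTor,
c-Src, Pip2 and Rac1 — representing basal activity before stimulation;
everything else starts OFF. Three input-less inhibitory phosphatases
(PTEN, SHIP2, PP2a) are *constitutive*: they carry no inward edges, hold
their state for all time, and their "knockout" consists of clamping them
ON rather than OFF.

Two structural motifs drive all the dynamics of interest:

1. **A negative feedback loop on Sos1.** Sos1 activates
   Ras → Raf1 → MEK1/2 → ERK1/2 → p90RSK (the last requiring active PDK1),
   and active ERK1/2 or p90RSK feedback-phosphorylates Sos1, switching it
   OFF. With the chain lengths in this transcription the loop settles into
   an 11-increment limit cycle in which Sos1 is ON for 5 increments and
   OFF for 6. The Rac1-activating Sos1–Eps8–Abi1 complex (node `Sos1E`)
   follows Sos1 and therefore pulses with the loop.
2. **An incoherent pair of paths onto Rac1.** The fast branch
   (PI3K → PIP3 → Akt, with IQGAP1 recruitment) activates the sole Rac1
   inhibitor pRacGAP1 at t = 5; the slower branch assembles `Sos1E`, which
   first fires at t = 6. Which of the two wins is not decidable from the
   wiring alone — it depends on the regulators' relative binding
   preference for Rac1, which is exactly what the hierarchy abstraction
   captures.

### Precedence semantics of the Rac1 rule

A GEF and a GAP cannot engage the same GTPase simultaneously, so when
several Rac1 regulators are active the highest-precedence one wins. With
activators $A \in \{\mathrm{Vav2}, \mathrm{RalBP1}, \mathrm{Sos1E}\}$ and
the inhibitor $I = \mathrm{pRacGAP1}$, a hierarchy assigns each activator
a side relative to $I$ and compiles to

$$\mathrm{Rac1}' \;=\; \bigvee_{A} \Big[ A \wedge \neg \big(\textstyle\bigvee I_{>A}\big) \Big] \;\vee\; \big[\mathrm{Rac1} \wedge \neg I\big],$$

where $I_{>A}$ are the inhibitors ranked above $A$. The self-maintenance
literal is required: Rac1 starts ON and must persist until the inhibitor
fires, which is what produces the observed one-increment OFF switch after
pRacGAP1 activates. Because activators on the same side of the inhibitor
are interchangeable, there are exactly $2^3 = 8$ distinct hierarchies
(`enumerate_hierarchies()`), and promoting an activator above the
inhibitor can only enlarge the rule's ON-set (a property the test suite
checks by truth-table enumeration).

The direct RhoA→Rac1 antagonism edge is grouped with the inhibitor guard
(an activator above pRacGAP1 also overrides RhoA's antagonism). Ranking
this edge above Sos1E would make it impossible for Rac1 to switch ON
while RhoA is still ON, contradicting the cyclic hierarchy's observed
trace, so the grouped form is the only consistent choice.

### Transcription choices

The full interaction table of the source model is a supplementary
document that is not machine-readable here, so the network shipped in
`inst/extdata/rcp_egfr_network.txt` is a fresh transcription. Every rule
carries a provenance tag: `curated` where the interaction is named
explicitly in the narrative sources, `transcribed` where the wiring was
read off pathway-map context and the exact gate is a modelling choice.
Two such choices deserve mention because the headline behaviours pin them
down:

* `Sos1E = Sos1 AND Eps8 AND Abi1 AND Ras`. The Ras conjunct encodes
  Ras-dependent activation of the complex; it also delays the complex's
  first firing to t = 6, one increment after pRacGAP1. Without it the
  complex would fire *before* the inhibitor and the initial Rac1-OFF
  switch of the cyclic hierarchy would never occur.
* `RalBP1 = RalA OR Ras`, a redundant short Ras route alongside
  Ras → RalGDS → RalA. The OR over two path lengths widens RalBP1's ON
  pulse to 7 of 11 increments; with a single chain the RalBP1-top
  hierarchies would show RhoA ON-fractions above one half,
  i.e. RhoA dominance, which is reserved for the Sos1E-top hierarchy.
* Grb2 is modelled as its own node in the EGFR1 → Shc → Grb2 → Sos1
  adaptor chain rather than folded into Sos1 activation; the extra chain
  length is also what separates the loop's timing from the Akt branch.

Basally active nodes (PDK1, mTor, c-Src, Pip2) carry self-maintaining
rules (`PDK1 = PDK1 OR PIP3` and so on); this keeps them ON from t = 0
while still allowing a knockout to silence them.

## Simulation and classification

Synchronous updates recompute every ruled node simultaneously;
trajectories are deterministic, so the attractor is found by hashing
states along the orbit until the first repeat (`find_attractor()`), which
the pigeonhole principle bounds by $2^N$ steps. Over the attractor cycle
each node is classed `stable_active`, `stable_inactive` or `cyclic`, and
the Rac1/RhoA pair maps to the output taxonomy: `rac_persistent`,
`switch`, `cyclic` (with a RhoA-dominance flag comparing ON-fractions),
or `other` for combinations reachable only under perturbation (e.g. both
outputs OFF after a Vav2 knockout). Note that under *every* hierarchy the
Sos1 feedback loop keeps oscillating — the hierarchy only changes Rac1's
rule — so even the "switch" attractor is an 11-cycle globally, with the
two outputs constant on it.

Random-asynchronous updates draw, at each increment, one node uniformly
from the currently unstable set (rule value ≠ state) and update it; if no
node is unstable the state carries over. "Unstable node" is the natural
reading of "at most one executable reaction per increment": it reduces to
invariance exactly at fixed points. The generator is seeded per run and
the caller's RNG state is restored, so traces are reproducible
bit-for-bit from `(network, T, seed)`. Robustness statistics default to
10 repeats of 2000 increments, summarised as each output's total ON time
from the first increment at which Rac1 is OFF and RhoA is ON; because the
source figure prints no numeric values, only the ordering
(RhoA > Rac1) and the persistence of cyclic activity are asserted.

In-silico knockouts remove all inward edges of one node and clamp it OFF
for all time *including t = 0* (so basally ON nodes obey "remained OFF
for all time"), or clamp the constitutive phosphatases ON. The screen
covers every non-output node under both experimentally admissible
hierarchies. Comparing screens across hierarchies is done at the level of
*effects* (did the knockout change the category relative to that
hierarchy's baseline?) because the baselines themselves already differ.

## The FRET pipeline

The image stage quantifies ratiometric biosensor movies in a crescent at
the cell front:

1. **Registration.** Channels are aligned per frame by upsampled
   cross-correlation: integer peak first, then a matrix-multiply DFT
   evaluates the correlation on a 1/100-px grid in a 1.5-px
   neighbourhood. Resampling uses a Fourier-domain phase ramp, which
   preserves the 0.01-px precision without choosing an interpolation
   kernel. Constant images yield a zero shift with a warning; estimates
   whose normalised correlation peak falls below 0.3 are flagged
   low-confidence.
2. **Band-pass.** The bright acceptor-direct channel is filtered with the
   à-trous (undecimated) wavelet transform using the separable 3-tap
   kernel (1, 2, 1)/4 dilated by $2^{j-1}$ at scale $j$, keeping detail
   scales 2–8: scale 1 carries single-pixel noise, the residual carries
   the stationary background. Boundary handling is mirror reflection
   about the edge pixel; this is an assumption, as is applying the
   threshold to raw band-passed values without per-frame normalisation.
   The largest dilated kernel spans $2^8 + 1 = 257$ px, so frames must be
   at least that large (the synthetic default is 288 × 288).
3. **Segmentation.** Fixed threshold (2000 grey values, a config default
   that presumes 16-bit acquisition) and 8-connected component labelling;
   all but the largest object are discarded. The labelling is implemented
   in-package because the available library routine is 4-connected and
   diagonal-touching pixels must merge. Because a band-pass removes an
   object's DC component, the recovered mask can differ from the planted
   object by a ring of boundary pixels even at zero noise; object-level
   recovery (only the largest object, Jaccard ≥ 0.99) is the meaningful
   guarantee and is what the tests assert.
4. **Ring and crescents.** The mask is eroded with a *disc* of radius 40
   px (isotropic ring thickness; the element shape is unstated in the
   protocol being reproduced, and a square would thin the ring on the
   diagonals) and subtracted, the ring's axis-aligned bounding box is
   quartered along its longer axis (ties break towards x), and the
   extremal quarters intersected with the ring give the two crescents.
   The manual front identification of the original protocol is replaced
   by a `front_hint` (axis end or crescent index) at frame 0; later
   frames pick the crescent with maximal pixel overlap with the previous
   front, which follows a rigidly translating cell without intervention.
5. **Ratio.** Numerator and denominator are Gaussian-smoothed
   (σ = 1.0 px) *before* dividing — the order matters on gradient images
   and is pinned by a test against a direct oracle — and pixels whose
   smoothed denominator equals zero are excluded rather than clipped.
   The per-frame mean over the front crescent and the mean of those
   means are reported; ratios are invariant to rescaling both channels,
   and display LUT bounds play no part in computation.

## Synthetic data

The generators define the conditions under which every claim is tested.

* `gen_random_network()` draws, per node, regulators with probability
  `edge_density` (default 0.25), groups them into 1–3 conjunctions OR-ed
  together, and negates literals with probability
  $1/(1+\mathrm{act\_inh\_ratio})$ (default ratio 3:1, activation-heavy
  like the curated network). Networks of ≤ 12 nodes are used for oracle
  equivalence because $2^{12}$ states keep exhaustive transition-graph
  enumeration exact and fast.
* `gen_fret_stack()` renders a rigidly translating ellipse (default
  semi-axes 70 × 52 px in a 288 × 288 frame, 2 px/frame drift): the
  masking channel is flat at 8000 grey values inside the cell (well above
  the 2000 threshold after band-passing, since a cell-sized object lies
  inside the kept 2–512 px pass-band), the donor is flat at 1000, and the
  FRET channel encodes a front/back ratio split along the long axis
  (defaults 1.8 front / 1.1 back, the contrast scale seen in leading-edge
  biosensor work where ratios range roughly 1.0–2.0). Noise is
  Poisson-like shot noise (variance `noise` × signal; 0 by default so
  exactness claims are checkable, with factor 20 ≈ 14% CV on the donor
  as the "moderate noise" condition) plus Gaussian read noise, emulating
  EM-CCD acquisition without modelling camera specifics. Known channel
  misalignments are planted with the same Fourier translation the
  registration inverts.

What the generators do *not* emulate — deforming cell outlines, spatially
varying expression, bleed-through, photobleaching — bounds what passing
tests show: the pipeline's correctness and recovery guarantees hold for
rigid, well-exposed cells, not arbitrary real movies.

## Numerical choices and limitations

* Attractor detection relies on synchronous determinism; asynchronous
  attractors are not enumerated (only trajectory statistics are
  reported).
* The asynchronous ON-time counts state occupancy per increment, not
  update events; with at most one flip per increment the two differ only
  by bookkeeping, and only orderings are asserted.
* Timing assertions are made *relative* (Rac1 switches one increment
  after its dominant regulator), not at absolute increments, so they are
  robust to transcription changes upstream of the receptor.
* The problem sizes used throughout (50 synchronous increments, 2000
  asynchronous increments × 10 seeds, 100 random networks ≤ 12 nodes,
  288-px frames with ≤ 8 frames) were chosen as the smallest sizes at
  which each claim is exercised in full.
* Double knockouts compose (`apply_knockout()` is idempotent and
  order-independent) but are not part of the screen; edge-level
  perturbations, SBML-qual I/O and multi-valued logic are out of scope.
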