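---
title: "From binding kinetics to cellular response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From binding kinetics to cellular response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsig)
```

## The scientific problem

Whether a receptor antagonist works in a living system depends not only on
its affinity but on *how fast* it binds and unbinds — and on the binding
kinetics of the endogenous agonists it competes with. At the neurokinin-1
(NK1) receptor this interplay is especially stark: substance P (SP)
associates 240-fold faster than neurokinin A (NKA), while clinically
successful antagonists such as aprepitant owe their efficacy to very slow
dissociation (koff on the order of 0.005 min^-1, a residence time of
hours). `kinsig` provides a mechanistic simulator for this situation —
competitive binding kinetics feeding a transient functional readout — plus
the analysis statistics used to quantify it: the kinetic rate index (KRI)
from dual-point competition association assays, peak analysis with
variable-slope concentration–response fitting and normalization,
IC50-at-EC80 inhibition fitting, the onset-of-activation slope over the
first 8 minutes, Dunnett many-to-one comparisons, and a surmountability
classification.

## The binding model

One receptor pool of density $R_{tot}$ (default 1, so all bound amounts
are fractional occupancies) interacts with up to a handful of ligands by
mass action:

$$\frac{dRL_i}{dt} = k_{on,i}\,L_i(t)\,R(t) - k_{off,i}\,RL_i(t),
\qquad R(t) = R_{tot} - \sum_i RL_i(t).$$

Free ligand concentrations $L_i(t)$ are piecewise constant between
addition events (no depletion — plate assays use a large reservoir of free
ligand relative to receptor). Pre-incubation is an antagonist-only event
for exactly 30 min before agonist addition, with no washout, matching the
functional protocols being emulated. The system is integrated with
`deSolve::lsoda` at rtol 1e-8 / atol 1e-10; event times are hard
breakpoints at which integration restarts, because the per-segment
right-hand side is then smooth.

Two closed forms serve as independent oracles. For two ligands co-added at
t = 0 the bound radioligand follows the Motulsky–Mahan biexponential
(`motulsky_mahan_binding()`, with the analytic equal-rate limit handled
explicitly rather than by division of near-zero differences); the ODE
matches it to better than 1e-4 relative over four decades of
concentrations and rate constants. At long times occupancy converges to
the Gaddum competitive-equilibrium expression (`gaddum_occupancy()`), and
a fast-equilibrating antagonist shifts an agonist curve by the Schild dose
ratio $1 + I/K_B$ (`schild_shift()`).

```{r}
ligs <- nk1_reference_ligands()
kd(ligs$SP)   # 0.1125 nM
kd(ligs$NKA)  # 190 nM
```

The SP and NKA rate constants are published values (kon 0.24 and 0.0010
nM^-1 min^-1; koff 0.027 and 0.19 min^-1). The antagonist fixtures are
*synthetic reconstructions*: rate constants for aprepitant and its
desfluoro analogue (DFA) are not published, so koff is taken as 0.0054
min^-1 for aprepitant (its reported room-temperature value) and as the
radioligand koff for DFA (whose KRI of 1.0 implies radioligand-like
dissociation), with KD = 10^-pKi and kon = koff/KD. The radioligand — a
labelled SP analogue — defaults to SP's own rate constants; this is an
assumption, as its individual rates are not published. Temperature is not
modelled; different assay temperatures are represented, if needed, by
supplying different rate constant sets.

## The transduction model

The measured signals (GloSensor-type cAMP luminescence; xCELLigence-type
impedance) rise and fall over tens of minutes while receptor occupancy is
often complete within one or two. The transient is generated by
first-order desensitization of newly activated receptor:

$$\frac{dA}{dt} = \frac{dB}{dt} - k_{des} A, \qquad
\frac{dr}{dt} = k_{syn}\,\frac{g\,\varepsilon\,A}{1 + g\,\varepsilon\,A}
 - k_{deg}\,(r - basal),$$

where $B(t)$ is agonist occupancy, $A$ the active (not yet desensitized)
fraction, and the hyperbolic coupling with gain $g$ is operational-model
style. This structure was chosen over plain response auto-decay because
desensitization makes the *time* of the peak concentration-dependent
(weak stimulation peaks later), as real traces do. Hyperbolic rather than
linear coupling lets two phenomena emerge without extra machinery:
receptor reserve (high gain compresses the EC50 well below the agonist
KD) and genuine Emax depression by slowly dissociating antagonists.

Two named calibrations are shipped and fully overridable:

| parameter | `camp` | `impedance` | units |
|---|---|---|---|
| gain      | 3    | 30   | – |
| k_syn     | 100  | 0.05 | readout units min^-1 |
| k_deg     | 0.06 | 0.08 | min^-1 |
| k_des     | 0.06 | 0.09 | min^-1 |
| basal     | 20   | 0.1  | readout units |

Both are calibrated so that a saturating agonist peaks 20–30 min after
stimulation (24 and 26 min respectively on the default grid). The
impedance profile's 10-fold higher gain encodes the observation that
label-free whole-cell readouts report systematically left-shifted
potencies (they integrate multiple signalling pathways; the cell lines
used carry more receptor reserve). Its consequence — morphology assays
pick up potency shifts, cAMP assays pick up Emax depression — reproduces
the qualitative assay-sensitivity split seen experimentally.

Replicate noise is multiplicative-plus-additive Gaussian
(`value * (1 + eps_m) + eps_a`), because plate luminescence and impedance
scatter scales with the signal; the default cv of 0.10 sits in the 5–15%
range typical of replicate scatter in such assays.

## Synthetic experiments

Protocol builders compose these pieces into the four experiment families:
agonist concentration–response with optional antagonist pre-incubation
(default panel 0.07/0.21/0.7 nM, 30 min), antagonist titration against a
fixed EC80 agonist challenge, dual-point competition association
(radioligand 2.5 nM, reads at t1 = 30 and t2 = 120 min), and single time
courses. `generate_dataset()` runs binding → transduction → noise for
every condition and emits a tidy table (one row per time point, condition
and replicate) with a metadata echo sufficient to regenerate the dataset
bit-for-bit; the JSON sidecar serializes doubles at 17 significant digits
for exactly that reason. Noise substreams are keyed by a string hash of
the condition id, so adding or reordering conditions leaves the other
conditions' draws untouched.

Time is exported with t = 0 at agonist addition (pre-incubation occupies
negative time internally and is shifted out), on a 1-min grid over 45 min
by default — the sampling interval of the original real-time reads is not
documented, and 1 min resolves both the 8-min onset window and the
20–30 min peak. The binding ODE itself runs on a finer 0.25-min internal
grid.

What the generator does *not* emulate: plate-geometry and edge effects,
liquid-handling artifacts, ligand depletion, luciferase substrate
kinetics, temperature, and G-protein-pathway branching. Passing tests
therefore demonstrate internal consistency of the kinetic theory and the
analysis chain, not instrument-level realism.

## Analysis procedures

**KRI.** The dual-point statistic is the ratio of competitor-inhibited
specific binding at the two reads, $KRI = B_{t1}/B_{t2}$: above 1 means
the competitor dissociates more slowly than the radioligand, below 1
faster. Nonspecific binding is taken as zero, so "specific binding" is
the bound-radioligand state itself. The assay design rule is to use the
competitor concentration giving roughly 50% (30–70%) inhibition *at the
read*: `dual_point_design_conc()` root-solves the Motulsky–Mahan model at
t2 for it. The distinction from the equilibrium IC50
(`gaddum_ic50()`) matters: at fixed KD an ultra-slow koff implies an
ultra-slow kon, and at the equilibrium IC50 such a competitor barely
binds within 120 min at all (KRI drifts back toward 1). With the
at-the-read design concentration, simulated KRI decreases monotonically
in competitor koff — from about 1.48 at koff 1e-4 min^-1 to 0.79 at
1 min^-1, crossing 1.000 exactly at the radioligand's own koff — spanning
the 0.7–2.0 range reported by kinetic screens of this receptor.

**Peak analysis and fitting.** The peak is the maximum of
(value − baseline) per trace; baseline is the mean of the pre-stimulation
window, or the first sample if none exists. No smoothing is applied —
replicates carry the noise handling. Two replicate conventions are
available: per-replicate peaks (default; required for replicate-level
statistics) and `aggregate_replicates = TRUE`, which averages the
replicate wells of one in-silico "experiment" into a single trace before
taking the peak, as plate workflows do. The averaged form is preferred
for curve fitting because the maximum of a noisy 46-point trace is biased
upward (about +7% at cv 0.05; averaging triplicates cuts it to under 4%).
Concentration–response curves are fitted by unweighted least squares to
the variable-slope logistic
$r = bottom + (top-bottom)/(1+10^{(\log EC_{50}-\log L)\,hill})$ with
minpack.lm's Levenberg–Marquardt, multi-started from five deterministic
log-spaced EC50 initializations; non-convergent or degenerate inputs
return a flagged result rather than an error. Normalization divides
everything by the fitted control top (less noise-sensitive than the
single largest observed value — a deliberate choice where the original
workflow is unstated), so the control's normalized Emax is 100% by
construction and the transformation is invariant to readout units.
EC80 = EC50·4^(1/hill) feeds the inhibition design; the IC50 fit is the
same logistic with negative slope, with the antagonist-free control
anchoring the upper asymptote.

**Onset.** The onset of receptor activation is the ordinary
least-squares slope of the readout over samples strictly after agonist
addition up to and including 8 min, fitted per replicate and averaged.
On the 1-min grid that is 8 points; at least 3 are required.

**Statistics and classification.** Group comparisons versus the
agonist-only control use one-way ANOVA followed by Dunnett's many-to-one
test (via multcomp; the multivariate-t integration is seeded, making
results reproducible). Statistics run on per-replicate values, not their
means. Surmountability is classified from normalized fits plus the
Dunnett result: *surmountable* when the Emax reduction is not
significant, *partially insurmountable* when significant but normalized
Emax stays at or above 50%, *insurmountable* below 50%. The 50% cut is a
package convention — the labels are used qualitatively in the
experimental literature — chosen so that reported examples (82%
significant → partially insurmountable; 7.8% → insurmountable) fall on
the intended sides.

## Design choices in the validation experiments

Two of the emergent-behaviour checks need design commitments the
underlying theory does not fix by itself.

*Probe dependency.* The claim is that the same slowly dissociating
antagonist suppresses the onset of NKA-driven activation at least as much
as SP-driven activation. At literally matched fractional occupancy
(same L/KD) this cannot hold in a pure mass-action model: at matched
occupancy the absolute association rate kon·L is proportional to koff, so
NKA — with its 7-fold larger koff — always out-associates SP and the
antagonist always suppresses SP more. What makes NKA the more sensitive
probe experimentally is that measured potencies are compressed relative
to affinities: the reported cAMP EC50s (2.2 nM for SP, 483 nM for NKA)
differ by a factor ~220, less than the 240-fold kon ratio, so at
equi-effective (EC80) challenge SP is the marginally faster binder and
NKA pays the larger kinetic penalty — both through free-pool competition
and through the ratchet by which every NKA dissociation event risks
recapture of the receptor by the long-residence antagonist. The package
therefore implements the "matched challenge" as the equi-effective EC80
challenge built from those reported potencies (8.8 and 1932 nM at hill
1), with a fast-associating, slowly dissociating antagonist
(kon 0.24 nM^-1 min^-1, koff 0.005 min^-1, 0.7 nM, 30-min
pre-incubation). Under that design the simulated onset folds are ~6.3
(SP) versus ~6.9 (NKA).

*Limit-behaviour tests.* The surmountable (Schild) limit is checked with
a fast-equilibrating agonist/antagonist pair (both koff ≥ 0.5 min^-1) so
the equilibrium assumption of the dose-ratio formula actually holds on
the assay timescale; the insurmountable limit uses koff 0.005 min^-1 at
10×KD — pre-incubation at exactly 2×KD cannot exceed ~36% equilibration
within 30 min for so slow a binder (the pre-equilibration rate is then
3·koff), so a higher multiple of KD is the regime the assay design
intends. The same logic bounds the residence-time monotonicity property
to antagonists that actually pre-equilibrate (koff ≥ 0.03 min^-1 at the
concentrations used).

## Numerical choices and degenerate inputs

- Integrator tolerances rtol 1e-8 / atol 1e-10; integrator failure is an
  error, never silent. Tiny negative round-off in bound series is clipped
  at 1e-12.
- The active-state ODE is propagated by an exact exponential update
  assuming piecewise-linear occupancy between grid points; the readout
  ODE runs on the same grid.
- The Motulsky–Mahan equal-rate degeneracy (KF = KS) switches to the
  analytic limit when the rate split is below 1e-10 of KF.
- Fits: concentrations must be strictly positive and, for the inhibition
  fit, the zero-antagonist control is represented three decades below the
  lowest tested dose. Responses with no spread, or fits converging with
  the wrong slope sign, are flagged (`converged = FALSE`), as are EC50s
  extrapolating more than one log outside the fitted range.
- All randomness flows from explicit integer seeds; dataset noise streams
  are condition-keyed, Dunnett integration is seeded, and `.Random.seed`
  is restored after use.

## Problem sizes

The shipped validation suite uses desk-scale problems chosen as the
smallest that exercise each property: 8-point concentration series,
1–3 replicates, 45-min horizons, 100 seeded repeats for parameter
recovery, and 2000 simulated experiments for the family-wise error check
of the Dunnett procedure (6 groups, n = 6, nominal alpha 0.05).

## Known limitations

- Free-ligand depletion and rebinding/diffusion microkinetics are not
  modelled; claims about "preventing rebinding" mechanisms are outside
  what this simulator can address.
- kon/koff are inputs, never fitted; the package does not estimate rate
  constants from competition-association data.
- The transduction stage is a generic transducer, deliberately agnostic
  about which G-protein pathway carries each readout.
- Reported empirical potency/efficacy tables for the antagonists cannot
  be reproduced quantitatively because their rate constants are not
  published; the antagonist fixtures are labelled reconstructions and all
  antagonist-dependent checks are property-based.
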