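---
title: "Predicting gas-phase charge states: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gas-phase charge states: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protomeR)
```

## The problem and the model

An electrosprayed small molecule carries its proton (or its vacancy) on
one of several titratable nitrogens or oxygens, and ion-mobility mass
spectrometry is sensitive to which one: different protomers have
different geometries and collision cross sections. protomeR ranks the
candidate charge sites with a two-pass screen so that expensive
quantum-chemical refinement can start from one or two models instead of
all of them.

The first pass is statistical: each candidate model is summarized by ten
rigid-motion-invariant steric/electronic descriptors and a
gradient-boosted-tree (GBT) regressor predicts its relative energy (RE,
kcal/mol). RE is always defined within one molecule's ensemble — the
most stable model of a system has RE 0 — so the regression target is
comparative, not an absolute energy. The second pass is physical: the
models that survive pruning are relaxed for a bounded number of
minimizer steps under a potential backend and reranked on the refined
relative energies; Boltzmann weighting converts those into gas-phase
mole fractions.

Protonation enumeration keeps every N or O with an available lone pair
(amide N and O included, quaternary/hypervalent N, nitro N and
oxonium-like O excluded); deprotonation keeps every N–H and O–H. This
deliberately over-enumerates relative to chemical intuition — a pyrrole
nitrogen, say, is rarely the preferred gas-phase protonation target —
because the ranking stage, not the perception stage, is where
unfavourable sites should lose. Carbon and othergen (S, P, Se) titration
are out of scope: gas-phase training evidence for them is thin and they
are rare in routine IM-MS work.

Sites that are equivalent under the molecular graph's automorphisms
(the two nitrogens of ethylenediamine) are collapsed to one
representative, implemented by iterated Weisfeiler–Lehman color
refinement seeded with element, degree, bond-order sum and hydrogen
count. On molecular graphs at this size the refinement separates
everything the automorphism group separates.

## The descriptors

Beyond atom counts (O, N, halogens F/Cl/Br/I, othergens S/P/Se) and the
charge-bearing atom's tabulated static dipole polarizability, the
descriptors are geometric. The center of electronegativity

$$\mathrm{COE} = \frac{\sum_i e_i \mathbf{r}_i}{\sum_i e_i}$$

is the electronegativity-weighted analogue of the center of mass: a
proxy for where electron density concentrates, hence where a proton is
attracted. The scale is Pauling — the conventional default — and the
table is snapshotted inside the package so values never drift with
dependency versions; the same applies to the masses (IUPAC 2021),
covalent radii (Cordero), van der Waals radii (Bondi) and
polarizabilities (2018 recommended static dipole values). The
interaction angle is measured at the COE vertex between rays to the COM
and to the CBA; the vertex choice is a convention (the geometry defines
three possible vertices) and is fixed, not fitted. It is computed in the
atan2 form, which stays well-conditioned when the three points are
nearly collinear.

The molecular surface area is a solvent-accessible Shrake–Rupley area
with a 1.4 Å probe and 960 dots per atom. Two numerical choices matter.
First, the dot template is a golden-spiral layout, so the area is
deterministic. Second, each atom's template is expressed in a local
frame anchored to its neighbour geometry (nearest atom defines the
first axis; the first non-collinear neighbour, ordered by rounded
distance then index, the second). This makes the discretized area
*exactly* invariant under rigid motion of the input rather than
invariant only in the many-dot limit — without it, rotations jitter the
area by ~0.1%, far above the 1e-6 invariance the feature contract
promises. Atoms in perfectly collinear environments fall back to an
arbitrary perpendicular, where burial is axisymmetric and the choice
cannot affect the count.

## Ranking, pruning and refinement

The GBT is an xgboost regressor (defaults: 300 trees, depth 6, learning
rate 0.1, single-threaded for bitwise reproducibility), trained with a
20% hold-out split *by system* so no molecule's ensemble straddles the
split. The stored held-out RMSE travels with the saved model because the
pruning heuristic needs it at prediction time:

$$\wedge = \frac{1}{3}\,\frac{\mathrm{RMSE} + \mathrm{RE}_{\min}}{\sigma + S}$$

with σ and S the population standard deviation and variance of the
ensemble's predicted REs. The expression is dimensionally heterogeneous
(kcal/mol over kcal/mol + kcal²/mol²); it is implemented literally in
kcal/mol units and treated as the heuristic it is. Intuitively: an
uncertain regressor (large RMSE) or a weakly separated ensemble (small
σ + S) should let more models through to refinement. The number
forwarded is k = clamp(⌈∧⌉, 1, n) — the ceiling preserves the
"capacity" reading and guarantees the safeguard that rank 1 always
advances. A single-model or all-tied ensemble makes the denominator
degenerate; the capacity is then defined as 1. Both σ-conventions and
the ∧→k mapping are population-form and ceiling by decision: the
population form is defined for n = 1, and any rounding rule sharper than
the ceiling would sometimes forward zero models.

Feature importance uses mean increase in RMSE (MIR): retrain without a
feature over repeated seeded splits and average the held-out RMSE
increase. It is slower than split-gain importances but measures the
quantity of interest directly.

Refinement is deliberately *soft*: at most 50 minimizer iterations.
The point is to relax the placed proton and local strain without letting
a cheap potential carry the structure to artifacts; the refined energies
are used comparatively, for reranking, not as thermochemistry. Backends
are pluggable behind a three-field contract (supported elements,
single-point energy, bounded minimize; kcal/mol at the interface). Two
ship with the package: a deterministic classical harmonic potential
(bond springs on the perceived topology plus a steep non-bonded
repulsion, minimized by L-BFGS) used throughout the tests, and an Open
Babel MMFF94/UFF wrapper. Both advertise the H/C/N/O/F/Cl/S element set
of the ANI-2x neural potential, so surrogate substitution — Br/I
temporarily become Cl, P/Se become S, then the symbols are restored
after optimization — is exercised exactly as a neural backend would
require it. The toy backend has no physical pretension beyond a
well-defined, element-dependent energy surface with minima near standard
covalent geometry; what it buys is bitwise determinism with no model
weights or downloads.

Mole fractions are Boltzmann populations of the refined REs at a
configurable temperature (default 298.15 K), with R =
1.98720425864×10⁻³ kcal/(mol·K). Ranking ties are broken by ascending
CBA index (first pass) and by the better initial rank (second pass) so
every run is deterministic.

## Building structures

SMILES input is embedded with RDKit's ETKDG distance-geometry method
under an explicit seed and relaxed with MMFF94; the step budget is
max(200, 10 × n_atoms) so small molecules always relax fully while
larger, floppier ones get proportionally more work. Seeded ETKDG was
chosen over Open Babel's 3D builder specifically because the latter's
conformer search is stochastic with no seed control, which would break
the pipeline's reproducibility contract. XYZ input is read as-is, with
bonds perceived by a covalent-radius criterion (1.25 × radius sum) —
standard, deterministic and testable. Proton placement puts the new H at
1.02 Å (N) or 0.98 Å (O) opposite the sum of existing bond vectors;
the exact distance is immaterial because geometries are re-optimized
downstream.

## What the synthetic generator does and does not show

The bundled generator emulates the *shape* of a real training table: per
system it draws 4–8 candidate models (matching the ~7 titratable sites
typical of IM-MS test molecules), samples descriptors over plausible
physical spans (distances 0–10 Å, angle 0–180°, MSA 50–800 Ų, counts
0–6), assigns a raw energy from a planted linear combination — by
default 2 kcal/mol per Å of CBA–COE distance — plus Gaussian noise at
10% of the signal range (2 kcal/mol), and converts to RE labels by
subtracting the per-system minimum.

Passing the recovery tests (held-out Spearman ≥ 0.8, per-system Kendall
τ ≥ 0.7 at 200 systems, MIR ranking the planted feature first) shows the
training, ranking and importance machinery is correct — it does *not*
show that ten descriptors suffice to predict DFT relative energies of
real protomers, which only a DFT-labelled table can establish. One
structural subtlety the generator exposes: because RE labels subtract a
per-system minimum, the label is not a pure function of the row's
features — it carries a per-system offset (the minimum of the planted
signal across the ensemble) that no regressor can explain from
single-row input. At 4–8 models per system that offset has a standard
deviation near 1 kcal/mol and sets an irreducible floor on held-out
RMSE even for noiseless labels; the noiseless-learnability test
therefore uses 30–40 models per system, where the offset vanishes and
near-zero error is actually attainable.

## Problem sizes and defaults

The test and acceptance workloads use 200 synthetic systems
(~1200 rows) for recovery checks, 150-tree retrains across 3 repeated
splits for MIR, 960 dots/atom for surface areas, 100 random rigid
motions per fixture for invariance, and the 13-molecule frozen library
for enumeration and end-to-end runs — sizes chosen so the full suite
characterizes every stage in well under a minute of compute while the
statistical assertions retain comfortable margins.

## Known limitations

- Single charges only; no carbon or othergen titration; neutral inputs.
- Bond perception from XYZ distances yields order-1 bonds; nitro-group
  and hypervalent exclusions use topology-based heuristics that can
  misclassify exotic valence states.
- The shipped backends are classical; refined REs and mole fractions
  from the toy backend are for machinery validation, not chemistry. A
  neural-potential backend can be plugged in through the
  `potential_backend()` contract.
- The acceptance capacity is a heuristic with no dimensional
  interpretation; its 1/3 prefactor is adopted as given.
- WL color refinement is exact on molecular graphs of practical size
  but is not a general automorphism solver.
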