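---
title: "Quantifying helicase interdomain conformations and assay kinetics"
author: "RecQLandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying helicase interdomain conformations and assay kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RecQLandscape)
```

## The problem

The catalytic core of RecQ-family helicases carries two RecA-like domains,
D1 and D2 (residues 1–219 and 220–364 in human RECQL5), followed by a
Zn²⁺-binding subdomain (365–437) that moves rigidly with D2. ATP binding and
hydrolysis open and close the D1–D2 cleft, and different crystal forms of
one protein — or different family members — are caught at different points
of this motion. Pairwise RMSD comparisons entangle this global hinge motion
with local rearrangements (loop conformations, helix-to-coil transitions at
the nucleotide site), so they answer "how different are these models"
without answering "how open is the cleft".

This package separates the two questions with a deliberately simple
coordinate system: four Cα positions that are structurally invariant within
each rigid unit — Q34 (motif 0) and L79 (motif Ia) on D1; T268 (motif IV)
and F420 (Zn subdomain) on the D2/Zn module — and two cross-domain distances
between them. Since distances are frame-free, no superposition enters the
coordinates themselves; superposition is only needed once, to identify the
anchors on a new structure, or to compute per-residue displacement profiles.

## The conformational coordinates

For a chain with anchor Cα positions $a_{Q34}, a_{L79}, a_{T268}, a_{F420}$,
the default ("cross1") landscape coordinates are

$$\mathrm{axis}_1 = \lVert a_{Q34} - a_{F420} \rVert, \qquad
  \mathrm{axis}_2 = \lVert a_{L79} - a_{T268} \rVert .$$

Which two of the four cross-domain pairings to use is a genuinely open
choice: intra-domain distances are rigid and carry no signal, which leaves
two complementary cross-domain schemes. Both are implemented
(`pairingScheme("cross1")`, `"cross2"`, or a custom list); `cross1` is the
default because it spans the cleft diagonally in both directions (motif 0 to
the Zn subdomain, motif Ia to motif IV) and, on the synthetic hinge
families below, both of its axes are strictly monotonic in the hinge angle
over 0–90°, so larger coordinates consistently mean a more open cleft.
Neither scheme is asserted to be the one behind any particular published
figure; conclusions about grouping are insensitive to the choice because
both schemes order the same states the same way.

Classification of landscape points uses seeded k-means (k = 2 by default,
largest mean axis1 labelled "open", smallest "closed"; k = 3 adds an
"intermediate" cluster), plus an optional margin band that flags points near
the cluster boundary as intermediate. A one-dimensional threshold method on
axis1 is available as a cross-check. When k equals the number of distinct
points, each point becomes its own centre directly (`stats::kmeans` requires
k strictly below the number of points); with fewer distinct points than k
the call fails with a parameter error rather than silently merging.

## Anchor transfer to homologs

Anchors are defined in RECQL5 numbering. For another structure (or a RECQL5
model with shifted numbering) the package derives the one-letter sequence
from the coordinates (selenomethionine reads as M, other non-standard
residues as X, numbering gaps preserved in the index), aligns it globally to
the reference with Needleman–Wunsch under BLOSUM62 and affine gap penalties
(open 10, extend 0.5 — classical protein defaults, exposed as arguments),
and maps each anchor through the aligned columns. An anchor falling in a gap
column, or landing on a residue without a Cα atom, is a hard
`unmappable-anchor` error, never a silent guess. Sequence-based transfer is
a simplification of transfer by structural superposition; at the sequence
identities within the RecQ core it recovers ≥ 99% of true correspondences
on 400-residue sequences carrying 10% substitutions (measured against the
homolog generator's exact mapping), and a manual override (`anchorOverrides`
in `runLandscape`) exists for curated cases where it would not.

The affine gap convention is that a gap of length $L$ costs
$\mathrm{open} + L \cdot \mathrm{extend}$. The test suite pins the
implementation to an exhaustive enumeration oracle over all short sequence
pairs, so the scoring convention is verified, not assumed. Among co-optimal
alignments the traceback is deterministic (the same input always yields the
same mapping); tests assert score optimality and determinism rather than
one specific tie-break order.

## Superposition and displacement profiles

`kabschSuperpose` implements the SVD form of the Kabsch algorithm in double
precision with reflection correction: if the determinant of the candidate
rotation is negative, the smallest singular direction is flipped, so the
result is always a proper rotation (orthonormal, det +1, both to 1e-8;
validity-checked on every object). Fewer than three pairs, or (near-)
collinear point sets (second singular value below 1e-8 of the first), raise
a `degenerate-superposition` error because the rotation is underdetermined.

Displacement profiles superpose structure B onto structure A using only the
Cα atoms of a frame domain, then report $\lVert x_B' - x_A \rVert$ for every
residue common to both structures. The frame defaults to D1 — the
nucleotide-binding domain is the natural fixed reference for reading out the
swing of D2/Zn — but is an explicit argument, since published displacement
figures do not always state their frame and the maximum displacement depends
on it. Residues present in only one structure are dropped, not imputed.

## Synthetic ground truth

The hinge generator (`makeHingeFamily`) builds each domain as an ideal
helical Cα walk (1.5 Å rise, 100° turn, 2.3 Å radius) — compact,
non-collinear point sets whose geometry is exactly known; no attempt is made
at physically realistic folds, B-factors or side chains, because the
quantities under test are purely geometric. D1 is held fixed; the D2/Zn
module is rigid-rotated about a hinge axis through the origin by the
requested angle. Rotation about an axis moves a point at perpendicular
distance $r$ along a chord of length $2 r \sin(\theta/2)$, which gives the
family a closed-form maximum displacement ($r_{\max}$ is recorded in the
truth table) and exact anchor distances for every member. The two domains
are laid out so that both cross-domain anchor distances are strictly
monotonic in the hinge angle over 0–90°, making "more open" well defined.
Coordinate noise, when requested, is applied to the mobile domain only, so
the fixed domain is bit-identical across a family — this keeps the analytic
chord-length truth exact for the frame-D1 profile and makes frame-RMSD
tests sharp. Missing-residue intervals emulate crystallographically
disordered loops. Structures round-trip through PDB at the format's 0.001 Å
coordinate precision.

Residue identities are sampled once per family under the seed, with the
four anchor positions pinned to their reference identities (GLN, LEU, THR,
PHE) so that sequence-based anchor mapping can be exercised end-to-end on
generator output. All generators are deterministic given their seed, and the
central self-consistency invariant — generator anchor distances equal
pipeline conformational coordinates to 1e-9 Å at zero noise — is tested
directly.

What passing on these fixtures does *not* show: robustness to real
crystallographic pathologies (alternate conformations beyond the altloc
policy, large local rearrangements inside a "rigid" domain, register errors
in homolog alignment at low identity). The fixtures isolate the arithmetic;
judgement on real structures still rests with the user.

## Assay models and numerical choices

The NADH-coupled assay reports ATP hydrolysis as loss of A₃₄₀
(ε = 6250 M⁻¹cm⁻¹): `traceToRate` takes the least-squares slope over the
initial fraction of the trace (`window`, default the whole trace, suitable
for pre-trimmed linear-phase data) and converts it to turnover,
$v = -\dot A/( \varepsilon \, l \, [E])$, in min⁻¹. Pathlength defaults to
a nominal 1 cm and should be calibrated for small-volume microplate wells.
A linear fit with R² below 0.9 attaches a "poor-linearity" note; a negative
computed turnover is clipped to zero with a warning. Both are flags on the
result, not exceptions — a screening run should not abort on one bad well.

Rate-versus-ATP curves are fit with the Michaelis–Menten law by
Levenberg–Marquardt least squares (three deterministic starts, best residual
sum of squares kept; tight convergence tolerances so noiseless data are
recovered to 1e-6 relative). K_m and k_cat are Michaelis–Menten-defined
quantities, so the rate law — not a logistic binding equation — is the
default model for rate data; `fitBinding4PL` accepts rate data for fidelity
comparisons when a logistic fit of rate curves is wanted.

Binding titrations use the four-parameter logistic model with per-curve
K_d, bottom and hill. `shareTop = TRUE` estimates one common top jointly
across curves — the constrained fit appropriate when weak binders never
reach saturation — started from the independent per-curve fits, which also
makes the nesting inequality (shared RSS ≥ unconstrained RSS) hold by
construction up to optimizer tolerance. K_d estimates more than 10-fold
outside the measured concentration range carry an extrapolation note.
Standard errors come from the local quadratic approximation at the optimum.

Simulated assay designs follow the real ones: 12 log-spaced protein
concentrations from 1 nM to 3 µM against a 10 nM probe with 2 mP additive
noise for binding; 8 log-spaced ATP concentrations from 3 µM to 0.8 mM with
5% proportional noise for rates; 10-minute linear traces with 0.002 AU
noise for progress curves. Noise is additive on polarization signals and
proportional on rates, matching how the respective measurement errors scale.

## Problem sizes

The validation suite runs on synthetic families of up to six 437-residue
chains, 100-replicate assay simulations, 1000-transform superposition
optimality sweeps, 100-transform invariance sweeps, 20-seed classification
repeats, and alignment oracles over all length ≤ 8 pairs of a 4-letter
alphabet. These sizes were chosen so every statistical check has comfortable
Monte-Carlo resolution while the whole suite stays interactive (well under a
minute).

## Known limitations

* Anchor transfer is sequence-based; distant homologs with shifted motifs
  may need the manual override.
* The landscape presumes the four anchors are rigid within their domains;
  a structure with deformation at an anchor will be misplaced, not flagged.
* No ensemble or free-energy weighting: each chain is one point, however
  many copies the crystal contains.
* The 4PL model treats the titration as a binding isotherm in total protein
  concentration; no probe-depletion correction is applied (relevant only
  when K_d approaches the 10 nM probe concentration).
* mmCIF reading is supported but PDB is the first-class dialect; no
  assembly or symmetry expansion is performed.
EOF
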