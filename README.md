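# RecQLandscape

Quantitative comparison of RecQ-family helicase conformations, with the
enzymatic-assay analyses that usually accompany such structural work.

RecQ helicases are superfamily-2 DNA helicases whose catalytic core consists
of two RecA-like domains, D1 and D2 (in human RECQL5, residues 1–219 and
220–364), plus a Zn²⁺-binding subdomain (residues 365–437) packed against D2.
ATP binding, hydrolysis and release drive an opening and closing of the
D1–D2 interdomain cleft; comparing crystal forms of one protein — or of the
whole family — requires separating this global hinge motion from local
structural differences. This package implements a compact, reproducible
toolkit for that comparison:

* **Invariant-anchor landscape.** Four structurally invariant Cα positions —
  Q34 (motif 0) and L79 (motif Ia) on D1, T268 (motif IV) and F420 (Zn
  subdomain) on D2/Zn, in RECQL5 numbering — define two cross-domain
  distances, `axis1 = |Cα(Q34) − Cα(F420)|` and
  `axis2 = |Cα(L79) − Cα(T268)|`. Each chain becomes one point on this 2D
  landscape; open (nucleotide-bound) and closed (APO) states separate into
  distinct groups, recovered by seeded k-means (`classifyStates`).
* **Rigid-body superposition.** SVD-based Kabsch superposition with
  reflection correction (`kabschSuperpose`), per-residue displacement
  profiles after aligning on a single domain (`displacementProfile`,
  default frame D1), and pairwise RMSD matrices.
* **Anchor transfer.** Needleman–Wunsch global alignment (BLOSUM62, affine
  gaps 10/0.5) of structure-derived sequences maps the RECQL5 anchors onto
  homologous structures (`globalAlign`, `mapAnchors`), with a manual
  override path for curated anchors.
* **Assay analysis.** NADH-coupled absorbance traces convert to turnover via
  Beer–Lambert, v = −(dA₃₄₀/dt)/(ε·l·[E]) with ε = 6250 M⁻¹cm⁻¹
  (`traceToRate`); ATPase rate curves are fit with Michaelis–Menten,
  v = k_cat·S/(K_m + S) (`fitMichaelisMenten`); fluorescence-polarization
  titrations with the four-parameter logistic model,
  FP(x) = bottom + (top − bottom)/(1 + (K_d/x)^h), optionally with a single
  shared top across curves (`fitBinding4PL`).
* **Synthetic ground truth.** Generators for two-domain hinge structures
  with exact anchor geometry (`makeHingeFamily`), homolog sequences with
  known correspondences (`makeHomologSequence`), and assay datasets with
  known parameters (`simulateBindingCurves`, `simulateRateCurves`,
  `simulateAbsorbanceTraces`), all deterministic under a seed.

Structures are read and written as PDB (`readStructure`, `writeStructure`;
mmCIF read supported), and end-to-end runs are orchestrated by
`runLandscape` and `runKineticsReport`.

## Worked example

Six synthetic chains from two hinge angles (15° and 75°, coordinate noise
0.3 Å), mirroring a set of independent crystallographic chains in two
conformational states:

```r
library(RecQLandscape)
fam <- makeHingeFamily(angles = c(15, 15, 15, 75, 75, 75), noiseSd = 0.3,
                       seed = 1, nucleotideStates = c("APO", "APO", "APO",
                                                      "ADP", "ADP", "ADP"))
tab <- buildLandscape(fam$structures)
print(tab, digits = 5)
#>   structure_id chain_id  axis1   axis2 nucleotide_state pairing
#> 1     hinge_01        A 264.46  78.100              APO  cross1
#> 2     hinge_02        A 263.79  78.843              APO  cross1
#> 3     hinge_03        A 264.47  78.416              APO  cross1
#> 4     hinge_04        A 315.72 152.806              ADP  cross1
#> 5     hinge_05        A 315.81 151.836              ADP  cross1
#> 6     hinge_06        A 315.56 152.248              ADP  cross1
classifyStates(tab, k = 2, seed = 0)
#>   structure_id chain_id  label
#> 1     hinge_01        A closed
#> ...
#> 6     hinge_06        A   open
```

The two anchor distances cluster tightly within each hinge angle (spread set
by the 0.3 Å noise) and split cleanly between angles; the wider-cleft group
is labelled "open". Fitting simulated assay data recovers the generating
constants with sensible standard errors:

```r
d <- simulateRateCurves(kcat = 631, km = 43e-6, noiseCV = 0.05, seed = 1)[[1]]
fitMichaelisMenten(d)
#> MMFit: kcat = 642.91 +/- 13.1 | Km = 4.3777e-05 +/- 3.38e-06 | n = 8

b <- simulateBindingCurves(kd = 29e-9, noiseSd = 2, seed = 1)[[1]]
fitBinding4PL(b)[[1]]
#> BindingFit: Kd = 2.8583e-08 | top = 201.93 | bottom = 48.231 | hill = 0.963
```

Here a single noisy 8-point rate curve returns k_cat within 2% and K_m
within 2% of the generating values (631 min⁻¹, 43 µM), and a single 12-point
titration returns K_d within 1.5% of the generating 29 nM.

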