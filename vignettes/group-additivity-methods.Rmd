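---
title: "Atom-group additivity models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-group additivity models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

GroupAdditivity estimates a molecular descriptor $Y$ as a sum of fitted
fragment contributions:

$$Y = \sum_i a_i A_i + \sum_j b_j B_j + C$$

where $A_i$ is the number of occurrences of the $i$-th *atom group*, $B_j$
the count of the $j$-th *special group*, $a_i$ and $b_j$ the fitted
contributions and $C$ an optional constant. An atom group is the smallest
still-distinguishable fragment: one backbone atom (any atom bound to at
least two other atoms, hydrogen included) together with its immediate
neighbourhood. Seven descriptors are supported with packaged tables or
derivations: heat of combustion (kJ/mol), heat of formation (indirect,
kJ/mol), logP (octanol/water), logS (mol/L), molar refractivity (cm³/mol),
molecular polarizability (10⁻²⁴ cm³) and aqueous toxicity toward
*Tetrahymena pyriformis* (pIGC₅₀, −log₁₀ mmol/L).

The additive form has two practical consequences. First, extendability: a
new structural motif only requires new table rows, never new code — the
table itself instructs the program which groups exist. Second, an
*applicability gate*: a contribution backed by too few training molecules
is merely the residual that makes those molecules fit exactly, so a
prediction is refused unless every atom group of the query is present in
the table and represented by at least three independent training molecules
(`checkApplicability()`). Special groups never block a prediction.

## The atom-group vocabulary

A backbone label is the element plus a subtype and charge mark: C and N are
subtyped `sp3`/`sp2`/`sp`/`aromatic` from the bond pattern, S by its
connection count (`S2`/`S4`), P likewise (`P3`/`P4`), and O, B, Si carry
the bare symbol (`backboneLabel()`). The neighbour term lists all adjacent
atoms element-major in the fixed rank order H > B > C > N > O > S > P >
Si > F > Cl > Br > J (iodine is written J), within an element by bond type
(single, `=`, `#`, aromatic `:`), with counts, an optional net-charge
suffix `(+)`/`(-)`, and — for the lone-pair backbones N sp3, O and S2 — a
π suffix `(pi)`/`(2pi)`/`(3pi)` counting neighbours in conjugated moieties
(aromatic, or carrying a double/triple bond to a third atom). The canonical
string is a fixed point of `parseNeighborTerm()`/`neighborTerm()`, and
every packaged table row is validated against the grammar at load time.

### Aromaticity model

The vocabulary types five-membered heteroaromatics in their Kekulé forms:
furan oxygen is `O C2(2pi)`, pyrrole-type NH is `N sp3 ...(2pi)`, thiophene
carbons are `C sp2 H=CS`, and no `C aromatic` key with an S or O ring
partner exists in any table. The package therefore deliberately uses a
benzenoid aromaticity model rather than a toolkit default: only
six-membered C/N rings in which every ring atom carries a double bond into
the candidate ring system are flagged aromatic (iterated to cover fused
kekulizations such as the middle ring of anthracene). Cross-conjugated
rings (quinones, 2H-pyridinones, cyclohexadienone tautomers) correctly
remain non-aromatic, which is what makes tautomer pairs distinguishable.

### Special groups

Special groups are corrections entered into the fit exactly like atom
groups:

* **HBridge** — intramolecular hydrogen bridge: an acidic H on neutral
  O/N/S within `specials$hbridge_max_dist` (default 2.5 Å) of a neutral
  O/N/F acceptor closing a 5–7-membered pseudo-ring. Charged partners are
  excluded: an ammonium–carboxylate contact is a salt bridge, and counting
  it would break the zwitterionic amino-acid conventions (glycine logP
  −3.22 admits no +0.49 bridge term). No donor–H–acceptor angle criterion
  is applied; the distance is configurable because the underlying method
  states none.
* **HH_lt2 / HH_2to2.3** — nonbonded H–H contacts binned below 2 Å and at
  2–2.3 Å. Pairs on the same or adjacent heavy atoms are excluded
  (minimum bond path 4): geminal H–H sits near 1.8 Å and would otherwise
  dominate the short bin, contradicting its small per-molecule frequency
  in the enthalpy table. Each unordered pair counts once.
* **Angle60 / Angle90 / Angle102** — ring-internal heavy-atom angles
  binned at ≤ 60.5°, (60.5, 90]° and (90, 102]° (the half-degree margin
  puts an ideal cyclopropane at exactly 60.0° into the strongest strain
  bin). Acyclic distorted angles are not counted.
* **Alkane / UnsatHC** — mutually exclusive per-carbon corrections for
  pure hydrocarbons (saturated vs. any CC unsaturation); both count all
  carbons and are zero for heteroatom-containing molecules.
* **XCH2n** — per-CH₂ correction for unbranched CH₂ chains (length > 1)
  ending in CH₃, NH₂, OH, SH or halogen. The default policy counts only
  chains attached to an aromatic ring: although the method's prose
  suggests applying it without restriction, the printed worked examples
  (ornithine logP −3.54, 1-hexadecanol logS −4.04) are reproduced only by
  the restricted rule, and worked-example fidelity wins. The unrestricted
  variant and an n−1 counting mode are available in the configuration.

Which specials apply to a prediction is dictated by the parameter table
itself: the enthalpy table carries the geometry terms, logP/logS carry the
H-bridge and hydrocarbon/chain corrections, and refractivity,
polarizability and toxicity use none — so no 3D geometry is ever required
for those three.

## 3D geometry

Geometry-dependent detectors need coordinates. SDF input retains its
coordinates; for SMILES (or 2D SDF) input the package embeds a conformer
with RDKit's ETKDGv3 through a small Python helper: a fixed-seed ensemble
of 8 conformers is generated, each is MMFF (fallback UFF) minimized, and
the lowest-energy member is kept. The ensemble matters: a single embedding
can land in a rotamer without the intramolecular hydrogen bond (e.g.
salicylaldehyde with the OH pointing away), while the energy-ranked
ensemble selects the bonded one. The procedure is deterministic for a
given seed (`embed$seed`, default 1), which keeps predictions reproducible
byte for byte. Open Babel's 3D generator is not used for embedding because
its conformer search is time-seeded.

Conformer quality is a genuine error source for the enthalpy descriptors:
H–H contact counts move by a pair or two between reasonable conformers
(±1.1–1.2 kJ/mol each), which is why the worked-example tolerances for the
heats of combustion/formation are ±6 and ±5 kJ/mol rather than the
±0.05 units used for the 2D descriptors.

## Fitting and validation

The training set is translated into an M × (N+1) matrix of group counts
(`buildDesignMatrix()`; the constant column is all ones and is used for
logP, logS, polarizability and toxicity, matching which printed tables
carry a `Const` row). Contributions solve the least-squares problem via
Gauss–Seidel sweeps on the normal equations from a zero start
(`gaussSeidelSolve()`): the normal matrix is symmetric positive
(semi-)definite, for which Gauss–Seidel converges; defaults are a per-sweep
update tolerance of 1e-8 (scaled by the iterate magnitude), 100,000 sweeps
maximum, natural column order. A tiny ridge (`solver$ridge`, e.g. 1e-8) is
available for rank-deficient instances; the reference method is silent on
regularization, so it defaults to off. Whether the original implementation
iterated on the normal equations or some other equalized form is not
documented; the normal-equations reading is adopted and verified against a
direct QR least-squares oracle to < 1e-6 on random instances up to 50×20.

Fit statistics follow the table footers: R², mean absolute deviation, and
the *sample standard deviation of signed residuals* (an RMSE variant is a
config switch; the SD reading matches the magnitudes printed alongside the
MAE). Statistics are computed over the molecules whose every atom group
passes the three-molecule gate, which is why their N is smaller than the
basis-set row.

Cross-validation (`crossValidate()`) uses the deterministic shifted k-fold
scheme: run r (0-based) holds out every k-th molecule starting at position
r+1, so each compound is a test item exactly once and no structure clusters
leave together. Per run the table is refitted on the remainder; test
molecules whose groups lose three-molecule support are excluded and N
decrements. Q² is computed over the pooled out-of-fold predictions with
the pooled experimental mean (per-run means differ negligibly at n ≫ k).
The input order is the training-file order; a seeded shuffle is available
but off by default, keeping the scheme RNG-free. Leave-one-out is k = n.

## Heat of formation

The heat of formation is obtained indirectly:
$\Delta H_f = \sum_p n_p \Delta H_f(p) - \Delta H_c$, with
element-balanced combustion products (C → CO₂, halogens → aqueous HX,
S → hydrated H₂SO₄ consuming 2 H, P → H₃PO₄, B → H₃BO₃, Si → SiO₂,
remaining H → liquid water, N → N₂). The product constants are
configurable; the CO₂ and H₂O defaults are the classic
thermochemical-calorie values (−94.051 and −68.315 kcal/mol) converted
with the 4.1868 J/cal factor, a one-time calibration fixed against the
printed acetone (−243.18) and phenol (−166.90) examples and then frozen —
it also reproduces 4-phenylazophenol to within 2 kJ/mol. Molecules with
more halogen than hydrogen are refused (the free-halogen combustion
variant is not implemented).

## The synthetic generator

`generateSyntheticSet()` produces random sparse count profiles over an
artificial group alphabet with known contributions and Gaussian noise —
exactly the linear structure the fitting and cross-validation machinery
sees after fragmentation. It emulates the count sparsity and
collinearity of real design matrices but none of the chemistry: no
grammar, no gate interactions, no geometry. Passing recovery tests
therefore validates the solver and the CV bookkeeping, not the
fragmentation rules; those are validated separately against hand-derived
profiles and the printed worked examples. Default study conditions for the
recovery checks are 500 profiles over 8 groups with counts 0–4,
contributions in ±2 and noise σ = 0.5 (20 seeds); noiseless sets must
recover the truth to 1e-6 and reach Q² = 1 within 1e-9. Problem sizes in
the test-suite were chosen at desk scale (n ≤ 500, k = 10) — statistically
informative while keeping a full run in well under a minute.

## Degenerate inputs and tie-breaks

* Methane-like molecules (a single backbone whose neighbours are all H)
  still fragment — the key `C sp3|H4` is emitted — and are then rejected
  by the gate, since no table carries such a key. Policy lives in the
  gate, keeping the fragmenter total.
* Charge-separated sulfoxide/sulfone input ([S⁺]–[O⁻]) is normalized to
  the hypervalent S=O form before typing, because the tables use
  `S4 ... =O` keys; nitro groups stay charge-separated, which is the form
  the tables use (`N(+) sp2 ... (-)`).
* Net neighbour charges beyond ±1 render as a bare sign; no packaged key
  needs more.
* Constant experimental vectors make R² undefined; it is flagged NA with
  a warning rather than fabricated.

## Limitations

Being strictly local, the model cannot see non-neighbouring effects —
gauche/cis interactions, buttressing, extended conjugation, intramolecular
charge transfer — beyond the few tabulated 3D corrections. Keto–enol
predictions inherit a known bias: most training exemplars of the enol
moiety are aromatic heterocycles, so isolated enols are over-stabilized.
logBB is deliberately not packaged: no full contribution table is
available for it, and group additivity is known to perform poorly on that
descriptor (cross-validated Q² below 0.5, the conventional threshold for
a meaningful model), so shipping a table would be misleading; the fitting
pipeline will happily build a user table from suitable training data. Predictions for molecules whose
groups sit near the three-molecule confirmation threshold should be read
as indicative.
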