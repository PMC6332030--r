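# GroupAdditivity

Extendable atom-group additivity models for molecular descriptors, for
cheminformatics and early drug-discovery work where fast, transparent,
structure-only property estimates are needed: heat of combustion, heat of
formation (derived), octanol/water logP, aqueous solubility logS, molar
refractivity, molecular polarizability, and aqueous toxicity toward
*Tetrahymena pyriformis* (pIGC50).

## The method

A molecule is broken down into its smallest still-distinguishable
fragments: every *backbone atom* (an atom bound to at least two others)
together with its immediate neighbourhood, encoded as a canonical
(atom-type, neighbour-term) pair such as `C sp3 | H2CN(+)` or
`O | HC(pi)`. A descriptor is then a contribution sum

    Y = sum_i a_i * A_i  +  sum_j b_j * B_j  +  C

over the atom-group counts `A_i`, a few special-group counts `B_j`
(intramolecular H-bridges, short H–H contacts, ring-strain angle classes,
per-carbon hydrocarbon corrections, CH2-chain corrections) and an optional
constant `C`. Contributions are fitted to experimental training data by
Gauss–Seidel least squares on the normal equations, and validated by a
deterministic shifted k-fold cross-validation (every k-th compound held
out, shifted by the run index, so each compound is tested exactly once).
A prediction is refused unless every atom group of the query is confirmed
by at least three training molecules (the applicability gate); the scheme
is extendable because new chemistry only adds table rows, never code.

The package ships transcribed contribution tables for the six directly
fitted descriptors (`inst/extdata/tables/*.tsv`), the fragmentation and
gating machinery, the fitter and cross-validator for building new tables
from your own training sets, and the indirect heat-of-formation route via
combustion stoichiometry.

## Worked example

```r
library(GroupAdditivity)

glycine <- parseSmiles("C(C(=O)[O-])[NH3+]", "glycine")  # zwitterion
pr <- predictDescriptor(glycine, packagedTable("logP"))
breakdown(pr)
#>            key count contribution subtotal
#>          Const     1         0.25     0.25
#>  C sp2|CO=O(-)     1        -2.32    -2.32
#>  C sp3|H2CN(+)     1        -0.34    -0.34
#>   N(+) sp3|H3C     1        -0.81    -0.81
pr
#> Prediction (logP): -3.22 log10 units
```

Glycine (as the zwitterion, the dominant solution form of amino acids)
fragments into three atom groups — the ammonium-bearing CH2, the
carboxylate carbon, and the ammonium nitrogen — whose logP contributions
plus the constant sum to −3.22, a slightly more hydrophilic estimate than
the measured −3.0. The breakdown always sums exactly to the reported
value. A molecule containing a group the table cannot confirm is rejected
with the offending keys listed rather than silently extrapolated.

Fitting and validating your own table:

```r
mols <- readSDF("train.sdf")                     # values in <LOGS_EXP> fields
tab  <- fitTable(mols, "logS")
crossValidate(mols, "logS", k = 10)              # shifted k-fold, Q2/MAE/SD
saveParameterTable(tab, "logS_custom.tsv")
```

A thin command-line wrapper (`inst/scripts/group-additivity`) exposes
`fragment`, `predict`, `fit`, `cv`, `hf` and `fixtures` subcommands with
JSON/CSV output and a `--config` JSON for all thresholds.

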