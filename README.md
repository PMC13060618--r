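# taamsf

Aspherical and independent-atom scattering factors for crystal structures,
in R.

Crystallographic and cryo-EM software almost universally models atomic
scattering with the independent atom model (IAM): every atom a neutral
sphere, its form factor a tabulated sum of Gaussians depending only on the
element.  That approximation hides bonding density and lone pairs at high
resolution and misrepresents electrostatic potential maps — which are
sensitive to atomic charge — at essentially any resolution.  `taamsf`
implements the practical alternative: the **transferable aspherical atom
model (TAAM)**, in which each atom receives precomputed Hansen–Coppens
multipolar parameters

> density = core + P_val · κ-scaled spherical valence
> + Σ_l Σ_m P_lm · R_l(κ′r) · d_lm(θ, φ),  l ≤ 4 (hexadecapoles)

from a bank of atom types keyed on local chemical environment, keeping the
refinable parameter count at the IAM's 10 per atom instead of the full
multipolar model's 37.

The package is aimed at method developers and crystallographers who want a
self-contained, inspectable implementation of the full chain:

* **Parameter banks** — a documented text schema for multipolar atom types
  (match rules, local-frame recipes, P_val/κ/κ′/P_lm, Slater radial
  functions), plus generated Slater shell sets and Gaussian IAM tables in
  four dialects (4-Gaussian+constant and 5-Gaussian X-ray; electron
  dialects fitted to 2 and 6 Å⁻¹).
* **Atom typing** — covalent-radius bond perception with symmetry images,
  minimum-cycle-basis ring detection, planarity analysis, most-specific-first
  bank matching, local coordinate frames, and a three-level fallback
  (multipolar → spherical Slater for Z ≤ 36 → Gaussian IAM) with per-atom
  reasons (missing hydrogens, altloc overlap, clashes, incomplete
  environments).
* **Form factors** — closed-form spherical-Bessel transforms of Slater
  functions (no quadrature in the production path), density-normalized real
  spherical harmonics, and Mott–Bethe conversion
  f_e(s) = (Z − f_x)/(8π²a₀s²) to electron scattering.
* **Structure factors and gradients** — direct summation over symmetry
  operators with isotropic/anisotropic Debye–Waller factors, analytic
  target gradients (xyz, B/U, occupancy) accumulated against caller-supplied
  ∂T/∂F so memory scales with parameters, never reflections × parameters,
  and an explicit per-reflection ∂F/∂p table for small problems.
* **Maps** — Fourier synthesis of electron-density (e Å⁻³) and
  electrostatic-potential (Å⁻²) maps, TAAM−IAM deformation maps with
  optional least-squares scaling, rmsd-based contour-level helpers, and a
  CCP4/MRC writer.
* **Fixtures** — deterministic toy crystals (methane, water, benzene,
  decalin, a peptide fragment, random P1 cells, a chiral P2₁ pair, altloc
  overlaps) so everything is testable offline.

Model input is PDB, mmCIF or small-molecule CIF.  All shipped bank values
are generated and physically plausible but synthetic — they exercise the
machinery; they are not published scattering tables.

## Worked example

Electron structure factors and a TAAM−IAM deformation map for a toy
N-methylacetamide crystal:

```r
library(taamsf)

bank  <- make_fixture_bank(0)               # 12-type toy bank, deterministic
st    <- make_structure("tripeptide-like")  # CH3-C(=O)-N(H)-CH3 in P1
graph <- build_bond_graph(st)
asn   <- assign_atom_types(st, graph, bank)
print(asn)
#> type assignment: 12 atoms, 83.3% multipolar
type_coverage_report(asn)$counts
#>       multipolar spherical-slater     gaussian-iam
#>               10                2                0

ms <- generate_reflections(st, d_min = 1.0)
sf <- direct_summation_sf(st, asn, ms, bank, radiation = "electron", mode = "taam")
print(sf)
#> structure factors: 5756 reflections, taam electron

dm <- deformation_map(st, asn, bank, d_min = 1.0, radiation = "electron")
#> Warning: multipolar coverage is 83.3%; deformation map mixes representation levels
print(dm)
#> real-space map 45x45x45 (electrostatic-potential), mean -5.116e-19, rms 0.01883
rmsd_contour_levels(dm, dm)$level_a
#> [1] 0.02824
```

The two methyl carbons have no bank type and fall back to the spherical
core+valence model, which is why coverage is 83% and the deformation map
warns; the map units are Å⁻² because electron structure factors carry the
Ångström unit.  The 1.5-rmsd level (0.028 Å⁻²) is the suggested display
contour when comparing against a matching IAM map.

A thin command-line wrapper covers the same ground:

```sh
Rscript inst/cli/taamsf sf   --model model.pdb --bank bank.txt --mode taam \
                             --radiation electron --d-min 1.0 --out out.hkl
Rscript inst/cli/taamsf type-report --model model.pdb --bank bank.txt --out report.json
```

Every run writes a JSON manifest recording the resolved configuration and
the multipolar coverage percentage — worth checking before trusting a TAAM
map.

## Documentation

The methods vignette (`vignettes/multipolar-scattering.Rmd`) describes the
model, the typing algorithm, the bank schema, every numerical convention
(normalizations, κ-scaling, F(000) policy, grid rules) and the known
limitations.  Function-level documentation lives in the roxygen comments in
`R/`.
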