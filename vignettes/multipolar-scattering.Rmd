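---
title: "Multipolar and independent-atom scattering factors with taamsf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipolar and independent-atom scattering factors with taamsf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taamsf)
```

## The model

Conventional crystallographic and cryo-EM calculations describe each atom as
a spherical, chemically inert electron cloud — the independent atom model
(IAM), in which the form factor depends only on the element and on
$s = \sin\theta/\lambda$, and is usually parameterized as a sum of Gaussians,
$f(s) = \sum_i a_i e^{-b_i s^2} + c$.  That picture ignores bonding density,
lone pairs and charge transfer, which matter at high resolution for X-rays
and at essentially all resolutions for electron scattering, where the
electrostatic potential is sensitive to net atomic charge.

The Hansen–Coppens multipolar formalism refines this by writing the atomic
density as three terms:

$$\rho(\mathbf r) = \rho_{core}(r)
  + P_{val}\,\kappa^3 \rho_{val}(\kappa r)
  + \sum_{l=1}^{4} R_l(\kappa' r) \sum_{m=-l}^{l} P_{lm}\, d_{lm}(\theta,\varphi)$$

a frozen spherical core, a spherical valence shell whose population
$P_{val}$ and contraction $\kappa$ allow charge transfer, and an aspherical
deformation expansion over real spherical harmonics $d_{lm}$ with radial
functions $R_l(r) \propto r^{n_l} e^{-\zeta r}$ and populations $P_{lm}$ up
to hexadecapoles ($l = 4$).  Refining all of this per atom would raise the
per-atom parameter count from 10 (positions, six anisotropic displacement
components, occupancy) to 37; the transferable aspherical atom model (TAAM)
instead *assigns* the multipolar parameters from a bank of precomputed atom
types keyed on local chemical environment, so the refinable count stays at
the IAM level while the density model gains the aspherical terms.
`count_refinable_parameters()` implements this bookkeeping.

The form factor of one multipolar atom at scattering vector $\mathbf g$
(with $H = 4\pi s = 2\pi|\mathbf g|$ and $\mathbf u$ the unit direction of
$\mathbf g$ in the atom's local frame) is

$$f(\mathbf g) = f_{core}(s) + P_{val} f_{val}(s;\kappa)
 + \sum_{l=1}^{4} 4\pi i^l \langle j_l \rangle(H; \kappa'\zeta, n_l)
   \sum_m P_{lm} d_{lm}(\mathbf u),$$

where $\langle j_l\rangle$ is the order-$l$ spherical-Bessel transform of the
density-normalized radial function.  `slater_fourier_bessel()` evaluates
these transforms with closed-form recursions built from the complex moment
integral $\int r^p e^{-(\zeta - iH)r} dr = p!/(\zeta-iH)^{p+1}$; a power-series
branch takes over for $H \le 0.1\,\zeta$, where the upward recursion in $l$
would lose precision to cancellation.  No numerical quadrature runs in the
production path; quadrature appears only as the independent oracle in the
test suite.

## Atom typing and the three-level fallback

`build_bond_graph()` perceives connectivity purely from coordinates and
elements: atoms bond when their distance lies between 0.4 Å and the sum of
their single-bond covalent radii plus a tolerance (default 0.40 Å, both
user-overridable), with symmetry images included.  Hydrogens are pruned to
their single nearest heavy-atom bond (ties to the lower atom index).  Ring
membership comes from a minimum cycle basis (sizes 3–8); planarity is the
RMS out-of-plane deviation of an atom and its neighbours against their
best-fit plane (threshold 0.10 Å RMS by default — the cutoff an ideal sp³
centre at ≈0.5 Å clears by a wide margin while genuinely planar sp²
environments sit near zero).

`assign_atom_types()` then gives every atom one of three representations:

* **multipolar** — the most specific matching bank entry (more satisfied
  constraints win; ties resolve by bank order), with a local frame built
  from the entry's recipe (Z along the first selector direction, X by
  Gram–Schmidt against Z, Y completing a right-handed frame);
* **spherical-slater** — core + spherical valence only, for elements up to
  krypton ($Z \le 36$) whenever no type matches, a frame selector cannot be
  resolved, or the two frame directions are collinear;
* **gaussian-iam** — the Gaussian parameterization, for heavier elements and
  for atoms whose positions overlap: pairs closer than 0.4 Å with different
  altloc labels are mutually invisible to bonding and both demoted, and
  same-altloc clashes are likewise demoted with a recorded reason.

Because many types require bonded hydrogens, models without them (waters in
particular) lose multipolar coverage; `type_coverage_report()` exposes the
per-level percentages and per-atom reasons so that users can check the
multipolar fraction before interpreting downstream maps.  The matching
grammar reaches first neighbours (exact element multiset), second
neighbours (minimum counts), and the planarity and ring flags; environments
that depend on more distant topology are outside this grammar and end up at
the spherical fallback.

## Structure factors and gradients

`direct_summation_sf()` computes
$F(\mathbf h) = \sum_{s}\sum_{j} occ_j\, f_j(R_s^T\mathbf h)\,
DW_j(R_s^T\mathbf h)\, e^{2\pi i\,\mathbf h\cdot(R_s\mathbf x_j + \mathbf t_s)}$
over explicit symmetry operators (P1, P-1, P2₁, P2₁2₁2₁ built in; mmCIF
operator loops accepted).  Direct summation is required because multipolar
densities are not sums of independent Gaussians, so the FFT shortcut that
serves the Gaussian IAM does not apply; the cost scales as reflections ×
atoms × operators.  The Debye–Waller factor is $e^{-Bs^2}$ (isotropic) or
$e^{-2\pi^2 \mathbf g^T U \mathbf g}$ with $U$ the Cartesian tensor, which
reproduces $B = 8\pi^2 U$ exactly in the isotropic limit.  Occupancies on
special positions are taken at face value — no automatic multiplicity
correction is applied, so an atom on a special position needs its occupancy
set accordingly by the user.

For refinement-style use, `sf_gradients()` takes per-reflection target
derivatives $\partial T/\partial F$ from the caller and accumulates
$\partial T/\partial p$ on the fly, so the output is proportional to the
number of parameters only — the explicit reflections × parameters derivative
table, which `per_reflection_sf_gradients()` materializes for small problems,
would run to hundreds of gigabytes at refinement scale and is guarded at
$10^7$ entries.  Positional gradients are reported per fractional coordinate
(the natural $2\pi i\,\mathbf h$ form); `gradients_to_cart()` converts to
per-Å.  Anisotropic ADP gradients are taken with respect to the six unique
*Cartesian* $U$ components — the same parameterization the `AtomSite` stores,
so finite-difference checks and user updates act on identical quantities;
off-diagonal components carry the factor two from symmetry.

For electron scattering the Mott–Bethe relation
$f_e(s) = \frac{1}{8\pi^2 a_0}\,\frac{Z - f_x(s)}{s^2}$ converts the X-ray
form factor; the constant is 0.0239337 Å.  The origin is special: for a
neutral Gaussian atom the limit is $C\sum_i a_i b_i$
(`mott_bethe_gaussian_origin()`), while ions make $F(000)$ divergent, which
is why map synthesis excludes the origin term by default.

## Maps

`fourier_map()` synthesizes
$\rho(\mathbf x) = \frac{1}{V}\sum_h F(h) e^{-2\pi i \mathbf h\cdot\mathbf x}$
on 2,3,5-smooth grids with spacing at most $d_{min}/3$ (oversampling
configurable, minimum 2), reconstituting Friedel mates from the unique set
and checking that the imaginary residue stays below $10^{-10}$ of the map
scale.  X-ray maps are electron density (e Å⁻³); electron-scattering maps
are electrostatic potential, with units Å/Å³ = Å⁻² following from the
Ångström unit of electron structure factors.  `deformation_map()` builds
TAAM − IAM difference maps, optionally scaling the IAM leg by the single
least-squares scalar $\kappa_{scale} = \sum \mathrm{Re}(\bar F_{iam} F_{taam})
/ \sum |F_{iam}|^2$ (a resolution-dependent scaling model was deliberately
not introduced); the IAM leg defaults to the Gaussian dialect valid to
6 Å⁻¹ for each radiation.  `rmsd_contour_levels()` implements the display
convention of contouring two maps at $k \times$ rmsd-about-the-mean each and
taking the midpoint, with $k = 1.5$ by default.

## The parameter bank and the generated reference data

No public serialization standard exists for multipolar banks, so the package
defines a line-oriented text schema (documented in the header of `R/bank.R`;
version 1) holding three record types: Slater shell sets per element,
Gaussian coefficient tables per dialect and element, and multipolar atom
types (match rule, frame recipe, $P_{core}$, $P_{val}$, $\kappa$, $\kappa'$,
radial powers and exponent, sparse $P_{lm}$).  Exponents are Å⁻¹ by default
with an explicit `unit bohr` flag accepted.  $\kappa'$ is a single scalar
shared across $l = 1..4$ within an entry, the common Hansen–Coppens
practice.

The reference spherical densities are generated, not transcribed: each
element's shells come from Slater's screening rules (one exponential shell
per shell group, density-normalized so the set integrates exactly to $Z$).
The four Gaussian dialects — four Gaussians plus a constant valid to
2 Å⁻¹, five Gaussians to 6 Å⁻¹, and two electron-scattering dialects fitted
to the Mott–Bethe conversion over 2 and 6 Å⁻¹ — are least-squares fits of
those reference curves, with $\sum_i a_i + c = Z$ enforced exactly for the
X-ray dialects (a small ridge keeps near-duplicate widths from producing
large cancelling amplitude pairs).  Evaluating a table beyond its fit range
warns rather than fails.  Consequently the numerical values in the shipped
bank (`inst/extdata/fixture_bank.txt`, regenerable with
`make_fixture_bank(0)`) are physically plausible but synthetic: they support
every structural and analytical property of the machinery without standing
in for published scattering tables.

One consequence worth knowing: a single-exponential valence shell has a
spherical-Bessel transform with a sign node (for second-row elements near
$s \approx 0.8$ Å⁻¹).  Below the node, increasing $\kappa$ (contraction)
raises the form factor as expected; beyond it the inequality reverses
because the (small, negative) transform broadens.  Multi-shell densities
from atomic-structure calculations push this node to higher $s$.

## The fixture generators

`make_structure()` provides deterministic toy crystals: methane, water
(with and without hydrogens), benzene, trans-decalin (fused chairs built by
reflecting a chair through its shared edge), an N-methylacetamide-like
peptide fragment, a 20-atom random P1 cell (minimum pairwise separation
1 Å under periodic boundaries, B factors 10–25 Å², two partial
occupancies), a chiral fragment in P2₁ and an altloc-overlap case.  Bond
lengths sit within 0.1 Å of standard values.  Coordinates are frozen at six
decimals so that files regenerate byte-identically from `(name, seed)` on
any platform; every stochastic step draws from one named seeded stream that
never touches the global RNG state.

These fixtures emulate chemical topology, symmetry and displacement
disorder.  They do not emulate experimental error models, solvent
contribution, radiation damage or finite data completeness, so a green test
suite demonstrates internal mathematical correctness of the scattering
machinery — transforms, symmetry, gradients, map algebra — and not agreement
with any measured data set.

## Numerical choices

* Fractional coordinates internally; Cartesian conversion puts **a** along
  x.  Friedel representatives are the lexicographically larger of
  $(h,k,l)$ and $-(h,k,l)$; phases are stored in degrees in $[-180, 180)$.
* Real spherical harmonics are density-normalized
  ($\int |d_{lm}|\,d\Omega = 2$ for $l \ge 1$); the normalization constants
  are computed once by separable adaptive quadrature and cached, making the
  convention self-verifying rather than transcribed.
* $\kappa$-scaling is implemented as exponent scaling $\zeta \to \kappa\zeta$
  with per-shell renormalization (algebraically equivalent to argument
  scaling with renormalization); $f(0) = P_{core} + P_{val}$ holds exactly.
* Deformation terms are defined as zero at $s = 0$; the $l \ge 1$ transforms
  vanish there analytically.
* Electron-scattering calculations refuse $s = 0$ outside the neutral
  Gaussian analytic-limit path, surfacing the ion divergence explicitly.
* Degenerate frame geometry (missing selector target, collinear Z and X
  references at $<10^{-6}$ of the projection norm) demotes the atom rather
  than fabricating an arbitrary axis.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at deliberately small scale,
chosen as the smallest sizes that still exercise every code path: toy
molecules of 3–28 atoms, a 20-atom random cell with a few hundred
reflections, 64³ FFT grids for the sampled-Gaussian oracle, 10 random
scattering vectors against the 3D quadrature oracle, and 40 random
parameter draws for the radial-transform box.  All oracle agreements are at
or far below the stated tolerances at these sizes, and every identity tested
(Friedel, translation, symmetry expansion, Parseval, contraction of the
explicit gradient table) is size-independent algebra.

## Limitations

Anomalous dispersion, bulk solvent, resolution-dependent scaling,
maximum-likelihood targets and the refinement loop itself are out of scope;
the least-squares target exists as a demonstration of the gradient
interface.  The typing grammar stops at second neighbours plus flags.
Space-group support covers the four groups used by the fixtures plus
operator loops read from mmCIF.  The parallel decomposition of the
reflection loop is embarrassingly simple but not implemented; the reference
implementation is single-threaded.
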