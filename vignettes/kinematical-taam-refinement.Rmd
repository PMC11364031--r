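---
title: "Scattering models in kinematical 3D ED refinement: methods and design"
author: "TaamKin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scattering models in kinematical 3D ED refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TaamKin)
```

## The problem

Three-dimensional electron diffraction (3D ED / MicroED) measures Bragg
intensities from sub-micrometre crystals. Because electrons scatter from the
electrostatic potential, the signal is sensitive to partial charges and to
the aspherical redistribution of valence electrons in bonds — far more so
than X-rays, particularly below 0.2 reciprocal Angstrom. Structures are
nevertheless routinely refined with the independent atom model (IAM), which
superposes spherical neutral (or formally charged) atoms. For metal
complexes this raises two linked questions this package is built to study:

1. Does assigning the metal its formal oxidation-state scattering factor
   (e.g. Fe3+ for an iron(III) complex) improve or damage a kinematical
   refinement?
2. How much of the misfit of IAM is carried by the organic ligands, and is
   it recovered by transferable aspherical atom model (TAAM) scattering
   factors built from Hansen-Coppens pseudoatoms?

The package implements the full computational chain needed to answer these
questions — form factors, structure factors, weighted least squares,
residual maps, multipole fitting, Bader charges — together with a
synthetic-data generator that provides an FeAcAc-like crystal with *known*
ground truth, so every stage is testable without any experimental download.

## Scattering models

**IAM.** X-ray factors are the standard analytic 4-Gaussian-plus-constant
parametrizations $f^x(s)=\sum_i a_i e^{-b_i s^2}+c$ with
$s=\sin\theta/\lambda$ in inverse Angstrom, embedded for H, C, O, Fe and
the ions O$^-$, Fe$^{2+}$, Fe$^{3+}$. Electron factors are obtained through
the Mott-Bethe relation
$$f^e(s) = \frac{m_0 e^2}{8\pi\epsilon_0 h^2}\,\frac{Z - f^x(s)}{s^2},$$
with the prefactor (about 0.023934 inverse Angstrom) computed from CODATA
constants, and refitted with four Gaussians so that any engine requiring
Gaussian coefficients can consume them. Neutral species are fitted on
$s \in [0, 1.2]$ using the analytic $s\to 0$ limit
$C\sum_i a_i b_i$ (the embedded tables carry a rounding-level residual
charge of order $10^{-3}$ e, which is removed before conversion because it
would otherwise inject a spurious $q/s^2$ spike); ions diverge as
$C q/s^2$ and are fitted on $[0.05, 1.2]$, which covers 0.85-Angstrom
data with margin. The fits are multi-start Levenberg-Marquardt; measured
residuals are below 0.1 % of the curve maximum for neutral species and
below 1 % for ions. A partially charged species such as O$^{0.5-}$ is the
exact linear mixture of the neutral and fully ionized curves, represented
without approximation as the concatenated 8-term Gaussian sum.

**Hansen-Coppens pseudoatoms.** The aspherical model of one atom is
$$\rho(\mathbf r) = P_{core}\,\rho_{core}(r)
 + P_{val}\,\kappa^3 \rho_{val}(\kappa r)
 + \sum_{l=1}^{l_{max}} \kappa'^3 R_l(\kappa' r)
   \sum_m P_{lm}\, y_{lm}(\hat{\mathbf r}),$$
with single-zeta Slater core and valence densities (exponents stored in a
versioned table, in inverse bohr), deformation radials
$R_l(r) \propto r^{n_l} e^{-\zeta r}$, and **orthonormal real spherical
harmonics** $y_{lm}$. Using orthonormal rather than density-normalized
harmonics is a deliberate convention choice: the same functions appear in
real and reciprocal space, so populations are self-consistent throughout
the package, and the Fourier transform takes the clean form
$$f(\mathbf h) = \frac{P_{core}}{N_{core}} f_{core}(s)
 + P_{val} f_{val}(s/\kappa)
 + \sum_{lm} 4\pi i^l P_{lm} f_l(k/\kappa')\, y_{lm}(\hat{\mathbf h}),
 \qquad k = 4\pi s,$$
with $f_l(k)=\int_0^\infty r^2 R_l(r) j_l(kr)\,dr$ evaluated in closed form
(sin/cos moment integrals), switching to the ascending series of $j_l$
when $k < 0.45\,\alpha$ where the closed form cancels catastrophically.
The spherical limit (all $P_{lm}=0$, $\kappa=1$, neutral $P_{val}$) equals
the embedded spherical atomic factor by construction and is enforced by
tests, as is agreement of every deformation order with adaptive numerical
quadrature. Local pseudoatom frames are built deterministically from the
two highest-priority bonded neighbours (priority: larger atomic number,
then shorter bond). Electron pseudoatom factors apply Mott-Bethe to the
complex X-ray factor with the element's nuclear charge, so a pseudoatom
with net spherical charge $q$ diverges at low angle with coefficient
proportional to $q$ — the key physical handle on the charged-IAM
question. The frozen core of iron is taken as the argon core plus 4s$^2$,
leaving 3d$^6$ as the refinable valence shell.

Form-factor tables (one complex value per reflection per atom, the content
of a `.tsc` file) are a first-class scattering source: structure factors
computed through a table are tested to equal the inline pseudoatom path to
$10^{-10}$, and tables round-trip through the plain-text `.tsc`
reader/writer.

## Structure factors and refinement

Kinematical structure factors are
$$F(\mathbf h) = \sum_{sites}\sum_{ops} occ\; f(\mathbf h R)\,
  T(\mathbf h R)\, e^{2\pi i(\mathbf h R \cdot \mathbf x + \mathbf h\cdot
  \mathbf t)},$$
with anisotropic Debye-Waller factors in the crystallographic $U_{ij}$
convention, $T=\exp(-2\pi^2\sum_{ij}U_{ij}h_ih_j a^*_ia^*_j)$. Space
groups are explicit operator lists (built-ins: P1, P-1, Pbca); symbol
parsing is intentionally out of scope. Correctness rests on oracle tests:
a naive double loop, Friedel symmetry, reality of centrosymmetric
structure factors, and the Pbca systematic absences.

Refinement minimizes $\sum w\,(F_o^2 - k F_c^2)^2$ with the standard
weighting scheme
$$w = 1/[\sigma^2(F_o^2) + (aP)^2 + bP],\qquad
  P = (\max(F_o^2,0) + 2F_c^2)/3,$$
by Levenberg-Marquardt with analytic derivatives for the scale, all non-H
fractional coordinates and $U_{ij}$ (isotropic $U$ for isotropic sites).
Hydrogens ride on their bonded parent with a fixed offset vector — X-H
distances are invariant to $10^{-6}$ Angstrom by construction — and
$U_{iso}(\mathrm H) = 1.2\,U_{eq}(\mathrm{parent})$ (1.5 for methyl),
updated between weighting macro-cycles. Weights are frozen within each
macro-cycle (two by default) and optionally re-optimized between them.
Convergence uses a relative objective change of $10^{-9}$ with an
iteration cap of 100 per cycle. The "strong" reflection set for R1 uses
$F_o > 4\sigma(F_o)$ with $F=\sqrt{\max(F^2,0)}$ and
$\sigma(F)=\sigma(F^2)/2F$ (floored), a deliberate simple-truncation
convention. An optional single extinction scalar
$F_c^2 \to F_c^2(1+gF_c^2)^{-1/2}$ is available for X-ray work and off by
default for electron data.

**Weight optimization** adjusts $(a,b)$ to flatten the binned goodness of
fit (10 intensity times 5 resolution bins) towards 1 by box-constrained
multi-start minimization of $\sum_{bins}(\mathrm{GooF}^2_{bin}-1)^2$. Two
measured behaviours are worth knowing. First, even on data whose noise
exactly matches $\sigma$, the optimum sits at a small nonzero $a$
(typically below 0.1): the weight couples to the residual through $P$,
and the heavy right tail of the squared-residual distribution rewards a
slight down-weighting of strong reflections. Second, for a badly fitting
model no weighting scheme can normalize the residuals and the optimizer
runs away to large $a$; the implementation detects this (default guard
$a > 0.5$) and falls back to the conventional $a=0.2, b=0$ with a
warning — mirroring how production refinement engines behave when weight
optimization fails for spherical models against electron data.

## Diagnostics

Resolution-shell R1 freezes the model and global scale and re-buckets the
reflections (default shells 8.65-2.00 and 2.00-0.85 Angstrom).
Displacement-ellipsoid health is summarized by the ratio of maximum to
minimum RMS principal components of the Cartesian $U$ tensor.
Model-vs-model agreement uses coordinate and bond-length RMSDs in
Cartesian space with covalent-radius bond detection (1.15 times the radius
sum).

Difference maps are Fourier syntheses
$\rho(\mathbf x)=V^{-1}\sum_h \Delta F\,e^{-2\pi i \mathbf h\cdot\mathbf x}$
on an FFT grid (default spacing about $d_{min}/4$ per axis), with
coefficients completed by Friedel mates and, when requested, space-group
expansion $F(\mathbf hR) = F(\mathbf h)e^{-2\pi i\mathbf h\cdot\mathbf t}$;
observed-minus-model maps take phases from the current model, and F(000)
is excluded. Map units carry an explicit tag (potential-difference maps in
inverse Angstrom squared for electron data, e per cubic Angstrom for
X-rays) instead of silent rescaling. The fractal-dimension diagnostic bins
residual levels into 101 equal-width bins symmetrized about zero and plots
$d_f(\rho_0) = \ln N(\rho_0)/\ln N_{total}$; its full width measures
residual magnitude and its asymmetry measures systematic model bias. A
flat map degenerates to a single bin with $d_f = 1$ by convention.
Parseval consistency and direct-sum spot checks anchor the synthesis.

## Multipole fitting and databanks

Static (zero-ADP) structure factors of an isolated molecule in an
artificial cubic P1 box (default 30 Angstrom) are the fitting target for
pseudoatom parameters; `refineMultipoles` adjusts the selected classes
($P_{val}$, $\kappa$, $P_{lm}$) to minimize amplitude residuals, reporting
$R=\sum||F_t|-|F_m||/\sum|F_t|$. Valence-only targets drop the frozen-core
contribution analytically on both sides. Refinement against
self-generated targets is an exact fixed point, and single perturbed
populations are recovered to $10^{-4}$ e — the two properties that make
the fallback target generator a sufficient stand-in for wavefunction
structure factors in routine testing. Producing those wavefunction
targets (a DFT calculation) is explicitly external to the package: any
(hkl, complex F) list can be supplied.

Atom types for databank averaging use a two-shell connectivity signature
(element plus the sorted multiset of neighbour elements with their own
bonded elements), which separates carbonyl from methine carbons and
methyl from methine hydrogens in an acetylacetonate while grouping all
six carbonyl oxygens. Per-type arithmetic averaging of $P_{val}$,
$\kappa$, $\kappa'$ and frame-aligned $P_{lm}$ builds a databank
(serializable as JSON); applying it to a new molecule instantiates
pseudoatoms with geometry-derived local frames, falling back to the
spherical neutral model for unmatched types — the hybrid treatment used
when a databank lacks parameters for a coordinated metal.

## Bader charges

`densityOnGrid` superposes pseudoatom densities on a molecular box grid
(defaults mirroring a 13.5 Angstrom cube; spacing is the user's
cost/accuracy dial). `baderPartition` assigns voxels to density maxima by
deterministic on-grid steepest ascent over the 26-neighbour stencil with
distance-weighted slopes and pointer doubling, matches maxima to atoms
within a 0.7 Angstrom capture radius (unmatched maxima are reported as
non-nuclear attractors and left unassigned), and integrates electrons per
basin. All-electron Slater densities have nuclear cusps far too sharp for
any affordable grid — a bare rectangle rule misplaces several core
electrons at iron — so the partition accepts the pseudoatom models and
applies an analytic nuclear-cusp correction: the quadrature error of each
atom's spherical density within 0.9 Angstrom of its nucleus is computed
against incomplete-gamma integrals and restored to its basin. With the
correction, isolated atoms integrate to their electron count within 0.02 e
at 0.1 Angstrom spacing.

A calibration fact that shaped the synthetic ground truth: Bader charges
of superposed atomic densities are much larger than the valence-population
charges that generate them, because the basin boundaries concentrate the
charge separation. A valence charge of only +0.3 on iron already yields a
Bader charge near +1.9 in the octahedral O environment. The generator
therefore uses a small $P_{val}$ charge on the metal (default
`feCharge = 0.3`) — this is what reproduces the qualitative published
pattern for such complexes (metal far below its formal +3, strongly
negative carbonyl oxygens near -1.3, positive carbonyl carbons near +1)
while keeping the low-angle scattering physics in the "small metal
charge" regime.

## The synthetic-data generator

`makeStructure` builds an idealized tris-chelate molecule (FeC15H21O6, 43
atoms; Fe-O 1.99, O-C 1.28, ring C-C 1.40, C-CH3 1.50 Angstrom, bite
angle 87.3 degrees, neutron-derived C-H distances 1.077/1.083) and places
it in the Pbca cell a = 15.35, b = 13.56, c = 16.50 Angstrom (Z = 8). The
placement (position, orientation, methyl torsions) is a fixed constant
set, chosen once by maximizing the minimum intermolecular contact (1.93
Angstrom) — idealized rigid geometry packs slightly tighter than a real
relaxed crystal, and this is the generator's packing, not a claim about
the real structure. Anisotropic ADPs grow with distance from the metal
and are oriented relative to the Fe direction, so ellipsoid diagnostics
have signal.

`simulateReflections` computes electron intensities under the chosen
truth ("iam" neutral spherical, or the aspherical "taam" pseudoatom
constants above), then applies the declared noise model
$$\sigma(F^2) = c\,\sqrt{bg + F^2 + g (F^2)^2},$$
with $g = 0.02$ and the two parameters $c$ and $bg$ solved so the overall
mean I/sigma is 8.41 and the highest-resolution shell's is 1.97 — the
two-point signal-decay envelope of the emulated experiment. The
background floor matters beyond realism: without it the weakest
reflections receive near-zero sigmas and unbounded weights, and
refinements against data from a *different* scattering truth are
dominated by them. Reflections are then deleted at random to 92 %
completeness. All randomness is governed by the single integer seed in
the spec; identical seeds give bit-identical data.

What the generator deliberately does **not** emulate: dynamical
(multiple) scattering — the dominant error source in real 3D ED data,
which kinematical refinement cannot model and which raises experimental
R1 values to the 15-25 % range; frame-level effects (tilt geometry,
partiality, scaling); and radiation damage. Consequently the synthetic
R1 values are much lower than experimental ones, and passing tests show
that the *machinery and orderings* behave correctly under kinematical
conditions, not that any particular experimental R1 would be reproduced.

## The comparison pipeline

`makeBenchmarkPair` simulates data under the aspherical truth and returns
a perturbed spherical starting model (0.02 Angstrom Cartesian
perturbations, hydrogens riding). `runComparison` then refines the same
start against the same data under each scattering variant — neutral IAM,
charged IAM (Fe3+ with O0.5-, the formal-oxidation-state assignment),
matched TAAM, or hybrid TAAM with a spherical neutral metal — and
assembles R1/wR2/GooF, locked shell R1, difference-map extrema, fractal
widths, ellipsoid ratios and RMSDs against a reference. Under these
conditions the package reproduces, by construction of the physics rather
than by assertion, the characteristic pattern: matched aspherical factors
fit best; the formal-charge IAM fits *worst* (its ionic factors
overestimate low-angle scattering); and the IAM-to-TAAM improvement
concentrates in the low-resolution shell. The acceptance test suite
asserts exactly these orderings, and `scripts/acceptance.R` recomputes
the quantities from scratch.

## Problem sizes and numerical choices

Default in-suite problem sizes were chosen for fast, deterministic tests:
most unit tests run at reduced resolution (1.1-1.4 Angstrom, 600-1700
reflections), while the acceptance blocks run the full 0.85 Angstrom
envelope (about 2700 unique reflections, 199 parameters), a 20 Angstrom
multipole-fitting box at 2.4 Angstrom resolution, and Bader integration
at 0.15 Angstrom spacing on a 13.5 Angstrom cube (0.75 million voxels).
Tie-breaks and degenerate inputs are fixed deterministically throughout:
ascent ties by stencil order, local axes by the neighbour-priority rule,
duplicate reflections by inverse-variance merging with a warning, empty
resolution shells report a count of zero with an NA statistic.

## Known limitations

Kinematical scattering only; operator-list space groups (no symbol
parsing beyond the built-ins); riding constraints only (no restraints or
rigid groups); a single isotropic extinction scalar; single-zeta Slater
atomic densities rather than full multi-zeta wavefunction expansions (the
spherical reference curves are therefore a few percent from
Hartree-Fock-quality tables at intermediate angles, which is immaterial
for the self-consistent synthetic studies but should be remembered when
comparing against external tabulations); and no redistribution of any
external multipole databank — users supply their own parameter files.
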