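# TaamKin

Kinematical refinement of 3D electron diffraction (3D ED / MicroED) data
with spherical (IAM) and multipolar (TAAM) scattering factors, for
studying how the scattering model — neutral atoms, formally charged ions,
or Hansen–Coppens aspherical pseudoatoms — changes the fit, the
displacement parameters and the residual maps of a refined metal-complex
structure.

Electrons scatter from the electrostatic potential, so low-angle electron
scattering factors are acutely sensitive to atomic charge: by the
Mott–Bethe relation

    f_e(s) = [m0 e^2 / (8 pi eps0 h^2)] * (Z - f_x(s)) / s^2,

a species with net charge q diverges as q/s^2 at low angle. Assigning a
metal its formal oxidation state (e.g. Fe3+ in an iron(III) complex)
therefore injects far more low-resolution scattering power than the real,
partially charged atom possesses. The package provides the machinery to
quantify this: Hansen–Coppens pseudoatom form factors

    f(h) = (Pcore/Ncore) f_core(s) + Pval f_val(s/kappa)
         + sum_lm 4 pi i^l P_lm f_l(4 pi s / kappa') y_lm(h_hat),

kinematical structure factors with anisotropic displacement parameters
and space-group symmetry, full-matrix Levenberg–Marquardt refinement
against F^2 with the standard weighting scheme
w = 1/[sigma^2 + (aP)^2 + bP], P = (Fo^2 + 2Fc^2)/3, riding hydrogens,
resolution-shell and ellipsoid diagnostics, FFT difference maps with
fractal-dimension residual analysis, multipole-parameter refinement
against theoretical structure factors with atom-type databank averaging,
and grid-based Bader (atoms-in-molecules) charge integration with an
analytic nuclear-cusp correction.

A synthetic-data generator emulates an orthorhombic Pbca
tris(acetylacetonato)iron(III) crystal (a = 15.35, b = 13.56, c = 16.50
angstrom, d_min = 0.85 angstrom, 92 % completeness, mean I/sigma 8.4)
with selectable ground truth, so the entire pipeline runs and is tested
with known answers and no downloads. File I/O covers small-molecule CIF
(structures and reflection loops), SHELX HKLF4, `.tsc` scattering-factor
tables, Gaussian cube grids and XYZ.

## Worked example

Simulate data under an aspherical ground truth, then refine the same
perturbed starting model with three scattering models (about a minute at
full resolution):

```r
library(TaamKin)

spec  <- simulationSpec(seed = 1)          # full 0.85-angstrom envelope
bench <- makeBenchmarkPair(spec)
report <- runComparison(
  bench$startModel, bench$data$reflections,
  list(scatteringVariant("IAM neutral",      "iam"),
       scatteringVariant("IAM charged Fe3+", "iam-charged"),
       scatteringVariant("TAAM",             "taam",
                         models = bench$truthModels)),
  config    = refinementConfig(optimizeWeights = TRUE, maxIter = 60),
  reference = bench$truth)
print(report)
```

```
Scattering-model comparison
            model R1_strong R1_all     wR2   GooF nRefl nStrong nParams
      IAM neutral   0.08394 0.1439 0.39740 0.6456  2685    1588     199
 IAM charged Fe3+   0.11000 0.1719 0.77310 0.5597  2685    1588     199
             TAAM   0.04397 0.1062 0.06468 1.0320  2685    1588     199
   weightA   weightB maxPeak minPeak fractalWidth meanEllipsoidRatio rmsdCoord
 4.756e-01  5.420000  0.2340 -0.2058       0.4355              1.607  0.015780
 4.605e-01 17.230000  0.3582 -0.3071       0.6597              2.236  0.019080
 3.898e-12  0.008993  0.1489 -0.1400       0.2860              1.253  0.003409
```

Reading the table: the matched aspherical model (TAAM) fits best
(R1 4.4 % on the strong reflections), the neutral IAM is 4 points worse
(8.4 %), and the formal-charge model is worst of all (11.0 %) — the ionic
Fe3+/O0.5- factors overestimate low-angle scattering. The TAAM
refinement also has the flattest goodness of fit (1.03), the narrowest
fractal-dimension curve of its residual map (0.286 vs 0.436 in the map
units), the healthiest displacement ellipsoids (mean max/min RMS ratio
1.25 vs 1.61), and coordinates closest to the ground truth (RMSD 0.003 vs
0.016 angstrom). The locked-parameter shell table
(`report$shells`) shows the improvement is concentrated at low
resolution: in the 8.65–2.00 angstrom shell R1 drops from 9.8 % (IAM) to
1.2 % (TAAM), while in the 2.00–0.85 angstrom shell it only drops from
7.9 % to 5.5 %.

Bader charges of the underlying aspherical density (cusp-corrected grid
integration) show why the neutral metal model is closer to the truth than
the formal charge:

```r
st    <- bench$truth
xyz   <- as.matrix(atomSites(st)[, c("x", "y", "z")]) %*%
           t(orthoMatrix(st@cell))
atoms <- data.frame(label = atomSites(st)$label,
                    element = atomSites(st)$element,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
grid  <- densityOnGrid(bench$truthModels, atoms, box = 13.5, spacing = 0.15)
bader <- baderPartition(grid, atoms, cuspModels = bench$truthModels)
baderCharges(bader)
# on this grid: Fe +1.90; O -1.29 on average; carbonyl C +1.01
```

The iron's Bader charge (+1.9) sits far below its formal +3, with the
charge separation carried by the ligand — and even that +1.9 arises from
a valence-population charge of only +0.3.

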