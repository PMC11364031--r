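Package: TaamKin
Title: Kinematical Refinement of 3D Electron Diffraction Data with
    Multipolar (TAAM) Scattering Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the choice of atomic scattering model
    (neutral or charged independent-atom model versus transferable
    aspherical atom model) affects kinematical least-squares refinement of
    small-molecule crystal structures against 3D electron diffraction
    data. Provides Gaussian and Hansen-Coppens multipole form factors for
    X-rays and electrons (via the Mott-Bethe relation), structure-factor
    calculation with anisotropic displacement parameters and space-group
    symmetry, weighted full-matrix Levenberg-Marquardt refinement against
    F-squared with riding hydrogens, resolution-shell and displacement
    ellipsoid diagnostics, Fourier difference maps with fractal-dimension
    residual analysis, multipole refinement against theoretical structure
    factors with atom-type databank averaging, grid-based Bader
    (atoms-in-molecules) charge integration, and a synthetic-data
    generator emulating an orthorhombic tris(acetylacetonato)iron(III)
    crystal so the whole pipeline can be exercised with known ground
    truth. Readers and writers for small-molecule CIF, SHELX HKLF4, .tsc
    scattering-factor tables, Gaussian cube grids and XYZ files are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'grid-io.R'
    'formfactor-gaussian.R'
    'formfactor-multipole.R'
    'bader.R'
    'cell-symmetry.R'
    'cif-io.R'
    'hklf-io.R'
    'maps.R'
    'statistics.R'
    'structure-factors.R'
    'multipole-fit.R'
    'refine.R'
    'synthetic.R'
    'pipeline.R'
    'tsc-io.R'
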