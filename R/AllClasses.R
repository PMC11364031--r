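#' @import methods
#' @include constants.R
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Sum-of-Gaussians atomic scattering factor
#'
#' Parametric scattering curve \eqn{f(s) = \sum_i a_i \exp(-b_i s^2) + c}
#' with \eqn{s = \sin\theta/\lambda} in inverse Angstrom.  Used both for
#' X-ray factors (amplitudes in electrons) and electron factors (amplitudes
#' in Angstrom).
#'
#' @slot speciesLabel Element symbol plus formal charge, e.g. "Fe3+".
#' @slot radiation Either "electron" or "xray".
#' @slot a Gaussian amplitudes.
#' @slot b Gaussian widths in Angstrom squared.
#' @slot c Additive constant (same units as \code{a}).
#' @export
setClass("GaussianFormFactor",
  representation(speciesLabel = "character", radiation = "character",
                 a = "numeric", b = "numeric", c = "numeric"),
  prototype(c = 0))

setValidity("GaussianFormFactor", function(object) {
  msg <- character()
  if (length(object@a) != length(object@b))
    msg <- c(msg, "a and b must have equal length")
  if (!object@radiation %in% c("electron", "xray"))
    msg <- c(msg, "radiation must be 'electron' or 'xray'")
  if (length(object@c) != 1) msg <- c(msg, "c must be a single value")
  if (length(msg)) msg else TRUE
})

#' Hansen-Coppens multipole pseudoatom model
#'
#' Pseudoatom electron density
#' \deqn{\rho(r) = P_{core}\rho_{core}(r) + P_{val}\kappa^3\rho_{val}(\kappa r)
#'   + \sum_{l\ge1} \kappa'^3 R_l(\kappa' r) \sum_m P_{lm} d_{lm}(\theta,\phi)}
#' with frozen-core and single-zeta Slater valence densities taken from the
#' element tables, and deformation radial functions
#' \eqn{R_l(r) \propto r^{n_l} e^{-\zeta r}}.
#'
#' @slot element Element symbol.
#' @slot Pcore Core population (electrons).
#' @slot Pval Spherical valence population (electrons).
#' @slot kappa Valence expansion-contraction scalar.
#' @slot kappaPrime Deformation radial scalar.
#' @slot Plm List indexed by l = 1..lmax; each entry a numeric vector of
#'   length 2l+1 of multipole populations, ordered m = -l..l.
#' @slot radialN Powers n_l of the deformation radial functions, l = 1..4.
#' @slot radialZeta Single Slater exponent of the deformation radial
#'   functions, in inverse bohr.
#' @slot localAxes 3x3 rotation matrix mapping local pseudoatom axes to the
#'   global Cartesian frame (columns are the local x, y, z directions).
#' @export
setClass("MultipoleAtomModel",
  representation(element = "character", Pcore = "numeric", Pval = "numeric",
                 kappa = "numeric", kappaPrime = "numeric", Plm = "list",
                 radialN = "numeric", radialZeta = "numeric",
                 localAxes = "matrix"),
  prototype(kappa = 1, kappaPrime = 1, Plm = list(), localAxes = diag(3)))

setValidity("MultipoleAtomModel", function(object) {
  msg <- character()
  if (!object@element %in% names(.slaterAtoms))
    msg <- c(msg, paste("no Slater model for element", object@element))
  if (length(object@Plm) > 4) msg <- c(msg, "l_max must be <= 4")
  for (l in seq_along(object@Plm))
    if (length(object@Plm[[l]]) != 2 * l + 1)
      msg <- c(msg, sprintf("Plm[[%d]] must have length %d", l, 2 * l + 1))
  if (object@kappa <= 0 || object@kappaPrime <= 0)
    msg <- c(msg, "kappa and kappaPrime must be positive")
  if (!all(dim(object@localAxes) == c(3, 3)))
    msg <- c(msg, "localAxes must be a 3x3 matrix")
  if (length(msg)) msg else TRUE
})

#' Per-reflection, per-atom complex form-factor table
#'
#' The in-memory image of a ".tsc" file: one complex scattering factor for
#' every (reflection, scatterer) pair.
#'
#' @slot hkl Integer matrix, one row per reflection.
#' @slot atoms Ordered scatterer labels.
#' @slot values Complex matrix, reflections in rows, atoms in columns.
#' @slot radiation Either "electron" or "xray".
#' @export
setClass("FormFactorTable",
  representation(hkl = "matrix", atoms = "character", values = "matrix",
                 radiation = "character"))

setValidity("FormFactorTable", function(object) {
  msg <- character()
  if (ncol(object@hkl) != 3) msg <- c(msg, "hkl must have 3 columns")
  if (nrow(object@values) != nrow(object@hkl))
    msg <- c(msg, "values must have one row per reflection")
  if (ncol(object@values) != length(object@atoms))
    msg <- c(msg, "values must have one column per atom")
  if (!is.complex(object@values)) msg <- c(msg, "values must be complex")
  if (length(msg)) msg else TRUE
})

#' Unit cell
#' @slot a,b,c Cell lengths in Angstrom.
#' @slot alpha,beta,gamma Cell angles in degrees.
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"),
  prototype(alpha = 90, beta = 90, gamma = 90))

setValidity("UnitCell", function(object) {
  p <- c(object@a, object@b, object@c)
  ang <- c(object@alpha, object@beta, object@gamma)
  if (any(p <= 0)) return("cell lengths must be positive")
  if (any(ang <= 0) || any(ang >= 180)) return("cell angles must be in (0, 180)")
  ca <- cos(ang * pi / 180)
  det <- 1 - sum(ca^2) + 2 * prod(ca)
  if (det <= 0) return("cell metric is not positive definite")
  TRUE
})

#' Space group as an explicit operator list
#' @slot symbol Hermann-Mauguin symbol (informative only).
#' @slot rotations List of integer 3x3 rotation matrices acting on
#'   fractional coordinates.
#' @slot translations List of fractional translation vectors.
#' @slot centrosymmetric Logical flag.
#' @export
setClass("SpaceGroup",
  representation(symbol = "character", rotations = "list",
                 translations = "list", centrosymmetric = "logical"),
  prototype(centrosymmetric = FALSE))

setValidity("SpaceGroup", function(object) {
  if (length(object@rotations) != length(object@translations))
    return("rotations and translations must have equal length")
  if (length(object@rotations) == 0) return("at least the identity is required")
  ok <- vapply(seq_along(object@rotations), function(i) {
    R <- object@rotations[[i]]
    all(dim(R) == c(3, 3)) && length(object@translations[[i]]) == 3
  }, logical(1))
  if (!all(ok)) return("malformed symmetry operation(s)")
  has_id <- any(vapply(seq_along(object@rotations), function(i)
    all(object@rotations[[i]] == diag(3)) &&
      all(object@translations[[i]] %% 1 == 0), logical(1)))
  if (!has_id) return("identity operation missing")
  TRUE
})

#' Crystal structure model
#'
#' Cell, symmetry, and an atom-site table with anisotropic displacement
#' parameters and per-atom scattering-model assignment.  The \code{sites}
#' data frame has columns label, element, x, y, z (fractional), occ, adpType
#' ("iso"/"aniso"), uiso, u11, u22, u33, u12, u13, u23 (crystallographic
#' U convention, Angstrom squared), partId, scattererRef.
#'
#' @slot cell A \code{UnitCell}.
#' @slot spaceGroup A \code{SpaceGroup}.
#' @slot sites Atom-site data frame (see Description).
#' @export
setClass("CrystalStructure",
  representation(cell = "UnitCell", spaceGroup = "SpaceGroup",
                 sites = "data.frame"))

.siteColumns <- c("label", "element", "x", "y", "z", "occ", "adpType", "uiso",
                  "u11", "u22", "u33", "u12", "u13", "u23", "partId",
                  "scattererRef")

setValidity("CrystalStructure", function(object) {
  miss <- setdiff(.siteColumns, colnames(object@sites))
  if (length(miss))
    return(paste("sites is missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(object@sites$label)) return("duplicate site labels")
  TRUE
})

#' Reflection data set
#'
#' Indexed intensities with uncertainties and derived resolution.
#'
#' @slot hkl Integer matrix of Miller indices.
#' @slot fobs2 Observed squared structure-factor amplitudes.
#' @slot sigma Standard uncertainties of \code{fobs2} (must be positive).
#' @slot d Resolution in Angstrom; \code{s = 1/(2 d)}.
#' @export
setClass("ReflectionSet",
  representation(hkl = "matrix", fobs2 = "numeric", sigma = "numeric",
                 d = "numeric"))

setValidity("ReflectionSet", function(object) {
  n <- nrow(object@hkl)
  if (ncol(object@hkl) != 3) return("hkl must have 3 columns")
  if (length(object@fobs2) != n || length(object@sigma) != n ||
      length(object@d) != n)
    return("fobs2, sigma and d must match the number of reflections")
  if (any(object@sigma <= 0)) return("all sigma must be positive")
  TRUE
})

#' Scalar field on a regular 3D grid
#'
#' @slot values 3D numeric array.
#' @slot origin Cartesian origin of voxel (1,1,1), in Angstrom.
#' @slot step 3x3 matrix whose columns are the Cartesian step vectors of the
#'   three grid axes, in Angstrom.
#' @slot periodic Whether the grid wraps (unit-cell map) or is a bounded
#'   molecular box.
#' @slot unit Unit tag of the values (e.g. "e/A^3" for electron density,
#'   "1/A^2" for electrostatic-potential difference maps).
#' @export
setClass("DensityGrid",
  representation(values = "array", origin = "numeric", step = "matrix",
                 periodic = "logical", unit = "character"),
  prototype(periodic = FALSE, unit = "e/A^3"))

setValidity("DensityGrid", function(object) {
  if (length(dim(object@values)) != 3) return("values must be a 3D array")
  if (length(object@origin) != 3) return("origin must have length 3")
  if (!all(dim(object@step) == c(3, 3))) return("step must be 3x3")
  TRUE
})

#' Result of a least-squares structure refinement
#'
#' @slot structure The refined \code{CrystalStructure}.
#' @slot scale Scale factor k applied as \eqn{F_{obs}^2 \approx k F_{calc}^2}.
#' @slot stats Named list: R1_strong, R1_all, wR2, goof, nObs, nParams,
#'   nStrong.
#' @slot weights The (a, b) weighting parameters used.
#' @slot converged Logical.
#' @slot iterations Number of Levenberg-Marquardt iterations.
#' @slot maxShift Largest absolute parameter shift in the final cycle.
#' @slot fcalc2 Scaled model intensities, one per input reflection.
#' @export
setClass("RefinementResult",
  representation(structure = "CrystalStructure", scale = "numeric",
                 stats = "list", weights = "numeric", converged = "logical",
                 iterations = "numeric", maxShift = "numeric",
                 fcalc2 = "numeric"))

#' Result of a Bader basin integration
#'
#' @slot atoms Data frame with columns label, element, Z, electrons, volume
#'   (Angstrom cubed) and charge (e).
#' @slot unassigned Electrons in basins not attached to any atom.
#' @slot totalElectrons Total grid integral of the density.
#' @export
setClass("BaderResult",
  representation(atoms = "data.frame", unassigned = "numeric",
                 totalElectrons = "numeric"))
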