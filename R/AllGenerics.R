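#' @include AllClasses.R
NULL

#' Evaluate a scattering factor at reciprocal resolution s
#' @param object A form-factor object.
#' @param s Reciprocal resolution \eqn{\sin\theta/\lambda} in inverse
#'   Angstrom (non-negative).
#' @param ... Further arguments for methods.
#' @return Numeric (or complex) scattering amplitudes, one per element of
#'   \code{s}.
#' @export
setGeneric("evaluateFormFactor", function(object, s, ...)
  standardGeneric("evaluateFormFactor"))

#' Cell parameters as a named vector
#' @param object A \code{UnitCell} or \code{CrystalStructure}.
#' @return Named numeric vector a, b, c, alpha, beta, gamma.
#' @export
setGeneric("cellParameters", function(object) standardGeneric("cellParameters"))

#' Atom-site table of a structure
#' @param object A \code{CrystalStructure}.
#' @return The sites data frame.
#' @export
setGeneric("atomSites", function(object) standardGeneric("atomSites"))

#' Symmetry operations of a structure or space group
#' @param object A \code{SpaceGroup} or \code{CrystalStructure}.
#' @return List with elements \code{rotations} and \code{translations}.
#' @export
setGeneric("symmetryOperations", function(object)
  standardGeneric("symmetryOperations"))

#' Reflection data as a data frame
#' @param object A \code{ReflectionSet}.
#' @return Data frame with h, k, l, fobs2, sigma, d, s.
#' @export
setGeneric("reflectionData", function(object) standardGeneric("reflectionData"))

#' Refinement statistics
#' @param object A \code{RefinementResult}.
#' @return Named list of agreement statistics.
#' @export
setGeneric("refinementStats", function(object)
  standardGeneric("refinementStats"))

#' Per-atom Bader charges
#' @param object A \code{BaderResult}.
#' @return Data frame of basin populations and net charges.
#' @export
setGeneric("baderCharges", function(object) standardGeneric("baderCharges"))

setMethod("cellParameters", "UnitCell", function(object)
  c(a = object@a, b = object@b, c = object@c, alpha = object@alpha,
    beta = object@beta, gamma = object@gamma))
setMethod("cellParameters", "CrystalStructure", function(object)
  cellParameters(object@cell))

setMethod("atomSites", "CrystalStructure", function(object) object@sites)

setMethod("symmetryOperations", "SpaceGroup", function(object)
  list(rotations = object@rotations, translations = object@translations))
setMethod("symmetryOperations", "CrystalStructure", function(object)
  symmetryOperations(object@spaceGroup))

setMethod("reflectionData", "ReflectionSet", function(object)
  data.frame(h = object@hkl[, 1], k = object@hkl[, 2], l = object@hkl[, 3],
             fobs2 = object@fobs2, sigma = object@sigma, d = object@d,
             s = 1 / (2 * object@d)))

setMethod("refinementStats", "RefinementResult", function(object) object@stats)

setMethod("baderCharges", "BaderResult", function(object) object@atoms)

setMethod("show", "GaussianFormFactor", function(object) {
  cat(sprintf("GaussianFormFactor %s (%s), %d terms, f(0) = %.4f\n",
              object@speciesLabel, object@radiation, length(object@a),
              sum(object@a) + object@c))
})

setMethod("show", "MultipoleAtomModel", function(object) {
  npl <- sum(vapply(object@Plm, function(p) sum(p != 0), numeric(1)))
  cat(sprintf(
    "MultipoleAtomModel %s: Pcore %.2f, Pval %.3f, kappa %.4f, kappa' %.4f, %d nonzero Plm\n",
    object@element, object@Pcore, object@Pval, object@kappa,
    object@kappaPrime, npl))
})

setMethod("show", "FormFactorTable", function(object) {
  cat(sprintf("FormFactorTable (%s): %d reflections x %d scatterers\n",
              object@radiation, nrow(object@hkl), length(object@atoms)))
})

setMethod("show", "UnitCell", function(object) {
  p <- cellParameters(object)
  cat(sprintf("UnitCell %.4f %.4f %.4f A, %.2f %.2f %.2f deg, V = %.1f A^3\n",
              p[1], p[2], p[3], p[4], p[5], p[6], cellVolume(object)))
})

setMethod("show", "SpaceGroup", function(object) {
  cat(sprintf("SpaceGroup %s, %d operations%s\n", object@symbol,
              length(object@rotations),
              if (object@centrosymmetric) " (centrosymmetric)" else ""))
})

setMethod("show", "CrystalStructure", function(object) {
  cat(sprintf("CrystalStructure: %d sites in %s\n", nrow(object@sites),
              object@spaceGroup@symbol))
  show(object@cell)
})

setMethod("show", "ReflectionSet", function(object) {
  cat(sprintf("ReflectionSet: %d reflections, d = %.2f-%.2f A, <I/sigma> = %.2f\n",
              nrow(object@hkl), max(object@d), min(object@d),
              mean(object@fobs2 / object@sigma)))
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityGrid %d x %d x %d (%s), range [%.4g, %.4g]%s\n",
              d[1], d[2], d[3], object@unit, min(object@values),
              max(object@values), if (object@periodic) ", periodic" else ""))
})

setMethod("show", "RefinementResult", function(object) {
  s <- object@stats
  cat(sprintf(
    "RefinementResult: R1 %.4f (strong) / %.4f (all), wR2 %.4f, GooF %.3f\n",
    s$R1_strong, s$R1_all, s$wR2, s$goof))
  cat(sprintf("  %d obs, %d params, %d iterations, converged: %s\n",
              s$nObs, s$nParams, object@iterations, object@converged))
})

setMethod("show", "BaderResult", function(object) {
  cat(sprintf("BaderResult: %d atoms, %.3f electrons integrated, %.4f unassigned\n",
              nrow(object@atoms), object@totalElectrons, object@unassigned))
})
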