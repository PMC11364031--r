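#' @include cell-symmetry.R formfactor-multipole.R
NULL

# Resolve one scatterer reference to per-reflection complex form factors.
# hklRot: n x 3 (possibly symmetry-rotated) integer indices
# hcart:  their Cartesian reciprocal vectors, s = |hcart|/2
.ffValues <- function(obj, hklRot, hcart, s, radiation) {
  if (is(obj, "GaussianFormFactor")) {
    if (obj@radiation != radiation)
      stop("form factor ", obj@speciesLabel, " is for ", obj@radiation,
           " radiation, not ", radiation)
    return(complex(real = evaluateFormFactor(obj, s)))
  }
  if (is(obj, "MultipoleAtomModel"))
    return(hcFormFactor(obj, hcart, radiation = radiation))
  if (is(obj, "FormFactorTable")) {
    if (obj@radiation != radiation)
      stop("form-factor table is for ", obj@radiation, " radiation")
    key <- paste(hklRot[, 1], hklRot[, 2], hklRot[, 3])
    tkey <- paste(obj@hkl[, 1], obj@hkl[, 2], obj@hkl[, 3])
    idx <- match(key, tkey)
    if (anyNA(idx)) {
      # Friedel completion: f(-h) = conj(f(h)) for real scatterer density
      neg <- match(paste(-hklRot[, 1], -hklRot[, 2], -hklRot[, 3]), tkey)
      take <- is.na(idx) & !is.na(neg)
      miss <- is.na(idx) & is.na(neg)
      if (any(miss))
        stop("reflection(s) absent from form-factor table: ",
             paste(key[miss][seq_len(min(5, sum(miss)))], collapse = "; "))
      vals <- complex(length(key))
      vals[!is.na(idx)] <- obj@values[idx[!is.na(idx)], attr(obj, "col")]
      vals[take] <- Conj(obj@values[neg[take], attr(obj, "col")])
      return(vals)
    }
    return(obj@values[idx, attr(obj, "col")])
  }
  if (is.function(obj)) return(complex(real = obj(s)))
  stop("unsupported scatterer object of class ", class(obj)[1])
}

# select one atom column of a FormFactorTable, keeping the table intact
.tableColumn <- function(tab, label) {
  j <- match(label, tab@atoms)
  if (is.na(j)) stop("atom ", label, " not present in form-factor table")
  attr(tab, "col") <- j
  tab
}

.resolveScatterer <- function(provider, ref, label) {
  obj <- provider[[ref]]
  if (is.null(obj)) stop("no scattering model for reference '", ref, "'")
  if (is(obj, "FormFactorTable")) obj <- .tableColumn(obj, label)
  obj
}

# anisotropic Debye-Waller exponent coefficients for (possibly rotated)
# integer indices; U in the CIF U_ij convention:
# T = exp(-2 pi^2 sum_ij U_ij h_i h_j a*_i a*_j)
.dwAniso <- function(hklRot, rl, u) {
  h <- hklRot
  -2 * pi^2 * (u[1] * (h[, 1] * rl[1])^2 + u[2] * (h[, 2] * rl[2])^2 +
               u[3] * (h[, 3] * rl[3])^2 +
               2 * u[4] * h[, 1] * h[, 2] * rl[1] * rl[2] +
               2 * u[5] * h[, 1] * h[, 3] * rl[1] * rl[3] +
               2 * u[6] * h[, 2] * h[, 3] * rl[2] * rl[3])
}

#' Kinematical structure factors
#'
#' Computes \eqn{F(h) = \sum_{sites}\sum_{ops} occ\, f(h R)\, T(h R)\,
#' e^{2\pi i (h R \cdot x + h \cdot t)}} with anisotropic or isotropic
#' Debye-Waller factors in the crystallographic U convention.
#'
#' @param structure A \code{CrystalStructure}; each site's
#'   \code{scattererRef} must resolve in \code{provider}.
#' @param hkl Integer matrix of Miller indices (or a \code{ReflectionSet}).
#' @param provider Named list mapping scatterer references to
#'   \code{GaussianFormFactor}, \code{MultipoleAtomModel},
#'   \code{FormFactorTable} or plain functions of s.
#' @param radiation "electron" or "xray".
#' @return Complex vector of structure factors, one per reflection.
#' @export
calcStructureFactors <- function(structure, hkl, provider,
                                 radiation = c("electron", "xray")) {
  radiation <- match.arg(radiation)
  if (is(hkl, "ReflectionSet")) hkl <- hkl@hkl
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  cell <- structure@cell
  ops <- symmetryOperations(structure)
  rl <- reciprocalLengths(cell)
  st <- structure@sites
  n <- nrow(hkl)
  Fc <- complex(n)
  for (iop in seq_along(ops$rotations)) {
    R <- ops$rotations[[iop]]; tr <- ops$translations[[iop]]
    hR <- hkl %*% R
    hcart <- reciprocalVectors(cell, hR)
    s <- sqrt(rowSums(hcart^2)) / 2
    phase0 <- drop(hkl %*% tr)  # careful: h.(Rx + t) = (hR).x + h.t
    for (ia in seq_len(nrow(st))) {
      obj <- .resolveScatterer(provider, st$scattererRef[ia], st$label[ia])
      f <- .ffValues(obj, hR, hcart, s, radiation)
      if (st$adpType[ia] == "aniso") {
        u <- as.numeric(st[ia, c("u11", "u22", "u33", "u12", "u13", "u23")])
        Tdw <- exp(.dwAniso(hR, rl, u))
      } else {
        Tdw <- exp(-8 * pi^2 * st$uiso[ia] * s^2)
      }
      ph <- 2 * pi * (drop(hR %*% as.numeric(st[ia, c("x", "y", "z")])) + phase0)
      Fc <- Fc + st$occ[ia] * f * Tdw * exp(1i * ph)
    }
  }
  Fc
}

#' Independent-atom-model scatterer provider
#'
#' Builds a provider assigning a Gaussian IAM factor to every element (or
#' species) occurring in a structure.
#'
#' @param structure A \code{CrystalStructure} (its \code{scattererRef}
#'   values are used as species labels).
#' @param radiation "electron" or "xray".
#' @return Named list of \code{GaussianFormFactor}s.
#' @export
iamProvider <- function(structure, radiation = c("electron", "xray")) {
  radiation <- match.arg(radiation)
  refs <- unique(structure@sites$scattererRef)
  out <- lapply(refs, function(r)
    if (radiation == "electron") electronFormFactor(r) else xrayFormFactor(r))
  names(out) <- refs
  out
}

#' Build a per-reflection form-factor table from pseudoatom models
#'
#' Evaluates aspherical form factors for every atom at every index needed
#' under the structure's symmetry (all distinct rotated indices), in the
#' global Cartesian frame, ready for table-driven structure-factor
#' calculation or .tsc export.
#'
#' @param structure A \code{CrystalStructure}.
#' @param hkl Integer matrix of (asymmetric-unit) Miller indices.
#' @param models Named list of \code{MultipoleAtomModel}, one per site
#'   label.
#' @param radiation "electron" or "xray".
#' @return A \code{FormFactorTable} covering all symmetry-rotated indices.
#' @export
formFactorTable <- function(structure, hkl, models,
                            radiation = c("electron", "xray")) {
  radiation <- match.arg(radiation)
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  ops <- symmetryOperations(structure)
  allh <- unique(do.call(rbind, lapply(ops$rotations, function(R) hkl %*% R)))
  storage.mode(allh) <- "integer"
  hcart <- reciprocalVectors(structure@cell, allh)
  s <- sqrt(rowSums(hcart^2)) / 2
  labels <- structure@sites$label
  vals <- sapply(labels, function(lb) {
    m <- models[[lb]]
    if (is.null(m)) stop("no multipole model for atom ", lb)
    hcFormFactor(m, hcart, radiation = radiation)
  })
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(labels))
  new("FormFactorTable", hkl = allh, atoms = as.character(labels),
      values = vals, radiation = radiation)
}

#' Provider serving every site from one form-factor table
#' @param structure A \code{CrystalStructure}.
#' @param table A \code{FormFactorTable} containing all site labels.
#' @return Named list suitable for \code{calcStructureFactors}; site
#'   \code{scattererRef}s must equal the site labels.
#' @export
tableProvider <- function(structure, table) {
  refs <- unique(structure@sites$scattererRef)
  out <- rep(list(table), length(refs))
  names(out) <- refs
  out
}
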