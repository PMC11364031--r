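#' @include formfactor-gaussian.R
NULL

# ---- Fourier-Bessel transforms of Slater-type radial functions ----------
#
# All transforms use the crystallographic kernel: for a radial function
# g(r) the order-l transform is  I_l(k) = int_0^inf r^2 g(r) j_l(k r) dr
# with k = 4 pi s = 2 pi |h|,  s = sin(theta)/lambda.

# closed-form sin/cos moments: int r^p e^(-a r) sin(kr) dr = Im p!/(a-ik)^(p+1)
.sinMoment <- function(p, a, k) Im(factorial(p) / (complex(real = a, imaginary = -k))^(p + 1))
.cosMoment <- function(p, a, k) Re(factorial(p) / (complex(real = a, imaginary = -k))^(p + 1))

# coefficients of j_l(x) = sum_j s_j x^-j sin(x) + c_j x^-j cos(x)
.jlCoef <- list(
  `0` = list(s = c(`1` = 1), c = numeric()),
  `1` = list(s = c(`2` = 1), c = c(`1` = -1)),
  `2` = list(s = c(`3` = 3, `1` = -1), c = c(`2` = -3)),
  `3` = list(s = c(`4` = 15, `2` = -6), c = c(`3` = -15, `1` = 1)),
  `4` = list(s = c(`5` = 105, `3` = -45, `1` = 1), c = c(`4` = -105, `2` = 10))
)

.doubleFactorial <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

#' Order-l Fourier-Bessel transform of a Slater radial function
#'
#' Computes \eqn{\int_0^\infty r^{m+2} e^{-\alpha r} j_l(k r)\,dr}
#' analytically, switching to the ascending series of \eqn{j_l} at small
#' \eqn{k/\alpha} where the closed form cancels catastrophically.
#'
#' @param k Transform variable \eqn{4\pi s}, vectorized (inverse Angstrom).
#' @param m Radial power (of the density function).
#' @param alpha Slater exponent (inverse Angstrom).
#' @param l Transform order, 0 to 4.
#' @return Numeric vector of the same length as \code{k}.
#' @export
slaterBesselTransform <- function(k, m, alpha, l) {
  if (l < 0 || l > 4) stop("l must be in 0..4")
  if (m + 2 - (l + 1) < 0) stop("radial power too small for order l")
  out <- numeric(length(k))
  small <- k < 0.45 * alpha
  if (any(small)) {
    ks <- k[small]
    acc <- 0
    t <- 0
    repeat {
      term <- (-1)^t / (2^t * factorial(t) * .doubleFactorial(2 * l + 2 * t + 1)) *
        ks^(l + 2 * t) * factorial(m + 2 + l + 2 * t) / alpha^(m + 3 + l + 2 * t)
      acc <- acc + term
      t <- t + 1
      if (max(abs(term)) < 1e-17 * max(abs(acc), 1e-300) || t > 60) break
    }
    out[small] <- acc
  }
  if (any(!small)) {
    kl <- k[!small]
    cf <- .jlCoef[[as.character(l)]]
    acc <- 0
    for (j in names(cf$s))
      acc <- acc + cf$s[[j]] * kl^(-as.numeric(j)) *
        .sinMoment(m + 2 - as.numeric(j), alpha, kl)
    for (j in names(cf$c))
      acc <- acc + cf$c[[j]] * kl^(-as.numeric(j)) *
        .cosMoment(m + 2 - as.numeric(j), alpha, kl)
    out[!small] <- acc
  }
  out
}

# per-electron scattering shape of a Slater shell with orbital quantum
# number n and orbital exponent zeta (inverse bohr): density r^(2n-2) e^(-2 zeta r)
.shellFactor <- function(s, n, zeta) {
  alpha <- 2 * zeta / .bohrToAngstrom
  m <- 2 * n - 2
  norm <- alpha^(m + 3) / factorial(m + 2)
  norm * slaterBesselTransform(4 * pi * s, m, alpha, 0)
}

#' Spherical core and valence scattering factors of an element
#'
#' X-ray scattering factors of the frozen-core and spherical-valence
#' densities of the embedded single-zeta Slater atomic models.
#' \code{coreFactor} is normalized to the number of core electrons at
#' \eqn{s = 0}; \code{valenceFactor} is normalized to 1.
#'
#' @param element Element symbol.
#' @param s Reciprocal resolution grid (inverse Angstrom).
#' @return Numeric vector.
#' @export
coreFactor <- function(element, s) {
  sh <- .slaterAtoms[[element]]$core
  if (length(sh) == 0) return(rep(0, length(s)))
  Reduce(`+`, lapply(sh, function(x) x$ne * .shellFactor(s, x$n, x$zeta)))
}

#' @rdname coreFactor
#' @export
valenceFactor <- function(element, s) {
  sh <- .slaterAtoms[[element]]$valence
  tot <- sum(vapply(sh, `[[`, numeric(1), "ne"))
  Reduce(`+`, lapply(sh, function(x)
    x$ne / tot * .shellFactor(s, x$n, x$zeta)))
}

.coreElectrons <- function(element)
  sum(vapply(.slaterAtoms[[element]]$core, `[[`, numeric(1), "ne"))

# ---- real spherical harmonics (orthonormal) -----------------------------

# Evaluate orthonormal real spherical harmonics y_lm at unit vectors.
# u: n x 3 matrix of unit vectors; returns n x (2l+1) matrix, m = -l..l.
# Convention: y_l0 = K P_l(cos t); y_l,+m = sqrt(2) K_lm P_l^m(cos t) cos(m phi);
# y_l,-m uses sin(m phi).  The Condon-Shortley phase of pracma::legendre is
# retained; the same functions are used in real and reciprocal space, so
# the multipole populations are defined in this fixed convention.
.realSphericalHarmonics <- function(l, u) {
  n <- nrow(u)
  if (l == 0) return(matrix(1 / sqrt(4 * pi), n, 1))
  ct <- pmin(1, pmax(-1, u[, 3]))
  phi <- atan2(u[, 2], u[, 1])
  P <- pracma::legendre(l, ct)           # (l+1) x n, rows m = 0..l
  if (is.null(dim(P))) P <- matrix(P, ncol = 1)
  out <- matrix(0, n, 2 * l + 1)
  K <- function(m) sqrt((2 * l + 1) / (4 * pi) *
                          factorial(l - m) / factorial(l + m))
  out[, l + 1] <- K(0) * P[1, ]
  for (m in seq_len(l)) {
    out[, l + 1 + m] <- sqrt(2) * K(m) * P[m + 1, ] * cos(m * phi)
    out[, l + 1 - m] <- sqrt(2) * K(m) * P[m + 1, ] * sin(m * phi)
  }
  out
}

# ---- Hansen-Coppens pseudoatom form factors -----------------------------

#' Construct a multipole pseudoatom model
#'
#' @param element Element symbol.
#' @param Pval Spherical valence population (electrons); defaults to the
#'   neutral valence count of the element.
#' @param kappa,kappaPrime Radial scaling parameters.
#' @param Plm List of deformation populations, indexed by l (each a vector
#'   of length 2l+1, m = -l..l); empty for a spherical atom.
#' @param Pcore Core population; defaults to the full frozen core.
#' @param localAxes 3x3 rotation matrix of the local frame (columns = local
#'   axes in global Cartesian coordinates).
#' @return A \code{MultipoleAtomModel}.
#' @export
multipoleAtomModel <- function(element, Pval = NULL, kappa = 1,
                               kappaPrime = 1, Plm = list(),
                               Pcore = NULL, localAxes = diag(3)) {
  if (is.null(Pval)) Pval <- .neutralValence[[element]]
  if (is.null(Pcore)) Pcore <- .coreElectrons(element)
  def <- .deformationRadialDefaults[[element]]
  new("MultipoleAtomModel", element = element, Pcore = Pcore, Pval = Pval,
      kappa = kappa, kappaPrime = kappaPrime, Plm = Plm,
      radialN = def$n_l, radialZeta = def$zeta, localAxes = localAxes)
}

#' Spherical neutral reference model of an element
#' @param element Element symbol.
#' @return A \code{MultipoleAtomModel} with neutral populations and no
#'   deformation terms.
#' @export
neutralAtomModel <- function(element) multipoleAtomModel(element)

#' Net spherical charge of a pseudoatom
#' @param model A \code{MultipoleAtomModel}.
#' @return \eqn{Z - P_{core} - P_{val}} in electrons.
#' @export
pseudoatomCharge <- function(model)
  atomicNumber(model@element) - model@Pcore - model@Pval

#' Hansen-Coppens aspherical form factor
#'
#' Evaluates the pseudoatom scattering factor at Cartesian reciprocal
#' vectors.  The X-ray factor is
#' \deqn{f(h) = \frac{P_{core}}{N_{core}} f_{core}(s) + P_{val} f_{val}(s/\kappa)
#'  + \sum_{l\ge1} 4\pi i^l f_l(k/\kappa') \sum_m P_{lm} y_{lm}(u_h)}
#' with \eqn{f_l} the order-l Fourier-Bessel transform of the normalized
#' deformation radial function and \eqn{y_{lm}} orthonormal real spherical
#' harmonics of the scattering direction in the pseudoatom local frame.
#' Electron factors apply the Mott-Bethe relation with the element's
#' nuclear charge to the complex X-ray factor.
#'
#' @param model A \code{MultipoleAtomModel}.
#' @param h Either an n x 3 matrix of Cartesian reciprocal vectors with
#'   \eqn{|h| = 1/d = 2s} (inverse Angstrom), or a numeric vector of s
#'   values for a spherical model.
#' @param radiation "xray" or "electron".
#' @return Complex vector of form-factor values.
#' @export
hcFormFactor <- function(model, h, radiation = c("xray", "electron")) {
  radiation <- match.arg(radiation)
  validObject(model)
  if (is.null(dim(h))) {
    if (length(model@Plm) > 0)
      stop("aspherical models require full reciprocal vectors, not just s")
    h <- cbind(2 * h, 0, 0)  # direction irrelevant for spherical terms
  }
  hnorm <- sqrt(rowSums(h^2))
  s <- hnorm / 2
  el <- model@element
  ncore <- .coreElectrons(el)
  fcore <- if (ncore > 0) model@Pcore / ncore * coreFactor(el, s) else 0
  f <- complex(real = fcore + model@Pval * valenceFactor(el, s / model@kappa))
  if (length(model@Plm) > 0) {
    u <- h / pmax(hnorm, 1e-300)
    u[hnorm == 0, ] <- rep(c(0, 0, 1), each = sum(hnorm == 0))
    ulocal <- u %*% model@localAxes   # components in the local frame
    zeta <- model@radialZeta / .bohrToAngstrom
    for (l in seq_along(model@Plm)) {
      P <- model@Plm[[l]]
      if (all(P == 0)) next
      n_l <- model@radialN[l]
      norm <- zeta^(n_l + 3) / factorial(n_l + 2)
      # kappa'-scaled radial kp^3 R_l(kp r) transforms to f_l(k / kp)
      fl <- norm * slaterBesselTransform(4 * pi * s / model@kappaPrime,
                                         n_l, zeta, l)
      ylm <- .realSphericalHarmonics(l, ulocal)
      ang <- drop(ylm %*% P)
      f <- f + 4 * pi * (1i)^l * fl * ang
    }
  }
  if (radiation == "electron") {
    if (any(s <= 0)) stop("electron factors require s > 0")
    Z <- atomicNumber(el)
    f <- .mottBetheConstant * (Z - f) / s^2
  }
  f
}

#' Spherical component of a pseudoatom scattering curve
#'
#' The curve \eqn{f = (P_{core}/N_{core}) f_{core}(s) + P_{val} f_{val}(s/\kappa)},
#' i.e. the multipole model with all deformation terms dropped, for
#' comparison against independent-atom-model curves.
#'
#' @param model A \code{MultipoleAtomModel}.
#' @param s Reciprocal resolution grid (inverse Angstrom).
#' @param radiation "xray" or "electron".
#' @return Numeric vector of scattering amplitudes.
#' @export
sphericalComponentCurve <- function(model, s,
                                    radiation = c("xray", "electron")) {
  radiation <- match.arg(radiation)
  spherical <- multipoleAtomModel(model@element, Pval = model@Pval,
                                  kappa = model@kappa, Pcore = model@Pcore)
  Re(hcFormFactor(spherical, s, radiation = radiation))
}

# ---- real-space pseudoatom densities (used by the Bader module) ---------

# per-electron Slater shell density at radii r (Angstrom)
.shellDensity <- function(r, n, zeta) {
  alpha <- 2 * zeta / .bohrToAngstrom
  m <- 2 * n - 2
  alpha^(m + 3) / (factorial(m + 2) * 4 * pi) * r^m * exp(-alpha * r)
}

#' Pseudoatom electron density at points
#'
#' Evaluates the Hansen-Coppens real-space density of one pseudoatom at
#' Cartesian points relative to the nucleus.
#'
#' @param model A \code{MultipoleAtomModel}.
#' @param xyz n x 3 matrix of Cartesian offsets from the nucleus (Angstrom).
#' @return Density values in electrons per cubic Angstrom.
#' @export
pseudoatomDensity <- function(model, xyz) {
  r <- sqrt(rowSums(xyz^2))
  el <- model@element
  rho <- numeric(length(r))
  core <- .slaterAtoms[[el]]$core
  ncore <- .coreElectrons(el)
  for (sh in core)
    rho <- rho + model@Pcore * sh$ne / ncore * .shellDensity(r, sh$n, sh$zeta)
  val <- .slaterAtoms[[el]]$valence
  tot <- sum(vapply(val, `[[`, numeric(1), "ne"))
  k <- model@kappa
  for (sh in val)
    rho <- rho + model@Pval * sh$ne / tot * k^3 *
      .shellDensity(k * r, sh$n, sh$zeta)
  if (length(model@Plm) > 0) {
    u <- xyz / pmax(r, 1e-300)
    u[r == 0, ] <- rep(c(0, 0, 1), each = sum(r == 0))
    ulocal <- u %*% model@localAxes
    zeta <- model@radialZeta / .bohrToAngstrom
    kp <- model@kappaPrime
    for (l in seq_along(model@Plm)) {
      P <- model@Plm[[l]]
      if (all(P == 0)) next
      n_l <- model@radialN[l]
      norm <- zeta^(n_l + 3) / factorial(n_l + 2)
      # int r^2 R_l(r) dr = 1; density term is kp^3 R_l(kp r) y_lm(u)
      Rl <- kp^3 * norm * (kp * r)^n_l * exp(-zeta * kp * r)
      ylm <- .realSphericalHarmonics(l, ulocal)
      rho <- rho + Rl * drop(ylm %*% P)
    }
  }
  rho
}
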