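# Physical constants and embedded scattering-factor / atomic-model tables.
#
# All reciprocal-space quantities use s = sin(theta)/lambda = 1/(2 d) in
# inverse Angstrom unless stated otherwise.

# Mott-Bethe prefactor m0 e^2 / (8 pi eps0 h^2), in inverse Angstrom,
# from CODATA 2018 exact/recommended values.
.mottBetheConstant <- local({
  m0 <- 9.1093837015e-31   # kg
  e <- 1.602176634e-19     # C
  eps0 <- 8.8541878128e-12 # F/m
  h <- 6.62607015e-34      # J s
  m0 * e^2 / (8 * pi * eps0 * h^2) * 1e-10
})

#' Mott-Bethe prefactor
#'
#' The constant \eqn{C = m_0 e^2 / (8\pi\epsilon_0 h^2)} in inverse Angstrom,
#' such that the electron scattering factor in Angstrom is
#' \eqn{f^e(s) = C (Z - f^x(s))/s^2} with \eqn{s = \sin\theta/\lambda} in
#' inverse Angstrom.
#'
#' @return A single numeric value (about 0.023934).
#' @export
mottBetheConstant <- function() .mottBetheConstant

.bohrToAngstrom <- 0.529177210903

# Analytic X-ray scattering factors, 4-Gaussian + constant parametrization
# (International-Tables-style coefficients): f(s) = sum a_i exp(-b_i s^2) + c.
# Species keys carry the formal charge ("O1-", "Fe3+").
.xrayFFTable <- list(
  "H"    = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
                b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305, Z = 1),
  "C"    = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
                b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600, Z = 6),
  "O"    = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
                b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800, Z = 8),
  "O1-"  = list(a = c(4.19160, 1.63969, 1.52673, -20.3070),
                b = c(12.8573, 4.17236, 47.0179, -0.01404), c = 21.9412, Z = 8),
  "Fe"   = list(a = c(11.7695, 7.35730, 3.52220, 2.30450),
                b = c(4.76110, 0.307200, 15.3535, 76.8805), c = 1.03690, Z = 26),
  "Fe2+" = list(a = c(11.0424, 7.37400, 4.13460, 0.439900),
                b = c(4.65380, 0.305300, 12.0546, 31.2809), c = 1.00970, Z = 26),
  "Fe3+" = list(a = c(11.1764, 7.38630, 3.39480, 0.072400),
                b = c(4.61470, 0.300500, 11.6729, 38.5566), c = 0.970700, Z = 26)
)

# Independent 5-Gaussian parametrization of neutral-atom *electron*
# scattering factors (Peng-style tabulation, in Angstrom). Used only as an
# external reference in validation; the working electron factors of the
# package are derived from the X-ray table through the Mott-Bethe relation.
.electronFFReference <- list(
  "H"  = list(a = c(0.0349, 0.1201, 0.1970, 0.0573, 0.1195),
              b = c(0.5347, 3.5867, 12.3471, 18.9525, 38.6269)),
  "C"  = list(a = c(0.0893, 0.2563, 0.7570, 1.0487, 0.3575),
              b = c(0.2465, 1.7100, 6.4094, 18.6113, 50.2523)),
  "O"  = list(a = c(0.0974, 0.2921, 0.6910, 0.6990, 0.2039),
              b = c(0.2067, 1.3815, 4.6943, 12.7105, 32.4726)),
  "Fe" = list(a = c(0.3946, 1.2725, 1.7031, 2.3140, 1.4795),
              b = c(0.2717, 2.0443, 7.6007, 29.9714, 86.2265))
)

.elementZ <- c(H = 1, C = 6, N = 7, O = 8, Fe = 26)

# Single-zeta Slater-type spherical atomic models.  Each shell carries its
# electron count, the orbital principal quantum number n and a single
# orbital exponent zeta (inverse bohr, Clementi-Raimondi-type effective
# exponents).  The shell density is |R_n(r)|^2-shaped: r^(2n-2) exp(-2 zeta r).
# Core/valence split: first-row atoms keep 1s in the core; Fe keeps the Ar
# core plus the frozen 4s^2, so its refinable valence is 3d^6.
.slaterAtoms <- list(
  H = list(core = list(), valence = list(list(n = 1, zeta = 1.000, ne = 1))),
  C = list(core = list(list(n = 1, zeta = 5.673, ne = 2)),
           valence = list(list(n = 2, zeta = 1.608, ne = 2),
                          list(n = 2, zeta = 1.568, ne = 2))),
  O = list(core = list(list(n = 1, zeta = 7.658, ne = 2)),
           valence = list(list(n = 2, zeta = 2.246, ne = 2),
                          list(n = 2, zeta = 2.227, ne = 4))),
  Fe = list(core = list(list(n = 1, zeta = 25.38, ne = 2),
                        list(n = 2, zeta = 9.17, ne = 2),
                        list(n = 2, zeta = 10.91, ne = 6),
                        list(n = 3, zeta = 4.93, ne = 2),
                        list(n = 3, zeta = 4.26, ne = 6),
                        list(n = 4, zeta = 1.36, ne = 2)),   # frozen 4s^2
            valence = list(list(n = 3, zeta = 3.73, ne = 6)))  # 3d^6
)

# Deformation radial function defaults: R_l(r) = N r^{n_l} exp(-zeta r),
# zeta in inverse bohr, one exponent per element (conventional multipole
# practice), powers n_l for l = 1..4.
.deformationRadialDefaults <- list(
  H  = list(n_l = c(1, 2, 2, 3), zeta = 2.26, l_max = 1),
  C  = list(n_l = c(2, 2, 3, 4), zeta = 3.18, l_max = 3),
  O  = list(n_l = c(2, 2, 3, 4), zeta = 4.50, l_max = 3),
  Fe = list(n_l = c(4, 4, 4, 4), zeta = 7.46, l_max = 4)
)

# Covalent radii (Angstrom) for bond detection.
.covalentRadii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, Fe = 1.32)

# Riding-hydrogen target distances (Angstrom), neutron-derived class values.
.ridingHDistances <- c(C_methyl = 1.077, C_secondary = 1.083, O_hydroxyl = 0.983)

.neutralValence <- c(H = 1, C = 4, O = 6, Fe = 6)  # Fe: refinable 3d^6

#' Atomic number lookup
#' @param element Character vector of element symbols.
#' @return Integer atomic numbers.
#' @export
atomicNumber <- function(element) {
  z <- .elementZ[element]
  if (anyNA(z)) stop("unknown element(s): ", paste(element[is.na(z)], collapse = ", "))
  unname(z)
}
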