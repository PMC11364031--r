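#' @include refine.R multipole-fit.R
NULL

#' Simulation conditions for the synthetic FeAcAc-like crystal
#'
#' Defaults emulate the experimental data envelope of a 3D ED study of
#' tris(acetylacetonato)iron(III): orthorhombic Pbca cell, 0.85 Angstrom
#' resolution, 92 percent completeness and a mean I/sigma of 8.4.
#'
#' @param cell Unit cell (default a = 15.35, b = 13.56, c = 16.50).
#' @param dmin,dmax Resolution range in Angstrom (default 0.85 to 8.65).
#' @param completeness Fraction of the unique reflections retained.
#' @param meanIOverSigma Target mean I/sigma of the noisy data.
#' @param shellIOverSigma Target mean I/sigma of the highest-resolution
#'   shell (d below 0.87 Angstrom, or the top 7 percent of reflections
#'   for low-resolution simulations); together with the overall target it
#'   fixes the background floor of the sigma model.
#' @param sigmaG Quadratic term g of the noise model
#'   \eqn{\sigma(F^2) \propto \sqrt{F^2 + g (F^2)^2}}.
#' @param groundTruth "iam" or "taam" scattering truth.
#' @param feCharge Spherical valence charge on Fe of the "taam" truth
#'   (default 0.3; the Bader charge of the resulting density is much
#'   larger, about +1.9, because basin integration of the overlapping
#'   atomic densities concentrates the charge separation).
#' @param seed Integer seed; fully determines the generated data.
#' @return List of class "simulationSpec".
#' @export
simulationSpec <- function(cell = unitCell(15.35, 13.56, 16.50),
                           dmin = 0.85, dmax = 8.65, completeness = 0.92,
                           meanIOverSigma = 8.41, shellIOverSigma = 1.97,
                           sigmaG = 0.02,
                           groundTruth = c("taam", "iam"), feCharge = 0.3,
                           seed = 1L) {
  groundTruth <- match.arg(groundTruth)
  stopifnot(completeness > 0, completeness <= 1)
  structure(list(cell = cell, dmin = dmin, dmax = dmax,
                 completeness = completeness,
                 meanIOverSigma = meanIOverSigma,
                 shellIOverSigma = shellIOverSigma, sigmaG = sigmaG,
                 groundTruth = groundTruth, feCharge = feCharge,
                 seed = as.integer(seed)), class = "simulationSpec")
}

# idealized tris(acetylacetonato)iron(III) molecule, Cartesian Angstrom,
# Fe at the origin.  Bond lengths: Fe-O 1.99, O-C 1.28, C-C(ring) 1.40,
# C-CH3 1.50, C-H 1.083/1.077; O-Fe-O bite angle 87.3 deg.
.feacacTemplate <- function(torsions = .placementDefaults$torsions) {
  bite <- 87.3 * pi / 180
  feo <- 1.99; oc <- 1.28; cc <- 1.40; cme <- 1.50
  hB <- .ridingHDistances[["C_secondary"]]; hMe <- .ridingHDistances[["C_methyl"]]
  O1 <- feo * c(cos(bite / 2), sin(bite / 2), 0)
  # carbonyl C: Fe-O-C angle 129 deg, in-plane, on the ring side
  uOFe <- -O1 / feo
  ang <- 129 * pi / 180
  rot2 <- function(v, t) c(cos(t) * v[1] - sin(t) * v[2],
                           sin(t) * v[1] + cos(t) * v[2], 0)
  C2a <- O1 + oc * rot2(uOFe, ang)
  C2b <- O1 + oc * rot2(uOFe, -ang)
  C2 <- if (C2a[1] > C2b[1]) C2a else C2b
  C3 <- c(C2[1] + sqrt(max(cc^2 - C2[2]^2, 0.1)), 0, 0)  # methine, on axis
  dirMe <- (C2 - O1) / oc + (C2 - C3) / sqrt(sum((C2 - C3)^2))
  dirMe <- dirMe / sqrt(sum(dirMe^2))
  C5 <- C2 + cme * dirMe
  H3 <- C3 + hB * c(1, 0, 0)
  tetra <- function(cM, cParent, dch, phi0) {
    w <- (cM - cParent); w <- w / sqrt(sum(w^2))
    p <- c(-w[2], w[1], 0)
    if (sqrt(sum(p^2)) < 1e-6) p <- c(1, 0, 0)
    p <- p / sqrt(sum(p^2))
    q <- c(w[2] * p[3] - w[3] * p[2], w[3] * p[1] - w[1] * p[3],
           w[1] * p[2] - w[2] * p[1])
    t(sapply(phi0 + c(0, 2 * pi / 3, 4 * pi / 3), function(phi)
      cM + dch * (w / 3 + sqrt(8) / 3 * (cos(phi) * p + sin(phi) * q))))
  }
  mirror <- function(v) c(v[1], -v[2], v[3])
  ligand <- function(phiA, phiB) {
    rbind(O1, C2, C5, tetra(C5, C2, hMe, phiA),
          C3, H3,
          mirror(O1), mirror(C2), mirror(C5),
          t(apply(tetra(C5, C2, hMe, phiB), 1, mirror)))
  }
  kinds <- c("O", "Ccarbonyl", "Cmethyl", "Hme", "Hme", "Hme",
             "Cmethine", "Hme2",
             "O", "Ccarbonyl", "Cmethyl", "Hme", "Hme", "Hme")
  # three ligand frames: chelate pairs on octahedral axes
  pairs <- list(list(e1 = c(1, 0, 0), e2 = c(0, 1, 0)),
                list(e1 = c(0, 0, 1), e2 = c(-1, 0, 0)),
                list(e1 = c(0, -1, 0), e2 = c(0, 0, -1)))
  atoms <- data.frame(element = "Fe", kind = "Fe", x = 0, y = 0, z = 0)
  for (ip in seq_along(pairs)) {
    pp <- pairs[[ip]]
    lig <- ligand(torsions[2 * ip - 1], torsions[2 * ip])
    u <- (pp$e1 + pp$e2) / sqrt(2)
    v <- (pp$e2 - pp$e1) / sqrt(2)
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    M <- cbind(u, v, w)
    xyz <- lig %*% t(M)
    el <- sub("^(O|C|H).*", "\\1", kinds)
    atoms <- rbind(atoms, data.frame(element = el, kind = kinds,
                                     x = xyz[, 1], y = xyz[, 2],
                                     z = xyz[, 3]))
  }
  atoms$label <- paste0(atoms$element,
                        stats::ave(seq_len(nrow(atoms)), atoms$element,
                                   FUN = seq_along))
  rownames(atoms) <- NULL
  atoms
}

# molecular placement in the Pbca cell (fractional Fe position and
# orientation, fixed constants chosen for clash-free packing)
.placementDefaults <- list(
  feFrac = c(0.35564538, 0.42841853, 0.33462185),
  euler = c(1.71320307, 2.84703259, 0.54367146),
  torsions = c(0.89013685, 0.17776438, 0.02303861, 1.10425433, 0.48063658,
               0.38695653))

.eulerMatrix <- function(e) {
  cz <- cos(e[1]); sz <- sin(e[1]); cy <- cos(e[2]); sy <- sin(e[2])
  cx <- cos(e[3]); sx <- sin(e[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Generate the synthetic FeAcAc-like crystal structure
#'
#' Builds an idealized tris-chelate molecule (FeC15H21O6, 43 atoms),
#' places it in the Pbca cell at a packing-optimized position, and
#' assigns anisotropic displacement parameters whose magnitude grows away
#' from the metal and whose principal axes are tied to the Fe-atom
#' direction, so displacement-ellipsoid diagnostics are exercised.
#'
#' @param spec A \code{\link{simulationSpec}}.
#' @return A \code{CrystalStructure} (asymmetric unit; Z = 8 under Pbca).
#' @export
makeStructure <- function(spec = simulationSpec()) {
  tpl <- .feacacTemplate()
  R <- .eulerMatrix(.placementDefaults$euler)
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(R)
  M <- orthoMatrix(spec$cell)
  frac <- sweep(xyz %*% t(solve(M)), 2, .placementDefaults$feFrac, `+`)
  n <- nrow(tpl)
  rFe <- sqrt(rowSums(xyz^2))
  sites <- data.frame(label = tpl$label, element = tpl$element,
                      x = frac[, 1], y = frac[, 2], z = frac[, 3],
                      occ = 1, adpType = ifelse(tpl$element == "H",
                                                "iso", "aniso"),
                      uiso = 0, u11 = NA_real_, u22 = NA_real_,
                      u33 = NA_real_, u12 = NA_real_, u13 = NA_real_,
                      u23 = NA_real_, partId = ifelse(tpl$element == "Fe",
                                                      1L, 2L),
                      scattererRef = tpl$element)
  for (i in seq_len(n)) {
    if (sites$adpType[i] != "aniso") next
    ueq <- 0.020 + 0.004 * rFe[i]
    aniso <- 1 + 0.35 * rFe[i] / max(rFe)   # outer atoms more anisotropic
    zdir <- if (rFe[i] > 1e-6) xyz[i, ] / rFe[i] else c(0, 0, 1)
    xref <- if (abs(zdir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    xdir <- xref - sum(xref * zdir) * zdir
    xdir <- xdir / sqrt(sum(xdir^2))
    ydir <- c(zdir[2] * xdir[3] - zdir[3] * xdir[2],
              zdir[3] * xdir[1] - zdir[1] * xdir[3],
              zdir[1] * xdir[2] - zdir[2] * xdir[1])
    Rloc <- cbind(xdir, ydir, zdir)
    evals <- ueq * c(aniso, 1, 2 - aniso) / mean(c(aniso, 1, 2 - aniso))
    Uc <- Rloc %*% diag(evals) %*% t(Rloc)
    # orthorhombic cell: the CIF U_ij tensor equals the Cartesian tensor
    sites[i, c("u11", "u22", "u33", "u12", "u13", "u23")] <-
      c(Uc[1, 1], Uc[2, 2], Uc[3, 3], Uc[1, 2], Uc[1, 3], Uc[2, 3])
  }
  st <- crystalStructure(spec$cell, spaceGroup("Pbca"), sites)
  # riding-style H isotropic ADPs from the parent U_eq
  rid <- .ridingTable(st)
  for (r in seq_len(nrow(rid))) {
    ueqP <- .uEq(spec$cell, as.numeric(
      st@sites[rid$parent[r], c("u11", "u22", "u33", "u12", "u13", "u23")]))
    st@sites$uiso[rid$h[r]] <- rid$factor[r] * ueqP
  }
  st
}

#' Ground-truth aspherical pseudoatom models of the synthetic crystal
#'
#' Generator constants of the "taam" truth: a partial charge on Fe (well
#' below the formal +3), strongly negative carbonyl oxygens balanced by
#' positive carbonyl carbons, weakly charged methyl/methine carbons and
#' hydrogens, and low-order deformation multipoles concentrated on the
#' organic ligand.
#'
#' @param structure The synthetic \code{CrystalStructure} from
#'   \code{\link{makeStructure}}.
#' @param feCharge Spherical valence charge of Fe (default 1.7).
#' @return Named list of \code{MultipoleAtomModel} per atom label.
#' @export
truthModels <- function(structure, feCharge = 0.3) {
  st <- structure@sites
  M <- orthoMatrix(structure@cell)
  xyz <- as.matrix(st[, c("x", "y", "z")]) %*% t(M)
  atoms <- data.frame(label = st$label, element = st$element,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  bonds <- detectBonds(atoms)
  neighborsOf <- function(i) c(bonds[bonds[, 1] == i, 2],
                               bonds[bonds[, 2] == i, 1])
  nH <- sum(st$element == "H")
  qH <- 0.03
  qCcarb <- 0.25; qCmethine <- -0.10; qCmethyl <- 0
  qO <- -(feCharge + nH * qH + 6 * qCcarb + 3 * qCmethine) / 6
  out <- list()
  for (i in seq_len(nrow(st))) {
    el <- st$element[i]
    axes <- localAxesFromNeighbors(atoms, bonds, i)
    mdl <- switch(el,
      Fe = multipoleAtomModel("Fe", Pval = 6 - feCharge, kappa = 1.05,
                              localAxes = axes),
      O = multipoleAtomModel("O", Pval = 6 - qO, kappa = 0.97,
                             kappaPrime = 1.0,
                             Plm = list(c(0, 0.06, 0),
                                        c(0, 0, 0.09, 0, 0)),
                             localAxes = axes),
      H = multipoleAtomModel("H", Pval = 1 - qH, kappa = 1.15,
                             Plm = list(c(0, 0.10, 0)), localAxes = axes),
      C = {
        nbEl <- st$element[neighborsOf(i)]
        q <- if ("O" %in% nbEl) qCcarb
             else if (sum(nbEl == "H") >= 3) qCmethyl else qCmethine
        Plm <- if (q == qCcarb)
          list(c(0, 0.05, 0), c(0, 0, 0.06, 0, 0),
               c(0, 0, 0, 0.04, 0, 0, 0))
        else list(c(0, 0.04, 0), c(0, 0, 0.04, 0, 0))
        multipoleAtomModel("C", Pval = 4 - q, kappa = 0.99, Plm = Plm,
                           localAxes = axes)
      })
    out[[as.character(st$label[i])]] <- mdl
  }
  out
}

# Two-point calibrated sigma model:
#   sigma(F^2) = scl * sqrt(bg + F^2 + g (F^2)^2)
# The background term bg (detector/background noise floor) and the scale
# are solved so the overall mean I/sigma hits the declared target and the
# highest-resolution shell hits its (much lower) declared target,
# emulating the signal decay of real tilt-series data.  Without the
# floor, the weakest reflections would get near-zero sigma and unbounded
# weights.
.sigmaModel <- function(f2, d, spec) {
  f2p <- pmax(f2, 0)
  shell <- d <= max(0.87, stats::quantile(d, 0.07))
  base <- function(bg) sqrt(bg + f2p + spec$sigmaG * f2p^2)
  scl <- function(bg) mean(f2 / base(bg)) / spec$meanIOverSigma
  shellMiss <- function(bg)
    mean(f2[shell] / base(bg)[shell]) / scl(bg) - spec$shellIOverSigma
  hi <- 1e6 * stats::median(f2p) + 1
  bg <- if (shellMiss(0) <= 0 || shellMiss(hi) >= 0) {
    # shell target unreachable (e.g. truncated low-resolution runs):
    # fall back to a modest noise floor
    0.05 * stats::median(f2p)
  } else stats::uniroot(shellMiss, c(0, hi), tol = 1e-10)$root
  if (bg <= 0) bg <- 0.01 * stats::median(f2p)
  base(bg) * scl(bg)
}

#' Simulate a reflection data set from a ground-truth model
#'
#' Computes kinematical electron intensities under the chosen truth
#' ("iam" neutral factors or the aspherical "taam" models), adds Gaussian
#' noise from the declared sigma model scaled to the target mean I/sigma,
#' and randomly deletes reflections down to the completeness target.
#' Fully reproducible from the spec's seed.
#'
#' @param structure The synthetic \code{CrystalStructure}.
#' @param spec A \code{\link{simulationSpec}}.
#' @param models Optional truth models (built from \code{feCharge} if
#'   omitted and the truth is "taam").
#' @param noise Noise scale multiplier (0 gives exact intensities).
#' @return List with \code{reflections} (a \code{ReflectionSet}),
#'   \code{fcalc2} (noise-free intensities of the kept reflections),
#'   \code{provider} (the truth scatterer provider) and \code{seed}.
#' @export
simulateReflections <- function(structure, spec = simulationSpec(),
                                models = NULL, noise = 1) {
  if (spec$dmin < 0.4)
    stop("dmin below the supported form-factor range (0.4 Angstrom)")
  set.seed(spec$seed)
  hkl <- uniqueReflections(spec$cell, spec$dmin, spec$dmax)
  provider <- if (spec$groundTruth == "iam") {
    iamProvider(structure, "electron")
  } else {
    if (is.null(models)) models <- truthModels(structure, spec$feCharge)
    prov <- models[as.character(structure@sites$label)]
    names(prov) <- structure@sites$label
    prov
  }
  st2 <- structure
  if (spec$groundTruth == "taam")
    st2@sites$scattererRef <- st2@sites$label
  Fc <- calcStructureFactors(st2, hkl, provider, "electron")
  f2 <- Mod(Fc)^2
  keep <- f2 > 1e-10 * max(f2)   # drop systematic absences as unmeasured
  hkl <- hkl[keep, , drop = FALSE]; f2 <- f2[keep]
  sig <- .sigmaModel(f2, dSpacing(spec$cell, hkl), spec)
  fobs2 <- f2 + noise * stats::rnorm(length(f2), 0, sig)
  sel <- sample.int(length(f2), round(spec$completeness * length(f2)))
  sel <- sort(sel)
  list(reflections = reflectionSet(hkl[sel, , drop = FALSE], fobs2[sel],
                                   sig[sel], spec$cell),
       fcalc2 = f2[sel], provider = provider, truthStructure = st2,
       seed = spec$seed)
}

#' Benchmark pair: aspherical-truth data plus a perturbed starting model
#'
#' Simulates data under the aspherical ("taam") truth and returns a
#' perturbed independent-atom starting model, so that refining the same
#' data with IAM versus matched aspherical factors reproduces the
#' characteristic R1 ordering and its low-resolution concentration.
#'
#' @param spec A \code{\link{simulationSpec}} (groundTruth is forced to
#'   "taam").
#' @param coordPerturbation Cartesian sigma of the coordinate perturbation
#'   in Angstrom (default 0.02).
#' @return List with \code{data} (simulation output), \code{startModel}
#'   (perturbed \code{CrystalStructure}), \code{truth} (the exact
#'   structure) and \code{truthModels}.
#' @export
makeBenchmarkPair <- function(spec = simulationSpec(),
                              coordPerturbation = 0.02) {
  spec$groundTruth <- "taam"
  truth <- makeStructure(spec)
  models <- truthModels(truth, spec$feCharge)
  sim <- simulateReflections(truth, spec, models = models)
  set.seed(spec$seed + 1000003L)
  start <- truth
  st <- start@sites
  nonH <- st$element != "H"
  M <- orthoMatrix(spec$cell)
  dx <- matrix(stats::rnorm(3 * sum(nonH), 0, coordPerturbation),
               ncol = 3) %*% t(solve(M))
  st[nonH, c("x", "y", "z")] <- st[nonH, c("x", "y", "z")] + dx
  ridge <- .ridingTable(start)
  for (r in seq_len(nrow(ridge)))   # hydrogens follow their parent
    st[ridge$h[r], c("x", "y", "z")] <-
      st[ridge$h[r], c("x", "y", "z")] +
      st[ridge$parent[r], c("x", "y", "z")] -
      start@sites[ridge$parent[r], c("x", "y", "z")]
  ucols <- c("u11", "u22", "u33")
  st[nonH, ucols] <- st[nonH, ucols] *
    (1 + matrix(stats::rnorm(3 * sum(nonH), 0, 0.05), ncol = 3))
  start@sites <- st
  list(data = sim, startModel = start, truth = truth,
       truthModels = models)
}

#' Minimum intermolecular contact distance
#'
#' Brute-force scan over symmetry mates and neighbouring cells.
#'
#' @param structure A \code{CrystalStructure}.
#' @return Minimum distance (Angstrom) between atoms of different
#'   molecules.
#' @export
minIntermolecularContact <- function(structure) {
  M <- orthoMatrix(structure@cell)
  asu <- as.matrix(structure@sites[, c("x", "y", "z")]) %% 1
  ex <- expandSymmetry(structure, wrap = TRUE)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- Inf
  for (io in unique(ex$op)) {
    mate <- as.matrix(ex[ex$op == io, c("x", "y", "z")])
    for (r in seq_len(nrow(shifts))) {
      if (io == 1 && all(shifts[r, ] == 0)) next
      mxyz <- sweep(mate, 2, shifts[r, ], `+`) %*% t(M)
      axyz <- asu %*% t(M)
      dd <- sqrt(outer(rowSums(axyz^2), rowSums(mxyz^2), `+`) -
                   2 * axyz %*% t(mxyz))
      best <- min(best, min(dd, na.rm = TRUE))
    }
  }
  best
}
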