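#' @include structure-factors.R statistics.R
NULL

#' Local pseudoatom axes from bonded neighbours
#'
#' Deterministic right-handed frame: local z points to the
#' highest-priority bonded neighbour (priority: larger atomic number,
#' then shorter bond), local x is the orthogonalized direction to the
#' next neighbour (or an arbitrary perpendicular for terminal atoms).
#'
#' @param atoms Data frame with element, x, y, z (Cartesian Angstrom).
#' @param bonds Bond index matrix from \code{\link{detectBonds}}.
#' @param i Atom index.
#' @return 3x3 rotation matrix (columns = local x, y, z in global frame).
#' @export
localAxesFromNeighbors <- function(atoms, bonds, i) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
  if (length(nb) == 0) return(diag(3))
  d <- sqrt(rowSums((xyz[nb, , drop = FALSE] -
                       matrix(xyz[i, ], length(nb), 3, byrow = TRUE))^2))
  pr <- order(-atomicNumber(atoms$element[nb]), d)
  nb <- nb[pr]; d <- d[pr]
  z <- (xyz[nb[1], ] - xyz[i, ]); z <- z / sqrt(sum(z^2))
  xref <- if (length(nb) >= 2) xyz[nb[2], ] - xyz[i, ]
          else if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- xref - sum(xref * z) * z
  if (sqrt(sum(x^2)) < 1e-8) x <- c(z[2], -z[1], 0)
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

#' Static structure factors of an isolated molecule in a box
#'
#' Places the molecule in an artificial cubic P1 cell and computes static
#' (zero-ADP) X-ray structure factors from pseudoatom models, the form
#' used for refining multipolar parameters against wavefunction-derived
#' structure factors.
#'
#' @param atoms Data frame with label, element, x, y, z (Cartesian
#'   Angstrom; the molecule is recentred in the box).
#' @param models Named list of \code{MultipoleAtomModel} per atom label.
#' @param boxLength Cubic cell edge in Angstrom (default 30).
#' @param dmin Resolution limit of the generated index sphere.
#' @param valenceOnly Drop the frozen-core contribution (core populations
#'   set to zero), giving valence-only structure factors.
#' @return List with hkl, f (complex), cell (a \code{UnitCell}),
#'   structure (the boxed P1 \code{CrystalStructure}) and valenceOnly.
#' @export
theoreticalStructureFactors <- function(atoms, models, boxLength = 30,
                                        dmin = 1.0, valenceOnly = FALSE) {
  cell <- unitCell(boxLength, boxLength, boxLength)
  ctr <- colMeans(atoms[, c("x", "y", "z")])
  frac <- sweep(as.matrix(atoms[, c("x", "y", "z")]), 2, ctr) / boxLength + 0.5
  sites <- data.frame(label = atoms$label, element = atoms$element,
                      x = frac[, 1], y = frac[, 2], z = frac[, 3],
                      scattererRef = atoms$label)
  st <- crystalStructure(cell, spaceGroup("P1"), sites)
  if (valenceOnly)
    models <- lapply(models, function(m) { m@Pcore <- 0; m })
  hkl <- uniqueReflections(cell, dmin, laue = "-1")
  f <- calcStructureFactors(st, hkl, models[as.character(atoms$label)],
                            radiation = "xray")
  list(hkl = hkl, f = f, cell = cell, structure = st,
       valenceOnly = valenceOnly)
}

# pack/unpack multipole parameters according to flags
.mpLayout <- function(models, flags) {
  lay <- list(); np <- 0
  for (nm in names(models)) {
    m <- models[[nm]]
    ent <- list()
    if (isTRUE(flags$Pval)) { ent$Pval <- np + 1; np <- np + 1 }
    if (isTRUE(flags$kappa)) { ent$kappa <- np + 1; np <- np + 1 }
    if (isTRUE(flags$Plm) && length(m@Plm) > 0) {
      nlm <- sum(vapply(m@Plm, length, integer(1)))
      ent$Plm <- np + seq_len(nlm); np <- np + nlm
    }
    lay[[nm]] <- ent
  }
  attr(lay, "np") <- np
  lay
}

.mpApply <- function(models, lay, par) {
  for (nm in names(lay)) {
    ent <- lay[[nm]]; m <- models[[nm]]
    if (!is.null(ent$Pval)) m@Pval <- par[ent$Pval]
    if (!is.null(ent$kappa)) m@kappa <- max(par[ent$kappa], 0.05)
    if (!is.null(ent$Plm)) {
      v <- par[ent$Plm]; off <- 0
      for (l in seq_along(m@Plm)) {
        m@Plm[[l]] <- v[off + seq_len(2 * l + 1)]
        off <- off + 2 * l + 1
      }
    }
    models[[nm]] <- m
  }
  models
}

.mpExtract <- function(models, lay) {
  par <- numeric(attr(lay, "np"))
  for (nm in names(lay)) {
    ent <- lay[[nm]]; m <- models[[nm]]
    if (!is.null(ent$Pval)) par[ent$Pval] <- m@Pval
    if (!is.null(ent$kappa)) par[ent$kappa] <- m@kappa
    if (!is.null(ent$Plm))
      par[ent$Plm] <- unlist(m@Plm)
  }
  par
}

#' Refine Hansen-Coppens multipole parameters against structure factors
#'
#' Least-squares fit of static pseudoatom structure-factor amplitudes to a
#' target set (typically wavefunction-derived), refining the selected
#' subset of P_val, kappa and P_lm per atom.  The agreement statistic is
#' \eqn{R = \sum ||F_t| - |F_m|| / \sum |F_t|}.
#'
#' @param models Named starting \code{MultipoleAtomModel} list (names =
#'   atom labels).
#' @param sf Target list as returned by
#'   \code{\link{theoreticalStructureFactors}}: hkl, f, cell, structure.
#'   When the target is valence-only the starting models' cores are
#'   dropped to match.
#' @param flags List with logicals Pval, kappa, Plm selecting the free
#'   parameter classes (default: all TRUE).
#' @param maxIter Iteration cap.
#' @return List with \code{models} (refined), \code{R}, \code{converged},
#'   and \code{parameters} (the packed parameter vector).
#' @export
refineMultipoles <- function(models, sf, flags = list(Pval = TRUE,
                                                      kappa = TRUE,
                                                      Plm = TRUE),
                             maxIter = 100) {
  st <- sf$structure@sites
  models <- models[as.character(st$label)]
  if (isTRUE(sf$valenceOnly))
    models <- lapply(models, function(m) { m@Pcore <- 0; m })
  lay <- .mpLayout(models, flags)
  np <- attr(lay, "np")
  if (np == 0) stop("no free parameters selected")
  if (np >= 2 * length(sf$f)) stop("underdetermined multipole refinement")
  hcart <- reciprocalVectors(sf$cell, sf$hkl)
  phases <- exp(2i * pi * (sf$hkl %*% t(as.matrix(st[, c("x", "y", "z")]))))
  ftarget <- Mod(sf$f)
  calcF <- function(mods) {
    F <- complex(length(sf$f))
    for (j in seq_len(nrow(st)))
      F <- F + phases[, j] * hcFormFactor(mods[[j]], hcart, "xray")
    F
  }
  residFn <- function(par) {
    mods <- .mpApply(models, lay, par)
    Mod(calcF(mods)) - ftarget
  }
  par0 <- .mpExtract(models, lay)
  J0 <- NULL
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = par0, fn = residFn,
    control = minpack.lm::nls.lm.control(maxiter = maxIter, ftol = 1e-12,
                                         ptol = 1e-12)))
  refined <- .mpApply(models, lay, fit$par)
  Fm <- calcF(refined)
  R <- sum(abs(ftarget - Mod(Fm))) / sum(ftarget)
  list(models = refined, R = R, converged = fit$info %in% 1:4,
       parameters = fit$par, layout = lay)
}

#' Assign chemical atom types from the molecular graph
#'
#' Two-shell connectivity signature: an atom's type is its element plus
#' the sorted multiset of (neighbour element + that neighbour's sorted
#' bonded elements).  Chemically equivalent atoms (the six carbonyl O of a
#' tris-acetylacetonate, the methyl versus methine hydrogens) receive
#' identical keys; disconnected atoms become singleton types with a
#' warning.
#'
#' @param atoms Data frame with element, x, y, z (Cartesian Angstrom).
#' @param bonds Optional precomputed bond matrix.
#' @return Character vector of type keys, one per atom.
#' @export
assignAtomTypes <- function(atoms, bonds = NULL) {
  if (is.null(bonds)) bonds <- detectBonds(atoms)
  nb <- lapply(seq_len(nrow(atoms)), function(i)
    sort(c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])))
  shell1 <- vapply(seq_len(nrow(atoms)), function(i)
    paste0(atoms$element[i], "(",
           paste(sort(atoms$element[nb[[i]]]), collapse = ""), ")"),
    character(1))
  keys <- vapply(seq_len(nrow(atoms)), function(i) {
    if (length(nb[[i]]) == 0) return(paste0(atoms$element[i], "[isolated]"))
    paste0(atoms$element[i], "[",
           paste(sort(shell1[nb[[i]]]), collapse = ""), "]")
  }, character(1))
  if (any(grepl("\\[isolated\\]", keys)))
    warning("disconnected atom(s) assigned singleton types")
  keys
}

#' Build a transferable multipole databank by atom-type averaging
#'
#' Arithmetic per-type mean of P_val, kappa, kappa' and the frame-aligned
#' P_lm populations (models are assumed to carry their P_lm in local axes
#' built by the same neighbour-priority rule, so direct averaging is
#' frame-consistent).
#'
#' @param models Named list of refined \code{MultipoleAtomModel}s.
#' @param typeKeys Character vector of type keys aligned with
#'   \code{models}.
#' @return A list of class "multipoleDatabank" keyed by type.
#' @export
buildDatabank <- function(models, typeKeys) {
  stopifnot(length(models) == length(typeKeys))
  bank <- list()
  for (key in unique(typeKeys)) {
    grp <- models[typeKeys == key]
    m0 <- grp[[1]]
    entry <- list(element = m0@element,
                  Pval = mean(vapply(grp, function(m) m@Pval, numeric(1))),
                  kappa = mean(vapply(grp, function(m) m@kappa, numeric(1))),
                  kappaPrime = mean(vapply(grp, function(m) m@kappaPrime,
                                           numeric(1))),
                  Plm = if (length(m0@Plm) == 0) list() else
                    lapply(seq_along(m0@Plm), function(l)
                      Reduce(`+`, lapply(grp, function(m) m@Plm[[l]])) /
                        length(grp)),
                  nExemplars = length(grp))
    bank[[key]] <- entry
  }
  structure(bank, class = "multipoleDatabank")
}

#' Apply a multipole databank to a molecule
#'
#' Matches each atom's connectivity type against the databank and
#' instantiates pseudoatom models with geometry-derived local axes.
#' Unmatched atoms fall back to the spherical neutral model (the hybrid
#' treatment used when a databank lacks parameters for, e.g., a
#' coordinated metal) unless \code{fallback = FALSE}.
#'
#' @param bank A databank from \code{\link{buildDatabank}}.
#' @param atoms Data frame with label, element, x, y, z (Cartesian
#'   Angstrom).
#' @param fallback Use spherical neutral models for unmatched types.
#' @return Named list of \code{MultipoleAtomModel}s.
#' @export
applyDatabank <- function(bank, atoms, fallback = TRUE) {
  bonds <- detectBonds(atoms)
  keys <- assignAtomTypes(atoms, bonds)
  out <- list()
  for (i in seq_len(nrow(atoms))) {
    entry <- bank[[keys[i]]]
    if (is.null(entry)) {
      if (!fallback)
        stop("no databank entry for type ", keys[i], " (atom ",
             atoms$label[i], ")")
      out[[as.character(atoms$label[i])]] <- neutralAtomModel(atoms$element[i])
    } else {
      out[[as.character(atoms$label[i])]] <- multipoleAtomModel(
        element = entry$element, Pval = entry$Pval, kappa = entry$kappa,
        kappaPrime = entry$kappaPrime, Plm = entry$Plm,
        localAxes = localAxesFromNeighbors(atoms, bonds, i))
    }
  }
  out
}

#' Serialize a multipole databank to JSON
#' @param bank A databank from \code{\link{buildDatabank}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeDatabank <- function(bank, path) {
  jsonlite::write_json(unclass(bank), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a multipole databank from JSON
#' @param path File path.
#' @return A "multipoleDatabank" list.
#' @export
readDatabank <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  bank <- lapply(raw, function(e) {
    e$Plm <- if (length(e$Plm) == 0) list() else
      lapply(e$Plm, as.numeric)
    e
  })
  structure(bank, class = "multipoleDatabank")
}
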