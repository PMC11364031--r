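#' @include AllGenerics.R
NULL

#' Construct a unit cell
#' @param a,b,c Cell lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return A \code{UnitCell}.
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90)
  new("UnitCell", a = a, b = b, c = c, alpha = alpha, beta = beta,
      gamma = gamma)

#' Orthogonalization matrix of a cell
#'
#' Returns the 3x3 matrix M such that Cartesian coordinates (Angstrom) are
#' \code{M \%*\% x} for fractional \code{x} (standard PDB convention: a
#' along x, b in the xy plane).
#'
#' @param cell A \code{UnitCell}.
#' @return 3x3 numeric matrix.
#' @export
orthoMatrix <- function(cell) {
  p <- cellParameters(cell)
  ca <- cos(p[4:6] * pi / 180); sg <- sin(p[6] * pi / 180)
  v <- sqrt(1 - sum(ca^2) + 2 * prod(ca))
  matrix(c(p[1], p[2] * ca[3], p[3] * ca[2],
           0, p[2] * sg, p[3] * (ca[1] - ca[2] * ca[3]) / sg,
           0, 0, p[3] * v / sg), 3, 3, byrow = TRUE)
}

#' Cell volume in cubic Angstrom
#' @param cell A \code{UnitCell}.
#' @return Numeric volume.
#' @export
cellVolume <- function(cell) det(orthoMatrix(cell))

#' Reciprocal cell lengths
#' @param cell A \code{UnitCell}.
#' @return Numeric vector (a*, b*, c*) in inverse Angstrom.
#' @export
reciprocalLengths <- function(cell) {
  B <- t(solve(orthoMatrix(cell)))  # columns are reciprocal basis vectors
  sqrt(colSums(B^2))
}

#' Resolution of reflections
#'
#' Standard reciprocal-metric d-spacing; \eqn{s = 1/(2d)}.
#'
#' @param cell A \code{UnitCell}.
#' @param hkl Integer matrix (n x 3) or length-3 vector of Miller indices.
#' @return d in Angstrom (Inf for the (0,0,0) entry).
#' @export
dSpacing <- function(cell, hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  B <- t(solve(orthoMatrix(cell)))        # reciprocal basis as columns
  hcart <- hkl %*% t(B)                   # h a* + k b* + l c*, Cartesian
  invd <- sqrt(rowSums(hcart^2))
  ifelse(invd == 0, Inf, 1 / invd)
}

#' Cartesian reciprocal vectors of reflections
#' @param cell A \code{UnitCell}.
#' @param hkl Integer matrix of Miller indices.
#' @return n x 3 matrix with rows of length 1/d (inverse Angstrom).
#' @export
reciprocalVectors <- function(cell, hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  B <- t(solve(orthoMatrix(cell)))
  hkl %*% t(B)
}

# ---- space groups -------------------------------------------------------

.parseSymop <- function(txt) {
  # "x, -y+1/2, z" -> rotation row-matrix + translation
  parts <- strsplit(gsub(" ", "", tolower(txt)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operation: ", txt)
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (i in 1:3) {
    p <- parts[i]
    for (j in 1:3) {
      ax <- c("x", "y", "z")[j]
      if (grepl(paste0("-", ax), p, fixed = TRUE)) R[i, j] <- -1
      else if (grepl(ax, p, fixed = TRUE)) R[i, j] <- 1
      p <- gsub(paste0("[+-]?", ax), "", p)
    }
    if (nchar(p) > 0) {
      if (grepl("/", p)) {
        nm <- as.numeric(strsplit(sub("^\\+", "", p), "/")[[1]])
        t[i] <- nm[1] / nm[2]
      } else t[i] <- as.numeric(p)
    }
  }
  list(R = R, t = t %% 1)
}

.symopString <- function(R, t) {
  ax <- c("x", "y", "z")
  fr <- function(v) {
    if (abs(v) < 1e-8) return("")
    f <- round(v * 12) / 12
    num <- round(f * 12); den <- 12; g <- .gcd(abs(num), den)
    paste0(if (f > 0) "+" else "-", abs(num) / g, "/", den / g)
  }
  vapply(1:3, function(i) {
    term <- ""
    for (j in 1:3) {
      if (R[i, j] == 1) term <- paste0(term, if (nchar(term)) "+" else "", ax[j])
      if (R[i, j] == -1) term <- paste0(term, "-", ax[j])
    }
    paste0(term, fr(t[i]))
  }, character(1)) |> paste(collapse = ", ")
}

.gcd <- function(a, b) if (b == 0) max(a, 1) else .gcd(b, a %% b)

.pbcaOps <- c("x, y, z", "-x+1/2, -y, z+1/2", "-x, y+1/2, -z+1/2",
              "x+1/2, -y+1/2, -z", "-x, -y, -z", "x+1/2, y, -z+1/2",
              "x, -y+1/2, z+1/2", "-x+1/2, y+1/2, z")

#' Construct a space group from operator strings
#'
#' Operator-list support covers the groups exercised by the package (P1,
#' P-1, Pbca and any user-supplied operator list); Hermann-Mauguin symbol
#' parsing is deliberately not implemented.
#'
#' @param symbol Hermann-Mauguin symbol, or one of the built-ins "P1",
#'   "P-1", "Pbca" to use the embedded generator table.
#' @param operations Character vector of "x, y, z"-style operator strings
#'   (ignored for built-ins).
#' @return A \code{SpaceGroup}.
#' @export
spaceGroup <- function(symbol, operations = NULL) {
  if (is.null(operations)) {
    operations <- switch(symbol,
      "P1" = "x, y, z",
      "P-1" = c("x, y, z", "-x, -y, -z"),
      "Pbca" = .pbcaOps,
      stop("no embedded operator table for ", symbol,
           "; supply operator strings"))
  }
  ops <- lapply(operations, .parseSymop)
  rot <- lapply(ops, `[[`, "R"); tra <- lapply(ops, `[[`, "t")
  centro <- any(vapply(rot, function(R) all(R == -diag(3)), logical(1)))
  new("SpaceGroup", symbol = symbol, rotations = rot, translations = tra,
      centrosymmetric = centro)
}

#' Unique reflections to a resolution limit
#'
#' Generates the full index sphere to \code{dmin}, removes (0,0,0) and
#' Friedel/Laue duplicates for the orthorhombic mmm Laue class (indices
#' reduced to non-negative h, k, l), which covers P1 (Friedel pairs only)
#' and Pbca.
#'
#' @param cell A \code{UnitCell}.
#' @param dmin Resolution limit in Angstrom.
#' @param dmax Optional low-resolution cutoff in Angstrom.
#' @param laue "mmm" (default) or "-1".
#' @return Integer matrix of unique hkl.
#' @export
uniqueReflections <- function(cell, dmin, dmax = Inf, laue = c("mmm", "-1")) {
  laue <- match.arg(laue)
  p <- cellParameters(cell)
  hmax <- floor(p[1:3] / dmin)
  g <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3]))
  d <- dSpacing(cell, g)
  g <- g[d >= dmin & d <= dmax & is.finite(d), , drop = FALSE]
  if (laue == "mmm") {
    g <- g[g[, 1] >= 0 & g[, 2] >= 0 & g[, 3] >= 0, , drop = FALSE]
  } else {
    keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
    g <- g[keep, , drop = FALSE]
  }
  g[order(-dSpacing(cell, g)), , drop = FALSE]
}

#' Construct a reflection set
#'
#' Duplicate indices are merged by inverse-variance averaging with a
#' warning (input data are normally assumed pre-merged).
#'
#' @param hkl Integer matrix of Miller indices.
#' @param fobs2 Observed intensities (F squared; negative values are kept).
#' @param sigma Positive standard uncertainties.
#' @param cell A \code{UnitCell} used to derive resolutions.
#' @return A \code{ReflectionSet}.
#' @export
reflectionSet <- function(hkl, fobs2, sigma, cell) {
  hkl <- as.matrix(hkl); storage.mode(hkl) <- "integer"
  dimnames(hkl) <- NULL
  if (any(sigma <= 0)) stop("all sigma must be positive")
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) {
    warning("duplicate reflections merged by inverse-variance averaging")
    w <- 1 / sigma^2
    fobs2 <- tapply(w * fobs2, key, sum) / tapply(w, key, sum)
    sigma <- sqrt(1 / tapply(w, key, sum))
    u <- !duplicated(key)
    hkl <- hkl[u, , drop = FALSE]
    ord <- match(paste(hkl[, 1], hkl[, 2], hkl[, 3]), names(fobs2))
    fobs2 <- as.numeric(fobs2[ord]); sigma <- as.numeric(sigma[ord])
  }
  new("ReflectionSet", hkl = hkl, fobs2 = as.numeric(fobs2),
      sigma = as.numeric(sigma), d = dSpacing(cell, hkl))
}

#' Construct a crystal structure
#'
#' @param cell A \code{UnitCell}.
#' @param spaceGroup A \code{SpaceGroup}.
#' @param sites Atom-site data frame; missing optional columns (occ,
#'   adpType, uiso, u11..u23, partId, scattererRef) are filled with
#'   defaults.
#' @return A \code{CrystalStructure}.
#' @export
crystalStructure <- function(cell, spaceGroup, sites) {
  defaults <- list(occ = 1, adpType = "iso", uiso = 0, u11 = NA_real_,
                   u22 = NA_real_, u33 = NA_real_, u12 = NA_real_,
                   u13 = NA_real_, u23 = NA_real_, partId = 1L,
                   scattererRef = NA_character_)
  for (nm in names(defaults))
    if (!nm %in% colnames(sites)) sites[[nm]] <- defaults[[nm]]
  sites$scattererRef <- ifelse(is.na(sites$scattererRef), sites$element,
                               sites$scattererRef)
  new("CrystalStructure", cell = cell, spaceGroup = spaceGroup,
      sites = sites[, .siteColumns])
}

#' Symmetry-expanded atom positions
#'
#' Applies all symmetry operations to the asymmetric unit.
#'
#' @param structure A \code{CrystalStructure}.
#' @param wrap Reduce positions into [0, 1).
#' @return Data frame with label, element, op index and fractional x, y, z.
#' @export
expandSymmetry <- function(structure, wrap = TRUE) {
  st <- structure@sites
  ops <- symmetryOperations(structure)
  out <- do.call(rbind, lapply(seq_along(ops$rotations), function(i) {
    xyz <- as.matrix(st[, c("x", "y", "z")]) %*% t(ops$rotations[[i]])
    xyz <- sweep(xyz, 2, ops$translations[[i]], `+`)
    if (wrap) xyz <- xyz %% 1
    data.frame(label = st$label, element = st$element, op = i,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  rownames(out) <- NULL
  out
}
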