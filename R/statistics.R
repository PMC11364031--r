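#' @include cell-symmetry.R
NULL

#' Refinement weighting scheme
#'
#' \deqn{w = 1 / [\sigma^2(F_o^2) + (aP)^2 + bP], \quad
#'   P = (\max(F_o^2, 0) + 2 F_c^2)/3.}
#' Negative observed intensities are floored at zero inside P.
#'
#' @param fobs2,sigma Observed intensities and their (positive) s.u.s.
#' @param fcalc2 Model intensities on the observed scale.
#' @param a,b Weighting parameters.
#' @return Numeric weights.
#' @export
refinementWeights <- function(fobs2, sigma, fcalc2, a = 0, b = 0) {
  if (any(sigma <= 0)) stop("all sigma must be positive")
  P <- (pmax(fobs2, 0) + 2 * fcalc2) / 3
  1 / (sigma^2 + (a * P)^2 + b * P)
}

# F and sigma(F) from F^2 by simple truncation:
# F = sqrt(max(F2, 0)), sigma(F) = sigma(F2) / (2 max(F, sigmaF2^(1/2)))
.fFromF2 <- function(f2, sig2) {
  f <- sqrt(pmax(f2, 0))
  sf <- sig2 / (2 * pmax(f, sqrt(sig2)))
  list(f = f, sig = sf)
}

#' Crystallographic agreement factors
#'
#' R1 on |F| over the strong subset (\eqn{F_o > cut\,\sigma(F_o)}) and over
#' all data, and wR2 on F-squared.
#'
#' @param fobs2,sigma Observed intensities and s.u.s.
#' @param fcalc2 Model intensities (unscaled).
#' @param scale Scale k applied as \eqn{F_o^2 \approx k F_c^2}.
#' @param cut Sigma multiple defining the strong subset (default 4).
#' @param weights Optional weights for wR2 (default 1/sigma^2).
#' @return List R1_strong, R1_all, wR2, nStrong, nAll.  R1_strong is NA if
#'   the cut set is empty.
#' @export
rFactors <- function(fobs2, sigma, fcalc2, scale = 1, cut = 4,
                     weights = NULL) {
  stopifnot(length(fobs2) == length(fcalc2))
  if (is.null(weights)) weights <- 1 / sigma^2
  o <- .fFromF2(fobs2, sigma)
  fc <- sqrt(scale) * sqrt(pmax(fcalc2, 0))
  r1 <- function(idx) if (!any(idx)) NA_real_ else
    sum(abs(o$f[idx] - fc[idx])) / sum(o$f[idx])
  strong <- o$f > cut * o$sig
  num <- sum(weights * (fobs2 - scale * fcalc2)^2)
  den <- sum(weights * fobs2^2)
  list(R1_strong = r1(strong), R1_all = r1(rep(TRUE, length(fobs2))),
       wR2 = sqrt(num / den), nStrong = sum(strong), nAll = length(fobs2))
}

#' Goodness of fit
#'
#' \deqn{GooF = \sqrt{\sum w (F_o^2 - k F_c^2)^2 / (n_{obs} - n_{params})}}
#'
#' @param fobs2 Observed intensities.
#' @param fcalc2 Model intensities (unscaled).
#' @param weights Weights.
#' @param nParams Number of refined parameters.
#' @param scale Scale factor k.
#' @return Numeric GooF.
#' @export
goodnessOfFit <- function(fobs2, fcalc2, weights, nParams, scale = 1) {
  n <- length(fobs2)
  if (n <= nParams) stop("degrees of freedom must be positive")
  sqrt(sum(weights * (fobs2 - scale * fcalc2)^2) / (n - nParams))
}

#' Resolution-shell R1 with locked parameters
#'
#' Partitions reflections by resolution and recomputes R1 per shell with
#' the model and global scale frozen.
#'
#' @param refl A \code{ReflectionSet}.
#' @param fcalc2 Model intensities for every reflection (unscaled).
#' @param scale Frozen global scale.
#' @param boundaries Shell boundaries in Angstrom, descending (n+1 values
#'   for n shells).
#' @param cut Sigma multiple for the strong subset.
#' @return Data frame with shell limits, counts and R1 values (strong and
#'   all); empty shells report count 0 and NA.
#' @export
shellR1 <- function(refl, fcalc2, scale, boundaries, cut = 4) {
  stopifnot(all(diff(boundaries) < 0))
  d <- refl@d
  out <- lapply(seq_len(length(boundaries) - 1), function(i) {
    hi <- boundaries[i]; lo <- boundaries[i + 1]
    idx <- d <= hi & d >= lo
    if (i > 1) idx <- d < hi & d >= lo
    if (!any(idx))
      return(data.frame(d_max = hi, d_min = lo, nStrong = 0L, nAll = 0L,
                        R1_strong = NA_real_, R1_all = NA_real_))
    r <- rFactors(refl@fobs2[idx], refl@sigma[idx], fcalc2[idx],
                  scale = scale, cut = cut)
    data.frame(d_max = hi, d_min = lo, nStrong = r$nStrong, nAll = r$nAll,
               R1_strong = r$R1_strong, R1_all = r$R1_all)
  })
  do.call(rbind, out)
}

# Cartesian displacement tensor from CIF U_ij
.uCartesian <- function(cell, u) {
  U <- matrix(c(u[1], u[4], u[5], u[4], u[2], u[6], u[5], u[6], u[3]), 3, 3)
  A <- orthoMatrix(cell)
  N <- diag(reciprocalLengths(cell))
  (A %*% N) %*% U %*% t(A %*% N)
}

#' Displacement ellipsoid axial ratios
#'
#' Ratio of maximum to minimum root-mean-square displacement components
#' (principal-axis analysis of the Cartesian U tensor) per anisotropic
#' atom; non-positive-definite tensors are flagged and excluded from the
#' mean.
#'
#' @param structure A \code{CrystalStructure}.
#' @param selection Optional logical/index vector of sites.
#' @return List with \code{perAtom} data frame (label, ratio, ok) and
#'   \code{mean}.
#' @export
ellipsoidRatios <- function(structure, selection = NULL) {
  st <- structure@sites
  if (!is.null(selection)) st <- st[selection, ]
  st <- st[st$adpType == "aniso", ]
  res <- lapply(seq_len(nrow(st)), function(i) {
    u <- as.numeric(st[i, c("u11", "u22", "u33", "u12", "u13", "u23")])
    ev <- eigen(.uCartesian(structure@cell, u), symmetric = TRUE,
                only.values = TRUE)$values
    ok <- all(ev > 0)
    data.frame(label = st$label[i],
               ratio = if (ok) sqrt(max(ev) / min(ev)) else NA_real_,
               ok = ok)
  })
  perAtom <- do.call(rbind, res)
  list(perAtom = perAtom, mean = mean(perAtom$ratio[perAtom$ok]))
}

#' Detect covalent bonds from interatomic distances
#'
#' Bonds are pairs closer than 1.15 times the sum of covalent radii.
#'
#' @param atoms Data frame with element and Cartesian x, y, z (Angstrom).
#' @return Two-column integer matrix of bonded atom indices.
#' @export
detectBonds <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- .covalentRadii[atoms$element]
  d <- as.matrix(dist(xyz))
  lim <- outer(r, r, `+`) * 1.15
  idx <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

#' Coordinate and bond-length RMSD between two models
#'
#' Atoms are matched by label; fractional coordinates are converted to
#' Cartesian through the first model's cell before comparison.  Bonds are
#' detected in the first model with covalent-radius tolerance.
#'
#' @param modelA,modelB \code{CrystalStructure}s with matching labels.
#' @param heavyOnly Restrict to non-hydrogen atoms (default TRUE).
#' @return List with \code{coordRmsd} and \code{bondRmsd} (Angstrom).
#' @export
rmsdModels <- function(modelA, modelB, heavyOnly = TRUE) {
  sa <- modelA@sites; sb <- modelB@sites
  if (heavyOnly) { sa <- sa[sa$element != "H", ]; sb <- sb[sb$element != "H", ] }
  idx <- match(sa$label, sb$label)
  if (anyNA(idx))
    stop("unmatched atom label(s): ",
         paste(sa$label[is.na(idx)], collapse = ", "))
  sb <- sb[idx, ]
  M <- orthoMatrix(modelA@cell)
  xa <- as.matrix(sa[, c("x", "y", "z")]) %*% t(M)
  xb <- as.matrix(sb[, c("x", "y", "z")]) %*% t(M)
  coordRmsd <- sqrt(mean(rowSums((xa - xb)^2)))
  atoms <- data.frame(element = sa$element, x = xa[, 1], y = xa[, 2],
                      z = xa[, 3])
  bonds <- detectBonds(atoms)
  bondRmsd <- if (nrow(bonds) == 0) NA_real_ else {
    la <- sqrt(rowSums((xa[bonds[, 1], , drop = FALSE] -
                          xa[bonds[, 2], , drop = FALSE])^2))
    lb <- sqrt(rowSums((xb[bonds[, 1], , drop = FALSE] -
                          xb[bonds[, 2], , drop = FALSE])^2))
    sqrt(mean((la - lb)^2))
  }
  list(coordRmsd = coordRmsd, bondRmsd = bondRmsd)
}

#' Optimize the weighting parameters a and b
#'
#' Iteratively adjusts (a, b) so that the goodness of fit is flat and
#' close to 1 across intensity and resolution bins (the criterion used to
#' reach normally distributed residuals), by minimizing
#' \eqn{\sum_{bins} (GooF_{bin}^2 - 1)^2} with box-constrained
#' optimization.
#'
#' @param fobs2,sigma Observed intensities and s.u.s.
#' @param fcalc2 Scaled model intensities.
#' @param nParams Number of refined parameters (degrees-of-freedom
#'   correction applied globally).
#' @param d Optional resolutions for resolution binning.
#' @param nIntensityBins,nResolutionBins Bin counts (default 10 x 5).
#' @param start Starting values for c(a, b).
#' @param aCap Runaway guard: when the optimized a exceeds this value
#'   (which happens for badly fitting models, where no weighting scheme
#'   can normalize the residuals), the optimization is declared failed and
#'   the conventional default (a = 0.2, b = 0) is returned with a
#'   warning.
#' @return List with \code{a}, \code{b}, \code{binTable}, \code{flatness}
#'   (max/min bin GooF) and \code{converged}.
#' @export
optimizeWeights <- function(fobs2, sigma, fcalc2, nParams = 0, d = NULL,
                            nIntensityBins = 10, nResolutionBins = 5,
                            start = c(0.05, 0), aCap = 0.5) {
  n <- length(fobs2)
  dofScale <- n / max(n - nParams, 1)
  ib <- cut(rank(fcalc2, ties.method = "first"), nIntensityBins,
            labels = FALSE)
  bins <- if (!is.null(d)) {
    rb <- cut(rank(d, ties.method = "first"), nResolutionBins,
              labels = FALSE)
    interaction(ib, rb, drop = TRUE)
  } else factor(ib)
  obj <- function(par) {
    w <- refinementWeights(fobs2, sigma, fcalc2, abs(par[1]), abs(par[2]))
    r2 <- w * (fobs2 - fcalc2)^2 * dofScale
    g2 <- tapply(r2, bins, mean)
    sum((g2 - 1)^2)
  }
  # multi-start: the objective is flat and multimodal in (a, b)
  starts <- unique(rbind(c(0, 0), start, c(0.02, 0), c(0.1, 0),
                         c(0.2, stats::median(sigma))))
  opt <- NULL
  for (r in seq_len(nrow(starts))) {
    cand <- stats::nlminb(starts[r, ], obj, lower = c(0, 0),
                          control = list(iter.max = 300))
    if (is.null(opt) || cand$objective < opt$objective) opt <- cand
  }
  a <- abs(opt$par[1]); b <- abs(opt$par[2])
  capped <- a > aCap
  if (capped) {
    warning("weighting optimization ran away (a = ", signif(a, 3),
            "); falling back to a = 0.2, b = 0")
    a <- 0.2; b <- 0
  }
  w <- refinementWeights(fobs2, sigma, fcalc2, a, b)
  g2 <- tapply(w * (fobs2 - fcalc2)^2 * dofScale, bins, mean)
  binTable <- data.frame(bin = names(g2), goof = sqrt(as.numeric(g2)),
                         n = as.numeric(table(bins)))
  list(a = a, b = b, binTable = binTable,
       flatness = max(binTable$goof) / min(binTable$goof),
       converged = opt$convergence == 0 && !capped, capped = capped)
}
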