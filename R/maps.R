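#' @include cell-symmetry.R
NULL

#' Expand unique reflections to the full sphere by space-group symmetry
#'
#' Applies \eqn{F(hR) = F(h)\,e^{-2\pi i h\cdot t}} for every operation and
#' adds Friedel mates, keeping one value per distinct index.
#'
#' @param hkl Integer matrix of unique Miller indices.
#' @param f Complex structure-factor-like coefficients.
#' @param sg A \code{SpaceGroup} (NULL: Friedel mates only).
#' @return List with the expanded \code{hkl} and \code{f}.
#' @export
expandReflections <- function(hkl, f, sg = NULL) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  allh <- hkl; allf <- f
  if (!is.null(sg)) {
    ops <- symmetryOperations(sg)
    pieces_h <- list(); pieces_f <- list()
    for (i in seq_along(ops$rotations)) {
      pieces_h[[i]] <- hkl %*% ops$rotations[[i]]
      pieces_f[[i]] <- f * exp(-2i * pi * drop(hkl %*% ops$translations[[i]]))
    }
    allh <- do.call(rbind, pieces_h); allf <- unlist(pieces_f)
  }
  allh <- rbind(allh, -allh); allf <- c(allf, Conj(allf))
  key <- paste(allh[, 1], allh[, 2], allh[, 3])
  keep <- !duplicated(key)
  list(hkl = allh[keep, , drop = FALSE], f = allf[keep])
}

#' Fourier difference synthesis
#'
#' Computes \eqn{\rho(x) = (1/V) \sum_h \Delta F(h) e^{-2\pi i h\cdot x}}
#' on a regular fractional grid over one unit cell by FFT.  The
#' coefficient set is completed with Friedel mates (and optionally
#' space-group symmetry); inconsistent Hermitian pairs are rejected.
#' F(000) is excluded by default.
#'
#' @param hkl Integer matrix of Miller indices.
#' @param deltaF Complex coefficients (e.g. \eqn{(|F_o| - |F_c|) e^{i\phi_c}}
#'   or a model-minus-model difference).
#' @param cell A \code{UnitCell}.
#' @param gridDim Length-3 integer grid dimensions; default chosen as at
#'   least four points per minimum d-spacing along each axis.
#' @param sg Optional \code{SpaceGroup} for wedge expansion.
#' @param excludeF000 Drop the (0,0,0) coefficient (default TRUE).
#' @param unit Unit tag of the map values.
#' @return A periodic \code{DensityGrid} over the unit cell.
#' @export
differenceMap <- function(hkl, deltaF, cell, gridDim = NULL, sg = NULL,
                          excludeF000 = TRUE, unit = "1/A^2") {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  ex <- expandReflections(hkl, deltaF, sg)
  hkl <- ex$hkl; deltaF <- ex$f
  # Hermitian consistency
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  negIdx <- match(paste(-hkl[, 1], -hkl[, 2], -hkl[, 3]), key)
  bad <- !is.na(negIdx) & Mod(deltaF - Conj(deltaF[negIdx])) >
    1e-6 * (1 + Mod(deltaF))
  if (any(bad))
    stop("non-Hermitian coefficients for a real map, e.g. at ",
         key[which(bad)[1]])
  if (excludeF000) {
    z <- hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0
    hkl <- hkl[!z, , drop = FALSE]; deltaF <- deltaF[!z]
  }
  if (is.null(gridDim)) {
    p <- cellParameters(cell)
    dmin <- min(dSpacing(cell, hkl))
    gridDim <- 2 * ceiling(2 * p[1:3] / dmin)  # ~ dmin/4 spacing, even
  }
  gridDim <- as.integer(gridDim)
  hmax <- apply(abs(hkl), 2, max)
  if (any(gridDim < 2 * hmax + 1))
    stop("grid too coarse for the index range; need at least ",
         paste(2 * hmax + 1, collapse = "x"))
  A <- array(0i, gridDim)
  idx <- sweep(hkl, 2, gridDim, `%%`) + 1
  A[cbind(idx[, 1], idx[, 2], idx[, 3])] <- deltaF
  vol <- cellVolume(cell)
  vals <- Re(fft(A)) / vol
  M <- orthoMatrix(cell)
  step <- M %*% diag(1 / gridDim)
  densityGrid(vals, origin = c(0, 0, 0), step = step, periodic = TRUE,
              unit = unit)
}

#' Grid extrema
#'
#' Largest and smallest map values with their positions.
#'
#' @param grid A \code{DensityGrid}.
#' @param fractional Return positions as fractions of the grid axes
#'   (default TRUE, natural for unit-cell maps).
#' @return List with max, min, and their positions.
#' @export
mapExtrema <- function(grid, fractional = TRUE) {
  v <- grid@values
  iMax <- which.max(v); iMin <- which.min(v)
  pos <- function(i) {
    d <- dim(v)
    ijk <- arrayInd(i, d) - 1
    if (fractional) drop(ijk / d)
    else drop(grid@origin + grid@step %*% drop(ijk))
  }
  list(max = v[iMax], min = v[iMin], maxPos = pos(iMax), minPos = pos(iMin))
}

#' Fractal-dimension curve of a residual map
#'
#' For each residual level \eqn{\rho_0} (bin centre), the fractal dimension
#' \eqn{d_f(\rho_0) = \ln N(\rho_0) / \ln N_{total}} where \eqn{N(\rho_0)}
#' counts grid points falling in that bin.  Bins are equal-width and
#' symmetric about zero; empty bins are omitted.  A flat map degenerates
#' to a single bin with \eqn{d_f = 1}.
#'
#' @param grid A \code{DensityGrid} covering one full unit cell.
#' @param nBins Number of bins (odd recommended; must be >= 3).
#' @return List with \code{curve} (data frame rho0, df, count),
#'   \code{width} (full range of populated levels) and \code{asymmetry}
#'   (sum of the extreme populated levels; 0 for a symmetric residual
#'   distribution).
#' @export
fractalDimension <- function(grid, nBins = 101) {
  if (nBins < 3) stop("nBins must be at least 3")
  v <- as.numeric(grid@values)
  ntot <- length(v)
  m <- max(abs(v))
  if (m == 0)
    return(list(curve = data.frame(rho0 = 0, df = 1, count = ntot),
                width = 0, asymmetry = 0))
  breaks <- seq(-m, m, length.out = nBins + 1)
  cnt <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                  nbins = nBins)
  mid <- (breaks[-1] + breaks[-(nBins + 1)]) / 2
  keep <- cnt > 0
  curve <- data.frame(rho0 = mid[keep], df = log(cnt[keep]) / log(ntot),
                      count = cnt[keep])
  list(curve = curve, width = diff(range(curve$rho0)),
       asymmetry = max(curve$rho0) + min(curve$rho0))
}
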