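#' @include synthetic.R maps.R
NULL

#' Scattering-model variant for a comparison run
#'
#' @param name Display name.
#' @param kind One of "iam" (neutral), "iam-charged" (formal metal charge
#'   with partially charged oxygen), "taam" (aspherical pseudoatom models
#'   for every atom) or "taam-hybrid" (aspherical ligand, spherical
#'   neutral metal).
#' @param models Named \code{MultipoleAtomModel} list (taam kinds).
#' @param chargedSpecies Named character vector mapping elements to
#'   charged species labels for "iam-charged", default
#'   c(Fe = "Fe3+", O = "O0.5-").
#' @return List of class "scatteringVariant".
#' @export
scatteringVariant <- function(name, kind = c("iam", "iam-charged", "taam",
                                             "taam-hybrid"),
                              models = NULL,
                              chargedSpecies = c(Fe = "Fe3+", O = "O0.5-")) {
  kind <- match.arg(kind)
  structure(list(name = name, kind = kind, models = models,
                 chargedSpecies = chargedSpecies),
            class = "scatteringVariant")
}

# instantiate (structure, provider) for a variant
.variantSetup <- function(variant, startModel, radiation = "electron") {
  st <- startModel
  st@sites$scattererRef <- st@sites$element
  if (variant$kind == "iam") {
    return(list(structure = st, provider = iamProvider(st, radiation)))
  }
  if (variant$kind == "iam-charged") {
    for (el in names(variant$chargedSpecies))
      st@sites$scattererRef[st@sites$element == el] <-
        variant$chargedSpecies[[el]]
    return(list(structure = st, provider = iamProvider(st, radiation)))
  }
  if (is.null(variant$models)) stop("taam variant needs pseudoatom models")
  st@sites$scattererRef <- st@sites$label
  prov <- variant$models[as.character(st@sites$label)]
  names(prov) <- st@sites$label
  if (variant$kind == "taam-hybrid") {
    fe <- st@sites$element == "Fe"
    st@sites$scattererRef[fe] <- st@sites$element[fe]
    prov <- c(prov[!fe], iamProvider(
      crystalStructure(st@cell, st@spaceGroup,
                       st@sites[fe, , drop = FALSE]), radiation))
  }
  list(structure = st, provider = prov)
}

#' Run the scattering-model comparison workflow
#'
#' Refines the same starting model against the same data under several
#' scattering-model variants and assembles the full diagnostic report:
#' global statistics, locked-parameter resolution-shell R1, difference-map
#' extrema and fractal-dimension summaries, displacement-ellipsoid ratios
#' and (optionally) RMSDs against a reference model.  A failing variant is
#' recorded and does not abort the others.
#'
#' @param startModel Starting \code{CrystalStructure}.
#' @param refl A \code{ReflectionSet}.
#' @param variants List of \code{\link{scatteringVariant}}s.
#' @param config A \code{\link{refinementConfig}}.
#' @param shellBoundaries Resolution-shell boundaries in Angstrom,
#'   descending (default c(8.65, 2.0, 0.85)).
#' @param reference Optional reference \code{CrystalStructure} for RMSDs.
#' @param radiation "electron" or "xray".
#' @param mapGrid Grid dimensions for difference maps (NULL for default).
#' @return List of class "comparisonReport" with \code{summary} (data
#'   frame), \code{shells}, \code{fractal}, \code{results} (per-variant
#'   \code{RefinementResult}s) and \code{errors}.
#' @export
runComparison <- function(startModel, refl, variants,
                          config = refinementConfig(optimizeWeights = TRUE),
                          shellBoundaries = c(8.65, 2.0, 0.85),
                          reference = NULL, radiation = "electron",
                          mapGrid = NULL) {
  rows <- list(); shells <- list(); fractal <- list(); results <- list()
  errors <- list()
  for (v in variants) {
    res <- tryCatch({
      setup <- .variantSetup(v, startModel, radiation)
      fit <- refineLsq(setup$structure, refl, setup$provider, config,
                       radiation = radiation)
      stats <- fit@stats
      sh <- shellR1(refl, fit@fcalc2 / fit@scale, fit@scale,
                    shellBoundaries, cut = config$sigmaCut)
      # observed-minus-calculated map with model phases
      setupR <- setup; setupR$structure <- fit@structure
      Fc <- calcStructureFactors(fit@structure, refl@hkl, setup$provider,
                                 radiation)
      fo <- sqrt(pmax(refl@fobs2, 0) / fit@scale)
      dF <- (fo - Mod(Fc)) * exp(1i * Arg(Fc))
      map <- differenceMap(refl@hkl, dF, startModel@cell, gridDim = mapGrid,
                           sg = startModel@spaceGroup, unit = "1/A^2")
      ex <- mapExtrema(map)
      fd <- fractalDimension(map)
      er <- ellipsoidRatios(fit@structure)
      rms <- if (!is.null(reference)) rmsdModels(fit@structure, reference)
             else list(coordRmsd = NA_real_, bondRmsd = NA_real_)
      list(fit = fit, sh = sh, ex = ex, fd = fd, er = er, rms = rms)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[v$name]] <- conditionMessage(res)
      next
    }
    stats <- res$fit@stats
    rows[[v$name]] <- data.frame(
      model = v$name, R1_strong = stats$R1_strong, R1_all = stats$R1_all,
      wR2 = stats$wR2, GooF = stats$goof, nRefl = stats$nObs,
      nStrong = stats$nStrong, nParams = stats$nParams,
      weightA = res$fit@weights[["a"]], weightB = res$fit@weights[["b"]],
      maxPeak = res$ex$max, minPeak = res$ex$min,
      fractalWidth = res$fd$width, meanEllipsoidRatio = res$er$mean,
      rmsdCoord = res$rms$coordRmsd, rmsdBond = res$rms$bondRmsd)
    shells[[v$name]] <- res$sh
    fractal[[v$name]] <- res$fd
    results[[v$name]] <- res$fit
  }
  structure(list(summary = do.call(rbind, rows), shells = shells,
                 fractal = fractal, results = results, errors = errors),
            class = "comparisonReport")
}

#' @export
print.comparisonReport <- function(x, ...) {
  cat("Scattering-model comparison\n")
  s <- x$summary
  if (!is.null(s)) {
    fmt <- s
    for (cn in setdiff(colnames(fmt), "model"))
      fmt[[cn]] <- signif(fmt[[cn]], 4)
    print(fmt, row.names = FALSE)
  }
  if (length(x$errors))
    for (nm in names(x$errors))
      cat("FAILED ", nm, ": ", x$errors[[nm]], "\n", sep = "")
  invisible(x)
}
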