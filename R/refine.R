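#' @include statistics.R structure-factors.R
NULL

#' Refinement configuration
#'
#' @param weightA,weightB Weighting-scheme parameters a and b.
#' @param optimizeWeights Re-optimize (a, b) after convergence and refine
#'   once more with the updated weights.
#' @param sigmaCut Sigma(F) multiple for the "strong" R1 subset.
#' @param refineCoords,refineAdp Which parameter classes are free.
#' @param extinction Refine a single isotropic extinction scalar g with
#'   \eqn{F_c^2 \to F_c^2 (1 + g F_c^2)^{-1/2}}.
#' @param maxIter Levenberg-Marquardt iteration cap per weighting cycle.
#' @param convergence Relative objective-change threshold.
#' @param weightCycles Number of reweighting macro-cycles.
#' @param parameterLocks Character vector of locked site labels (their
#'   coordinates and ADPs stay fixed).
#' @return A list of class "refinementConfig".
#' @export
refinementConfig <- function(weightA = 0, weightB = 0,
                             optimizeWeights = FALSE, sigmaCut = 4,
                             refineCoords = TRUE, refineAdp = TRUE,
                             extinction = FALSE, maxIter = 100,
                             convergence = 1e-9, weightCycles = 2,
                             parameterLocks = character()) {
  structure(list(weightA = weightA, weightB = weightB,
                 optimizeWeights = optimizeWeights, sigmaCut = sigmaCut,
                 refineCoords = refineCoords, refineAdp = refineAdp,
                 extinction = extinction, maxIter = maxIter,
                 convergence = convergence, weightCycles = weightCycles,
                 parameterLocks = parameterLocks),
            class = "refinementConfig")
}

# Identify riding hydrogens: each H bonded to exactly one non-H parent.
# Returns data frame h (site index), parent (site index), factor (U tie).
.ridingTable <- function(structure) {
  st <- structure@sites
  M <- orthoMatrix(structure@cell)
  xyz <- as.matrix(st[, c("x", "y", "z")]) %*% t(M)
  atoms <- data.frame(element = st$element, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3])
  bonds <- detectBonds(atoms)
  hIdx <- which(st$element == "H")
  if (length(hIdx) == 0)
    return(data.frame(h = integer(), parent = integer(), factor = numeric()))
  parent <- vapply(hIdx, function(i) {
    nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    nb <- nb[st$element[nb] != "H"]
    if (length(nb) == 0) NA_integer_ else nb[which.min(
      sqrt(colSums((t(xyz[nb, , drop = FALSE]) - xyz[i, ])^2)))]
  }, integer(1))
  nH <- table(parent)
  fac <- ifelse(nH[as.character(parent)] >= 3, 1.5, 1.2)
  ok <- !is.na(parent)
  data.frame(h = hIdx[ok], parent = parent[ok], factor = as.numeric(fac)[ok])
}

.uEq <- function(cell, u) mean(eigen(.uCartesian(cell, u), symmetric = TRUE,
                                     only.values = TRUE)$values)

# ---- least-squares engine -----------------------------------------------

# Precompute geometry-independent quantities for fast repeated F and
# Jacobian evaluation.
.sfEngine <- function(structure, hkl, provider, radiation) {
  cell <- structure@cell
  ops <- symmetryOperations(structure)
  rl <- reciprocalLengths(cell)
  st <- structure@sites
  nref <- nrow(hkl)
  nops <- length(ops$rotations)
  hR <- lapply(ops$rotations, function(R) hkl %*% R)
  phase0 <- lapply(ops$translations, function(tr) drop(hkl %*% tr))
  s2 <- lapply(hR, function(h) {
    hc <- reciprocalVectors(cell, h); rowSums(hc^2) / 4
  })
  ff <- lapply(seq_len(nops), function(io) {
    hc <- reciprocalVectors(cell, hR[[io]])
    s <- sqrt(s2[[io]])
    sapply(seq_len(nrow(st)), function(ia) {
      obj <- .resolveScatterer(provider, st$scattererRef[ia], st$label[ia])
      .ffValues(obj, hR[[io]], hc, s, radiation)
    })
  })
  list(cell = cell, st = st, rl = rl, nref = nref, nops = nops, hR = hR,
       phase0 = phase0, s2 = s2, ff = ff)
}

# dw exponent coefficient matrices per op: columns multiply u11..u23
.dwCoefs <- function(eng) {
  lapply(eng$hR, function(h) {
    rl <- eng$rl
    -2 * pi^2 * cbind((h[, 1] * rl[1])^2, (h[, 2] * rl[2])^2,
                      (h[, 3] * rl[3])^2,
                      2 * h[, 1] * h[, 2] * rl[1] * rl[2],
                      2 * h[, 1] * h[, 3] * rl[1] * rl[3],
                      2 * h[, 2] * h[, 3] * rl[2] * rl[3])
  })
}

#' Full-matrix least-squares refinement against F-squared
#'
#' Minimizes \eqn{\sum w (F_o^2 - k F_c^2)^2} over the scale, non-hydrogen
#' fractional coordinates and anisotropic (or isotropic) displacement
#' parameters with the Levenberg-Marquardt algorithm and analytic
#' derivatives.  Hydrogens ride on their bonded parent (fixed offset
#' vector, so X-H distances are invariant) with
#' \eqn{U_{iso}(H) = 1.2 U_{eq}} of the parent (1.5 for methyl groups),
#' updated between weighting cycles.
#'
#' @param structure Starting \code{CrystalStructure}.
#' @param refl A \code{ReflectionSet}.
#' @param provider Scatterer provider (see
#'   \code{\link{calcStructureFactors}}).
#' @param config A \code{\link{refinementConfig}}.
#' @param radiation "electron" or "xray".
#' @return A \code{RefinementResult}.
#' @export
refineLsq <- function(structure, refl, provider, config = refinementConfig(),
                      radiation = c("electron", "xray")) {
  radiation <- match.arg(radiation)
  st <- structure@sites
  eng <- .sfEngine(structure, refl@hkl, provider, radiation)
  dw <- .dwCoefs(eng)
  riding <- .ridingTable(structure)
  free <- which(st$element != "H" & !(st$label %in% config$parameterLocks))
  # parameter layout: [k, (x,y,z)*free?, U*free?]
  parIndex <- list(scale = 1L)
  np <- 1L
  if (config$refineCoords) {
    parIndex$coords <- lapply(seq_along(free), function(i)
      np + (i - 1) * 3 + 1:3)
    np <- np + 3 * length(free)
  }
  if (config$refineAdp) {
    parIndex$adp <- lapply(seq_along(free), function(i) {
      nu <- if (st$adpType[free[i]] == "aniso") 6L else 1L
      out <- np + seq_len(nu); np <<- np + nu; out
    })
  }
  if (config$extinction) { parIndex$exti <- np + 1L; np <- np + 1L }
  if (np >= eng$nref)
    stop("refinement underdetermined: ", np, " parameters for ", eng$nref,
         " reflections")

  uisoH <- st$uiso  # working H isotropic U, tied to parent Ueq per cycle
  state <- new.env(parent = emptyenv())

  packSites <- function(par) {
    s2 <- st
    if (config$refineCoords)
      for (i in seq_along(free))
        s2[free[i], c("x", "y", "z")] <- par[parIndex$coords[[i]]]
    if (config$refineAdp)
      for (i in seq_along(free)) {
        ui <- par[parIndex$adp[[i]]]
        if (length(ui) == 6)
          s2[free[i], c("u11", "u22", "u33", "u12", "u13", "u23")] <- ui
        else s2[free[i], "uiso"] <- ui
      }
    # riding H follow their parent
    if (nrow(riding) > 0 && config$refineCoords) {
      off <- state$offsets
      for (r in seq_len(nrow(riding))) {
        ih <- riding$h[r]; ip <- riding$parent[r]
        s2[ih, c("x", "y", "z")] <-
          as.numeric(s2[ip, c("x", "y", "z")]) + off[r, ]
      }
    }
    s2$uiso[st$element == "H"] <- uisoH[st$element == "H"]
    s2
  }
  state$offsets <- if (nrow(riding) > 0)
    as.matrix(st[riding$h, c("x", "y", "z")]) -
      as.matrix(st[riding$parent, c("x", "y", "z")])
  else matrix(0, 0, 3)

  # evaluate F and per-(site,op) term cache for the Jacobian
  evalF <- function(sites) {
    terms <- vector("list", eng$nops)
    Fc <- complex(eng$nref)
    xyz <- as.matrix(sites[, c("x", "y", "z")])
    for (io in seq_len(eng$nops)) {
      tm <- matrix(0i, eng$nref, nrow(sites))
      for (ia in seq_len(nrow(sites))) {
        if (sites$adpType[ia] == "aniso") {
          u <- as.numeric(sites[ia, c("u11", "u22", "u33", "u12", "u13",
                                      "u23")])
          Tdw <- exp(drop(dw[[io]] %*% u))
        } else Tdw <- exp(-8 * pi^2 * sites$uiso[ia] * eng$s2[[io]])
        ph <- 2 * pi * (drop(eng$hR[[io]] %*% xyz[ia, ]) + eng$phase0[[io]])
        tm[, ia] <- sites$occ[ia] * eng$ff[[io]][, ia] * Tdw * exp(1i * ph)
      }
      terms[[io]] <- tm
      Fc <- Fc + rowSums(tm)
    }
    list(F = Fc, terms = terms)
  }

  model <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (identical(state$key, key)) return(state$val)
    sites <- packSites(par)
    ev <- evalF(sites)
    f2 <- Mod(ev$F)^2
    if (config$extinction) f2 <- f2 / sqrt(1 + max(par[parIndex$exti], 0) * f2)
    state$key <- key
    state$val <- list(sites = sites, ev = ev, f2raw = Mod(ev$F)^2, f2 = f2)
    state$val
  }

  residFn <- function(par) {
    m <- model(par)
    state$sqw * (refl@fobs2 - par[1] * m$f2)
  }

  jacFn <- function(par) {
    m <- model(par)
    ev <- m$ev
    J <- matrix(0, eng$nref, np)
    k <- par[1]
    extiFac <- if (config$extinction) {
      g <- max(par[parIndex$exti], 0)
      (1 + g * m$f2raw)^(-1/2) - 0.5 * g * m$f2raw * (1 + g * m$f2raw)^(-3/2)
    } else 1
    # d f2 / d p = 2 Re( conj(F) dF/dp ) (chain through extinction)
    addCol <- function(j, dF) {
      J[, j] <<- J[, j] - state$sqw * k * extiFac * 2 * Re(Conj(ev$F) * dF)
    }
    J[, 1] <- -state$sqw * m$f2
    childOf <- split(seq_len(nrow(riding)), riding$parent)
    for (ii in seq_along(free)) {
      ia <- free[ii]
      if (config$refineCoords) {
        for (ax in 1:3) {
          dF <- complex(eng$nref)
          for (io in seq_len(eng$nops)) {
            dF <- dF + ev$terms[[io]][, ia] * 2i * pi * eng$hR[[io]][, ax]
            ch <- childOf[[as.character(ia)]]
            if (!is.null(ch)) for (r in ch)
              dF <- dF + ev$terms[[io]][, riding$h[r]] * 2i * pi *
                eng$hR[[io]][, ax]
          }
          addCol(parIndex$coords[[ii]][ax], dF)
        }
      }
      if (config$refineAdp) {
        cols <- parIndex$adp[[ii]]
        if (length(cols) == 6) {
          for (uu in 1:6) {
            dF <- complex(eng$nref)
            for (io in seq_len(eng$nops))
              dF <- dF + ev$terms[[io]][, ia] * dw[[io]][, uu]
            addCol(cols[uu], dF)
          }
        } else {
          dF <- complex(eng$nref)
          for (io in seq_len(eng$nops))
            dF <- dF + ev$terms[[io]][, ia] * (-8 * pi^2 * eng$s2[[io]])
          addCol(cols, dF)
        }
      }
    }
    if (config$extinction) {
      g <- max(par[parIndex$exti], 0)
      dfe <- -0.5 * m$f2raw^2 * (1 + g * m$f2raw)^(-3/2)
      J[, parIndex$exti] <- -state$sqw * k * dfe
    }
    J
  }

  # initial parameter vector
  par <- numeric(np)
  if (config$refineCoords)
    for (i in seq_along(free))
      par[parIndex$coords[[i]]] <- as.numeric(st[free[i], c("x", "y", "z")])
  if (config$refineAdp)
    for (i in seq_along(free)) {
      cols <- parIndex$adp[[i]]
      par[cols] <- if (length(cols) == 6)
        as.numeric(st[free[i], c("u11", "u22", "u33", "u12", "u13", "u23")])
      else st$uiso[free[i]]
    }
  if (config$extinction) par[parIndex$exti] <- 1e-6

  a <- config$weightA; b <- config$weightB
  f2 <- { state$sqw <- rep(1, eng$nref); model(par)$f2 }
  par[1] <- sum(refl@fobs2 * f2 / refl@sigma^2) /
    sum(f2^2 / refl@sigma^2)
  totalIter <- 0; converged <- FALSE; maxShift <- NA_real_
  for (cycle in seq_len(config$weightCycles)) {
    # tie H U_iso to current parent Ueq, freeze weights for the cycle
    m <- model(par)
    if (nrow(riding) > 0) {
      for (r in seq_len(nrow(riding))) {
        ip <- riding$parent[r]
        ue <- if (m$sites$adpType[ip] == "aniso")
          .uEq(eng$cell, as.numeric(m$sites[ip, c("u11", "u22", "u33",
                                                  "u12", "u13", "u23")]))
        else m$sites$uiso[ip]
        uisoH[riding$h[r]] <- riding$factor[r] * ue
      }
      state$key <- NULL
      m <- model(par)
    }
    w <- refinementWeights(refl@fobs2, refl@sigma, par[1] * m$f2, a, b)
    state$sqw <- sqrt(w)
    state$key <- NULL
    p0 <- par
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = par, fn = residFn, jac = jacFn,
      control = minpack.lm::nls.lm.control(maxiter = config$maxIter,
                                           ftol = config$convergence,
                                           ptol = 1e-10, gtol = 0)))
    par <- fit$par
    totalIter <- totalIter + fit$niter
    converged <- fit$info %in% c(1, 2, 3, 4)
    maxShift <- max(abs(par - p0))
    if (config$optimizeWeights && cycle < config$weightCycles) {
      m <- model(par)
      ow <- suppressWarnings(optimizeWeights(
        refl@fobs2, refl@sigma, par[1] * m$f2, nParams = np, d = refl@d))
      a <- ow$a; b <- ow$b
    }
  }
  m <- model(par)
  w <- refinementWeights(refl@fobs2, refl@sigma, par[1] * m$f2, a, b)
  refined <- structure
  refined@sites <- m$sites
  rf <- rFactors(refl@fobs2, refl@sigma, m$f2, scale = par[1],
                 cut = config$sigmaCut)
  stats <- list(R1_strong = rf$R1_strong, R1_all = rf$R1_all, wR2 = rf$wR2,
                goof = goodnessOfFit(refl@fobs2, m$f2, w, np,
                                     scale = par[1]),
                nObs = eng$nref, nParams = np, nStrong = rf$nStrong)
  new("RefinementResult", structure = refined, scale = par[1],
      stats = stats, weights = c(a = a, b = b), converged = converged,
      iterations = totalIter, maxShift = maxShift,
      fcalc2 = par[1] * m$f2)
}
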