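# Shared fixtures, built once per test file and memoised.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# small random P1 structure for structure-factor oracles
randomP1 <- function(n = 5, seed = 2) {
  set.seed(seed)
  sites <- data.frame(label = paste0("A", seq_len(n)),
                      element = sample(c("C", "O", "H", "Fe"), n,
                                       replace = TRUE),
                      x = runif(n), y = runif(n), z = runif(n))
  crystalStructure(unitCell(8, 9, 10), spaceGroup("P1"), sites)
}

# brute-force structure factors: explicit double loop, no symmetry
bruteForceSF <- function(structure, hkl, provider, radiation = "electron") {
  st <- atomSites(structure)
  ops <- symmetryOperations(structure)
  sapply(seq_len(nrow(hkl)), function(i) {
    h <- hkl[i, ]
    acc <- 0 + 0i
    for (io in seq_along(ops$rotations)) {
      R <- ops$rotations[[io]]; tr <- ops$translations[[io]]
      for (j in seq_len(nrow(st))) {
        x <- as.numeric(st[j, c("x", "y", "z")])
        xs <- drop(R %*% x) + tr
        d <- dSpacing(structure@cell, h)
        s <- 1 / (2 * d)
        obj <- provider[[st$scattererRef[j]]]
        f <- if (is(obj, "GaussianFormFactor")) evaluateFormFactor(obj, s)
             else stop("brute force supports Gaussian factors only")
        u <- if (st$adpType[j] == "aniso") {
          rl <- reciprocalLengths(structure@cell)
          uu <- as.numeric(st[j, c("u11", "u22", "u33", "u12", "u13", "u23")])
          hh <- drop(h %*% R)
          exp(-2 * pi^2 * (uu[1] * (hh[1] * rl[1])^2 +
                             uu[2] * (hh[2] * rl[2])^2 +
                             uu[3] * (hh[3] * rl[3])^2 +
                             2 * uu[4] * hh[1] * hh[2] * rl[1] * rl[2] +
                             2 * uu[5] * hh[1] * hh[3] * rl[1] * rl[3] +
                             2 * uu[6] * hh[2] * hh[3] * rl[2] * rl[3]))
        } else exp(-8 * pi^2 * st$uiso[j] * s^2)
        acc <- acc + st$occ[j] * f * u * exp(2i * pi * sum(h * xs))
      }
    }
    acc
  })
}

# reduced-resolution synthetic crystal + noise-free IAM data (fast)
smallIamSim <- function() fixture("smallIamSim", function() {
  spec <- simulationSpec(dmin = 1.3, seed = 101)
  spec$groundTruth <- "iam"
  st <- makeStructure(spec)
  sim <- simulateReflections(st, spec, noise = 0)
  list(spec = spec, structure = st, sim = sim)
})

# the synthetic molecule as a Cartesian atom table
moleculeAtoms <- function(structure) {
  M <- orthoMatrix(structure@cell)
  xyz <- as.matrix(atomSites(structure)[, c("x", "y", "z")]) %*% t(M)
  data.frame(label = atomSites(structure)$label,
             element = atomSites(structure)$element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}
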