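# a small rigid test molecule: one acac-like fragment (O-C(-CH3)=CH-)
.fragmentAtoms <- function() {
  st <- makeStructure(simulationSpec(seed = 55))
  atoms <- moleculeAtoms(st)
  atoms[1:15, ]   # Fe + one ligand
}

test_that("refinement against self-generated targets is an exact fixed point", {
  atoms <- .fragmentAtoms()
  models <- lapply(seq_len(nrow(atoms)), function(i)
    neutralAtomModel(atoms$element[i]))
  names(models) <- atoms$label
  sf <- theoreticalStructureFactors(atoms, models, boxLength = 14,
                                    dmin = 1.3)
  out <- refineMultipoles(models, sf, flags = list(Pval = TRUE,
                                                   kappa = TRUE,
                                                   Plm = FALSE))
  expect_lt(out$R, 1e-8)
  for (nm in names(models)) {
    expect_equal(out$models[[nm]]@Pval, models[[nm]]@Pval, tolerance = 1e-6)
    expect_equal(out$models[[nm]]@kappa, models[[nm]]@kappa,
                 tolerance = 1e-6)
  }
})

test_that("a perturbed valence population is recovered from structure factors", {
  atoms <- .fragmentAtoms()
  truth <- lapply(seq_len(nrow(atoms)), function(i)
    neutralAtomModel(atoms$element[i]))
  names(truth) <- atoms$label
  oLab <- atoms$label[atoms$element == "O"][1]
  truth[[oLab]]@Pval <- truth[[oLab]]@Pval + 0.5
  sf <- theoreticalStructureFactors(atoms, truth, boxLength = 14,
                                    dmin = 1.3)
  start <- truth
  start[[oLab]]@Pval <- start[[oLab]]@Pval - 0.5
  out <- refineMultipoles(start, sf, flags = list(Pval = TRUE,
                                                  kappa = FALSE,
                                                  Plm = FALSE))
  expect_equal(out$models[[oLab]]@Pval, truth[[oLab]]@Pval,
               tolerance = 1e-4)
  expect_lt(out$R, 1e-6)
})

test_that("valence-only targets drop the frozen core consistently", {
  atoms <- .fragmentAtoms()[2:6, ]
  models <- lapply(seq_len(nrow(atoms)), function(i)
    neutralAtomModel(atoms$element[i]))
  names(models) <- atoms$label
  sf <- theoreticalStructureFactors(atoms, models, boxLength = 12,
                                    dmin = 1.5, valenceOnly = TRUE)
  sfFull <- theoreticalStructureFactors(atoms, models, boxLength = 12,
                                        dmin = 1.5, valenceOnly = FALSE)
  expect_true(any(Mod(sf$f - sfFull$f) > 0.1))
  out <- refineMultipoles(models, sf, flags = list(Pval = TRUE,
                                                   kappa = FALSE,
                                                   Plm = FALSE))
  expect_lt(out$R, 1e-8)  # cores dropped on both sides: exact fixed point
})

test_that("atom typing groups chemically equivalent atoms", {
  st <- makeStructure(simulationSpec(seed = 55))
  atoms <- moleculeAtoms(st)
  keys <- assignAtomTypes(atoms)
  el <- atoms$element
  # six equivalent carbonyl O, six methyl C, six carbonyl C, three methine
  expect_length(unique(keys[el == "O"]), 1)
  cKeys <- keys[el == "C"]
  expect_length(unique(cKeys), 3)
  expect_equal(sort(as.numeric(table(cKeys))), c(3, 6, 6))
  # carbonyl vs methine C distinct by construction
  bonds <- detectBonds(atoms)
  nb <- function(i) atoms$element[c(bonds[bonds[, 1] == i, 2],
                                    bonds[bonds[, 2] == i, 1])]
  carbonyl <- which(el == "C" &
                      vapply(seq_len(nrow(atoms)),
                             function(i) "O" %in% nb(i), logical(1)))
  methine <- which(el == "C" &
                     vapply(seq_len(nrow(atoms)), function(i)
                       sum(nb(i) == "C") == 2 && !"O" %in% nb(i),
                       logical(1)))
  expect_false(any(keys[carbonyl] %in% keys[methine]))
  # methane toy: four equivalent H
  d <- 1.09 / sqrt(3)
  methane <- data.frame(element = c("C", "H", "H", "H", "H"),
                        x = c(0, d, -d, d, -d), y = c(0, d, -d, -d, d),
                        z = c(0, d, d, -d, -d))
  kM <- assignAtomTypes(methane)
  expect_length(unique(kM[-1]), 1)
  # disconnected atom becomes a singleton type with a warning
  lone <- rbind(methane, data.frame(element = "O", x = 30, y = 30, z = 30))
  expect_warning(kL <- assignAtomTypes(lone), "disconnected")
  expect_match(kL[6], "isolated")
})

test_that("databank averaging and application round-trip", {
  st <- makeStructure(simulationSpec(seed = 55))
  atoms <- moleculeAtoms(st)
  models <- truthModels(st)
  keys <- assignAtomTypes(atoms)
  bank <- buildDatabank(models, keys)
  # two exemplars average arithmetically
  m1 <- multipoleAtomModel("O", Pval = 5.8)
  m2 <- multipoleAtomModel("O", Pval = 6.2)
  b2 <- buildDatabank(list(A = m1, B = m2), c("t", "t"))
  expect_equal(b2$t$Pval, 6.0)
  # averaging commutes with permutation of equivalent atoms
  perm <- sample(seq_along(models))
  bankP <- buildDatabank(models[perm], keys[perm])
  for (k in names(bank)) expect_equal(bank[[k]]$Pval, bankP[[k]]$Pval)
  # single-exemplar types: build -> apply reproduces the per-type models
  applied <- applyDatabank(bank, atoms)
  for (i in seq_len(nrow(atoms))) {
    lb <- atoms$label[i]
    expect_equal(applied[[lb]]@Pval, bank[[keys[i]]]$Pval)
    expect_equal(applied[[lb]]@kappa, bank[[keys[i]]]$kappa)
  }
  # unmatched type falls back to the spherical neutral model
  odd <- data.frame(label = "N1", element = "N", x = 0, y = 0, z = 0)
  suppressWarnings(
    expect_error(applyDatabank(bank, odd, fallback = FALSE), "no databank"))
  # (N has no Slater model; use an unmatched Fe environment instead)
  feOnly <- data.frame(label = "Fe9", element = "Fe", x = 0, y = 0, z = 0)
  expect_warning(fb <- applyDatabank(bank, feOnly))
  s <- c(0.1, 0.4)
  expect_equal(sphericalComponentCurve(fb$Fe9, s),
               sphericalComponentCurve(neutralAtomModel("Fe"), s))
  # JSON round trip
  p <- tempfile(fileext = ".json")
  writeDatabank(bank, p)
  back <- readDatabank(p)
  k1 <- names(bank)[1]
  expect_equal(back[[k1]]$Pval, bank[[k1]]$Pval, tolerance = 1e-12)
  expect_equal(back[[k1]]$Plm, bank[[k1]]$Plm, tolerance = 1e-12)
})

test_that("build-apply on unique types reproduces per-atom form factors exactly", {
  # bent water-like toy: every pseudoatom parameter set is reproduced
  # because each type has identical exemplars
  atoms <- data.frame(label = c("O1", "H1", "H2"), element = c("O", "H", "H"),
                      x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0)
  bonds <- detectBonds(atoms)
  mkH <- function(i) multipoleAtomModel(
    "H", Pval = 0.9, kappa = 1.12, Plm = list(c(0, 0.12, 0)),
    localAxes = localAxesFromNeighbors(atoms, bonds, i))
  models <- list(O1 = multipoleAtomModel(
    "O", Pval = 6.2, kappa = 0.96,
    Plm = list(c(0, 0.08, 0), c(0, 0, 0.05, 0, 0)),
    localAxes = localAxesFromNeighbors(atoms, bonds, 1)),
    H1 = mkH(2), H2 = mkH(3))
  bank <- buildDatabank(models, assignAtomTypes(atoms, bonds))
  applied <- applyDatabank(bank, atoms)
  h <- rbind(c(0.2, 0.1, 0.3), c(-0.15, 0.4, 0.05))
  for (lb in names(models))
    expect_equal(hcFormFactor(applied[[lb]], h),
                 hcFormFactor(models[[lb]], h), tolerance = 1e-10)
})
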