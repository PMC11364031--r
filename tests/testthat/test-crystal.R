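test_that("d-spacings follow the reciprocal metric", {
  cub <- unitCell(10, 10, 10)
  expect_equal(dSpacing(cub, c(1, 0, 0)), 10)
  expect_equal(dSpacing(cub, c(1, 1, 0)), 10 / sqrt(2))
  expect_equal(dSpacing(unitCell(15.35, 13.56, 16.50), c(2, 0, 0)), 7.675)
  expect_equal(dSpacing(cub, c(0, 0, 0)), Inf)
  # triclinic sanity: |h a* + k b* + l c*| oracle
  tc <- unitCell(7, 8, 9, 95, 101, 112)
  B <- t(solve(orthoMatrix(tc)))
  h <- c(2, -1, 3)
  expect_equal(dSpacing(tc, h), 1 / sqrt(sum((B %*% h)^2)))
})

test_that("space-group operator algebra closes and parses", {
  sg <- spaceGroup("Pbca")
  expect_length(sg@rotations, 8)
  expect_true(sg@centrosymmetric)
  # closure modulo lattice translations
  ops <- symmetryOperations(sg)
  key <- function(R, t) paste(c(R, round(t %% 1, 6)), collapse = ",")
  allKeys <- vapply(seq_along(ops$rotations), function(i)
    key(ops$rotations[[i]], ops$translations[[i]]), character(1))
  for (i in seq_along(ops$rotations)) for (j in seq_along(ops$rotations)) {
    R <- ops$rotations[[i]] %*% ops$rotations[[j]]
    t <- drop(ops$rotations[[i]] %*% ops$translations[[j]]) +
      ops$translations[[i]]
    expect_true(key(R, t) %in% allKeys)
  }
})

test_that("structure factors: single atom, brute force, Friedel, absences", {
  # single atom at origin, P1, U = 0: F = f(s) for every reflection
  one <- crystalStructure(unitCell(10, 10, 10), spaceGroup("P1"),
                          data.frame(label = "C1", element = "C",
                                     x = 0, y = 0, z = 0))
  hkl <- rbind(c(1, 0, 0), c(2, 1, 0), c(3, 3, 1))
  prov <- iamProvider(one, "electron")
  s <- 1 / (2 * dSpacing(one@cell, hkl))
  expect_equal(calcStructureFactors(one, hkl, prov, "electron"),
               complex(real = evaluateFormFactor(prov$C, s)),
               tolerance = 1e-12)
  # random P1 structure vs naive double loop
  p1 <- randomP1()
  hkl5 <- uniqueReflections(p1@cell, 1.5)[1:40, ]
  prov5 <- iamProvider(p1, "electron")
  expect_equal(calcStructureFactors(p1, hkl5, prov5, "electron"),
               bruteForceSF(p1, hkl5, prov5), tolerance = 1e-10)
  # Friedel symmetry with anisotropic ADPs
  st <- smallIamSim()$structure
  provP <- iamProvider(st, "electron")
  h <- rbind(c(1, 2, 3), c(3, 1, 2), c(2, 5, 1))
  Fp <- calcStructureFactors(st, h, provP, "electron")
  Fm <- calcStructureFactors(st, -h, provP, "electron")
  expect_equal(Mod(Fp), Mod(Fm), tolerance = 1e-10)
  # centrosymmetry forces real structure factors
  expect_lt(max(abs(Im(Fp)) / Mod(Fp)), 1e-8)
  # Pbca systematic absences: 0kl k odd, h0l l odd, hk0 h odd
  habs <- rbind(c(0, 1, 1), c(0, 3, 5), c(1, 0, 1), c(5, 0, 3),
                c(1, 1, 0), c(3, 5, 0))
  Fabs <- calcStructureFactors(st, habs, provP, "electron")
  expect_lt(max(Mod(Fabs)), 1e-8 * max(Mod(Fp)))
})

test_that("table-driven and inline aspherical factors give identical structure factors", {
  st <- smallIamSim()$structure
  models <- truthModels(st)
  stT <- st
  stT@sites$scattererRef <- stT@sites$label
  hkl <- uniqueReflections(st@cell, 1.6)[seq(1, 300, by = 7), ]
  inlineProv <- models[as.character(stT@sites$label)]
  Finline <- calcStructureFactors(stT, hkl, inlineProv, "electron")
  tab <- formFactorTable(stT, hkl, models, "electron")
  Ftable <- calcStructureFactors(stT, hkl, tableProvider(stT, tab),
                                 "electron")
  expect_equal(Finline, Ftable, tolerance = 1e-10)
  # missing reflection is reported by index
  tiny <- tab
  expect_error(
    calcStructureFactors(stT, rbind(c(9L, 9L, 9L)),
                         tableProvider(stT, tiny), "electron"),
    "absent")
})

test_that("CIF files round-trip structures and reflection loops", {
  sim <- smallIamSim()
  st <- sim$structure
  refl <- sim$sim$reflections
  p <- tempfile(fileext = ".cif")
  writeCif(st, p, block = "synthetic", reflections = refl)
  back <- readCif(p, block = "synthetic")
  expect_lt(max(abs(atomSites(back$structure)$x - atomSites(st)$x)), 1e-6)
  expect_lt(max(abs(atomSites(back$structure)$u11 - atomSites(st)$u11),
                na.rm = TRUE), 1e-6)  # printed precision of the writer
  expect_equal(back$structure@spaceGroup@symbol, "Pbca")
  expect_length(back$structure@spaceGroup@rotations, 8)
  expect_equal(back$reflections@hkl, refl@hkl)
  expect_equal(back$reflections@fobs2, refl@fobs2, tolerance = 1e-4)
  expect_equal(atomSites(back$structure)$partId, atomSites(st)$partId)
  # isotropic-only CIF parses without aniso loop
  iso <- st
  iso@sites$adpType <- "iso"; iso@sites$uiso <- 0.03
  writeCif(iso, p)
  backIso <- readCif(p)
  expect_true(all(atomSites(backIso$structure)$adpType == "iso"))
  # missing mandatory items are reported by tag
  writeLines(c("data_x", "_cell_length_a 10"), p)
  expect_error(readCif(p), "_cell_length_b")
})

test_that("HKLF4 files parse, reject bad sigmas and round-trip byte-identically", {
  cell <- unitCell(10, 11, 12)
  p <- tempfile(fileext = ".hkl")
  writeLines(c("   1   0   0  123.45    2.50",
               "   0   2   0   -4.25    1.10",
               "   1   1   1    0.00    0.75",
               "   0   0   0    0.00    0.00"), p)
  refl <- readHklf4(p, cell)
  expect_equal(nrow(refl@hkl), 3)
  expect_equal(refl@fobs2[2], -4.25)  # negative intensities kept
  writeLines(c("   1   0   0  123.45   -2.50",
               "   0   0   0    0.00    0.00"), p)
  expect_error(readHklf4(p, cell), "line 1")
  writeLines("   1   0", p)
  expect_error(readHklf4(p, cell), "line 1")
  # round trip
  sim <- smallIamSim()$sim$reflections
  p2 <- tempfile(fileext = ".hkl"); p3 <- tempfile(fileext = ".hkl")
  writeHklf4(sim, p2)
  writeHklf4(readHklf4(p2, unitCell(15.35, 13.56, 16.50)), p3)
  expect_identical(readLines(p2), readLines(p3))
})

test_that("duplicate reflections merge by inverse-variance averaging", {
  cell <- unitCell(10, 10, 10)
  expect_warning(
    rs <- reflectionSet(rbind(c(1, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                        fobs2 = c(10, 16, 5), sigma = c(1, 2, 1), cell),
    "merged")
  expect_equal(nrow(rs@hkl), 2)
  w <- c(1, 1 / 4)
  expect_equal(rs@fobs2[1], sum(w * c(10, 16)) / sum(w))
  expect_equal(rs@sigma[1], sqrt(1 / sum(w)))
  expect_error(reflectionSet(rbind(c(1, 0, 0)), 5, 0, cell), "sigma")
})

test_that("cube and XYZ files round-trip", {
  set.seed(8)
  g <- densityGrid(array(runif(4 * 5 * 6), c(4, 5, 6)),
                   origin = c(-1, 0, 0.5), step = c(0.25, 0.25, 0.25))
  atoms <- data.frame(element = c("Fe", "O"), x = c(0, 1.9),
                      y = c(0, 0), z = c(0.2, 0))
  p <- tempfile(fileext = ".cube")
  writeCube(g, p, atoms)
  back <- readCube(p)
  expect_equal(back$grid@values, g@values, tolerance = 1e-4)
  expect_equal(back$grid@origin, g@origin, tolerance = 1e-5)
  expect_equal(back$atoms$element, c("Fe", "O"))
  p2 <- tempfile(fileext = ".xyz")
  writeXyz(atoms, p2)
  expect_equal(readXyz(p2)$x, atoms$x, tolerance = 1e-6)
})
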