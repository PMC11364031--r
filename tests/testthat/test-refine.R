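test_that("the weighting scheme reproduces hand-computed values", {
  expect_equal(refinementWeights(4, 2, 4, 0, 0), 1 / 4)
  # P = (3 + 2*3)/3 = 3; w = 1/(1 + (1*3)^2) = 0.1
  expect_equal(refinementWeights(3, 1, 3, a = 1, b = 0), 0.1)
  # published-style optimized weights, evaluated by hand:
  a <- 0.1483; b <- 5.0209
  fo2 <- 250; sig <- 12; fc2 <- 240
  P <- (fo2 + 2 * fc2) / 3
  expect_equal(refinementWeights(fo2, sig, fc2, a, b),
               1 / (sig^2 + (a * P)^2 + b * P))
  # negative observed intensities are floored inside P
  expect_equal(refinementWeights(-5, 2, 6, 1, 1),
               1 / (4 + ((-5 + 5 + 2 * 6) / 3)^2 + (2 * 6 + 0) / 3))
  expect_error(refinementWeights(1, 0, 1), "sigma")
})

test_that("R factors and GooF match their definitions and a naive loop", {
  set.seed(3)
  fo2 <- rexp(100, 1 / 50); sig <- sqrt(fo2) + 1
  expect_equal(rFactors(fo2, sig, fo2)$R1_all, 0)
  expect_equal(rFactors(fo2, sig, fo2)$R1_strong, 0)
  # uniform 10 % amplitude overestimate
  r <- rFactors(fo2, sig, fo2 * 1.1^2, scale = 1, cut = 0)
  expect_equal(r$R1_all, 0.1, tolerance = 1e-12)
  # naive-loop oracle
  fc2 <- fo2 * (1 + rnorm(100, 0, 0.1))
  k <- 1.07
  r2 <- rFactors(fo2, sig, fc2, scale = k, cut = 4)
  fo <- sqrt(pmax(fo2, 0)); sf <- sig / (2 * pmax(fo, sqrt(sig)))
  fc <- sqrt(k * pmax(fc2, 0))
  strong <- fo > 4 * sf
  expect_equal(r2$R1_strong, sum(abs(fo[strong] - fc[strong])) / sum(fo[strong]),
               tolerance = 1e-12)
  expect_equal(r2$wR2,
               sqrt(sum((fo2 - k * fc2)^2 / sig^2) / sum(fo2^2 / sig^2)),
               tolerance = 1e-12)
  # GooF
  w <- 1 / sig^2
  expect_equal(goodnessOfFit(fo2, fo2, w, 10), 0)
  resid <- fo2 + sig
  expect_equal(goodnessOfFit(resid, fo2, w, 10),
               sqrt(100 / 90), tolerance = 1e-12)
  expect_equal(goodnessOfFit(fo2, fc2, w, 7, scale = k),
               sqrt(sum(w * (fo2 - k * fc2)^2) / 93), tolerance = 1e-12)
  expect_error(goodnessOfFit(fo2, fc2, w, 100), "freedom")
})

test_that("shell R1 with locked parameters equals filtered recomputation", {
  sim <- smallIamSim()
  refl <- sim$sim$reflections
  fc2 <- sim$sim$fcalc2 * (1 + 0.05 * sin(seq_along(sim$sim$fcalc2)))
  whole <- shellR1(refl, fc2, 1, c(8.65, 1.3))
  expect_equal(whole$R1_strong,
               rFactors(refl@fobs2, refl@sigma, fc2)$R1_strong)
  two <- shellR1(refl, fc2, 1, c(8.65, 2.0, 1.3))
  for (i in 1:2) {
    idx <- if (i == 1) refl@d >= 2.0 else refl@d < 2.0
    expect_equal(two$R1_strong[i],
                 rFactors(refl@fobs2[idx], refl@sigma[idx], fc2[idx])$R1_strong)
    expect_equal(two$nAll[i], sum(idx))
  }
  empty <- shellR1(refl, fc2, 1, c(20, 15, 1.3))
  expect_equal(empty$nAll[1], 0)
  expect_true(is.na(empty$R1_strong[1]))
})

test_that("ellipsoid ratios are principal-axis RMS ratios", {
  cell <- unitCell(10, 10, 10)
  mk <- function(u) crystalStructure(cell, spaceGroup("P1"),
    data.frame(label = "A1", element = "C", x = 0.1, y = 0.2, z = 0.3,
               adpType = "aniso", u11 = u[1], u22 = u[2], u33 = u[3],
               u12 = u[4], u13 = u[5], u23 = u[6]))
  expect_equal(ellipsoidRatios(mk(c(0.02, 0.02, 0.02, 0, 0, 0)))$mean, 1)
  expect_equal(ellipsoidRatios(mk(c(0.04, 0.01, 0.01, 0, 0, 0)))$mean, 2)
  set.seed(5)
  A <- matrix(rnorm(9), 3); U <- crossprod(A) / 50 + diag(3) * 0.01
  r <- ellipsoidRatios(mk(c(U[1, 1], U[2, 2], U[3, 3], U[1, 2], U[1, 3],
                            U[2, 3])))$mean
  ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(r, sqrt(max(ev) / min(ev)), tolerance = 1e-10)
  # non-positive-definite tensors are flagged, not averaged
  bad <- ellipsoidRatios(mk(c(0.02, 0.02, -0.01, 0, 0, 0)))
  expect_false(bad$perAtom$ok[1])
})

test_that("model RMSDs use Cartesian coordinates and detected bonds", {
  st <- smallIamSim()$structure
  expect_equal(rmsdModels(st, st)$coordRmsd, 0)
  expect_equal(rmsdModels(st, st)$bondRmsd, 0)
  shifted <- st
  shifted@sites$x <- shifted@sites$x + 0.1 / cellParameters(st)[["a"]]
  r <- rmsdModels(st, shifted)
  expect_equal(r$coordRmsd, 0.1, tolerance = 1e-9)
  expect_equal(r$bondRmsd, 0, tolerance = 1e-9)  # rigid shift keeps bonds
  bad <- st
  bad@sites$label[1] <- "ZZ9"
  expect_error(rmsdModels(st, bad), "unmatched")
})

test_that("noise-free refinement is a fixed point and recovers perturbations", {
  sim <- smallIamSim()
  st <- sim$structure
  prov <- iamProvider(st, "electron")
  cfg <- refinementConfig(weightCycles = 1, maxIter = 15)
  fit0 <- refineLsq(st, sim$sim$reflections, prov, cfg)
  expect_lt(fit0@stats$R1_all, 1e-6)
  expect_true(fit0@converged)
  # perturb non-H coordinates by ~0.05 A (H riding along), refine, recover
  set.seed(77)
  start <- st
  sts <- start@sites
  nonH <- sts$element != "H"
  shift <- matrix(0, nrow(sts), 3)
  shift[nonH, ] <- matrix(rnorm(3 * sum(nonH), 0, 0.05), ncol = 3) %*%
    t(solve(orthoMatrix(st@cell)))
  rid <- TaamKin:::.ridingTable(start)
  shift[rid$h, ] <- shift[rid$parent, ]
  sts[, c("x", "y", "z")] <- sts[, c("x", "y", "z")] + shift
  start@sites <- sts
  fit <- refineLsq(start, sim$sim$reflections, prov,
                   refinementConfig(weightCycles = 2, maxIter = 60))
  M <- orthoMatrix(st@cell)
  dx <- (as.matrix(fit@structure@sites[nonH, c("x", "y", "z")]) -
           as.matrix(st@sites[nonH, c("x", "y", "z")])) %*% t(M)
  expect_lt(max(abs(dx)), 1e-4)
  # riding constraint: X-H distances unchanged by refinement
  hIdx <- rid$h
  dH <- function(struct) {
    xyz <- as.matrix(struct@sites[, c("x", "y", "z")]) %*% t(M)
    sqrt(rowSums((xyz[rid$h, , drop = FALSE] -
                    xyz[rid$parent, , drop = FALSE])^2))
  }
  expect_equal(dH(fit@structure), dH(start), tolerance = 1e-6)
  # overdetermination guard
  tiny <- reflectionSet(sim$sim$reflections@hkl[1:50, ],
                        sim$sim$reflections@fobs2[1:50],
                        sim$sim$reflections@sigma[1:50], st@cell)
  expect_error(refineLsq(st, tiny, prov, cfg), "underdetermined")
})

test_that("weight optimization flattens binned GooF and finds injected inflation", {
  sim <- smallIamSim()
  f2 <- sim$sim$fcalc2
  sig <- sim$sim$reflections@sigma
  set.seed(12)
  # noise exactly matching sigma: optimal (a, b) near zero
  fo2 <- f2 + rnorm(length(f2), 0, sig)
  ow <- optimizeWeights(fo2, sig, f2, nParams = 0,
                        d = sim$sim$reflections@d)
  # a small residual a (< 0.1) absorbs the weight-residual correlation
  # through P even for exactly matched sigmas; b stays small against the
  # sigma scale
  expect_lt(ow$a, 0.1)
  expect_lt(ow$b, stats::median(sig))
  expect_lt(ow$flatness, 4.5)
  # variance inflated proportionally to P^2: recovered a near injection
  # (binned estimation on ~1200 reflections carries sampling scatter)
  aInj <- 0.12
  P <- (pmax(fo2, 0) + 2 * f2) / 3
  fo2b <- f2 + rnorm(length(f2), 0, sqrt(sig^2 + (aInj * P)^2))
  ow2 <- optimizeWeights(fo2b, sig, f2, nParams = 0,
                         d = sim$sim$reflections@d)
  expect_lt(abs(ow2$a - aInj), 0.08)
  expect_gt(ow2$a, ow$a)
})
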