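# RDFs, the neutron-weighted total, S(Q) and Guinier extraction.

idealGasFixture <- function(n = 400, box = 8, seed = 41) {
  set.seed(seed)
  AtomSet(data.frame(
    atomName = "SC", residueName = "MOE", residueIndex = seq_len(n),
    chainId = 1L, atomRole = "sidechain", mass = 12, element = "C",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box)),
    box = rep(box, 3))
}

test_that("an ideal gas has g(r) = 1 within sampling noise", {
  a <- idealGasFixture(n = 600)
  p <- partialRDF(a, selectionA = list(selection = "all"),
                  rMax = 3.5, binWidth = 0.1)
  mids <- (p@breaks[-1] + p@breaks[-length(p@breaks)]) / 2
  body <- p@g[mids > 0.5]
  expect_lt(max(abs(body - 1)), 0.25)
  expect_lt(abs(mean(body) - 1), 0.03)
})

test_that("a fixed pair occupies exactly the bin containing its distance", {
  a <- AtomSet(data.frame(
    atomName = "SC", residueName = "MOE", residueIndex = 1:2, chainId = 1L,
    atomRole = "sidechain", mass = 12, element = "C",
    x = c(1, 1.73), y = 1, z = 1), box = c(6, 6, 6))
  p <- partialRDF(a, selectionA = list(selection = "all"),
                  rMax = 2.5, binWidth = 0.1)
  expect_equal(which(p@g > 0), 8L)   # 0.73 nm falls in [0.7, 0.8)
})

test_that("pair histogram equals the brute-force all-pairs oracle", {
  a <- idealGasFixture(n = 180, box = 5, seed = 42)
  breaks <- seq(0, 2.4, by = 0.08)
  oracle <- bruteRDFCounts(coordsNm(a), NULL, breaks, boxDims(a))
  p <- partialRDF(a, selectionA = list(selection = "all"),
                  rMax = 2.4, binWidth = 0.08)
  vol <- prod(boxDims(a)); n <- nAtoms(a)
  shell <- 4 / 3 * pi * diff(breaks^3)
  gOracle <- oracle / (n * (n - 1) * shell / vol)
  expect_equal(p@g, gOracle, tolerance = 1e-12)
})

test_that("rMax beyond the half-box is refused", {
  a <- idealGasFixture(n = 50, box = 4)
  expect_error(partialRDF(a, selectionA = list(selection = "all"),
                          rMax = 2.5, binWidth = 0.1), "half")
})

test_that("single-species weighting collapses to the partial itself", {
  a <- idealGasFixture(n = 200)
  partials <- elementPartialRDFs(a, selection = "all", rMax = 3,
                                 binWidth = 0.1)
  expect_named(partials, "C-C")
  tot <- totalWeightedRDF(partials)
  expect_equal(tot@g, partials[["C-C"]]@g, tolerance = 1e-12)
})

test_that("equal scattering lengths cancel out of the weighted total", {
  set.seed(43)
  n <- 120
  a <- AtomSet(data.frame(
    atomName = "SC", residueName = "MOE", residueIndex = seq_len(n),
    chainId = 1L, atomRole = "sidechain", mass = 12,
    element = sample(c("C", "O"), n, replace = TRUE),
    x = runif(n, 0, 5), y = runif(n, 0, 5), z = runif(n, 0, 5)),
    box = c(5, 5, 5))
  partials <- elementPartialRDFs(a, selection = "all", rMax = 2,
                                 binWidth = 0.1)
  bEq <- c(C = 5, O = 5)
  totEq <- totalWeightedRDF(partials, blengths = bEq)
  # composition-weighted total with unit weights
  cC <- partials[["C-C"]]@densities[1]
  cO <- partials[["O-O"]]@densities[1]
  gComp <- (cC^2 * partials[["C-C"]]@g + cO^2 * partials[["O-O"]]@g +
              2 * cC * cO * partials[["C-O"]]@g) / (cC + cO)^2
  expect_equal(totEq@g, unname(gComp), tolerance = 1e-12)
})

test_that("a hand-computed two-species Faber-Ziman sum is reproduced", {
  g1 <- new("RDFProfile", breaks = 0:3, g = c(0, 2, 1),
            pairLabels = c("C", "C"), densities = c(C = 0.4, C = 0.4))
  g2 <- new("RDFProfile", breaks = 0:3, g = c(1, 1, 1),
            pairLabels = c("O", "O"), densities = c(O = 0.1, O = 0.1))
  g12 <- new("RDFProfile", breaks = 0:3, g = c(0, 0.5, 1),
             pairLabels = c("C", "O"), densities = c(C = 0.4, O = 0.1))
  b <- c(C = 2, O = -1)
  tot <- totalWeightedRDF(list("C-C" = g1, "O-O" = g2, "C-O" = g12),
                          blengths = b)
  denom <- (0.4 * 2 + 0.1 * (-1))^2
  hand <- (0.4^2 * 4 * g1@g + 0.1^2 * 1 * g2@g +
             2 * 0.4 * 0.1 * 2 * (-1) * g12@g) / denom
  expect_equal(tot@g, unname(hand), tolerance = 1e-12)
})

test_that("missing pairs and mismatched bins are rejected", {
  g1 <- new("RDFProfile", breaks = 0:3, g = c(0, 2, 1),
            pairLabels = c("C", "C"), densities = c(C = 0.4, C = 0.4))
  g12 <- new("RDFProfile", breaks = 0:3, g = c(0, 0.5, 1),
             pairLabels = c("C", "O"), densities = c(C = 0.4, O = 0.1))
  expect_error(totalWeightedRDF(list("C-C" = g1, "C-O" = g12)), "missing")
  g2bad <- new("RDFProfile", breaks = seq(0, 6, 2), g = c(1, 1, 1),
               pairLabels = c("O", "O"), densities = c(O = 0.1, O = 0.1))
  expect_error(totalWeightedRDF(list("C-C" = g1, "C-O" = g12,
                                     "O-O" = g2bad)), "binning")
})

test_that("structureless g(r) = 1 transforms to S(Q) = 1 exactly", {
  flat <- new("RDFProfile", breaks = seq(0, 5, 0.05),
              g = rep(1, 100), pairLabels = "total-weighted",
              densities = c(C = 0.5))
  for (w in c("lorch", "none")) {
    sq <- structureFactor(flat, rho = 0.5, Q = seq(0.01, 0.5, 0.01),
                          window = w)
    expect_equal(sq@S, rep(1, length(sq@Q)), tolerance = 1e-14)
  }
})

test_that("quadrature matches a closed-form transform within 1 percent", {
  # g(r) - 1 = exp(-r^2/(2 s^2)) has the analytic transform
  # 4 pi rho int r^2 h(r) sinc(Qr) dr = rho (2 pi s^2)^{3/2} exp(-Q^2 s^2/2)
  s <- 0.35; rho <- 0.8
  breaks <- seq(0, 6, by = 0.01)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  prof <- new("RDFProfile", breaks = breaks,
              g = 1 + exp(-mids^2 / (2 * s^2)),
              pairLabels = "total-weighted", densities = c(C = rho))
  Q <- seq(0.01, 0.2, by = 0.01)
  sq <- structureFactor(prof, rho = rho, Q = Q, window = "none")
  exact <- 1 + rho * (2 * pi * s^2)^(3 / 2) * exp(-(Q * 10)^2 * s^2 / 2)
  expect_equal(sq@S, exact, tolerance = 0.01)
})

test_that("doubling the bin resolution barely moves S(Q) in the Guinier window", {
  sph <- generateIdealBody("solid_sphere", size = 3, nPoints = 1500, seed = 44)
  a <- atoms(sph); a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + 20
  sphB <- AtomSet(a, box = c(40, 40, 40))
  Q <- seq(0.005, 0.1, by = 0.005)
  sqs <- lapply(c(0.04, 0.02), function(bw) {
    p <- partialRDF(sphB, selectionA = list(selection = "all"),
                    rMax = 10, binWidth = bw)
    structureFactor(p, rho = 1500 / 40^3, Q = Q)
  })
  expect_lt(max(abs(sqs[[1]]@S - sqs[[2]]@S) / sqs[[2]]@S), 0.01)
})

test_that("Guinier analysis inverts a synthetic exponential exactly", {
  Q <- seq(0.01, 0.1, length.out = 30)
  prof <- new("StructureFactorProfile", Q = Q,
              S = exp(-(Q * 10)^2 * 3^2 / 3), rho = 1, scaling = 1)
  expect_equal(guinierRg(prof), 3, tolerance = 1e-10)
  # 1 percent multiplicative noise, 50 points: within 2 percent
  set.seed(45)
  Q2 <- seq(0.005, 0.1, length.out = 50)
  noisy <- new("StructureFactorProfile", Q = Q2,
               S = exp(-(Q2 * 10)^2 * 3 / 3) * (1 + rnorm(50, 0, 0.01)),
               rho = 1, scaling = 1)
  expect_equal(guinierRg(noisy), sqrt(3), tolerance = 0.02)
  # rising S(Q) has no Guinier decay
  bad <- new("StructureFactorProfile", Q = Q,
             S = exp(+(Q * 10)^2), rho = 1, scaling = 1)
  expect_error(guinierRg(bad), "no Guinier decay")
})

test_that("forward model: Guinier Rg of a micelle matches the direct Rg", {
  sys <- generateMicelle(smallMicelleSpec(seed = 18, nChains = 6L,
                                          waterShellThickness = 0))
  f1 <- frames(sys)[[1]]
  box <- boxDims(f1)
  bigBox <- c(30, 30, 30)
  a <- atoms(selectAtoms(f1, "micelle"))
  a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] - box[1] / 2 + 15
  mic <- AtomSet(a, box = bigBox)
  partials <- elementPartialRDFs(mic, selection = "micelle", rMax = 10,
                                 binWidth = 0.02)
  tot <- totalWeightedRDF(partials)
  rho <- nAtoms(mic) / prod(bigBox)
  sq <- structureFactor(tot, rho = rho, Q = seq(0.005, 0.12, by = 0.0025))
  rgG <- guinierRg(sq, QMax = 0.1)
  rgD <- gyration(mic)@rg
  expect_lt(abs(rgG - rgD) / rgD, 0.10)
})
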