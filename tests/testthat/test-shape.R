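# Gyration tensor, shape metrics and the per-frame analysis.

test_that("two unit masses on the x axis give eigenvalues (1, 0, 0)", {
  a <- AtomSet(data.frame(
    atomName = "SC", residueName = "MOE", residueIndex = 1:2, chainId = 1L,
    atomRole = "sidechain", mass = 1, element = "C",
    x = c(-1, 1), y = 0, z = 0))
  g <- gyration(a)
  expect_equal(g@eigenvalues, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(g@rg, 1, tolerance = 1e-12)
})

test_that("tensor trace equals the direct mass-weighted second moment", {
  set.seed(21)
  a <- AtomSet(data.frame(
    atomName = "SC", residueName = "MOE", residueIndex = 1:20, chainId = 1L,
    atomRole = "sidechain", mass = runif(20, 1, 40), element = "C",
    x = rnorm(20), y = rnorm(20), z = rnorm(20)))
  tens <- gyrationTensor(a)
  at <- atoms(a)
  com <- colSums(coordsNm(a) * at$mass) / sum(at$mass)
  direct <- sum(at$mass * rowSums(sweep(coordsNm(a), 2, com)^2)) /
    sum(at$mass)
  expect_equal(sum(diag(tens)), direct, tolerance = 1e-12)
  # Rg^2 == sum of eigenvalues, both weightings
  for (w in c("mass", "scattering_length")) {
    g <- gyration(a, w)
    expect_equal(g@rg^2, sum(g@eigenvalues), tolerance = 1e-12)
  }
})

test_that("equal weights make mass and scattering tensors identical", {
  set.seed(22)
  a <- AtomSet(data.frame(
    atomName = "SC", residueName = "MOE", residueIndex = 1:15, chainId = 1L,
    atomRole = "sidechain", mass = 12.011, element = "C",
    x = rnorm(15), y = rnorm(15), z = rnorm(15)))
  tm <- gyrationTensor(a, "mass")
  tb <- gyrationTensor(a, "scattering_length")
  expect_equal(tm, tb, tolerance = 1e-12)
})

test_that("shape metrics hit the printed ideal-case values", {
  expect_equal(unname(shapeMetrics(c(1, 1, 1))), c(0, 0), tolerance = 1e-14)
  expect_equal(unname(shapeMetrics(c(1, 1, 0))[["shape"]]), -0.25,
               tolerance = 1e-14)
  expect_equal(unname(shapeMetrics(c(1, 0, 0))), c(1, 2), tolerance = 1e-14)
  expect_error(shapeMetrics(c(0, 0, 0)), "all-zero")
  expect_error(shapeMetrics(c(0, 1, 0)), "descending")
})

test_that("shape metrics scale-invariance and bounds over random spectra", {
  set.seed(23)
  for (i in 1:2000) {
    l <- sort(runif(3), decreasing = TRUE)
    m <- shapeMetrics(l)
    expect_true(m["asphericity"] >= 0 && m["asphericity"] <= 1)
    expect_true(m["shape"] >= -0.25 && m["shape"] <= 2)
    m2 <- shapeMetrics(l * 7.3)
    expect_equal(unname(m), unname(m2), tolerance = 1e-8)
  }
})

test_that("descriptors are invariant under rigid rotation and translation", {
  set.seed(24)
  sys <- generateMicelle(smallMicelleSpec(seed = 13, nChains = 3L,
                                          waterShellThickness = 0))
  f1 <- frames(sys)[[1]]
  mic <- selectAtoms(f1, "micelle")
  g0 <- gyration(mic)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  a <- atoms(mic)
  a[, c("x", "y", "z")] <- coordsNm(mic) %*% R + 5
  g1 <- gyration(AtomSet(a))
  expect_equal(g1@eigenvalues, g0@eigenvalues, tolerance = 1e-10)
  expect_equal(g1@asphericity, g0@asphericity, tolerance = 1e-10)
  expect_equal(g1@shape, g0@shape, tolerance = 1e-10)
})

test_that("stretching one ellipsoid axis strictly increases asphericity", {
  asp <- vapply(c(1, 1.5, 2.2, 3), function(s) {
    body <- generateIdealBody("ellipsoid", size = c(s, 1, 1),
                              nPoints = 30000, seed = 3)
    gyration(body)@asphericity
  }, numeric(1))
  expect_true(all(diff(asp) > 0))
})

test_that("shell-augmented Rg is at least the micelle-only Rg", {
  sys <- generateMicelle(smallMicelleSpec(seed = 14, nChains = 3L,
                                          waterShellThickness = 0.35,
                                          waterDensity = 15))
  plain <- analyzeFrames(sys)
  shell <- analyzeFrames(sys, includeShell = TRUE)
  expect_gte(shell$rg, plain$rg)
  # cross-check the shell-augmented value against a direct sum
  f1 <- unwrapMolecules(frames(sys)[[1]])
  aug <- solvationShell(f1, cutoff = 0.35)
  at <- atoms(aug)
  com <- colSums(coordsNm(aug) * at$mass) / sum(at$mass)
  direct <- sqrt(sum(at$mass * rowSums(sweep(coordsNm(aug), 2, com)^2)) /
                   sum(at$mass))
  expect_equal(shell$rg, direct, tolerance = 1e-10)
})

test_that("per-frame Rg fluctuation is consistent with the planted jitter", {
  sig <- 0.03
  sys <- generateMicelle(smallMicelleSpec(seed = 15, nChains = 4L,
                                          waterShellThickness = 0,
                                          nFrames = 12L, jitterSigma = sig))
  res <- analyzeFrames(sys)
  expect_equal(nrow(res), 12L)
  # jitter adds ~sigma^2 per coordinate to Rg^2 in expectation:
  # Rg^2(jittered) ~ Rg0^2 + 3 sigma^2 (1 - 1/n); fluctuations stay well
  # below the jitter scale itself
  drift <- abs(res$rg[-1] - res$rg[1])
  expect_lt(max(drift), 10 * sig)
  expect_gt(stats::sd(res$rg[-1]), 0)
})

test_that("empty selections abort naming the frame", {
  sys <- generateMicelle(smallMicelleSpec(seed = 16, nChains = 2L,
                                          waterShellThickness = 0))
  f1 <- frames(sys)[[1]]
  a <- atoms(f1)
  noDec <- MicelleSystem(AtomSet(a[a$residueName != "DEC", , drop = FALSE],
                                 box = boxDims(f1)),
                         nChains(sys), chainSequence(sys))
  expect_error(suppressMessages(analyzeFrames(noDec, selection = "core")),
               "frame 1")
})

test_that("near-zero net scattering length triggers the warning", {
  # hydrogens only: b(1H) < 0, so a tiny selection can cross zero
  a <- AtomSet(data.frame(
    atomName = "HW1", residueName = "WAT", residueIndex = 1:3, chainId = 0L,
    atomRole = "water_hydrogen", mass = 1.008, element = "H",
    x = c(0, 1, 2), y = 0, z = 0))
  at <- atoms(a)
  at$element <- c("H", "H", "D")  # net b: 2(-3.739) + 6.671 = -0.81 fm
  a2 <- AtomSet(at)
  expect_warning(gyrationTensor(a2, "scattering_length"), "1 fm")
})
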