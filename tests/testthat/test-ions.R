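# Coordination, neighbor distances, salt bridges, condensation.

test_that("a sodium planted at 0.30 nm of one oxygen is coordinated once", {
  a <- twoChainFixture(ccDist = 1.4, naPos = c(0.12 + 0.30, 0.05, 0))
  h <- coordinationHistogram(a, "sodium", cutoff = 0.35)
  # one group sees the ion, the other does not
  expect_equal(unname(h@counts), c(1, 1))
  expect_equal(sum(h@probabilities), 1)
})

test_that("a partner at exactly the cutoff is excluded (strict <)", {
  a <- twoChainFixture(ccDist = 5, naPos = c(0.12 + 0.35, 0.05, 0))
  h <- coordinationHistogram(a, "sodium", cutoff = 0.35)
  expect_equal(unname(h@counts[1]), 2)  # both groups see nothing
  aIn <- twoChainFixture(ccDist = 5, naPos = c(0.12 + 0.349, 0.05, 0))
  hIn <- coordinationHistogram(aIn, "sodium", cutoff = 0.35)
  expect_equal(sum(as.integer(names(hIn@counts)) *
                     hIn@counts), 1)
})

test_that("water coordination equals the brute-force all-pairs count", {
  bath <- waterBathFixture(nWater = 100, seed = 51)
  oracle <- bruteCoordination(bath, "water_oxygen", 0.35)
  h <- coordinationHistogram(bath, "water_oxygen", cutoff = 0.35)
  got <- rep(as.integer(names(h@counts)), h@counts)
  expect_equal(sort(got), sort(oracle))
})

test_that("two mutually nearest carboxylates record the same distance", {
  a <- twoChainFixture(ccDist = 0.8)
  nn <- nearestInterchainCarboxylate(a)
  expect_equal(nn@distances, c(0.8, 0.8), tolerance = 1e-12)
})

test_that("a triangle of charged chains gives enumerated nearest distances", {
  # chains at pairwise carbon distances 0.5, 0.7, 0.9
  # place carbons at coordinates realizing those distances
  ax <- c(0, 0, 0); bx <- c(0.5, 0, 0)
  # |c - a| = 0.7, |c - b| = 0.9
  cxv <- (0.5^2 + 0.7^2 - 0.9^2) / (2 * 0.5)
  cyv <- sqrt(0.7^2 - cxv^2)
  rows <- do.call(rbind, Map(function(p, ch) rbind(
    atomRow("carboxylate_carbon", p[1], p[2], p[3], chain = ch, resi = 1L),
    atomRow("carboxylate_oxygen", p[1] + 0.1, p[2] + 0.05, p[3], chain = ch,
            resi = 1L),
    atomRow("carboxylate_oxygen", p[1] - 0.1, p[2] + 0.05, p[3], chain = ch,
            resi = 1L, name = "OD2")),
    list(ax, bx, c(cxv, cyv, 0)), 1:3))
  rows <- rbind(rows, atomRow("sodium", 3, 3, 3, chain = 0L, resi = 9L))
  a <- AtomSet(rows)
  nn <- nearestInterchainCarboxylate(a)
  expect_equal(sort(nn@distances), c(0.5, 0.5, 0.7), tolerance = 1e-12)
})

test_that("neighbor distances equal the brute-force scan on a generated micelle", {
  sys <- generateMicelle(smallMicelleSpec(seed = 52, waterShellThickness = 0))
  nn <- nearestInterchainCarboxylate(sys)
  oracle <- bruteNearestInterchain(frames(sys)[[1]])
  expect_equal(nn@distances, oracle, tolerance = 1e-12)
  # KDE density integrates to unit area
  area <- sum(nn@kde$y) * mean(diff(nn@kde$x))
  expect_equal(area, 1, tolerance = 1e-6)
})

test_that("a single charged chain cannot yield interchain distances", {
  rows <- rbind(
    atomRow("carboxylate_carbon", 0, 0, 0, chain = 1L, resi = 1L),
    atomRow("carboxylate_oxygen", 0.1, 0, 0, chain = 1L, resi = 1L),
    atomRow("carboxylate_oxygen", -0.1, 0, 0, chain = 1L, resi = 1L,
            name = "OD2"),
    atomRow("sodium", 1, 1, 1, chain = 0L, resi = 2L))
  expect_error(nearestInterchainCarboxylate(AtomSet(rows)), "two chains")
})

test_that("a planted equidistant sodium is counted as a bridge", {
  # carbons 0.45 nm apart, sodium 0.4 nm from both
  h <- sqrt(0.4^2 - 0.225^2)
  a <- twoChainFixture(ccDist = 0.45, naPos = c(0.225, -h, 0))
  rep <- saltBridges(a)
  expect_equal(nrow(rep@bridges), 1L)
  expect_equal(rep@fraction05, 100)
})

test_that("a one-sided sodium is not a bridge", {
  a <- twoChainFixture(ccDist = 0.45, naPos = c(-0.4, 0, 0))
  # sodium at 0.40 nm from carbon A but 0.85 nm from carbon B
  rep <- saltBridges(a)
  expect_equal(nrow(rep@bridges), 0L)
  expect_equal(rep@fraction05, 0)
})

test_that("bridge fractions equal the exhaustive oracle on planted systems", {
  for (seed in c(53, 54)) {
    sys <- generateMicelle(smallMicelleSpec(seed = seed,
                                            plantedSaltBridges = 2L,
                                            waterShellThickness = 0))
    f1 <- frames(sys)[[1]]
    oracle <- bruteBridgeStats(f1)
    rep <- saltBridges(sys)
    expect_equal(rep@fraction05, oracle$frac[1])
    expect_equal(rep@fraction10, oracle$frac[2])
    expect_equal(unname(rep@qualifying), oracle$qual)
  }
})

test_that("planted condensation fractions are recovered within one ion", {
  for (f in c(0, 0.25)) {
    sys <- generateMicelle(smallMicelleSpec(seed = 55,
                                            naCondensationFraction = f,
                                            waterShellThickness = 0))
    nNa <- attr(sys, "groundTruth")$nSodium
    got <- condensedFraction(sys)
    expect_lte(abs(got - 100 * round(f * nNa) / nNa), 100 / nNa + 1e-9)
  }
})

test_that("statistics are invariant under chain relabeling and atom order", {
  sys <- generateMicelle(smallMicelleSpec(seed = 56, plantedSaltBridges = 1L,
                                          waterShellThickness = 0))
  f1 <- frames(sys)[[1]]
  rep0 <- saltBridges(f1)
  a <- atoms(f1)
  perm <- sample(seq_len(nrow(a)))
  a2 <- a[perm, , drop = FALSE]
  # relabel chains by a permutation
  map <- sample(nChains(sys))
  a2$chainId[a2$chainId > 0] <- map[a2$chainId[a2$chainId > 0]]
  rep1 <- saltBridges(AtomSet(a2, box = boxDims(f1)))
  expect_equal(rep1@fraction05, rep0@fraction05)
  expect_equal(rep1@fraction10, rep0@fraction10)
  expect_equal(rep1@condensedFraction, rep0@condensedFraction)
  expect_equal(nrow(rep1@bridges), nrow(rep0@bridges))
  h0 <- coordinationHistogram(f1, "sodium")
  h1 <- coordinationHistogram(AtomSet(a2, box = boxDims(f1)), "sodium")
  expect_equal(sort(rep(as.integer(names(h0@counts)), h0@counts)),
               sort(rep(as.integer(names(h1@counts)), h1@counts)))
})

test_that("the 0.5 nm fraction may exceed the 1.0 nm fraction", {
  # two close bridged pairs, one distant unbridged pair within 1.0 nm:
  # fraction05 = 100%, fraction10 < 100%
  h <- sqrt(0.4^2 - 0.225^2)
  rows <- rbind(
    atoms(twoChainFixture(ccDist = 0.45, naPos = c(0.225, -h, 0))))
  far <- atoms(twoChainFixture(ccDist = 0.9))
  far$chainId <- far$chainId + 2L
  far[, c("x", "y", "z")] <- far[, c("x", "y", "z")] + 5
  a <- AtomSet(rbind(rows, far))
  rep <- saltBridges(a)
  expect_equal(rep@fraction05, 100)
  expect_lt(rep@fraction10, rep@fraction05)
})
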