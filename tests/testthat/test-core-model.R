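# Readers/writers, selections and the solvation shell.

test_that("a hand-written PDB with a sodium ion parses to the right roles", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CG  COE A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  OD1 COE A   1       1.200   0.500   0.000  1.00  0.00           O",
    "ATOM      3  NA   NA 0   2       3.000   0.000   0.000  1.00  0.00          NA",
    "END"), tf)
  a <- readConfiguration(tf)
  expect_s4_class(a, "AtomSet")
  expect_equal(nAtoms(a), 3L)
  expect_equal(sum(atoms(a)$atomRole == "sodium"), 1L)
  # PDB Angstroms become nm on read
  expect_equal(unname(coordsNm(a)[2, 1]), 0.12)
  expect_equal(atoms(a)$chainId, c(1L, 1L, 0L))
})

test_that("a GRO box line is read as nm box vector", {
  tf <- tempfile(fileext = ".gro")
  writeLines(c("toy", "    1",
               "    1NA      NA    1   1.000   2.000   3.000",
               "  25.00000  25.00000  25.00000"), tf)
  a <- readConfiguration(tf)
  expect_equal(boxDims(a), c(25, 25, 25))
  expect_equal(unname(coordsNm(a)[1, ]), c(1, 2, 3))
})

test_that("unknown residue tokens are rejected by name", {
  tf <- tempfile(fileext = ".gro")
  writeLines(c("toy", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       1L, "XYZ", "BB", 1L, 1, 2, 3),
               "   5.00000   5.00000   5.00000"), tf)
  expect_error(readConfiguration(tf), "XYZ")
})

test_that("write/read round-trips preserve atoms, order, chains and coords", {
  sys <- generateMicelle(smallMicelleSpec(seed = 4, nChains = 3L,
                                          waterShellThickness = 0.2))
  f1 <- frames(sys)[[1]]
  for (fmt in c("gro", "pdb")) {
    tf <- tempfile(fileext = paste0(".", fmt))
    writeConfiguration(f1, tf)
    r <- readConfiguration(tf)
    expect_equal(nAtoms(r), nAtoms(f1))
    expect_identical(atoms(r)$atomRole, atoms(f1)$atomRole)
    expect_identical(atoms(r)$chainId, atoms(f1)$chainId)
    tol <- if (fmt == "gro") 5e-4 else 5e-5  # format precision in nm
    expect_lt(max(abs(coordsNm(r) - coordsNm(f1))), tol + 1e-12)
  }
})

test_that("multi-frame files round-trip frame by frame", {
  sys <- generateMicelle(smallMicelleSpec(seed = 9, nChains = 2L,
                                          waterShellThickness = 0,
                                          nFrames = 3L))
  for (fmt in c("gro", "pdb")) {
    tf <- tempfile(fileext = paste0(".", fmt))
    writeConfiguration(sys, tf)
    r <- readConfiguration(tf)
    expect_length(r, 3L)
    expect_lt(max(abs(coordsNm(r[[3]]) - coordsNm(frames(sys)[[3]]))), 1e-3)
  }
})

test_that("named selections behave as the analyses expect", {
  sys <- generateMicelle(smallMicelleSpec(seed = 2, nChains = 4L,
                                          waterShellThickness = 0.25))
  f1 <- frames(sys)[[1]]
  # one COO- group carries exactly two oxygens
  oneCOE <- selectAtoms(f1, role = "carboxylate_oxygen", chain = 1L)
  expect_equal(nAtoms(oneCOE),
               2L * length(chainSequence(sys)@chargePositions))
  # the DEC block spans 5 residues per chain
  core1 <- selectAtoms(f1, residue = "DEC", chain = 1L)
  expect_equal(length(unique(atoms(core1)$residueIndex)), 5L)
  # idempotence
  s1 <- selectAtoms(f1, "core")
  s2 <- selectAtoms(s1, "core")
  expect_identical(atoms(s1), atoms(s2))
  # partition: core + corona == micelle
  core <- selectAtoms(f1, "core")
  corona <- selectAtoms(f1, "corona")
  mic <- selectAtoms(f1, "micelle")
  expect_setequal(c(atoms(core)$id, atoms(corona)$id), atoms(mic)$id)
  # empty selection is legal, flagged by message
  expect_message(selectAtoms(f1, residue = "DEC", role = "sodium"),
                 "no atoms")
})

test_that("solvation shell applies the oxygen-decides whole-molecule rule", {
  solute <- atomRow("sidechain", 2, 2, 2)
  nearW <- rbind(
    atomRow("water_oxygen", 2.30, 2, 2, chain = 0L, resi = 2L),
    atomRow("water_hydrogen", 2.38, 2, 2, chain = 0L, resi = 2L))
  farW <- rbind(  # oxygen at 0.36 nm: just beyond the 0.35 nm cutoff
    atomRow("water_oxygen", 2.36, 2, 2, chain = 0L, resi = 3L),
    atomRow("water_hydrogen", 2.30, 2, 2, chain = 0L, resi = 3L))
  a <- AtomSet(rbind(solute, nearW, farW), box = c(5, 5, 5))
  sh <- solvationShell(a, cutoff = 0.35)
  ri <- unique(atoms(sh)$residueIndex[atoms(sh)$atomRole == "water_oxygen"])
  expect_equal(ri, 2L)                       # 0.30 nm in, 0.36 nm out
  expect_equal(sum(atoms(sh)$atomRole == "water_hydrogen"), 1L)
})

test_that("solvation shell matches a brute-force scan and is rigid-motion/wrap invariant", {
  sys <- generateMicelle(smallMicelleSpec(seed = 6, nChains = 2L,
                                          waterShellThickness = 0.35,
                                          waterDensity = 12))
  f1 <- frames(sys)[[1]]
  a <- atoms(f1); xyz <- coordsNm(f1); box <- boxDims(f1)
  sol <- which(!(a$residueName %in% c("WAT", "NA")))
  ow <- which(a$atomRole == "water_oxygen")
  inShell <- vapply(ow, function(o) {
    any(vapply(sol, function(s)
      minImageDist(xyz[o, ], xyz[s, ], box) < 0.35, logical(1)))
  }, logical(1))
  expected <- sort(a$residueIndex[ow[inShell]])
  sh <- solvationShell(f1, cutoff = 0.35)
  got <- sort(unique(atoms(sh)$residueIndex[
    atoms(sh)$atomRole == "water_oxygen"]))
  expect_identical(got, expected)

  # rigid translation plus periodic wrapping must not change membership
  a2 <- a
  a2[, c("x", "y", "z")] <-
    (as.matrix(a[, c("x", "y", "z")]) + 1.7) %% box[1]
  f2 <- AtomSet(a2, box = box)
  sh2 <- solvationShell(f2, cutoff = 0.35)
  expect_identical(sort(unique(atoms(sh2)$residueIndex[
    atoms(sh2)$atomRole == "water_oxygen"])), expected)
})

test_that("unwrapping restores a molecule split across the boundary", {
  sys <- generateMicelle(smallMicelleSpec(seed = 3, nChains = 2L,
                                          waterShellThickness = 0))
  f1 <- frames(sys)[[1]]
  box <- boxDims(f1)
  g0 <- gyration(selectAtoms(unwrapMolecules(f1), "micelle"))
  # push the micelle into a box corner so wrapping splits it, then wrap
  a <- atoms(f1)
  a[, c("x", "y", "z")] <-
    (as.matrix(a[, c("x", "y", "z")]) + box[1] / 2) %% box[1]
  fw <- AtomSet(a, box = box)
  g1 <- gyration(selectAtoms(unwrapMolecules(fw), "micelle"))
  expect_equal(g1@rg, g0@rg, tolerance = 1e-10)
})
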