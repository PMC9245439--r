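#' @include atoms.R pbc.R select.R
NULL

#' Construct a SyntheticMicelleSpec
#'
#' Parameters of the synthetic micelle generator. Defaults emulate the
#' chain-1 system: aggregation number 28, a 25-mer with a 5-residue DEC
#' block and one COE at the chain end, a compact hydrophobic core of
#' radius 1.2 nm, a 1.8 nm hydrophilic corona, a 0.5 nm explicit hydration
#' shell at liquid-water number density (33.3 molecules/nm^3), one sodium
#' counterion per carboxylate with a 10 percent planted condensation
#' fraction (most counterions dispersed, as observed for singly charged
#' micelles), and no planted salt bridges.
#'
#' @param nChains aggregation number N.
#' @param sequence a [ChainSequence-class].
#' @param coreRadius hydrophobic core radius, nm.
#' @param coronaThickness corona shell thickness, nm.
#' @param waterShellThickness explicit hydration shell thickness, nm.
#' @param waterDensity water number density in the shell, molecules/nm^3.
#' @param naCondensationFraction fraction of sodium ions planted strictly
#'   within 0.35 nm of a carboxylate oxygen (0-1).
#' @param plantedSaltBridges number of planted COO-Na-COO interchain
#'   bridges (sodium within 0.5 nm of both carboxylate carbons, carbons
#'   closer than 0.5 nm).
#' @param aspectRatios relative semi-axes (a, b, c) of the core ellipsoid.
#' @param nFrames number of frames; frames beyond the first add Gaussian
#'   jitter of `jitterSigma` to every coordinate.
#' @param jitterSigma per-coordinate jitter standard deviation, nm.
#' @param chargeSurfaceBias 0-1; how strongly carboxylate side groups are
#'   pulled toward the outer micelle surface (0 keeps them at their
#'   backbone radius).
#' @param seed RNG seed; same seed gives byte-identical output.
#' @return A [SyntheticMicelleSpec-class].
#' @export
#' @examples
#' spec <- SyntheticMicelleSpec(nChains = 6, waterShellThickness = 0.3)
SyntheticMicelleSpec <- function(nChains = 28L,
                                 sequence = ChainSequence(25L),
                                 coreRadius = 1.2,
                                 coronaThickness = 1.8,
                                 waterShellThickness = 0.5,
                                 waterDensity = 33.3,
                                 naCondensationFraction = 0.1,
                                 plantedSaltBridges = 0L,
                                 aspectRatios = c(1, 1, 1),
                                 nFrames = 1L,
                                 jitterSigma = 0.02,
                                 chargeSurfaceBias = 0.5,
                                 seed = 1L) {
  methods::new("SyntheticMicelleSpec",
               nChains = as.integer(nChains), sequence = sequence,
               coreRadius = coreRadius, coronaThickness = coronaThickness,
               waterShellThickness = waterShellThickness,
               waterDensity = waterDensity,
               naCondensationFraction = naCondensationFraction,
               plantedSaltBridges = as.integer(plantedSaltBridges),
               aspectRatios = as.numeric(aspectRatios),
               nFrames = as.integer(nFrames), jitterSigma = jitterSigma,
               chargeSurfaceBias = chargeSurfaceBias, seed = as.integer(seed))
}

setMethod("show", "SyntheticMicelleSpec", function(object) {
  cat(sprintf(paste0(
    "SyntheticMicelleSpec: N = %d chains, %d charge(s)/chain, core %.2f nm,",
    " corona %.2f nm\n  condensation fraction %.2f, %d planted bridge(s),",
    " %d frame(s), seed %d\n"),
    object@nChains, length(object@sequence@chargePositions),
    object@coreRadius, object@coronaThickness,
    object@naCondensationFraction, object@plantedSaltBridges,
    object@nFrames, object@seed))
})

.unitVec <- function(v) v / sqrt(sum(v^2))

.randomUnit <- function(n = 1L) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# a unit vector perpendicular to u
.perpUnit <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unitVec(ref - sum(ref * u) * u)
}

#' Generate a synthetic micelle with planted structural ground truth
#'
#' Builds a coarse-grained (one bead per heavy group) micelle
#' configuration: the DEC blocks fill an ellipsoidal core, the hydrophilic
#' residues a surrounding corona with carboxylate side groups biased toward
#' the outer surface, one sodium per carboxylate with a planted condensed
#' fraction (strictly within 0.35 nm of a carboxylate oxygen) and planted
#' interchain COO-Na-COO salt bridges, and an explicit 3-site water shell
#' filled by rejection sampling with a hard 0.25 nm inter-bead floor.
#' Everything is reproducible from the spec seed.
#'
#' The planted ground truth (condensed sodium count, bridge geometry,
#' water count) is attached as `attr(x, "groundTruth")`.
#'
#' @param spec a [SyntheticMicelleSpec-class].
#' @return A [MicelleSystem-class] with `spec@nFrames` frames.
#' @export
#' @examples
#' sys <- generateMicelle(SyntheticMicelleSpec(
#'   nChains = 4, waterShellThickness = 0.3, seed = 7))
#' nChains(sys)
generateMicelle <- function(spec) {
  stopifnot(methods::is(spec, "SyntheticMicelleSpec"))
  methods::validObject(spec)
  set.seed(spec@seed)
  seqr <- spec@sequence@residues
  nRes <- length(seqr)
  nCharge <- length(spec@sequence@chargePositions)
  nNa <- spec@nChains * nCharge
  k <- spec@plantedSaltBridges
  if (k > 0 && nNa < k)
    stop("cannot plant ", k, " bridges with only ", nNa, " sodium ions")
  if (k > 0 && (nCharge == 0 || spec@nChains < 2))
    stop("planted bridges need carboxylate groups on at least two chains")
  Rcore <- spec@coreRadius
  Rout <- Rcore + spec@coronaThickness

  ## ---- polymer beads ----------------------------------------------------
  rows <- list()
  dirs <- .randomUnit(spec@nChains)
  nDec <- sum(seqr == "DEC")
  for (ch in seq_len(spec@nChains)) {
    u <- dirs[ch, ]
    prev <- NULL
    for (ri in seq_len(nRes)) {
      # target radius: DEC block inside the core, hydrophilic block through
      # the corona; lateral random walk gives chains realistic bead spacing
      rTarget <- if (ri <= nDec) Rcore * (0.25 + 0.7 * (ri - 0.5) / nDec)
                 else Rcore + spec@coronaThickness * (ri - nDec - 0.4) / (nRes - nDec)
      if (is.null(prev)) {
        pos <- rTarget * u
      } else {
        lat <- .perpUnit(u)
        lat2 <- pracmaCross(u, lat)
        ang <- stats::runif(1, 0, 2 * pi)
        step <- 0.33 * (cos(ang) * lat + sin(ang) * lat2)
        pos <- prev + step
        pos <- rTarget * .unitVec(pos)  # project back to its shell radius
      }
      prev <- pos
      bb <- pos * spec@aspectRatios
      res <- seqr[ri]
      rows[[length(rows) + 1L]] <- data.frame(
        atomName = "BB", residueName = res, residueIndex = ri, chainId = ch,
        atomRole = "backbone", x = bb[1], y = bb[2], z = bb[3])
      # side group, radially outward of the backbone bead
      if (res == "COE") {
        rg <- rTarget + spec@chargeSurfaceBias * (Rout - rTarget)
        g0 <- (rg * .unitVec(pos)) * spec@aspectRatios
        out <- .unitVec(g0)
        sc <- g0; cg <- g0 + 0.15 * out
        o1 <- cg + 0.125 * .unitVec(out + 0.6 * .perpUnit(out))
        o2 <- cg + 0.125 * .unitVec(out - 0.6 * .perpUnit(out))
        rows[[length(rows) + 1L]] <- data.frame(
          atomName = c("SC", "CG", "OD1", "OD2"), residueName = res,
          residueIndex = ri, chainId = ch,
          atomRole = c("sidechain", "carboxylate_carbon",
                       "carboxylate_oxygen", "carboxylate_oxygen"),
          x = c(sc[1], cg[1], o1[1], o2[1]),
          y = c(sc[2], cg[2], o1[2], o2[2]),
          z = c(sc[3], cg[3], o1[3], o2[3]))
      } else {
        sc <- bb + 0.15 * .unitVec(bb)
        rows[[length(rows) + 1L]] <- data.frame(
          atomName = "SC", residueName = res, residueIndex = ri, chainId = ch,
          atomRole = "sidechain", x = sc[1], y = sc[2], z = sc[3])
      }
    }
  }
  poly <- do.call(rbind, rows)

  ## ---- planted salt bridges --------------------------------------------
  polyXYZ <- function() as.matrix(poly[, c("x", "y", "z")])
  carbIdx <- function() which(poly$atomRole == "carboxylate_carbon")
  oxIdx <- function() which(poly$atomRole == "carboxylate_oxygen")
  groupKey <- function(i) paste(poly$chainId[i], poly$residueIndex[i])

  nCond <- round(spec@naCondensationFraction * nNa)
  naPos <- matrix(numeric(0), 0, 3)
  naCondensedPlan <- logical(0)
  usedGroups <- character(0)
  kCondBridges <- min(k, nCond)
  if (k > 0) {
    ci <- carbIdx()
    groups <- data.frame(idx = ci, chain = poly$chainId[ci],
                         key = vapply(ci, groupKey, ""))
    if (nrow(groups) < 2L) stop("planted bridges need at least two groups")
    placed <- 0L
    tries <- 0L
    while (placed < k) {
      tries <- tries + 1L
      if (tries > 200L * k)
        stop("could not plant the requested salt bridges after bounded retries")
      avail <- groups[!(groups$key %in% usedGroups), ]
      if (nrow(avail) < 2L || length(unique(avail$chain)) < 2L)
        stop("not enough carboxylate groups on distinct chains to plant ",
             k, " bridges")
      gA <- avail[sample(nrow(avail), 1L), ]
      gBpool <- avail[avail$chain != gA$chain, ]
      gB <- gBpool[sample(nrow(gBpool), 1L), ]
      c1 <- as.numeric(poly[gA$idx, c("x", "y", "z")])
      tdir <- .perpUnit(.unitVec(c1))
      ang <- stats::runif(1, 0, 2 * pi)
      t2 <- pracmaCross(.unitVec(c1), tdir)
      tv <- cos(ang) * tdir + sin(ang) * t2
      c2 <- c1 + 0.45 * tv
      mid <- (c1 + c2) / 2
      nrm <- .unitVec(-mid)  # point the sodium inward
      nrm <- .unitVec(nrm - sum(nrm * tv) * tv)
      na <- mid + 0.32 * nrm
      # keep the planted sodium clear of every uninvolved carboxylate oxygen
      others <- setdiff(oxIdx(),
                        which(groupKey(seq_len(nrow(poly))) %in%
                                c(gA$key, gB$key)))
      if (length(others)) {
        dmin <- min(sqrt(rowSums(
          sweep(polyXYZ()[others, , drop = FALSE], 2, na)^2)))
        if (dmin < 0.45) next
      }
      condensedThis <- placed < kCondBridges
      # rebuild the oxygens of both groups around the planted geometry
      reOx <- function(cc, towardNa) {
        uNa <- .unitVec(na - cc)
        if (towardNa) {
          oA <- cc + 0.125 * uNa                 # condensed contact ~0.266 nm
          oB <- cc + 0.125 * .unitVec(-uNa + 0.8 * .perpUnit(uNa))
        } else {
          oA <- cc + 0.125 * .unitVec(-uNa + 0.5 * .perpUnit(uNa))
          oB <- cc + 0.125 * .unitVec(-uNa - 0.5 * .perpUnit(uNa))
        }
        rbind(oA, oB)
      }
      # move group B beside group A and rewrite both groups' geometry
      moveGroup <- function(key, cc) {
        sel <- which(vapply(seq_len(nrow(poly)), groupKey, "") == key &
                       poly$atomRole %in% c("sidechain", "carboxylate_carbon",
                                            "carboxylate_oxygen"))
        cgSel <- sel[poly$atomRole[sel] == "carboxylate_carbon"]
        shift <- cc - as.numeric(poly[cgSel, c("x", "y", "z")])
        poly[sel, c("x", "y", "z")] <<-
          sweep(as.matrix(poly[sel, c("x", "y", "z")]), 2, -shift)
      }
      moveGroup(gB$key, c2)
      oxySel <- function(key) which(
        vapply(seq_len(nrow(poly)), groupKey, "") == key &
          poly$atomRole == "carboxylate_oxygen")
      poly[oxySel(gA$key), c("x", "y", "z")] <- reOx(c1, condensedThis)
      poly[oxySel(gB$key), c("x", "y", "z")] <- reOx(c2, FALSE)
      naPos <- rbind(naPos, na)
      naCondensedPlan <- c(naCondensedPlan, condensedThis)
      usedGroups <- c(usedGroups, gA$key, gB$key)
      placed <- placed + 1L
    }
  }

  ## ---- remaining sodium ions -------------------------------------------
  xyzAll <- polyXYZ()
  oxAll <- xyzAll[oxIdx(), , drop = FALSE]
  nPlainCond <- nCond - kCondBridges
  for (i in seq_len(nPlainCond)) {
    ok <- FALSE
    for (tr in 1:500) {
      o <- oxAll[sample(nrow(oxAll), 1L), ]
      na <- o + stats::runif(1, 0.27, 0.32) * .unitVec(o)
      dAll <- sqrt(rowSums(sweep(rbind(xyzAll, naPos), 2, na)^2))
      if (min(dAll) >= 0.25) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place condensed sodium after bounded retries")
    naPos <- rbind(naPos, na)
    naCondensedPlan <- c(naCondensedPlan, TRUE)
  }
  nFree <- nNa - nrow(naPos)
  maxR <- max(sqrt(rowSums(xyzAll^2)))
  Rw0 <- maxR + 0.15
  Rw1 <- Rw0 + max(spec@waterShellThickness, 0.3)
  for (i in seq_len(nFree)) {
    ok <- FALSE
    for (tr in 1:500) {
      r <- (stats::runif(1, Rw0^3, Rw1^3))^(1 / 3)
      na <- r * as.numeric(.randomUnit(1))
      if (nrow(oxAll) &&
          min(sqrt(rowSums(sweep(oxAll, 2, na)^2))) < 0.45) next
      dAll <- sqrt(rowSums(sweep(rbind(xyzAll, naPos), 2, na)^2))
      if (min(dAll) >= 0.25) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place free sodium after bounded retries")
    naPos <- rbind(naPos, na)
    naCondensedPlan <- c(naCondensedPlan, FALSE)
  }

  ## ---- water shell -------------------------------------------------------
  Rin <- maxR + 0.15
  Rsh <- Rin + spec@waterShellThickness
  vol <- 4 / 3 * pi * (Rsh^3 - Rin^3)
  nW <- if (spec@waterShellThickness > 0) round(spec@waterDensity * vol) else 0L
  wO <- matrix(0, max(nW, 1L), 3)
  fixed <- rbind(xyzAll, naPos)
  placedW <- 0L
  attempts <- 0L
  floor2 <- 0.25^2
  while (placedW < nW) {
    attempts <- attempts + 1L
    if (attempts > 60L * nW)
      stop("water density infeasible for a 0.25 nm overlap floor; ",
           "reduce waterDensity or thicken the shell")
    r <- (stats::runif(1, Rin^3, Rsh^3))^(1 / 3)
    cand <- r * as.numeric(.randomUnit(1))
    if (min(rowSums(sweep(fixed, 2, cand)^2)) < floor2) next
    if (placedW > 0L &&
        min(rowSums(sweep(wO[seq_len(placedW), , drop = FALSE], 2,
                          cand)^2)) < floor2) next
    placedW <- placedW + 1L
    wO[placedW, ] <- cand
  }
  if (nW == 0L) wO <- matrix(0, 0, 3)

  ## ---- assemble the atom table -------------------------------------------
  resBase <- spec@nChains * nRes
  naDF <- if (nNa > 0) data.frame(
    atomName = "NA", residueName = "NA",
    residueIndex = resBase + seq_len(nNa), chainId = 0L, atomRole = "sodium",
    x = naPos[, 1], y = naPos[, 2], z = naPos[, 3]) else NULL
  watDF <- NULL
  if (nW > 0) {
    # rigid 3-site water: O-H 0.1 nm, H-O-H 104.5 degrees, random orientation
    hw <- lapply(seq_len(nW), function(i) {
      o <- wO[i, ]
      b1 <- as.numeric(.randomUnit(1))
      b2 <- .perpUnit(b1)
      half <- 104.5 / 2 * pi / 180
      h1 <- o + 0.1 * (cos(half) * b1 + sin(half) * b2)
      h2 <- o + 0.1 * (cos(half) * b1 - sin(half) * b2)
      rbind(h1, h2)
    })
    hw <- do.call(rbind, hw)
    watDF <- data.frame(
      atomName = rep(c("OW", "HW1", "HW2"), nW),
      residueName = "WAT",
      residueIndex = rep(resBase + nNa + seq_len(nW), each = 3L),
      chainId = 0L,
      atomRole = rep(c("water_oxygen", "water_hydrogen", "water_hydrogen"), nW),
      x = as.vector(rbind(wO[, 1], hw[seq(1, 2 * nW, 2), 1], hw[seq(2, 2 * nW, 2), 1])),
      y = as.vector(rbind(wO[, 2], hw[seq(1, 2 * nW, 2), 2], hw[seq(2, 2 * nW, 2), 2])),
      z = as.vector(rbind(wO[, 3], hw[seq(1, 2 * nW, 2), 3], hw[seq(2, 2 * nW, 2), 3])))
  }
  allDF <- rbind(poly, naDF, watDF)
  boxEdge <- 2 * (Rsh + 0.6)
  allDF[, c("x", "y", "z")] <- allDF[, c("x", "y", "z")] + boxEdge / 2

  base <- AtomSet(allDF, box = rep(boxEdge, 3), frameIndex = 1L)
  frames <- vector("list", spec@nFrames)
  frames[[1L]] <- base
  if (spec@nFrames > 1L) {
    for (f in 2:spec@nFrames) {
      a <- base@atoms
      a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
        matrix(stats::rnorm(3L * nrow(a), sd = spec@jitterSigma), ncol = 3)
      frames[[f]] <- methods::initialize(base, atoms = a,
                                         frameIndex = as.integer(f))
    }
  }
  polymerMass <- sum(base@atoms$mass[base@atoms$chainId > 0L])
  conc <- 100 * polymerMass / sum(base@atoms$mass)
  sys <- MicelleSystem(frames, spec@nChains, spec@sequence, conc)
  attr(sys, "groundTruth") <- list(
    nSodium = nNa, nCondensed = sum(naCondensedPlan),
    condensationFraction = if (nNa > 0) sum(naCondensedPlan) / nNa else NA_real_,
    plantedBridges = k, nWater = nW, seed = spec@seed)
  sys
}

# cross product (small helper; kept local to avoid a dependency for one call)
pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct an IdealBodySpec
#'
#' @param kind `"solid_sphere"`, `"rod"`, `"disk"` or `"ellipsoid"`.
#' @param size size parameters in nm: radius for sphere/disk, length for
#'   rod, semi-axes (a, b, c) for ellipsoid.
#' @param nPoints number of equal-mass points.
#' @param massPerPoint mass per point, amu.
#' @param seed RNG seed.
#' @return An [IdealBodySpec-class].
#' @export
IdealBodySpec <- function(kind, size, nPoints = 1000L, massPerPoint = 1,
                          seed = 1L) {
  methods::new("IdealBodySpec", kind = kind, size = as.numeric(size),
               nPoints = as.integer(nPoints), massPerPoint = massPerPoint,
               seed = as.integer(seed))
}

#' Generate an ideal geometric body
#'
#' Equal-mass point clouds with known gyration properties, used as
#' analytic fixtures: `solid_sphere` (uniform in a ball of radius R;
#' Rg/R -> sqrt(3/5)), `rod` (points on a segment; lambda2 = lambda3 = 0,
#' shape parameter 2), `disk` (uniform in a flat disc; lambda1 = lambda2,
#' lambda3 = 0, shape parameter -0.25), `ellipsoid` (uniform in a solid
#' ellipsoid with semi-axes a, b, c).
#'
#' @param spec an [IdealBodySpec-class], or a kind string when the
#'   remaining arguments are given.
#' @param ... passed to [IdealBodySpec()] when `spec` is a string.
#' @return An [AtomSet-class] of equal-mass points (aperiodic).
#' @export
#' @examples
#' sph <- generateIdealBody("solid_sphere", size = 3, nPoints = 2000)
generateIdealBody <- function(spec, ...) {
  if (is.character(spec)) spec <- IdealBodySpec(spec, ...)
  methods::validObject(spec)
  set.seed(spec@seed)
  n <- spec@nPoints
  xyz <- switch(
    spec@kind,
    solid_sphere = {
      r <- spec@size[1] * stats::runif(n)^(1 / 3)
      r * .randomUnit(n)
    },
    rod = {
      L <- spec@size[1]
      cbind(0, 0, stats::runif(n, -L / 2, L / 2))
    },
    disk = {
      R <- spec@size[1]
      r <- R * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th), 0)
    },
    ellipsoid = {
      axes <- rep(spec@size, length.out = 3)
      r <- stats::runif(n)^(1 / 3)
      u <- .randomUnit(n)
      sweep(r * u, 2, axes, "*")
    })
  AtomSet(data.frame(
    atomName = "SC", residueName = "MOE", residueIndex = seq_len(n),
    chainId = 1L, atomRole = "sidechain",
    mass = spec@massPerPoint, element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}
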