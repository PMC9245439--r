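# Independent brute-force oracles and small fixture builders.
# Every oracle is a direct O(n^2)/exhaustive translation of the definition,
# kept free of the package's vectorized code paths.

minImageDist <- function(p, q, box = NULL) {
  d <- p - q
  if (!is.null(box) && !anyNA(box)) d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# plain atom table builder for hand-made fixtures
atomRow <- function(role, x, y, z, chain = 1L, resi = 1L,
                    name = NULL, res = NULL) {
  defaults <- list(
    carboxylate_carbon = c("CG", "COE"), carboxylate_oxygen = c("OD1", "COE"),
    water_oxygen = c("OW", "WAT"), water_hydrogen = c("HW1", "WAT"),
    sodium = c("NA", "NA"), backbone = c("BB", "MOE"),
    sidechain = c("SC", "MOE"))
  d <- defaults[[role]]
  data.frame(atomName = name %||% d[1], residueName = res %||% d[2],
             residueIndex = resi, chainId = chain, atomRole = role,
             x = x, y = y, z = z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force RDF histogram counts (ordered pairs, self-pairs excluded)
bruteRDFCounts <- function(A, B = NULL, breaks, box = NULL) {
  same <- is.null(B)
  if (same) B <- A
  counts <- numeric(length(breaks) - 1L)
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (same && i == j) next
    d <- minImageDist(A[i, ], B[j, ], box)
    k <- findInterval(d, breaks, rightmost.closed = FALSE, left.open = FALSE)
    if (k >= 1 && k <= length(counts) && d < max(breaks)) {
      counts[k] <- counts[k] + 1
    }
  }
  counts
}

# brute-force coordination counts per COO- group (strict <, either oxygen)
bruteCoordination <- function(frame, partnerRole, cutoff) {
  a <- atoms(frame)
  xyz <- coordsNm(frame)
  box <- boxDims(frame); if (anyNA(box)) box <- NULL
  ci <- which(a$atomRole == "carboxylate_carbon")
  partners <- which(a$atomRole == partnerRole)
  out <- integer(0)
  for (i in ci) {
    ox <- which(a$atomRole == "carboxylate_oxygen" &
                  a$chainId == a$chainId[i] &
                  a$residueIndex == a$residueIndex[i])
    nc <- 0L
    for (p in partners) {
      hit <- FALSE
      for (o in ox)
        if (minImageDist(xyz[o, ], xyz[p, ], box) < cutoff) hit <- TRUE
      if (hit) nc <- nc + 1L
    }
    out <- c(out, nc)
  }
  out
}

# brute-force nearest interchain carboxylate carbon distance per carbon
bruteNearestInterchain <- function(frame) {
  a <- atoms(frame)
  xyz <- coordsNm(frame)
  box <- boxDims(frame); if (anyNA(box)) box <- NULL
  ci <- which(a$atomRole == "carboxylate_carbon")
  vapply(ci, function(i) {
    best <- Inf
    for (j in ci) {
      if (a$chainId[j] == a$chainId[i]) next
      best <- min(best, minImageDist(xyz[i, ], xyz[j, ], box))
    }
    best
  }, numeric(1))
}

# exhaustive salt-bridge detection over all sodium x nearest-pair combos
bruteBridgeStats <- function(frame, bridgeCutoff = 0.5,
                             thresholds = c(0.5, 1.0)) {
  a <- atoms(frame)
  xyz <- coordsNm(frame)
  box <- boxDims(frame); if (anyNA(box)) box <- NULL
  ci <- which(a$atomRole == "carboxylate_carbon")
  naI <- which(a$atomRole == "sodium")
  nearest <- integer(length(ci))
  nd <- numeric(length(ci))
  for (k in seq_along(ci)) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_along(ci)) {
      if (a$chainId[ci[j]] == a$chainId[ci[k]]) next
      d <- minImageDist(xyz[ci[k], ], xyz[ci[j], ], box)
      if (d < best) { best <- d; bj <- j }
    }
    nearest[k] <- bj; nd[k] <- best
  }
  bridgedPair <- function(k) {
    for (n in naI) {
      d1 <- minImageDist(xyz[ci[k], ], xyz[n, ], box)
      d2 <- minImageDist(xyz[ci[nearest[k]], ], xyz[n, ], box)
      if (d1 < bridgeCutoff && d2 < bridgeCutoff) return(TRUE)
    }
    FALSE
  }
  qual <- c(0, 0); bridged <- c(0, 0)
  for (k in seq_along(ci)) for (t in 1:2) {
    if (nd[k] < thresholds[t]) {
      qual[t] <- qual[t] + 1
      if (bridgedPair(k)) bridged[t] <- bridged[t] + 1
    }
  }
  list(qual = qual, bridged = bridged,
       frac = ifelse(qual > 0, 100 * bridged / qual, NA_real_))
}

# accessible area of two intersecting spheres of (expanded) radii R1, R2
# at center distance d: each sphere loses the spherical cap buried in the
# other one
twoSphereAccessible <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- (R2 - R1 + d) * (R2 + R1 - d) / (2 * d)
  h2 <- (R1 - R2 + d) * (R1 + R2 - d) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# small water-bath fixture: one COO- group and randomly placed waters
waterBathFixture <- function(nWater = 100, seed = 1, box = c(4, 4, 4)) {
  set.seed(seed)
  rows <- rbind(
    atomRow("carboxylate_carbon", 2, 2, 2, resi = 1L),
    atomRow("carboxylate_oxygen", 2.12, 2, 2, resi = 1L),
    atomRow("carboxylate_oxygen", 1.88, 2, 2, resi = 1L,
            name = "OD2"))
  wat <- do.call(rbind, lapply(seq_len(nWater), function(i) {
    p <- runif(3, 0, box[1])
    rbind(atomRow("water_oxygen", p[1], p[2], p[3], chain = 0L,
                  resi = 1L + i),
          atomRow("water_hydrogen", p[1] + 0.08, p[2], p[3], chain = 0L,
                  resi = 1L + i),
          atomRow("water_hydrogen", p[1] - 0.08, p[2], p[3], chain = 0L,
                  resi = 1L + i, name = "HW2"))
  }))
  AtomSet(rbind(rows, wat), box = box)
}

# a tiny two-chain charged fixture with one sodium, fully hand-placed
twoChainFixture <- function(ccDist = 0.8, naPos = NULL, box = NA) {
  rows <- rbind(
    atomRow("carboxylate_carbon", 0, 0, 0, chain = 1L, resi = 1L),
    atomRow("carboxylate_oxygen", 0.12, 0.05, 0, chain = 1L, resi = 1L),
    atomRow("carboxylate_oxygen", -0.12, 0.05, 0, chain = 1L, resi = 1L,
            name = "OD2"),
    atomRow("carboxylate_carbon", ccDist, 0, 0, chain = 2L, resi = 1L),
    atomRow("carboxylate_oxygen", ccDist + 0.12, 0.05, 0, chain = 2L,
            resi = 1L),
    atomRow("carboxylate_oxygen", ccDist - 0.12, 0.05, 0, chain = 2L,
            resi = 1L, name = "OD2"))
  if (!is.null(naPos))
    rows <- rbind(rows, atomRow("sodium", naPos[1], naPos[2], naPos[3],
                                chain = 0L, resi = 3L))
  AtomSet(rows, box = if (all(is.na(box))) rep(NA_real_, 3) else box)
}

smallMicelleSpec <- function(seed = 1, ...) {
  args <- list(nChains = 6L, sequence = ChainSequence(c(21L, 23L, 25L)),
               waterShellThickness = 0.3, seed = seed)
  do.call(SyntheticMicelleSpec, utils::modifyList(args, list(...)))
}
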