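setOldClass("data.frame")

.RESIDUE_TOKENS <- c("DEC", "MOE", "COE", "WAT", "NA")
.ATOM_ROLES <- c("backbone", "sidechain", "carboxylate_carbon",
                 "carboxylate_oxygen", "water_oxygen", "water_hydrogen",
                 "sodium")

.validAtomSet <- function(object) {
  msg <- character()
  a <- object@atoms
  need <- c("id", "atomName", "element", "mass", "x", "y", "z",
            "chainId", "residueName", "residueIndex", "atomRole")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("atoms table missing columns:",
                        paste(setdiff(need, names(a)), collapse = ", ")))
  else {
    if (nrow(a) > 0L) {
      if (any(!is.finite(a$mass)) || any(a$mass <= 0))
        msg <- c(msg, "all masses must be finite and > 0")
      if (any(!is.finite(c(a$x, a$y, a$z))))
        msg <- c(msg, "all coordinates must be finite")
      bad <- setdiff(unique(a$residueName), .RESIDUE_TOKENS)
      if (length(bad))
        msg <- c(msg, paste("unknown residue token(s):", paste(bad, collapse = ", ")))
      badr <- setdiff(unique(a$atomRole), .ATOM_ROLES)
      if (length(badr))
        msg <- c(msg, paste("unknown atom role(s):", paste(badr, collapse = ", ")))
      # COE is the only residue allowed to carry carboxylate roles
      carb <- a$atomRole %in% c("carboxylate_carbon", "carboxylate_oxygen")
      if (any(carb & a$residueName != "COE"))
        msg <- c(msg, "carboxylate roles are only allowed on COE residues")
    }
  }
  b <- object@box
  if (length(b) != 3L) msg <- c(msg, "box must be length 3 (NA when aperiodic)")
  else if (!all(is.na(b)) && (any(is.na(b)) || any(b <= 0)))
    msg <- c(msg, "box edges must all be > 0 (or all NA)")
  if (length(msg)) msg else TRUE
}

#' AtomSet: a single molecular configuration
#'
#' One frame of a molecular system: an ordered per-atom table (id, atom name,
#' element, mass in amu, coordinates in nm, chain id, residue name and index,
#' atom role) plus an optional orthorhombic periodic box (nm edges) and a
#' frame index. All coordinates are held in nanometres regardless of the file
#' format they came from. Water and sodium atoms carry `chainId = 0`; polymer
#' atoms carry the 1-based chain id of the peptoid chain they belong to.
#'
#' Atom roles distinguish the sites the analyses key on: `backbone`,
#' `sidechain`, `carboxylate_carbon`, `carboxylate_oxygen`, `water_oxygen`,
#' `water_hydrogen`, `sodium`. Only COE residues may carry carboxylate roles.
#'
#' @slot atoms data.frame with columns id, atomName, element, mass, x, y, z,
#'   chainId, residueName, residueIndex, atomRole.
#' @slot box numeric(3), box edges in nm, or `NA` for aperiodic systems.
#' @slot frameIndex integer frame label.
#' @seealso [AtomSet()], [readConfiguration()], [selectAtoms()]
#' @export
setClass("AtomSet",
         slots = c(atoms = "data.frame", box = "numeric", frameIndex = "integer"),
         prototype = list(atoms = data.frame(), box = rep(NA_real_, 3),
                          frameIndex = 1L),
         validity = .validAtomSet)

.validChainSequence <- function(object) {
  msg <- character()
  r <- object@residues
  if (!all(r %in% c("DEC", "MOE", "COE")))
    msg <- c(msg, "residues must be DEC, MOE or COE")
  cp <- which(r == "COE")
  if (!identical(as.integer(object@chargePositions), as.integer(cp)))
    msg <- c(msg, "chargePositions must be exactly the indices of COE residues")
  if (length(msg)) msg else TRUE
}

#' ChainSequence: residue architecture of one peptoid chain
#'
#' An ordered residue list over the three-monomer vocabulary DEC (N-decyl,
#' hydrophobic), MOE (N-methoxyethyl, neutral hydrophilic) and COE
#' (N-carboxyethyl, anionic). The default architecture is a 25-mer: a block
#' of 5 consecutive DEC residues (the core-forming block) followed by 20
#' hydrophilic residues carrying 1 or 3 COE sites. Charge positions are
#' reported 1-based.
#'
#' @slot residues character vector of residue tokens.
#' @slot chargePositions integer indices (1-based) of the COE residues.
#' @seealso [ChainSequence()], [chainPreset()]
#' @export
setClass("ChainSequence",
         slots = c(residues = "character", chargePositions = "integer"),
         validity = .validChainSequence)

.validMicelleSystem <- function(object) {
  msg <- character()
  if (!length(object@frames)) msg <- c(msg, "at least one frame required")
  if (!all(vapply(object@frames, is, logical(1), class2 = "AtomSet")))
    msg <- c(msg, "frames must all be AtomSet objects")
  n <- object@nChains
  if (length(n) != 1L || is.na(n) || n < 1L)
    msg <- c(msg, "nChains must be a positive integer")
  nCharges <- length(object@sequence@chargePositions)
  for (i in seq_along(object@frames)) {
    a <- object@frames[[i]]@atoms
    poly <- !(a$atomRole %in% c("water_oxygen", "water_hydrogen", "sodium"))
    if (any(!(a$chainId[poly] %in% seq_len(n)))) {
      msg <- c(msg, sprintf(
        "frame %d: every non-water, non-sodium atom must belong to one of %d chains",
        i, n))
      break
    }
    nNa <- sum(a$atomRole == "sodium")
    if (nNa != n * nCharges) {
      msg <- c(msg, sprintf(
        "frame %d: sodium count (%d) must equal nChains x charges per chain (%d)",
        i, nNa, n * nCharges))
      break
    }
  }
  if (length(msg)) msg else TRUE
}

#' MicelleSystem: a micelle trajectory with its chain architecture
#'
#' An ordered collection of configuration frames together with the
#' aggregation number N (number of chains in the micelle), the shared
#' [ChainSequence-class] and, optionally, the nominal concentration in
#' weight percent. Electroneutrality is enforced: the sodium count must
#' equal N times the number of carboxylate sites per chain.
#'
#' @slot frames list of [AtomSet-class], one per frame.
#' @slot nChains integer aggregation number.
#' @slot sequence the [ChainSequence-class] of every chain.
#' @slot concentration numeric weight percent (NA when unknown).
#' @seealso [MicelleSystem()], [generateMicelle()]
#' @export
setClass("MicelleSystem",
         slots = c(frames = "list", nChains = "integer",
                   sequence = "ChainSequence", concentration = "numeric"),
         prototype = list(concentration = NA_real_),
         validity = .validMicelleSystem)

.validSyntheticSpec <- function(object) {
  msg <- character()
  if (object@naCondensationFraction < 0 || object@naCondensationFraction > 1)
    msg <- c(msg, "naCondensationFraction must lie in [0, 1]")
  if (any(object@aspectRatios <= 0)) msg <- c(msg, "aspect ratios must be > 0")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@coreRadius <= 0 || object@coronaThickness <= 0 ||
      object@waterShellThickness < 0)
    msg <- c(msg, "core radius / corona thickness must be > 0 and water shell >= 0")
  if (object@waterDensity < 0) msg <- c(msg, "waterDensity must be >= 0")
  if (object@plantedSaltBridges < 0) msg <- c(msg, "plantedSaltBridges must be >= 0")
  if (length(msg)) msg else TRUE
}

#' SyntheticMicelleSpec: parameters of the synthetic micelle generator
#'
#' Describes the micelle to generate: aggregation number, chain sequence,
#' core/corona/hydration-shell geometry (nm), water number density
#' (molecules/nm^3), the fraction of sodium counterions planted as condensed
#' (within 0.35 nm of a carboxylate oxygen), the number of planted
#' COO-Na-COO salt bridges, ellipsoidal aspect ratios, frame count and
#' inter-frame Gaussian jitter, and the RNG seed.
#'
#' @seealso [SyntheticMicelleSpec()], [generateMicelle()]
#' @export
setClass("SyntheticMicelleSpec",
         slots = c(nChains = "integer", sequence = "ChainSequence",
                   coreRadius = "numeric", coronaThickness = "numeric",
                   waterShellThickness = "numeric", waterDensity = "numeric",
                   naCondensationFraction = "numeric",
                   plantedSaltBridges = "integer",
                   aspectRatios = "numeric", nFrames = "integer",
                   jitterSigma = "numeric", chargeSurfaceBias = "numeric",
                   seed = "integer"),
         validity = .validSyntheticSpec)

.validIdealBodySpec <- function(object) {
  msg <- character()
  if (!(object@kind %in% c("solid_sphere", "rod", "disk", "ellipsoid")))
    msg <- c(msg, "kind must be one of solid_sphere, rod, disk, ellipsoid")
  if (object@nPoints < 4L) msg <- c(msg, "nPoints must be >= 4")
  if (any(object@size <= 0)) msg <- c(msg, "size parameters must be > 0")
  if (object@massPerPoint <= 0) msg <- c(msg, "massPerPoint must be > 0")
  if (length(msg)) msg else TRUE
}

#' IdealBodySpec: an ideal geometric body for analytic checks
#'
#' Point clouds with closed-form gyration properties: `solid_sphere`
#' (uniform points in a ball), `rod` (points on a line segment), `disk`
#' (uniform points in a thin planar disc) and `ellipsoid` (uniform points in
#' a solid ellipsoid). Used as fixtures against the analytic limits of the
#' shape descriptors (rod: shape parameter 2; disk: shape parameter -0.25;
#' sphere: Rg/R = sqrt(3/5)).
#'
#' @seealso [IdealBodySpec()], [generateIdealBody()]
#' @export
setClass("IdealBodySpec",
         slots = c(kind = "character", size = "numeric", nPoints = "integer",
                   massPerPoint = "numeric", seed = "integer"),
         validity = .validIdealBodySpec)

.validGyrationResult <- function(object) {
  msg <- character()
  l <- object@eigenvalues
  if (length(l) != 3L || is.unsorted(rev(l)) || any(l < -1e-12))
    msg <- c(msg, "eigenvalues must be three non-negative values, descending")
  if (abs(object@rg^2 - sum(l)) > 1e-8 * max(1, sum(l)))
    msg <- c(msg, "rg^2 must equal the eigenvalue sum")
  if (object@asphericity < -1e-12 || object@asphericity > 1 + 1e-12)
    msg <- c(msg, "asphericity out of [0, 1]")
  if (object@shape < -0.25 - 1e-12 || object@shape > 2 + 1e-12)
    msg <- c(msg, "shape parameter out of [-0.25, 2]")
  if (length(msg)) msg else TRUE
}

#' GyrationResult: gyration-tensor descriptors of one configuration
#'
#' Eigenvalues (lambda1 >= lambda2 >= lambda3, nm^2) of the weighted
#' gyration tensor, their mean, the radius of gyration Rg (nm; Rg^2 equals
#' the eigenvalue sum), the scattering-length-weighted Rgb when computed,
#' the asphericity (0 for a sphere, 1 for a rod), the shape parameter
#' (-0.25 perfect oblate to 2 perfect prolate) and the eigenvalue ratios
#' lambda2/lambda1 and lambda3/lambda1.
#'
#' @seealso [gyration()], [shapeMetrics()]
#' @export
setClass("GyrationResult",
         slots = c(eigenvalues = "numeric", lambdaMean = "numeric",
                   rg = "numeric", rgb = "numeric", asphericity = "numeric",
                   shape = "numeric", ratios = "numeric", weighting = "character"),
         prototype = list(rgb = NA_real_),
         validity = .validGyrationResult)

.validSASAResult <- function(object) {
  msg <- character()
  if (any(object@perAtom < 0)) msg <- c(msg, "per-atom areas must be >= 0")
  if (abs(object@total - sum(object@perAtom)) > 1e-6 * max(1, object@total))
    msg <- c(msg, "total must equal the per-atom sum")
  if (object@probeRadius < 0) msg <- c(msg, "probe radius must be >= 0")
  if (length(msg)) msg else TRUE
}

#' SASAResult: solvent-accessible surface area of one configuration
#'
#' Total SASA (nm^2), the per-atom decomposition, SASA per chain (total
#' divided by the aggregation number, NA when no chain count applies), the
#' probe radius (nm) and the number of test points per atomic sphere.
#'
#' @seealso [computeSASA()]
#' @export
setClass("SASAResult",
         slots = c(total = "numeric", perAtom = "numeric", perChain = "numeric",
                   probeRadius = "numeric", nSpherePoints = "integer"),
         prototype = list(perChain = NA_real_),
         validity = .validSASAResult)

.validRDFProfile <- function(object) {
  msg <- character()
  b <- object@breaks
  if (length(b) < 2L || is.unsorted(b, strictly = TRUE))
    msg <- c(msg, "breaks must be strictly increasing")
  if (length(object@g) != length(b) - 1L)
    msg <- c(msg, "g must have one value per bin")
  if (any(object@g < -1e-12)) msg <- c(msg, "g must be >= 0")
  if (length(msg)) msg else TRUE
}

#' RDFProfile: a binned radial distribution function
#'
#' g(r) on uniform half-open bins `[lo, hi)` (nm) together with the pair
#' labels (two species, or `"total-weighted"` for the neutron-weighted sum)
#' and the number densities (nm^-3) used in the normalization.
#'
#' @seealso [partialRDF()], [totalWeightedRDF()]
#' @export
setClass("RDFProfile",
         slots = c(breaks = "numeric", g = "numeric", pairLabels = "character",
                   densities = "numeric"),
         validity = .validRDFProfile)

.validSQProfile <- function(object) {
  msg <- character()
  if (length(object@Q) != length(object@S))
    msg <- c(msg, "Q and S must have equal length")
  if (any(object@Q <= 0) || is.unsorted(object@Q, strictly = TRUE))
    msg <- c(msg, "Q must be positive and strictly increasing")
  if (any(!is.finite(object@S))) msg <- c(msg, "S must be finite")
  if (length(msg)) msg else TRUE
}

#' StructureFactorProfile: the static structure factor S(Q)
#'
#' S evaluated on a strictly increasing grid of momentum transfer Q
#' (inverse Angstroms, matching the axis convention of SANS plots), with
#' the number density rho (nm^-3) used in the transform and any vertical
#' scaling constant applied for alignment with experiment.
#'
#' @seealso [structureFactor()], [guinierRg()]
#' @export
setClass("StructureFactorProfile",
         slots = c(Q = "numeric", S = "numeric", rho = "numeric",
                   scaling = "numeric"),
         prototype = list(scaling = 1),
         validity = .validSQProfile)

.validCoordHist <- function(object) {
  msg <- character()
  if (length(object@probabilities) &&
      abs(sum(object@probabilities) - 1) > 1e-9)
    msg <- c(msg, "probabilities must sum to 1")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
}

#' CoordinationHistogram: partner counts around carboxylate groups
#'
#' For each (COO- group, frame) pair, the number N_c of distinct partner
#' atoms (sodium ions or water oxygens) lying strictly within the cutoff of
#' either carboxylate oxygen, histogrammed over all group/frame pairs and
#' normalized to probabilities.
#'
#' @seealso [coordinationHistogram()]
#' @export
setClass("CoordinationHistogram",
         slots = c(partner = "character", cutoff = "numeric",
                   counts = "numeric", probabilities = "numeric",
                   nSites = "integer", nFrames = "integer"),
         validity = .validCoordHist)

.validNeighborDist <- function(object) {
  msg <- character()
  if (any(object@distances <= 0)) msg <- c(msg, "all distances must be > 0")
  if (length(msg)) msg else TRUE
}

#' NeighborDistanceDistribution: interchain carboxylate carbon distances
#'
#' One distance per (carboxylate carbon, frame): the distance to the
#' nearest carboxylate carbon on a different chain. Carries the raw
#' distances, a unit-area histogram and a unit-area KDE-smoothed density.
#'
#' @seealso [nearestInterchainCarboxylate()]
#' @export
setClass("NeighborDistanceDistribution",
         slots = c(distances = "numeric", histogram = "list", kde = "list",
                   bandwidth = "numeric"),
         validity = .validNeighborDist)

.validSaltBridgeReport <- function(object) {
  msg <- character()
  fr <- c(object@fraction05, object@fraction10, object@condensedFraction)
  fr <- fr[!is.na(fr)]
  if (any(fr < 0 | fr > 100)) msg <- c(msg, "fractions must lie in [0, 100]")
  if (nrow(object@bridges) &&
      any(object@bridges$chainA == object@bridges$chainB))
    msg <- c(msg, "bridge members must sit on different chains")
  if (length(msg)) msg else TRUE
}

#' SaltBridgeReport: salt-bridge and counterion-condensation statistics
#'
#' The per-frame list of detected COO-Na-COO bridges (sodium id, the two
#' carboxylate carbon ids and their chain ids), the percentage of
#' nearest-interchain carbon pairs below 0.5 nm (and below 1.0 nm) that are
#' bridged by a sodium ion, and the percentage of sodium ions condensed
#' (strictly within 0.35 nm of any carboxylate oxygen). The two bridge
#' fractions are computed on different qualifying sets, so the 0.5 nm
#' fraction routinely exceeds the 1.0 nm one.
#'
#' @seealso [saltBridges()]
#' @export
setClass("SaltBridgeReport",
         slots = c(bridges = "data.frame", fraction05 = "numeric",
                   fraction10 = "numeric", condensedFraction = "numeric",
                   qualifying = "numeric", cutoffs = "numeric"),
         validity = .validSaltBridgeReport)

.validDescriptorSeries <- function(object) {
  msg <- character()
  q <- object@quartiles
  if (length(q) == 3L && is.unsorted(q)) msg <- c(msg, "quartiles must be ordered")
  if (length(msg)) msg else TRUE
}

#' DescriptorSeries: summary of a per-frame descriptor
#'
#' A named per-frame numeric series with its mean, a block-averaged
#' standard error, quartiles, and a kernel density estimate on a stated
#' grid (unit area).
#'
#' @seealso [summarizeSeries()]
#' @export
setClass("DescriptorSeries",
         slots = c(name = "character", values = "numeric", mean = "numeric",
                   se = "numeric", quartiles = "numeric", kde = "list",
                   nBlocks = "integer"),
         validity = .validDescriptorSeries)

#' CorrelationTable: pairwise Pearson correlations between descriptors
#'
#' Rows of (descriptor A, descriptor B, Pearson r); `r` is `NA` when a
#' member has zero variance. `n` is the aligned sample size.
#'
#' @seealso [correlateDescriptors()]
#' @export
setClass("CorrelationTable",
         slots = c(pairs = "data.frame", n = "integer"))
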