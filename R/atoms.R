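#' @include AllClasses.R AllGenerics.R elements.R
NULL

#' Construct an AtomSet
#'
#' Builds a single-configuration [AtomSet-class] from a per-atom table.
#' Coordinates must already be in nanometres; [readConfiguration()] performs
#' unit conversion for file input.
#'
#' @param atoms data.frame with columns `id`, `atomName`, `element`, `mass`,
#'   `x`, `y`, `z`, `chainId`, `residueName`, `residueIndex`, `atomRole`.
#'   Missing `id` is filled with the row number; missing `element` and `mass`
#'   are inferred from the atom role via the bead tables.
#' @param box numeric(3) orthorhombic box edges in nm, or `NA` (aperiodic).
#' @param frameIndex integer frame label.
#' @return An [AtomSet-class].
#' @export
#' @examples
#' a <- AtomSet(data.frame(
#'   atomName = "NA", residueName = "NA", residueIndex = 1,
#'   chainId = 0, atomRole = "sodium", x = 0, y = 0, z = 0))
#' nAtoms(a)
AtomSet <- function(atoms, box = rep(NA_real_, 3), frameIndex = 1L) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$id)) atoms$id <- seq_len(nrow(atoms))
  if (is.null(atoms$atomName)) atoms$atomName <- atoms$atomRole
  if (is.null(atoms$element))
    atoms$element <- unname(.elementForRole(atoms$atomRole))
  if (is.null(atoms$mass))
    atoms$mass <- .massForAtom(atoms$residueName, atoms$atomName, atoms$atomRole)
  atoms$chainId <- as.integer(atoms$chainId)
  atoms$residueIndex <- as.integer(atoms$residueIndex)
  atoms$id <- as.integer(atoms$id)
  rownames(atoms) <- NULL
  methods::new("AtomSet", atoms = atoms, box = as.numeric(box),
               frameIndex = as.integer(frameIndex))
}

#' @rdname atomset-accessors
#' @export
setMethod("atoms", "AtomSet", function(x) x@atoms)

#' @rdname atomset-accessors
#' @export
setMethod("coordsNm", "AtomSet",
          function(x) as.matrix(x@atoms[, c("x", "y", "z")]))

#' @rdname atomset-accessors
#' @export
setMethod("boxDims", "AtomSet", function(x) x@box)

#' @rdname atomset-accessors
#' @export
setMethod("nAtoms", "AtomSet", function(x) nrow(x@atoms))

#' @rdname atomset-accessors
#' @export
setMethod("frameIndex", "AtomSet", function(x) x@frameIndex)

setMethod("show", "AtomSet", function(object) {
  b <- object@box
  cat(sprintf("AtomSet: %d atoms, frame %d, box %s nm\n",
              nAtoms(object), object@frameIndex,
              if (all(is.na(b))) "absent"
              else paste(format(b, digits = 4), collapse = " x ")))
  tb <- table(object@atoms$residueName)
  cat("  residues:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
})

#' Construct a ChainSequence
#'
#' Builds the default 25-mer block architecture: `blockLength` consecutive
#' DEC residues followed by hydrophilic residues, with COE placed at
#' `chargePositions` (1-based, must fall in the hydrophilic block) and MOE
#' elsewhere. Pass `residues` directly to override the architecture.
#'
#' @param chargePositions integer positions of the COE residues.
#' @param length total chain length (default 25).
#' @param blockLength length of the leading hydrophobic DEC block (default 5).
#' @param residues optional explicit residue vector; overrides the rest.
#' @return A [ChainSequence-class].
#' @export
#' @examples
#' ChainSequence(25)           # singly charged, end position
#' ChainSequence(c(21, 23, 25))
ChainSequence <- function(chargePositions = integer(), length = 25L,
                          blockLength = 5L, residues = NULL) {
  if (is.null(residues)) {
    chargePositions <- sort(as.integer(chargePositions))
    if (any(chargePositions <= blockLength | chargePositions > length))
      stop("charge positions must lie in the hydrophilic block (",
           blockLength + 1L, "..", length, ")")
    residues <- c(rep("DEC", blockLength), rep("MOE", length - blockLength))
    residues[chargePositions] <- "COE"
  }
  methods::new("ChainSequence", residues = as.character(residues),
               chargePositions = which(residues == "COE"))
}

setMethod("show", "ChainSequence", function(object) {
  cat(sprintf("ChainSequence: %d residues, %d charge site(s) at [%s]\n",
              length(object@residues), length(object@chargePositions),
              paste(object@chargePositions, collapse = ", ")))
})

#' Sequence presets for the published chain library
#'
#' Returns the chain architecture and aggregation number of one of the
#' eight studied sequences: a 25-mer with a 5-residue DEC block and 20
#' hydrophilic residues, singly charged (chains 1-5, one COE moving from
#' the chain end toward the hydrophobic junction) or triply charged
#' (chains 6-8, three COE sites moving likewise). Exact charge positions
#' for chains 2-5 and 6-8 are only depicted graphically in the source
#' library, so these positions are approximate; supply explicit
#' `chargePositions` to [ChainSequence()] for a different placement.
#'
#' @param name `"chain1"` .. `"chain8"`.
#' @return list with elements `sequence` ([ChainSequence-class]) and
#'   `nChains` (aggregation number).
#' @export
#' @examples chainPreset("chain1")
chainPreset <- function(name = sprintf("chain%d", 1:8)) {
  name <- match.arg(name)
  presets <- list(
    chain1 = list(pos = 25L,            n = 28L),
    chain2 = list(pos = 20L,            n = 25L),
    chain3 = list(pos = 15L,            n = 23L),
    chain4 = list(pos = 10L,            n = 18L),
    chain5 = list(pos = 6L,             n = 13L),
    chain6 = list(pos = c(21L, 23L, 25L), n = 18L),
    chain7 = list(pos = c(13L, 15L, 17L), n = 17L),
    chain8 = list(pos = c(6L, 8L, 10L),   n = 12L)
  )
  p <- presets[[name]]
  list(sequence = ChainSequence(p$pos), nChains = p$n)
}

#' Construct a MicelleSystem
#'
#' @param frames list of [AtomSet-class] (or a single `AtomSet`).
#' @param nChains integer aggregation number.
#' @param sequence the shared [ChainSequence-class].
#' @param concentration weight percent, optional.
#' @return A [MicelleSystem-class].
#' @export
MicelleSystem <- function(frames, nChains, sequence,
                          concentration = NA_real_) {
  if (methods::is(frames, "AtomSet")) frames <- list(frames)
  methods::new("MicelleSystem", frames = frames, nChains = as.integer(nChains),
               sequence = sequence, concentration = as.numeric(concentration))
}

#' @rdname micellesystem-accessors
#' @export
setMethod("frames", "MicelleSystem", function(x) x@frames)

#' @rdname micellesystem-accessors
#' @export
setMethod("nFrames", "MicelleSystem", function(x) length(x@frames))

#' @rdname micellesystem-accessors
#' @export
setMethod("nChains", "MicelleSystem", function(x) x@nChains)

#' @rdname micellesystem-accessors
#' @export
setMethod("chainSequence", "MicelleSystem", function(x) x@sequence)

setMethod("show", "MicelleSystem", function(object) {
  cat(sprintf(
    "MicelleSystem: N = %d chains, %d frame(s), %d charge site(s)/chain\n",
    object@nChains, length(object@frames),
    length(object@sequence@chargePositions)))
  show(object@frames[[1]])
})

#' A tiny example configuration
#'
#' Three COE carboxylate beads and a sodium ion; used in documentation
#' examples.
#'
#' @return An [AtomSet-class] with 4 atoms.
#' @export
exampleAtomSet <- function() {
  AtomSet(data.frame(
    atomName = c("CG", "OD1", "OD2", "NA"),
    residueName = c("COE", "COE", "COE", "NA"),
    residueIndex = c(1L, 1L, 1L, 2L),
    chainId = c(1L, 1L, 1L, 0L),
    atomRole = c("carboxylate_carbon", "carboxylate_oxygen",
                 "carboxylate_oxygen", "sodium"),
    x = c(0, 0.11, -0.11, 0.3), y = c(0, 0.06, 0.06, 0), z = 0))
}
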