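#' @include atoms.R pbc.R
NULL

#' Select atoms by named selection, residue, role or chain
#'
#' Returns the subset of atoms matching every supplied criterion, in the
#' original order. Named selections follow the conventions of the micelle
#' analyses: `"micelle"` is every non-water, non-sodium atom, `"core"` all
#' DEC-residue atoms, `"corona"` the micelle minus the core (MOE + COE),
#' `"water"` all water atoms, `"sodium"` the counterions, `"all"`
#' everything. An empty result is legal (a message is emitted, not an
#' error), and selection is idempotent.
#'
#' @param x an [AtomSet-class].
#' @param selection a named selection token, or `NULL`.
#' @param residue residue name(s) to keep (DEC/MOE/COE/WAT/NA).
#' @param role atom role(s) to keep (see [roleMap()]).
#' @param chain chain id(s) to keep.
#' @param element element symbol(s) to keep.
#' @return An [AtomSet-class] with the matching atoms.
#' @export
#' @examples
#' a <- exampleAtomSet()
#' nAtoms(selectAtoms(a, role = "carboxylate_oxygen"))
selectAtoms <- function(x, selection = NULL, residue = NULL, role = NULL,
                        chain = NULL, element = NULL) {
  stopifnot(methods::is(x, "AtomSet"))
  a <- x@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection)) {
    selection <- match.arg(selection,
                           c("all", "micelle", "core", "corona", "water",
                             "sodium"))
    keep <- keep & switch(
      selection,
      all = TRUE,
      micelle = !(a$residueName %in% c("WAT", "NA")),
      core = a$residueName == "DEC",
      corona = a$residueName %in% c("MOE", "COE"),
      water = a$residueName == "WAT",
      sodium = a$atomRole == "sodium")
  }
  if (!is.null(residue)) keep <- keep & a$residueName %in% residue
  if (!is.null(role)) keep <- keep & a$atomRole %in% role
  if (!is.null(chain)) keep <- keep & a$chainId %in% chain
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!any(keep)) message("selection returned no atoms")
  methods::initialize(x, atoms = a[keep, , drop = FALSE])
}

#' Solute plus its solvation shell
#'
#' Returns the selected solute atoms together with every water molecule
#' whose oxygen lies strictly within `cutoff` of any solute atom. Whole
#' water molecules are included (the oxygen decides, its hydrogens follow),
#' so mass-weighted descriptors of the augmented set are not corrupted by
#' fragmented molecules. Minimum-image distances are used when the
#' configuration has a periodic box. The default cutoff of 0.35 nm is the
#' first minimum of the water oxygen-oxygen radial distribution function,
#' the conventional definition of the first solvation shell.
#'
#' @param x an [AtomSet-class] containing solute and water.
#' @param soluteSelection named selection passed to [selectAtoms()]
#'   (default `"micelle"`).
#' @param cutoff shell cutoff in nm.
#' @param heavyOnly if `TRUE`, only non-hydrogen solute atoms are tested
#'   against the cutoff (the default tests all solute atoms).
#' @return An [AtomSet-class]: solute atoms plus included water molecules,
#'   in the original atom order.
#' @export
solvationShell <- function(x, soluteSelection = "micelle", cutoff = 0.35,
                           heavyOnly = FALSE) {
  stopifnot(methods::is(x, "AtomSet"), cutoff > 0)
  a <- x@atoms
  soluteIdx <- which(!(a$residueName %in% c("WAT", "NA")))
  if (!is.null(soluteSelection) && !identical(soluteSelection, "micelle")) {
    soluteIdx <- which(a$id %in% selectAtoms(x, soluteSelection)@atoms$id)
  }
  probeIdx <- soluteIdx
  if (heavyOnly) probeIdx <- probeIdx[a$element[probeIdx] != "H"]
  if (!length(probeIdx)) stop("empty solute selection")
  ow <- which(a$atomRole == "water_oxygen")
  if (!length(ow)) stop("no water oxygens present")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  box <- if (.hasBox(x@box)) x@box else NULL
  dmin <- .minDistToSet(xyz[ow, , drop = FALSE], xyz[probeIdx, , drop = FALSE],
                        box = box)
  inShell <- a$residueIndex[ow[dmin < cutoff]]
  waterIdx <- which(a$atomRole %in% c("water_oxygen", "water_hydrogen") &
                      a$residueIndex %in% inShell)
  keep <- sort(unique(c(soluteIdx, waterIdx)))
  methods::initialize(x, atoms = a[keep, , drop = FALSE])
}
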