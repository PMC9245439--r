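#' @include AllClasses.R
NULL

# Element property tables. All user-overridable at call sites that use them.

#' Standard atomic masses (amu)
#'
#' Masses for the elements appearing in peptoid micelle systems.
#'
#' @return Named numeric vector, amu.
#' @export
#' @examples atomicMasses()["Na"]
atomicMasses <- function() {
  c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, Na = 22.98977)
}

#' Coherent neutron scattering lengths (fm)
#'
#' Bound coherent scattering lengths (Sears compilation). H and D are
#' distinct entries; the negative value of 1H is the reason scattering-
#' length-weighted averages can have small net weight.
#'
#' @return Named numeric vector, fm.
#' @export
#' @examples scatteringLengths()[c("H", "D", "O")]
scatteringLengths <- function() {
  c(H = -3.7390, D = 6.671, C = 6.6460, N = 9.36, O = 5.803, Na = 3.63)
}

#' Bondi van der Waals radii (nm)
#'
#' Radius set used by the SASA calculation; pass a modified copy to
#' [computeSASA()] to override.
#'
#' @return Named numeric vector, nm.
#' @export
#' @examples bondiRadii()["O"]
bondiRadii <- function() {
  c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, Na = 0.227)
}

# Coarse bead masses (amu) for the one-bead-per-heavy-group representation
# of the generator: a peptoid backbone unit (glycine-equivalent C2H3NO),
# the decyl (C10H21), methoxyethyl (C3H7O) and carboxyethyl-linker (C2H4)
# side groups, explicit carboxylate C and O beads, and 3-site water.
.BEAD_MASSES <- c(backbone = 57.05, dec_side = 141.27, moe_side = 59.09,
                  coe_link = 28.05, carb_c = 12.011, carb_o = 15.999,
                  water_o = 15.999, water_h = 1.008, sodium = 22.98977)

#' Atom-role inference table
#'
#' Maps (residue name, atom name) to the atom role the analyses key on.
#' Residue aliases from common file dialects are normalized first
#' (SOL/HOH/TIP3 -> WAT, SOD/NA+ -> NA). Users may supply their own table
#' (same three columns) to [readConfiguration()].
#'
#' @return data.frame with columns `residueName`, `atomName`, `atomRole`.
#' @export
#' @examples head(roleMap())
roleMap <- function() {
  rbind(
    data.frame(residueName = "DEC",
               atomName = c("BB", "SC"),
               atomRole = c("backbone", "sidechain")),
    data.frame(residueName = "MOE",
               atomName = c("BB", "SC"),
               atomRole = c("backbone", "sidechain")),
    data.frame(residueName = "COE",
               atomName = c("BB", "SC", "CG", "OD1", "OD2"),
               atomRole = c("backbone", "sidechain", "carboxylate_carbon",
                            "carboxylate_oxygen", "carboxylate_oxygen")),
    data.frame(residueName = "WAT",
               atomName = c("OW", "HW1", "HW2"),
               atomRole = c("water_oxygen", "water_hydrogen", "water_hydrogen")),
    data.frame(residueName = "NA",
               atomName = "NA",
               atomRole = "sodium")
  )
}

.RESIDUE_ALIASES <- c(SOL = "WAT", HOH = "WAT", TIP3 = "WAT", WAT = "WAT",
                      SOD = "NA", "NA+" = "NA", "NA" = "NA",
                      DEC = "DEC", MOE = "MOE", COE = "COE")

.normalizeResidue <- function(res) {
  res <- toupper(trimws(res))
  out <- unname(.RESIDUE_ALIASES[res])
  bad <- unique(res[is.na(out)])
  if (length(bad))
    stop("unknown residue token(s): ", paste(bad, collapse = ", "))
  out
}

.inferRoles <- function(residueName, atomName, map = roleMap()) {
  key <- paste(residueName, toupper(trimws(atomName)))
  lut <- stats::setNames(map$atomRole, paste(map$residueName, map$atomName))
  role <- unname(lut[key])
  if (anyNA(role)) {
    miss <- unique(key[is.na(role)])
    stop("no atom role mapping for: ", paste(miss, collapse = ", "),
         " (supply a custom role map)")
  }
  role
}

# Element inferred from the atom role / atom name used by the bead model.
.elementForRole <- function(role) {
  c(backbone = "C", sidechain = "C", carboxylate_carbon = "C",
    carboxylate_oxygen = "O", water_oxygen = "O", water_hydrogen = "H",
    sodium = "Na")[role]
}

.massForAtom <- function(residueName, atomName, role) {
  m <- rep(NA_real_, length(role))
  m[role == "backbone"] <- .BEAD_MASSES[["backbone"]]
  m[role == "sidechain" & residueName == "DEC"] <- .BEAD_MASSES[["dec_side"]]
  m[role == "sidechain" & residueName == "MOE"] <- .BEAD_MASSES[["moe_side"]]
  m[role == "sidechain" & residueName == "COE"] <- .BEAD_MASSES[["coe_link"]]
  m[role == "carboxylate_carbon"] <- .BEAD_MASSES[["carb_c"]]
  m[role == "carboxylate_oxygen"] <- .BEAD_MASSES[["carb_o"]]
  m[role == "water_oxygen"] <- .BEAD_MASSES[["water_o"]]
  m[role == "water_hydrogen"] <- .BEAD_MASSES[["water_h"]]
  m[role == "sodium"] <- .BEAD_MASSES[["sodium"]]
  m
}
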