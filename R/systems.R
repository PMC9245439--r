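#' @include atoms.R
NULL

#' Overview of the studied polypeptoid micelle systems
#'
#' The eight simulated systems: aggregation number N (from experiment),
#' water count, nominal concentration (wt %) and cubic box edge (Angstrom).
#' The box of each system was sized by the water count needed to dilute
#' the micelle to about 1 wt %, which makes the water count and the box
#' edge mutually consistent at liquid-water density (see
#' [boxEdgeFromWaterCount()]).
#'
#' @return data.frame with columns `chain`, `nSurfactant`, `nWater`,
#'   `concentration`, `boxEdgeA`.
#' @export
#' @examples polypeptoidSystems()
polypeptoidSystems <- function() {
  data.frame(
    chain = 1:8,
    nSurfactant = c(28L, 25L, 23L, 18L, 13L, 18L, 17L, 12L),
    nWater = c(516703L, 461503L, 434591L, 332282L, 239960L, 369782L,
               315291L, 206465L),
    concentration = c(1.01, 1.01, 1.01, 1.02, 1.01, 1.00, 1.00, 1.00),
    boxEdgeA = c(250, 241, 234, 216, 194, 223, 212, 184)
  )
}

#' Cubic box edge implied by a water count
#'
#' The edge (in Angstroms) of the cubic box that holds `nWater` water
#' molecules at a given liquid-water mass density, neglecting the solute
#' volume: a consistency check between a system's water count and its
#' stated box dimensions.
#'
#' @param nWater number of water molecules.
#' @param massDensity water mass density, g/cm^3 (default 0.997 at 300 K).
#' @return box edge in Angstroms.
#' @export
#' @examples
#' boxEdgeFromWaterCount(516703)  # about 249 A, matching the 250 A box
boxEdgeFromWaterCount <- function(nWater, massDensity = 0.997) {
  avogadro <- 6.02214076e23
  mWater <- 18.01528              # g/mol
  rhoA3 <- massDensity / mWater * avogadro * 1e-24  # molecules per A^3
  (nWater / rhoA3)^(1 / 3)
}
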