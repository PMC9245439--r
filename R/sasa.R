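#' @include atoms.R select.R
NULL

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
# No RNG: SASA results are exactly reproducible for a fixed point count.
.goldenSpiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolling-probe SASA by point counting: each atom's van der Waals sphere
#' is expanded by the probe radius (default 0.14 nm, a water-sized probe)
#' and covered with a deterministic quasi-uniform set of test points; a
#' point is accessible iff it lies outside every other expanded sphere,
#' and the per-atom area is the accessible fraction times the expanded
#' sphere area \eqn{4\pi(r_{vdW}+r_{probe})^2}. Water and sodium atoms are
#' excluded from the solute by default (the SASA of "the micelle" measures
#' its exposure to the solvent). Periodic images are ignored: the micelle
#' is assumed whole and far from its images.
#'
#' @param x an [AtomSet-class].
#' @param probeRadius probe radius, nm.
#' @param nSpherePoints test points per atom (>= 64; default 960).
#' @param radii element -> van der Waals radius table in nm
#'   (default [bondiRadii()]); an element without an entry is an error
#'   naming the element.
#' @param includeSolvent if `TRUE`, water and sodium atoms are kept in the
#'   solute.
#' @param aggregationNumber chain count used for the SASA-per-chain value;
#'   default: the number of distinct positive chain ids present.
#' @return A [SASAResult-class].
#' @export
#' @examples
#' one <- AtomSet(data.frame(atomName = "NA", residueName = "NA",
#'   residueIndex = 1, chainId = 0, atomRole = "sodium", x = 0, y = 0, z = 0))
#' computeSASA(one, includeSolvent = TRUE)@total  # 4*pi*(0.227+0.14)^2
computeSASA <- function(x, probeRadius = 0.14, nSpherePoints = 960L,
                        radii = bondiRadii(), includeSolvent = FALSE,
                        aggregationNumber = NULL) {
  stopifnot(methods::is(x, "AtomSet"), nSpherePoints >= 64L)
  a <- x@atoms
  if (!includeSolvent) {
    keep <- !(a$residueName %in% c("WAT", "NA"))
    a <- a[keep, , drop = FALSE]
  }
  if (!nrow(a)) stop("no solute atoms for SASA")
  rv <- unname(radii[a$element])
  if (anyNA(rv))
    stop("no van der Waals radius for element(s): ",
         paste(unique(a$element[is.na(rv)]), collapse = ", "))
  R <- rv + probeRadius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  sph <- .goldenSpiralPoints(nSpherePoints)
  # neighbor lists: only spheres that can overlap matter
  maxR <- max(R)
  d <- .pairDistances(xyz, xyz)
  perAtom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < R[i] + R & seq_len(n) != i)
    pts <- sweep(sph * R[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, nSpherePoints)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 >= R[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    perAtom[i] <- frac * 4 * pi * R[i]^2
  }
  nCh <- if (is.null(aggregationNumber)) {
    ids <- unique(a$chainId[a$chainId > 0L])
    if (length(ids)) length(ids) else NA_integer_
  } else as.integer(aggregationNumber)
  methods::new("SASAResult", total = sum(perAtom), perAtom = perAtom,
               perChain = if (is.na(nCh)) NA_real_ else sum(perAtom) / nCh,
               probeRadius = probeRadius,
               nSpherePoints = as.integer(nSpherePoints))
}

setMethod("show", "SASAResult", function(object) {
  cat(sprintf(
    "SASAResult: total = %.3f nm^2 over %d atoms (probe %.2f nm, %d points)%s\n",
    object@total, length(object@perAtom), object@probeRadius,
    object@nSpherePoints,
    if (is.na(object@perChain)) ""
    else sprintf("; per chain = %.3f nm^2", object@perChain)))
})

#' Per-frame SASA of a micelle trajectory
#'
#' @param system a [MicelleSystem-class].
#' @param ... passed to [computeSASA()].
#' @return data.frame with columns `frame`, `total`, `perChain` (nm^2).
#' @export
sasaFrames <- function(system, ...) {
  stopifnot(methods::is(system, "MicelleSystem"))
  out <- lapply(seq_along(system@frames), function(f) {
    s <- computeSASA(system@frames[[f]],
                     aggregationNumber = system@nChains, ...)
    data.frame(frame = f, total = s@total, perChain = s@perChain)
  })
  do.call(rbind, out)
}

#' SASA versus Rg-squared ratio table
#'
#' For micelles of overall spherical symmetry the ratio of average total
#' SASA between two systems approximately equals the ratio of their
#' Rg^2 (the surface of an ideal sphere, 4 pi R_H^2, is proportional to
#' Rg^2 through Rg = 0.775 R_H). The table reports, with the reference
#' system in the numerator, SASA_ref/SASA_sys and Rg_ref^2/Rg_sys^2 plus
#' their difference as a sphericity diagnostic: a rough or elongated
#' surface inflates the SASA ratio relative to the Rg^2 ratio.
#'
#' @param results named list; each element a list with components `sasa`
#'   (a [SASAResult-class] or a numeric mean total SASA) and `rg` (a
#'   [GyrationResult-class] or a numeric mean Rg in nm).
#' @param reference name of the reference system (default: first).
#' @return data.frame: `system`, `sasaRatio`, `rgSqRatio`, `difference`.
#' @export
sasaRgRatioTable <- function(results, reference = names(results)[1]) {
  stopifnot(reference %in% names(results))
  getv <- function(el) {
    s <- el$sasa; g <- el$rg
    s <- if (methods::is(s, "SASAResult")) s@total else as.numeric(s)
    g <- if (methods::is(g, "GyrationResult")) g@rg else as.numeric(g)
    if (g == 0) stop("zero Rg in ratio table")
    c(s, g)
  }
  ref <- getv(results[[reference]])
  rows <- lapply(names(results), function(nm) {
    v <- getv(results[[nm]])
    data.frame(system = nm,
               sasaRatio = ref[1] / v[1],
               rgSqRatio = ref[2]^2 / v[2]^2)
  })
  out <- do.call(rbind, rows)
  out$difference <- out$sasaRatio - out$rgSqRatio
  out
}
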