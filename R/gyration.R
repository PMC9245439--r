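#' @include atoms.R select.R pbc.R
NULL

#' Weighted gyration tensor
#'
#' The weighted second-moment tensor of atomic positions about the
#' weighted center,
#' \deqn{T_{ab} = \sum_i w_i (r_{i,a} - c_a)(r_{i,b} - c_b) / \sum_i w_i,}
#' with weights either atomic masses or coherent neutron scattering
#' lengths. Its trace equals Rg^2 for the same weighting, and its ordered
#' eigenvalues are the squared principal radii of gyration. Scattering
#' lengths may be negative (1H); a warning is emitted when the net
#' scattering length of the selection is nearly zero (|sum b| < 1 fm),
#' where the weighted mean becomes ill-conditioned.
#'
#' @param x an [AtomSet-class].
#' @param weighting `"mass"` or `"scattering_length"`.
#' @param blengths scattering-length table (fm), see [scatteringLengths()].
#' @return 3 x 3 symmetric numeric matrix, nm^2.
#' @export
#' @examples
#' a <- generateIdealBody("rod", size = 4, nPoints = 100)
#' diag(gyrationTensor(a))
gyrationTensor <- function(x, weighting = c("mass", "scattering_length"),
                           blengths = scatteringLengths()) {
  weighting <- match.arg(weighting)
  stopifnot(methods::is(x, "AtomSet"), nAtoms(x) >= 1L)
  a <- x@atoms
  if (weighting == "mass") {
    w <- a$mass
  } else {
    w <- unname(blengths[a$element])
    if (anyNA(w))
      stop("no scattering length for element(s): ",
           paste(unique(a$element[is.na(w)]), collapse = ", "))
    if (abs(sum(w)) < 1)
      warning("net scattering length of the selection is below 1 fm; ",
              "the scattering-length-weighted tensor is ill-conditioned")
  }
  W <- sum(w)
  if (W == 0) stop("total weight is zero; cannot form the gyration tensor")
  xyz <- coordsNm(x)
  ctr <- colSums(xyz * w) / W
  d <- sweep(xyz, 2, ctr)
  (t(d) %*% (d * w)) / W
}

#' Asphericity and shape parameter from gyration eigenvalues
#'
#' For ordered eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0}
#' of the gyration tensor:
#' \deqn{b = 1 - 3(\lambda_1\lambda_2 + \lambda_2\lambda_3 +
#'   \lambda_3\lambda_1) / (\lambda_1+\lambda_2+\lambda_3)^2}
#' (asphericity, 0 for a sphere up to 1 for a rod), and
#' \deqn{S = 27(\lambda_1-\bar\lambda)(\lambda_2-\bar\lambda)
#'   (\lambda_3-\bar\lambda)/(\lambda_1+\lambda_2+\lambda_3)^3}
#' (shape parameter) with \eqn{\bar\lambda} the eigenvalue mean. S is
#' bounded between -0.25 (perfect oblate: two equal eigenvalues, third
#' zero) and 2 (perfect prolate: one nonzero eigenvalue); negative values
#' are oblate, positive prolate, and a sphere gives 0 for both
#' descriptors.
#'
#' @param eigenvalues numeric(3), descending, non-negative, not all zero.
#' @return named numeric: `asphericity`, `shape`.
#' @export
#' @examples
#' shapeMetrics(c(1, 1, 0))   # perfect oblate
#' shapeMetrics(c(1, 0, 0))   # perfect prolate
shapeMetrics <- function(eigenvalues) {
  l <- as.numeric(eigenvalues)
  if (length(l) != 3L || anyNA(l)) stop("three eigenvalues required")
  if (any(l < 0)) stop("eigenvalues must be non-negative")
  if (is.unsorted(rev(l))) stop("eigenvalues must be in descending order")
  s <- sum(l)
  if (s == 0) stop("all-zero eigenvalues: shape descriptors undefined")
  asph <- 1 - 3 * (l[1] * l[2] + l[2] * l[3] + l[3] * l[1]) / s^2
  shp <- 27 * prod(l - mean(l)) / s^3
  c(asphericity = asph, shape = shp)
}

#' Gyration descriptors of one configuration
#'
#' Diagonalizes the weighted gyration tensor and packages eigenvalues,
#' Rg, shape descriptors and eigenvalue ratios into a
#' [GyrationResult-class]. Degenerate eigenvalues are ordered by the
#' stable descending sort of the eigendecomposition.
#'
#' @param x an [AtomSet-class].
#' @param weighting weighting of the tensor used for the eigen-spectrum
#'   and `rg` (`"mass"` or `"scattering_length"`).
#' @param rgb if `TRUE`, additionally compute the scattering-length-
#'   weighted radius of gyration Rgb (from its own tensor).
#' @param blengths scattering-length table (fm).
#' @return A [GyrationResult-class].
#' @export
#' @examples
#' gyration(generateIdealBody("solid_sphere", size = 3, nPoints = 5000))
gyration <- function(x, weighting = c("mass", "scattering_length"),
                     rgb = FALSE, blengths = scatteringLengths()) {
  weighting <- match.arg(weighting)
  tens <- gyrationTensor(x, weighting, blengths)
  ev <- eigen(tens, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  if (any(ev < -1e-8 * max(abs(ev))))
    stop("gyration tensor has a significantly negative eigenvalue")
  ev[ev < 0] <- 0  # clip eigen round-off
  sm <- shapeMetrics(ev)
  rgbVal <- NA_real_
  if (rgb) {
    tb <- gyrationTensor(x, "scattering_length", blengths)
    rgbVal <- sqrt(max(sum(diag(tb)), 0))
  }
  methods::new("GyrationResult",
               eigenvalues = ev, lambdaMean = mean(ev),
               rg = sqrt(sum(ev)), rgb = rgbVal,
               asphericity = unname(sm["asphericity"]),
               shape = unname(sm["shape"]),
               ratios = c(l2_l1 = ev[2] / ev[1], l3_l1 = ev[3] / ev[1]),
               weighting = weighting)
}

setMethod("show", "GyrationResult", function(object) {
  cat(sprintf(
    paste0("GyrationResult (%s-weighted): Rg = %.4f nm%s\n",
           "  eigenvalues (nm^2): %.4f >= %.4f >= %.4f\n",
           "  asphericity = %.4f, shape = %.4f, l2/l1 = %.3f, l3/l1 = %.3f\n"),
    object@weighting, object@rg,
    if (is.na(object@rgb)) "" else sprintf(", Rgb = %.4f nm", object@rgb),
    object@eigenvalues[1], object@eigenvalues[2], object@eigenvalues[3],
    object@asphericity, object@shape, object@ratios[1], object@ratios[2]))
})

#' Per-frame gyration analysis of a micelle trajectory
#'
#' Applies the gyration-tensor analysis to every frame of a
#' [MicelleSystem-class]: the selection is extracted (default the whole
#' micelle; `"core"` restricts to the DEC block), optionally augmented
#' with its first solvation shell (whole water molecules whose oxygen lies
#' within `shellCutoff` of any selected atom), and periodic frames are
#' made whole before the tensor is formed.
#'
#' @param system a [MicelleSystem-class].
#' @param selection named selection (see [selectAtoms()]).
#' @param weighting tensor weighting for the eigen-spectrum.
#' @param includeShell include the first hydration shell before analysis.
#' @param shellCutoff shell cutoff in nm (default 0.35).
#' @param rgb additionally report the scattering-length-weighted Rgb.
#' @param unwrap make molecules whole across periodic boundaries first.
#' @return data.frame with one row per frame: `frame`, `lambda1..3` (nm^2),
#'   `rg` (nm), `rgb` (nm or NA), `asphericity`, `shape`, `l2_l1`, `l3_l1`.
#' @export
analyzeFrames <- function(system, selection = "micelle",
                          weighting = c("mass", "scattering_length"),
                          includeShell = FALSE, shellCutoff = 0.35,
                          rgb = FALSE, unwrap = TRUE) {
  weighting <- match.arg(weighting)
  stopifnot(methods::is(system, "MicelleSystem"))
  out <- lapply(seq_along(system@frames), function(f) {
    fr <- system@frames[[f]]
    if (unwrap) fr <- unwrapMolecules(fr)
    sel <- if (includeShell)
      solvationShell(fr, soluteSelection = selection, cutoff = shellCutoff)
    else selectAtoms(fr, selection)
    if (nAtoms(sel) == 0L)
      stop("empty selection '", selection, "' in frame ", f)
    g <- gyration(sel, weighting, rgb = rgb)
    data.frame(frame = f,
               lambda1 = g@eigenvalues[1], lambda2 = g@eigenvalues[2],
               lambda3 = g@eigenvalues[3], rg = g@rg, rgb = g@rgb,
               asphericity = g@asphericity, shape = g@shape,
               l2_l1 = g@ratios[1], l3_l1 = g@ratios[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
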