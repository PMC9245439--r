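#' @include atoms.R select.R pbc.R
NULL

# bins cover [0, rMax] truncated to a whole number of bins
.rdfBreaks <- function(rMax, binWidth)
  seq(0, by = binWidth, length.out = floor(rMax / binWidth) + 1L)

#' Partial radial distribution function
#'
#' Standard pair-count g(r) between two atom selections on uniform
#' half-open bins `[lo, hi)`, normalized by the ideal-gas shell count at
#' the partner number density: for a cross pair
#' \eqn{g_{\alpha\beta}(r) = V n_{\alpha\beta}(r) /
#'   (N_\alpha N_\beta V_{shell}(r))}, with self-pairs excluded when the
#' two selections coincide. Minimum-image distances are used; `rMax` may
#' not exceed half the smallest box edge. Multiple frames are pooled.
#'
#' @param x an [AtomSet-class], a list of them, or a [MicelleSystem-class].
#' @param selectionA,selectionB lists of arguments to [selectAtoms()]
#'   (e.g. `list(role = "water_oxygen")`), or named selection strings.
#'   `selectionB = NULL` means the same selection as A.
#' @param rMax histogram range, nm.
#' @param binWidth bin width, nm.
#' @param labels length-2 character pair labels recorded in the profile.
#' @return An [RDFProfile-class].
#' @export
partialRDF <- function(x, selectionA, selectionB = NULL, rMax, binWidth,
                       labels = NULL) {
  framesList <- if (methods::is(x, "MicelleSystem")) x@frames
                else if (methods::is(x, "AtomSet")) list(x) else x
  same <- is.null(selectionB)
  applySel <- function(fr, sel) {
    if (is.character(sel)) selectAtoms(fr, sel)
    else do.call(selectAtoms, c(list(fr), sel))
  }
  breaks <- .rdfBreaks(rMax, binWidth)
  counts <- numeric(length(breaks) - 1L)
  nA <- nB <- 0
  vol <- NA_real_
  for (fr in framesList) {
    box <- fr@box
    if (!.hasBox(box))
      stop("partialRDF needs a periodic box for its normalization")
    if (rMax > min(box) / 2 + 1e-9)
      stop("rMax (", rMax, " nm) exceeds half the smallest box edge (",
           min(box) / 2, " nm)")
    A <- applySel(fr, selectionA)
    B <- if (same) A else applySel(fr, selectionB)
    if (nAtoms(A) == 0L || nAtoms(B) == 0L) stop("empty RDF selection")
    dd <- .pairDistanceVector(coordsNm(A), if (same) NULL else coordsNm(B),
                              box = box)
    h <- graphics::hist(dd[dd < max(breaks)], breaks = breaks, plot = FALSE,
                        right = FALSE)$counts
    if (same) h <- 2 * h  # unordered pairs counted once above
    counts <- counts + h
    nA <- nA + nAtoms(A); nB <- nB + nAtoms(B)
    vol <- prod(box)
  }
  nFrames <- length(framesList)
  nA <- nA / nFrames; nB <- nB / nFrames
  shell <- 4 / 3 * pi * diff(breaks^3)
  # ordered pair count normalization; N_B - 1 partners for a same-species pair
  nPartner <- if (same) max(nB - 1, 1) else nB
  g <- (counts / nFrames) / (nA * nPartner * shell / vol)
  if (is.null(labels)) {
    lab <- function(s) if (is.character(s)) s else paste(
      unlist(s), collapse = "&")
    labels <- c(lab(selectionA), if (same) lab(selectionA) else lab(selectionB))
  }
  dens <- c(nA / vol, nB / vol)
  names(dens) <- make.unique(labels)
  methods::new("RDFProfile", breaks = breaks, g = g, pairLabels = labels,
               densities = dens)
}

setMethod("show", "RDFProfile", function(object) {
  cat(sprintf("RDFProfile [%s]: %d bins on [0, %.3g) nm\n",
              paste(object@pairLabels, collapse = " - "),
              length(object@g), max(object@breaks)))
})

#' Element-pair partial RDFs of a selection
#'
#' Computes the partial g(r) for every unordered element pair present in
#' the selection, the ingredients of the neutron-weighted total.
#'
#' @param x an [AtomSet-class], list of them, or [MicelleSystem-class].
#' @param selection named selection (default `"micelle"`: water is never
#'   included in the structure-factor convention, and sodium is excluded
#'   by default).
#' @param rMax,binWidth histogram range and bin width, nm.
#' @return named list of [RDFProfile-class] (names like `"C-O"`).
#' @export
elementPartialRDFs <- function(x, selection = "micelle", rMax, binWidth) {
  framesList <- if (methods::is(x, "MicelleSystem")) x@frames
                else if (methods::is(x, "AtomSet")) list(x) else x
  frSub <- lapply(framesList, function(fr) selectAtoms(fr, selection))
  els <- sort(unique(frSub[[1]]@atoms$element))
  out <- list()
  for (i in seq_along(els)) for (j in i:length(els)) {
    prof <- partialRDF(
      frSub,
      selectionA = list(element = els[i]),
      selectionB = if (i == j) NULL else list(element = els[j]),
      rMax = rMax, binWidth = binWidth,
      labels = c(els[i], els[j]))
    out[[paste(els[i], els[j], sep = "-")]] <- prof
  }
  out
}

#' Neutron-weighted total radial distribution function
#'
#' Faber-Ziman combination of the partial g(r):
#' \deqn{g(r) = \sum_{\alpha\beta} c_\alpha c_\beta b_\alpha b_\beta
#'   g_{\alpha\beta}(r) / (\sum_\alpha c_\alpha b_\alpha)^2,}
#' where \eqn{c_\alpha} are number densities and \eqn{b_\alpha} coherent
#' scattering lengths. All partials must share identical binning and cover
#' every species pair of the selection.
#'
#' @param partials named list of [RDFProfile-class] with names
#'   `"A-B"` over element symbols, as from [elementPartialRDFs()].
#' @param blengths scattering-length table (fm), see [scatteringLengths()].
#' @return An [RDFProfile-class] with `pairLabels = "total-weighted"`.
#' @export
totalWeightedRDF <- function(partials, blengths = scatteringLengths()) {
  if (!length(partials)) stop("no partials supplied")
  prs <- strsplit(names(partials), "-", fixed = TRUE)
  species <- sort(unique(unlist(prs)))
  breaks <- partials[[1]]@breaks
  for (p in partials)
    if (!isTRUE(all.equal(p@breaks, breaks)))
      stop("partials have mismatched binning")
  # species densities, consistency-checked across partials
  conc <- stats::setNames(rep(NA_real_, length(species)), species)
  for (i in seq_along(partials)) {
    p <- partials[[i]]
    for (j in 1:2) {
      sp <- prs[[i]][j]
      cj <- unname(p@densities[j])
      if (is.na(conc[sp])) conc[sp] <- cj
      else if (abs(conc[sp] - cj) > 1e-9 * max(conc[sp], cj))
        stop("inconsistent number density for species ", sp)
    }
  }
  need <- outer(species, species, paste, sep = "-")
  need <- need[upper.tri(need, diag = TRUE)]
  miss <- setdiff(need, names(partials))
  if (length(miss))
    stop("missing partial(s): ", paste(miss, collapse = ", "))
  b <- blengths[species]
  if (anyNA(b))
    stop("no scattering length for element(s): ",
         paste(species[is.na(b)], collapse = ", "))
  denom <- sum(conc * b)^2
  num <- numeric(length(breaks) - 1L)
  for (i in seq_along(species)) for (j in seq_along(species)) {
    key <- if (i <= j) paste(species[i], species[j], sep = "-")
           else paste(species[j], species[i], sep = "-")
    num <- num + conc[species[i]] * conc[species[j]] *
      b[species[i]] * b[species[j]] * partials[[key]]@g
  }
  methods::new("RDFProfile", breaks = breaks, g = unname(num / denom),
               pairLabels = "total-weighted", densities = conc)
}

.sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

#' Static structure factor from the total g(r)
#'
#' Isotropic Fourier transform of the pair correlations,
#' \deqn{S(Q) = 1 + 4\pi\rho \int_0^{r_{max}} r^2 (g(r)-1)
#'   \frac{\sin(Qr)}{Qr} W(r)\, dr,}
#' evaluated by midpoint quadrature over the histogram bins. S(Q) is
#' directly proportional to the coherent neutron scattering intensity. A
#' Lorch window \eqn{W(r) = \mathrm{sinc}(\pi r / r_{max})} suppresses
#' truncation ripples by default; `window = "none"` gives the raw
#' transform. Q is in inverse Angstroms to match SANS axis conventions
#' (r is handled in nm internally). An optional vertical scaling constant
#' supports alignment with an experimental curve.
#'
#' @param gTotal an [RDFProfile-class] (typically the neutron-weighted
#'   total).
#' @param rho number density of the scatterers, nm^-3.
#' @param Q strictly increasing grid of momentum transfer, inverse
#'   Angstroms.
#' @param window `"lorch"` or `"none"`.
#' @param scaling vertical scaling constant applied to S (default 1).
#' @return A [StructureFactorProfile-class].
#' @export
structureFactor <- function(gTotal, rho, Q, window = c("lorch", "none"),
                            scaling = 1) {
  window <- match.arg(window)
  stopifnot(methods::is(gTotal, "RDFProfile"), all(Q > 0),
            !is.unsorted(Q, strictly = TRUE))
  br <- gTotal@breaks
  rMid <- (br[-1] + br[-length(br)]) / 2
  dr <- diff(br)
  w <- if (window == "lorch") .sinc(pi * rMid / max(br)) else rep(1, length(rMid))
  Qnm <- Q * 10  # A^-1 -> nm^-1
  h <- (gTotal@g - 1) * rMid^2 * w * dr
  S <- vapply(Qnm, function(q) 1 + 4 * pi * rho * sum(h * .sinc(q * rMid)),
              numeric(1))
  methods::new("StructureFactorProfile", Q = as.numeric(Q),
               S = scaling * S, rho = rho, scaling = scaling)
}

setMethod("show", "StructureFactorProfile", function(object) {
  cat(sprintf(
    "StructureFactorProfile: %d Q points on [%.3g, %.3g] A^-1 (rho = %.3g nm^-3)\n",
    length(object@Q), min(object@Q), max(object@Q), object@rho))
})

#' Guinier-regime radius of gyration from S(Q)
#'
#' In the Guinier regime (conventionally Q <= 0.1 inverse Angstroms for
#' micellar SANS), ln S(Q) is linear in Q^2 with slope -Rg^2/3. Fits a
#' least-squares line to ln S over the points with `Q <= QMax` (at least
#' 5 required) and returns Rg in nm; a non-negative slope is an error
#' signaling non-Guinier input.
#'
#' @param profile a [StructureFactorProfile-class].
#' @param QMax upper Q bound of the fit window, inverse Angstroms.
#' @return Rg estimate in nm.
#' @export
#' @examples
#' Q <- seq(0.01, 0.1, length.out = 20)
#' prof <- new("StructureFactorProfile", Q = Q,
#'             S = exp(-(Q * 10)^2 * 3^2 / 3), rho = 1, scaling = 1)
#' guinierRg(prof)  # 3 nm by construction
guinierRg <- function(profile, QMax = 0.1) {
  stopifnot(methods::is(profile, "StructureFactorProfile"))
  keep <- profile@Q <= QMax & profile@S > 0
  if (sum(keep) < 5L)
    stop("need at least 5 positive S(Q) points with Q <= ", QMax)
  q2 <- (profile@Q[keep] * 10)^2  # nm^-2
  fit <- stats::lm(log(profile@S[keep]) ~ q2)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("non-negative Guinier slope: input shows no Guinier decay")
  sqrt(-3 * slope)
}
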