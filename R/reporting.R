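#' @include atoms.R
NULL

#' Summarize a per-frame descriptor series
#'
#' Mean with a block-averaged standard error (the series is split into
#' `nBlocks` contiguous blocks; SE is the standard deviation of the block
#' means divided by sqrt(nBlocks), which remains honest under the frame-
#' to-frame correlation of trajectory data), quartiles, and a unit-area
#' kernel density estimate. The KDE is a reporting transform only; all
#' statistics are computed on the raw values.
#'
#' @param values numeric per-frame series (length >= `nBlocks`).
#' @param nBlocks number of blocks for the SE (default 10).
#' @param name descriptor name carried in the result.
#' @return A [DescriptorSeries-class].
#' @export
#' @examples
#' s <- summarizeSeries(rnorm(100), name = "rg")
#' s@mean; s@se
summarizeSeries <- function(values, nBlocks = 10L, name = "series") {
  values <- as.numeric(values)
  if (length(values) < nBlocks)
    stop("need at least ", nBlocks, " values for ", nBlocks, " blocks")
  blockId <- cut(seq_along(values), nBlocks, labels = FALSE)
  bm <- tapply(values, blockId, mean)
  se <- stats::sd(bm) / sqrt(nBlocks)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75)))
  kde <- if (stats::var(values) > 0) {
    dd <- stats::density(values)
    area <- sum(dd$y) * mean(diff(dd$x))
    list(x = dd$x, y = dd$y / area)
  } else list()
  methods::new("DescriptorSeries", name = name, values = values,
               mean = mean(values), se = se, quartiles = q, kde = kde,
               nBlocks = as.integer(nBlocks))
}

setMethod("show", "DescriptorSeries", function(object) {
  cat(sprintf(
    "DescriptorSeries '%s': n = %d, mean = %.4g +/- %.2g (SE, %d blocks)\n  quartiles: %.4g / %.4g / %.4g\n",
    object@name, length(object@values), object@mean, object@se,
    object@nBlocks, object@quartiles[1], object@quartiles[2],
    object@quartiles[3]))
})

#' Two-dimensional joint density with mode detection
#'
#' A 2D kernel density estimate (unit total mass) on a regular grid, with
#' its local maxima reported to expose bimodality: a system hopping
#' between two conformations shows two distinct maxima in, e.g., the
#' SASA-versus-Rg plane. Maxima are interior grid points exceeding all 8
#' neighbors and at least 5 percent of the global maximum (suppressing
#' noise modes).
#'
#' @param x,y equal-length numeric series (length >= 10), both with
#'   nonzero variance.
#' @param gridSize grid dimensions (default 64 x 64).
#' @param bandwidth optional length-2 bandwidths for [MASS::kde2d()].
#' @return list with `x`, `y`, `z` (density grid, unit mass) and `maxima`
#'   (data.frame of mode locations and densities).
#' @export
#' @examples
#' set.seed(1)
#' jd <- jointDistribution(rnorm(200), rnorm(200))
#' nrow(jd$maxima)
jointDistribution <- function(x, y, gridSize = c(64L, 64L),
                              bandwidth = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 10L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate (zero-variance) input; use a 1D summary instead")
  gridSize <- rep(as.integer(gridSize), length.out = 2L)
  h <- if (is.null(bandwidth))
    c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
  else rep(bandwidth, length.out = 2L)
  kd <- MASS::kde2d(x, y, n = gridSize, h = h)
  dx <- mean(diff(kd$x)); dy <- mean(diff(kd$y))
  z <- kd$z / (sum(kd$z) * dx * dy)
  nx <- length(kd$x); ny <- length(kd$y)
  thr <- 0.05 * max(z)
  maxima <- list()
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    v <- z[i, j]
    if (v < thr) next
    nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v >= max(nb) && sum(nb == v) == 1L) {
      maxima[[length(maxima) + 1L]] <-
        data.frame(x = kd$x[i], y = kd$y[j], density = v)
    }
  }
  maxima <- if (length(maxima)) do.call(rbind, maxima)
            else data.frame(x = numeric(), y = numeric(), density = numeric())
  maxima <- maxima[order(-maxima$density), , drop = FALSE]
  # merge plateau maxima closer than one bandwidth: one physical mode can
  # split into adjacent grid maxima under KDE wiggle
  keep <- rep(TRUE, nrow(maxima))
  if (nrow(maxima) > 1L) {
    for (i in 2:nrow(maxima)) for (j in seq_len(i - 1L)) {
      if (keep[j] &&
          abs(maxima$x[i] - maxima$x[j]) < h[1] &&
          abs(maxima$y[i] - maxima$y[j]) < h[2]) keep[i] <- FALSE
    }
  }
  maxima <- maxima[keep, , drop = FALSE]
  rownames(maxima) <- NULL
  list(x = kd$x, y = kd$y, z = z, maxima = maxima)
}

#' Pairwise Pearson correlations between descriptors
#'
#' Computes the Pearson correlation coefficient for every requested pair
#' of aligned per-frame descriptor series (default: all pairs, e.g. Rg
#' against asphericity, shape and SASA). A zero-variance member yields
#' `NA` with a message rather than an error.
#'
#' @param descriptors named list of equal-length numeric series.
#' @param pairs optional 2-column matrix/data.frame of descriptor name
#'   pairs; default all unordered pairs.
#' @return A [CorrelationTable-class].
#' @export
#' @examples
#' x <- rnorm(50)
#' correlateDescriptors(list(a = x, b = 2 * x + 1))
correlateDescriptors <- function(descriptors, pairs = NULL) {
  stopifnot(is.list(descriptors), length(descriptors) >= 2L,
            !is.null(names(descriptors)))
  len <- unique(vapply(descriptors, length, integer(1)))
  if (length(len) != 1L) stop("descriptor series must be aligned (equal length)")
  nms <- names(descriptors)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nms, 2))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    n1 <- pairs[i, 1]; n2 <- pairs[i, 2]
    v1 <- descriptors[[n1]]; v2 <- descriptors[[n2]]
    r <- if (stats::var(v1) == 0 || stats::var(v2) == 0) {
      message("zero variance in '", n1, "' or '", n2, "': r undefined")
      NA_real_
    } else stats::cor(v1, v2)
    data.frame(a = n1, b = n2, r = r)
  })
  methods::new("CorrelationTable", pairs = do.call(rbind, rows),
               n = len)
}

setMethod("show", "CorrelationTable", function(object) {
  cat(sprintf("CorrelationTable (n = %d):\n", object@n))
  p <- object@pairs
  for (i in seq_len(nrow(p)))
    cat(sprintf("  r(%s, %s) = %s\n", p$a[i], p$b[i],
                format(p$r[i], digits = 3)))
})
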