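#' @include atoms.R
NULL

# Periodic-boundary helpers (orthorhombic boxes only).

.hasBox <- function(box) length(box) == 3L && !anyNA(box)

# Minimum-image displacement components for one dimension.
.minImage1 <- function(d, edge) d - edge * round(d / edge)

# Chunked pairwise distance matrix between coordinate matrices A (nA x 3)
# and B (nB x 3), with minimum-image wrapping when a box is supplied.
# Returns the full nA x nB matrix; chunking bounds peak memory.
.pairDistances <- function(A, B, box = NULL, chunk = 4096L) {
  nA <- nrow(A); nB <- nrow(B)
  out <- matrix(0, nA, nB)
  periodic <- !is.null(box) && .hasBox(box)
  for (start in seq(1L, nB, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nB)
    d2 <- 0
    for (k in 1:3) {
      dk <- outer(A[, k], B[idx, k], "-")
      if (periodic) dk <- .minImage1(dk, box[k])
      d2 <- d2 + dk * dk
    }
    out[, idx] <- sqrt(d2)
  }
  out
}

# For each row of A, the minimum distance to any row of B (minimum image).
.minDistToSet <- function(A, B, box = NULL, chunk = 2048L) {
  nA <- nrow(A)
  best <- rep(Inf, nA)
  periodic <- !is.null(box) && .hasBox(box)
  for (start in seq(1L, nrow(B), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(B))
    d2 <- 0
    for (k in 1:3) {
      dk <- outer(A[, k], B[idx, k], "-")
      if (periodic) dk <- .minImage1(dk, box[k])
      d2 <- d2 + dk * dk
    }
    best <- pmin(best, sqrt(.rowMins(d2)))
  }
  best
}

.rowMins <- function(m) {
  if (is.null(dim(m))) return(m)
  do.call(pmin, c(as.data.frame(m), list(na.rm = FALSE)))
}

# All pair distances within/between sets as a flat vector (for histograms).
# When A and B are the same set, each unordered pair appears once and
# self-pairs are excluded.
.pairDistanceVector <- function(A, B = NULL, box = NULL, chunk = 4096L) {
  same <- is.null(B)
  if (same) B <- A
  periodic <- !is.null(box) && .hasBox(box)
  if (same && !periodic) return(as.numeric(stats::dist(A)))
  res <- vector("list", ceiling(nrow(B) / chunk))
  j <- 0L
  for (start in seq(1L, nrow(B), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(B))
    d2 <- 0
    for (k in 1:3) {
      dk <- outer(A[, k], B[idx, k], "-")
      if (periodic) dk <- .minImage1(dk, box[k])
      d2 <- d2 + dk * dk
    }
    d <- sqrt(d2)
    if (same) {
      keep <- outer(seq_len(nrow(A)), idx, "<")
      d <- d[keep]
    }
    j <- j + 1L
    res[[j]] <- as.numeric(d)
  }
  unlist(res, use.names = FALSE)
}

#' Make molecules whole across periodic boundaries
#'
#' Unwraps each chain (and each water molecule) by minimum-image chaining:
#' the first atom of a chain anchors it and every subsequent atom is placed
#' at the minimum-image position relative to its predecessor in atom order.
#' A micelle wrapped across a periodic boundary yields a meaningless
#' gyration tensor, so the shape analyses unwrap before computing it.
#' A no-op for aperiodic configurations.
#'
#' @param x An [AtomSet-class].
#' @return An [AtomSet-class] with contiguous molecules.
#' @export
unwrapMolecules <- function(x) {
  stopifnot(methods::is(x, "AtomSet"))
  box <- x@box
  if (!.hasBox(box)) return(x)
  a <- x@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  # molecule key: polymer chains by chainId; waters by residueIndex;
  # each sodium is its own molecule
  key <- ifelse(a$atomRole %in% c("water_oxygen", "water_hydrogen"),
                paste0("w", a$residueIndex),
                ifelse(a$atomRole == "sodium", paste0("i", a$id),
                       paste0("c", a$chainId)))
  groups <- split(seq_len(nrow(a)), key)
  for (g in groups) {
    if (length(g) < 2L) next
    for (j in 2:length(g)) {
      d <- xyz[g[j], ] - xyz[g[j - 1L], ]
      xyz[g[j], ] <- xyz[g[j - 1L], ] + (d - box * round(d / box))
    }
  }
  # re-image whole molecules so the aggregate is contiguous: every
  # molecule center is brought to its minimum image relative to the
  # first polymer chain (or the first molecule when no polymer exists)
  centers <- lapply(groups, function(g) colMeans(xyz[g, , drop = FALSE]))
  polyKeys <- names(groups)[startsWith(names(groups), "c")]
  refKey <- if (length(polyKeys)) polyKeys[1] else names(groups)[1]
  ref <- centers[[refKey]]
  for (k in names(groups)) {
    d <- centers[[k]] - ref
    shift <- -box * round(d / box)
    if (any(shift != 0)) {
      g <- groups[[k]]
      xyz[g, ] <- sweep(xyz[g, , drop = FALSE], 2, shift, "+")
    }
  }
  a[, c("x", "y", "z")] <- xyz
  methods::initialize(x, atoms = a)
}
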