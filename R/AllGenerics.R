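#' @include AllClasses.R
NULL

#' Accessors for atomistic containers
#'
#' `atoms()` returns the per-atom table of an [AtomSet-class];
#' `coordsNm()` the n x 3 coordinate matrix in nanometres; `boxDims()` the
#' orthorhombic box edges in nm (or `NA` when aperiodic); `nAtoms()` the atom
#' count; `frameIndex()` the frame label of the configuration.
#'
#' @param x An `AtomSet` (or, where documented, a `MicelleSystem`).
#' @return `atoms()`: a `data.frame`; `coordsNm()`: a numeric matrix;
#'   `boxDims()`: numeric length-3; `nAtoms()`, `frameIndex()`: integers.
#' @aliases atoms coordsNm boxDims nAtoms frameIndex
#' @name atomset-accessors
#' @examples
#' a <- exampleAtomSet()
#' nAtoms(a)
#' head(atoms(a))
NULL

#' @rdname atomset-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atomset-accessors
#' @export
setGeneric("coordsNm", function(x) standardGeneric("coordsNm"))

#' @rdname atomset-accessors
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' @rdname atomset-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname atomset-accessors
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' Accessors for micelle systems
#'
#' `frames()` returns the list of per-frame [AtomSet-class] objects,
#' `nFrames()` their number, `nChains()` the aggregation number and
#' `chainSequence()` the [ChainSequence-class] shared by all chains.
#'
#' @param x A `MicelleSystem`.
#' @return See above.
#' @aliases frames nFrames nChains chainSequence
#' @name micellesystem-accessors
NULL

#' @rdname micellesystem-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname micellesystem-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname micellesystem-accessors
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))

#' @rdname micellesystem-accessors
#' @export
setGeneric("chainSequence", function(x) standardGeneric("chainSequence"))
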