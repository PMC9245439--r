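#' @include atoms.R
NULL

# chain-id <-> PDB chain letter encoding (solvent/ions are chain "0")
.CHAIN_POOL <- c(LETTERS, letters)

.chainLetter <- function(chainId) {
  ifelse(chainId == 0L, "0", .CHAIN_POOL[chainId])
}

.chainFromLetter <- function(ch) {
  out <- match(ch, .CHAIN_POOL)
  out[ch == "0" | is.na(out)] <- 0L
  as.integer(out)
}

#' Read a molecular configuration
#'
#' Reads a PDB (via bio3d) or GRO-dialect file into one [AtomSet-class] per
#' frame. Coordinates are converted to nanometres on read (PDB files are in
#' Angstroms, GRO files already in nm). Residue aliases (SOL/HOH -> WAT,
#' SOD -> NA) are normalized and atom roles inferred from the
#' (residue, atom name) mapping table; unknown residue tokens are an error
#' naming the token.
#'
#' Chain assignment: PDB chain identifiers map to integer chain ids
#' (solvent and ions are chain 0, written as PDB chain "0"). The GRO format
#' has no chain field, so polymer chains are written with per-chain residue
#' numbering restarting at 1 and are re-identified on read by those
#' numbering resets; water and sodium are always chain 0.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param map atom-role mapping table, see [roleMap()].
#' @return A single [AtomSet-class], or a list of them for multi-frame files.
#' @seealso [writeConfiguration()]
#' @export
readConfiguration <- function(path, format = c("auto", "pdb", "gro"),
                              map = roleMap()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(format, pdb = .readPDB(path, map), gro = .readGRO(path, map))
  if (length(out) == 1L) out[[1L]] else out
}

.readPDB <- function(path, map) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  a <- pdb$atom
  res <- .normalizeResidue(a$resid)
  aname <- toupper(trimws(a$elety))
  role <- .inferRoles(res, aname, map)
  tmpl <- data.frame(
    id = seq_len(nrow(a)), atomName = aname,
    element = unname(.elementForRole(role)),
    mass = .massForAtom(res, aname, role),
    x = 0, y = 0, z = 0,
    chainId = .chainFromLetter(a$chain),
    residueName = res, residueIndex = as.integer(a$resno), atomRole = role)
  xyzMat <- pdb$xyz
  if (is.null(dim(xyzMat))) xyzMat <- matrix(xyzMat, nrow = 1)
  lapply(seq_len(nrow(xyzMat)), function(f) {
    m <- matrix(xyzMat[f, ], ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
    tmpl[, c("x", "y", "z")] <- m
    AtomSet(tmpl, box = rep(NA_real_, 3), frameIndex = f)
  })
}

.readGRO <- function(path, map) {
  lines <- readLines(path)
  framesOut <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("malformed GRO: bad atom count at line ", i + 1L)
    rows <- lines[(i + 2L):(i + 1L + n)]
    boxLine <- trimws(lines[i + 2L + n])
    resno <- as.integer(substr(rows, 1, 5))
    resnm <- trimws(substr(rows, 6, 10))
    aname <- toupper(trimws(substr(rows, 11, 15)))
    xyz <- vapply(list(c(21, 28), c(29, 36), c(37, 44)),
                  function(p) suppressWarnings(
                    as.numeric(substr(rows, p[1], p[2]))),
                  numeric(n))
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    if (anyNA(xyz))
      stop("malformed GRO coordinate field(s) near line ", i + 2L)
    res <- .normalizeResidue(resnm)
    role <- .inferRoles(res, aname, map)
    solvent <- role %in% c("water_oxygen", "water_hydrogen", "sodium")
    chainId <- integer(n)
    # polymer chains: residue numbering restarts at each new chain
    poly <- which(!solvent)
    if (length(poly)) {
      rp <- resno[poly]
      newChain <- c(TRUE, diff(rp) < 0L)
      chainId[poly] <- cumsum(newChain)
    }
    boxv <- as.numeric(strsplit(boxLine, "\\s+")[[1]])[1:3]
    if (all(boxv == 0)) boxv <- rep(NA_real_, 3)
    frame <- AtomSet(data.frame(
      id = seq_len(n), atomName = aname,
      element = unname(.elementForRole(role)),
      mass = .massForAtom(res, aname, role),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      chainId = chainId, residueName = res, residueIndex = resno,
      atomRole = role), box = boxv, frameIndex = length(framesOut) + 1L)
    framesOut[[length(framesOut) + 1L]] <- frame
    i <- i + 3L + n
  }
  framesOut
}

#' Write a molecular configuration
#'
#' Writes one or more frames to PDB (via bio3d; multi-frame as
#' MODEL/ENDMDL blocks) or to the GRO dialect (multi-frame as concatenated
#' blocks). PDB coordinates are written in Angstroms, GRO in nm.
#'
#' @param x an [AtomSet-class], a list of them, or a [MicelleSystem-class].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
writeConfiguration <- function(x, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  frames <- if (methods::is(x, "MicelleSystem")) x@frames
            else if (methods::is(x, "AtomSet")) list(x) else x
  switch(format,
         pdb = .writePDB(frames, path),
         gro = .writeGRO(frames, path))
  invisible(path)
}

.writePDB <- function(frames, path) {
  multi <- length(frames) > 1L
  blocks <- lapply(seq_along(frames), function(f) {
    a <- frames[[f]]@atoms
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    suppressWarnings(bio3d::write.pdb(
      file = tmp,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]) * 10)),
      resno = a$residueIndex, resid = a$residueName,
      eleno = a$id, elety = a$atomName,
      chain = .chainLetter(a$chainId), elesy = a$element))
    txt <- readLines(tmp)
    txt <- txt[!grepl("^END", txt)]
    if (multi) c(sprintf("MODEL %8d", f), txt, "ENDMDL") else txt
  })
  writeLines(c(unlist(blocks), "END"), path)
}

.writeGRO <- function(frames, path) {
  blocks <- lapply(frames, function(fr) {
    a <- fr@atoms
    solvent <- a$atomRole %in% c("water_oxygen", "water_hydrogen", "sodium")
    resno <- a$residueIndex
    # per-chain residue numbering so chains are recoverable on read
    resno[!solvent] <- stats::ave(a$residueIndex[!solvent], a$chainId[!solvent],
                                  FUN = function(r) as.integer(factor(r)))
    box <- fr@box
    if (anyNA(box)) box <- rep(0, 3)  # GRO convention: 0-box means aperiodic
    c("MicelleMetrics configuration",
      sprintf("%5d", nrow(a)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              resno %% 100000L, a$residueName, a$atomName,
              a$id %% 100000L, a$x, a$y, a$z),
      sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  })
  writeLines(unlist(blocks), path)
}

#' Write an analysis table as CSV
#'
#' CSV writer used by the pipeline: a single documented header line
#' followed by the data, no row names, full precision.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnalysisCSV <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
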