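#' @describeIn Molecule atom count A.
#' @param x,object a Molecule.
#' @export
setMethod("nAtoms", "Molecule", function(x) length(x@elements))

#' @describeIn ConformerEnsemble atom count A of the shared topology.
#' @param x,object a ConformerEnsemble.
#' @export
setMethod("nAtoms", "ConformerEnsemble", function(x) length(x@elements))

#' @describeIn ConformerEnsemble number of frames.
#' @export
setMethod("nFrames", "ConformerEnsemble", function(x) length(x@frames))

#' @export
#' @describeIn Molecule element symbols.
setMethod("atomElements", "Molecule", function(x) x@elements)

#' @export
#' @describeIn ConformerEnsemble element symbols.
setMethod("atomElements", "ConformerEnsemble", function(x) x@elements)

#' @export
#' @describeIn Molecule A x 3 coordinate matrix.
setMethod("atomCoordinates", "Molecule", function(x) x@coordinates)

#' @export
#' @describeIn Molecule bond pair matrix.
setMethod("molBonds", "Molecule", function(x) x@bonds)

#' @export
#' @describeIn ConformerEnsemble bond pair matrix.
setMethod("molBonds", "ConformerEnsemble", function(x) x@bonds)

#' @export
#' @describeIn Molecule identifier.
setMethod("molName", "Molecule", function(x) x@name)

#' @export
#' @describeIn ConformerEnsemble identifier.
setMethod("molName", "ConformerEnsemble", function(x) x@name)

#' @describeIn ConformerEnsemble extract frame \code{i} as a Molecule.
#' @param i frame index.
#' @export
setMethod("getFrame", "ConformerEnsemble", function(x, i) {
    i <- as.integer(i)
    if (i < 1L || i > length(x@frames))
        stop("frame index ", i, " out of range [1, ", length(x@frames), "]")
    Molecule(x@elements, x@frames[[i]], x@bonds,
             name = sprintf("%s/frame%d", x@name, i))
})

#' Center coordinates on the geometric mean position
#'
#' Subtracts the unweighted column means, so the centered matrix has zero
#' column sums; interatomic distances are unchanged.
#'
#' @param coordinates numeric A x 3 matrix.
#' @return the centered A x 3 matrix.
#' @examples
#' centerCoordinates(rbind(c(0, 0, 0), c(2, 0, 0)))
#' @export
centerCoordinates <- function(coordinates) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) < 1L) stop("need at least one atom")
    sweep(coordinates, 2L, colMeans(coordinates), "-")
}

#' Perceive covalent bonds from interatomic distances
#'
#' Atoms i and j are bonded iff their distance is below
#' \code{factor * (rcov_i + rcov_j)}, using Cordero-style single-bond covalent
#' radii. This recovers connectivity for inputs that carry none (XYZ files,
#' coordinates extracted from simulation frames).
#'
#' @param elements character vector of element symbols.
#' @param coordinates numeric A x 3 matrix (Angstrom), all values finite.
#' @param factor tolerance multiplier on the summed radii (default 1.2).
#' @return integer two-column matrix of bonded pairs (atom1 < atom2).
#' @examples
#' perceiveBonds(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)))
#' @export
perceiveBonds <- function(elements, coordinates, factor = 1.2) {
    coordinates <- as.matrix(coordinates)
    if (!all(is.finite(coordinates)))
        stop("coordinates must be finite")
    A <- length(elements)
    if (nrow(coordinates) != A)
        stop("coordinate rows must equal element count")
    r <- covalentRadii(elements)
    if (A < 2L) return(.canonicalBonds(matrix(integer(0), ncol = 2L)))
    d <- as.matrix(stats::dist(coordinates))
    cutoff <- factor * outer(r, r, "+")
    hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
    .canonicalBonds(hit[, c("row", "col"), drop = FALSE])
}

.guessFormat <- function(path) {
    ext <- tolower(sub(".*\\.", "", path))
    switch(ext, sdf = "sdf", mol = "sdf", xyz = "xyz",
           pdb = "pdb", ent = "pdb",
           stop("cannot infer structure format from extension '.", ext,
                "'; pass 'format' explicitly"))
}

#' Read a molecular structure or conformer ensemble
#'
#' Supports SDF/MOL (V2000 connection table, via \pkg{ChemmineR}), XYZ
#' (element + x y z lines; bonds are perceived from covalent radii), and PDB
#' (ATOM/HETATM records, via \pkg{bio3d}; MODEL blocks become conformer
#' frames). Multi-record SDF, multi-block XYZ and multi-MODEL PDB inputs
#' yield a [ConformerEnsemble-class]; single-conformer inputs yield a
#' [Molecule-class].
#'
#' @param path file path.
#' @param format one of "auto", "sdf", "xyz", "pdb".
#' @param multi how to treat multi-record inputs: "ensemble" (default;
#'   requires one shared topology) or "list" (a list of Molecules, e.g. for a
#'   compound library SDF).
#' @param bondFactor covalent-radius multiplier for bond perception where the
#'   format carries no connectivity.
#' @return A Molecule, ConformerEnsemble, or list of Molecules.
#' @export
readStructure <- function(path, format = c("auto", "sdf", "xyz", "pdb"),
                          multi = c("ensemble", "list"), bondFactor = 1.2) {
    format <- match.arg(format)
    multi <- match.arg(multi)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") format <- .guessFormat(path)
    mols <- switch(format,
                   sdf = .readSDF(path),
                   xyz = .readXYZ(path, bondFactor),
                   pdb = .readPDB(path, bondFactor))
    if (length(mols) == 1L) return(mols[[1L]])
    if (multi == "list") return(mols)
    .molsToEnsemble(mols, provenance = path)
}

.molsToEnsemble <- function(mols, provenance = "") {
    ref <- mols[[1L]]
    A <- nAtoms(ref)
    for (m in mols[-1L]) {
        if (nAtoms(m) != A)
            stop("ensemble error: inconsistent atom counts across ",
                 "conformers (", A, " vs ", nAtoms(m), ")")
        if (!identical(atomElements(m), atomElements(ref)) ||
            !identical(molBonds(m), molBonds(ref)))
            stop("ensemble error: conformers do not share one topology; ",
                 "use multi = \"list\" for multi-molecule files")
    }
    ConformerEnsemble(atomElements(ref), molBonds(ref),
                      lapply(mols, atomCoordinates),
                      provenance = provenance, name = molName(ref))
}

.readSDF <- function(path) {
    sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                       error = function(e)
                           stop("SDF parse error in '", path, "': ",
                                conditionMessage(e), call. = FALSE))
    ok <- ChemmineR::validSDF(sdfset)
    if (!all(ok))
        stop("SDF parse error in '", path, "': record(s) ",
             paste(which(!ok), collapse = ", "), " malformed")
    lapply(seq_along(sdfset), function(i) {
        sdf <- sdfset[[i]]
        ab <- ChemmineR::atomblock(sdf)
        bb <- ChemmineR::bondblock(sdf)
        elements <- sub("_\\d+$", "", rownames(ab))
        bonds <- if (nrow(bb)) as.matrix(bb[, 1:2, drop = FALSE])
                 else matrix(integer(0), ncol = 2L)
        nm <- ChemmineR::sdfid(sdf)
        if (!length(nm) || !nzchar(nm)) nm <- sprintf("sdf_record_%d", i)
        Molecule(elements, ab[, 1:3, drop = FALSE], bonds, name = nm)
    })
}

.readXYZ <- function(path, bondFactor) {
    lines <- readLines(path)
    mols <- list()
    pos <- 1L
    while (pos <= length(lines)) {
        if (!grepl("\\S", lines[pos])) { pos <- pos + 1L; next }
        n <- suppressWarnings(as.integer(trimws(lines[pos])))
        if (is.na(n) || n < 1L)
            stop("XYZ parse error at line ", pos,
                 ": expected an atom count, got '", lines[pos], "'")
        if (pos + 1L + n > length(lines))
            stop("XYZ parse error at line ", pos, ": atom count ", n,
                 " exceeds remaining lines")
        comment <- lines[pos + 1L]
        elements <- character(n)
        xyz <- matrix(NA_real_, n, 3L)
        for (a in seq_len(n)) {
            ln <- pos + 1L + a
            tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
            if (length(tok) < 4L)
                stop("XYZ parse error at line ", ln,
                     ": expected 'element x y z', got '", lines[ln], "'")
            val <- suppressWarnings(as.numeric(tok[2:4]))
            if (anyNA(val))
                stop("XYZ parse error at line ", ln,
                     ": non-numeric coordinate in '", lines[ln], "'")
            elements[a] <- tok[1L]
            xyz[a, ] <- val
        }
        nm <- if (grepl("\\S", comment)) trimws(comment)
              else sprintf("xyz_block_%d", length(mols) + 1L)
        mols[[length(mols) + 1L]] <- list(elements = elements, xyz = xyz,
                                          name = nm)
        pos <- pos + 2L + n
    }
    if (!length(mols)) stop("XYZ parse error: no atom blocks in '", path, "'")
    bonds <- perceiveBonds(mols[[1L]]$elements, mols[[1L]]$xyz, bondFactor)
    lapply(mols, function(m) Molecule(m$elements, m$xyz, bonds, name = m$name))
}

.readPDB <- function(path, bondFactor) {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e)
                        stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    elements <- pdb$atom$elesy
    if (is.null(elements) || !all(nzchar(trimws(elements))))
        elements <- bio3d::atom2ele(pdb)
    elements <- .normalizeSymbol(elements)
    xyz <- pdb$xyz
    nframes <- nrow(xyz)
    frames <- lapply(seq_len(nframes), function(i)
        matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
    bonds <- perceiveBonds(elements, frames[[1L]], bondFactor)
    nm <- tools::file_path_sans_ext(basename(path))
    lapply(seq_len(nframes), function(i)
        Molecule(elements, frames[[i]], bonds,
                 name = if (nframes == 1L) nm
                        else sprintf("%s_model%d", nm, i)))
}

#' Write a structure or ensemble to SDF, XYZ or PDB
#'
#' Ensembles become multi-record SDF, multi-block XYZ, or multi-MODEL PDB.
#' Coordinates are written at the format's customary precision (SDF/XYZ four
#' or more decimals, PDB three).
#'
#' @param x a [Molecule-class] or [ConformerEnsemble-class].
#' @param path output file path.
#' @param format "auto" (from the extension), "sdf", "xyz" or "pdb".
#' @return invisibly, \code{path}.
#' @export
writeStructure <- function(x, path, format = c("auto", "sdf", "xyz", "pdb")) {
    format <- match.arg(format)
    if (format == "auto") format <- .guessFormat(path)
    frames <- if (is(x, "ConformerEnsemble")) x@frames
              else list(atomCoordinates(x))
    lines <- switch(format,
        sdf = .formatSDF(atomElements(x), molBonds(x), frames, molName(x)),
        xyz = .formatXYZ(atomElements(x), frames, molName(x)),
        pdb = .formatPDB(atomElements(x), frames))
    writeLines(lines, path)
    invisible(path)
}

.formatSDF <- function(elements, bonds, frames, name) {
    unlist(lapply(seq_along(frames), function(f) {
        xyz <- frames[[f]]
        c(name, "  RGetaway", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                  length(elements), nrow(bonds)),
          sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                  xyz[, 1L], xyz[, 2L], xyz[, 3L], elements),
          if (nrow(bonds))
              sprintf("%3d%3d%3d%3d", bonds[, 1L], bonds[, 2L], 1L, 0L),
          "M  END", "$$$$")
    }))
}

.formatXYZ <- function(elements, frames, name) {
    unlist(lapply(frames, function(xyz)
        c(sprintf("%d", length(elements)), name,
          sprintf("%-3s %14.8f %14.8f %14.8f",
                  elements, xyz[, 1L], xyz[, 2L], xyz[, 3L]))))
}

.formatPDB <- function(elements, frames) {
    multi <- length(frames) > 1L
    A <- length(elements)
    atomName <- substr(paste0(toupper(elements), seq_len(A)), 1L, 4L)
    body <- lapply(seq_along(frames), function(f) {
        xyz <- frames[[f]]
        rec <- sprintf(
            "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(A), atomName, xyz[, 1L], xyz[, 2L], xyz[, 3L],
            1, 0, toupper(elements))
        if (multi) c(sprintf("MODEL %8d", f), rec, "ENDMDL") else rec
    })
    c(unlist(body), "END")
}
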