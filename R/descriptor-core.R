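#' Molecular influence (leverage) matrix
#'
#' Computes H = M (M'M)^- M' from the centered molecular matrix M (A x 3
#' coordinates), exactly as the hat matrix of a linear regression on the
#' coordinates. The diagonal entries h_ii are the leverages: atoms far from
#' the molecular geometric center have high leverage. A Moore-Penrose
#' pseudo-inverse handles rank-deficient (planar or collinear) geometries, for
#' which trace(H) drops from 3 to 2 or 1.
#'
#' @param coordinates numeric A x 3 matrix, already centered (column means
#'   zero to within 1e-6 of the coordinate scale); see [centerCoordinates()].
#' @return An [InfluenceResult-class] with the full matrix and its diagonal.
#' @examples
#' xyz <- centerCoordinates(cbind(0:3, 0, 0))
#' leverages(influenceMatrix(xyz))  # 0.45 0.05 0.05 0.45
#' @export
influenceMatrix <- function(coordinates) {
    M <- as.matrix(coordinates)
    if (nrow(M) < 1L) stop("need at least one atom")
    scale <- max(abs(M), 1e-12)
    if (any(abs(colMeans(M)) > 1e-6 * scale))
        stop("coordinates are not centered; call centerCoordinates() first")
    H <- M %*% MASS::ginv(crossprod(M)) %*% t(M)
    H <- (H + t(H)) / 2
    h <- pmin(pmax(diag(H), 0), 1)
    new("InfluenceResult", H = H, leverages = h)
}

#' @describeIn influenceMatrix leverages stored in an InfluenceResult.
#' @param x an InfluenceResult.
#' @export
setMethod("leverages", "InfluenceResult", function(x) x@leverages)

#' Topological distance matrix
#'
#' Minimum bond-count path lengths between all atom pairs, from breadth-first
#' search on the (unweighted) bond graph. Pairs in different connected
#' fragments get \code{Inf} and never contribute to any autocorrelation lag.
#'
#' @param bonds two-column matrix of bonded atom index pairs.
#' @param nAtoms total atom count A.
#' @return numeric A x A matrix; d_ii = 0, unreachable pairs Inf.
#' @examples
#' topologicalDistances(rbind(c(1, 2), c(2, 3), c(3, 4)), 4)[1, 4]  # 3
#' @export
topologicalDistances <- function(bonds, nAtoms) {
    nAtoms <- as.integer(nAtoms)
    bonds <- .canonicalBonds(bonds)
    g <- igraph::make_empty_graph(n = nAtoms, directed = FALSE)
    if (nrow(bonds))
        g <- igraph::add_edges(g, as.vector(t(bonds)))
    D <- igraph::distances(g)
    dimnames(D) <- NULL
    D
}

.rAutoCore <- function(elements, coordinates, bonds, k, weights, name) {
    A <- length(elements)
    if (A < 2L) stop("descriptor needs at least two atoms")
    k <- as.integer(k)
    if (k < 1L) stop("'k' must be a positive integer lag")
    cc <- centerCoordinates(coordinates)
    h <- leverages(influenceMatrix(cc))
    w <- if (weights == "mass") normalizedMasses(elements) else rep(1, A)
    D <- topologicalDistances(bonds, A)
    perAtom <- numeric(A)
    idx <- which(D == k & upper.tri(D), arr.ind = TRUE)
    value <- 0
    if (nrow(idx)) {
        i <- idx[, 1L]; j <- idx[, 2L]
        rij <- sqrt(rowSums((cc[i, , drop = FALSE] -
                             cc[j, , drop = FALSE])^2))
        if (any(rij == 0))
            stop("degenerate geometry: atoms ",
                 paste(sprintf("(%d,%d)", i[rij == 0], j[rij == 0]),
                       collapse = ", "),
                 " coincide on a contributing pair (r_ij = 0)")
        terms <- sqrt(h[i] * h[j]) / rij * w[i] * w[j]
        value <- sum(terms)
        half <- terms / 2
        perAtom <- as.vector(tapply(c(half, half), factor(c(i, j),
                                    levels = seq_len(A)), sum))
        perAtom[is.na(perAtom)] <- 0
    }
    new("DescriptorResult", value = value, k = k, weightScheme = weights,
        perAtom = perAtom, leverages = h, elements = elements,
        name = name)
}

#' @describeIn rAutocorrelation compute R_k.w for one conformation; returns a
#'   [DescriptorResult-class] carrying the value, leverages and the per-atom
#'   decomposition (each pair term split half-and-half).
#' @export
setMethod("rAutocorrelation", "Molecule", function(x, k = 3L,
                                                   weights = c("mass",
                                                               "unit")) {
    weights <- match.arg(weights)
    .rAutoCore(x@elements, x@coordinates, x@bonds, k, weights, x@name)
})

#' @describeIn rAutocorrelation one descriptor value per frame, in frame
#'   order; identical to computing on each extracted Molecule.
#' @export
setMethod("rAutocorrelation", "ConformerEnsemble",
          function(x, k = 3L, weights = c("mass", "unit")) {
    weights <- match.arg(weights)
    vapply(seq_along(x@frames), function(f) {
        res <- tryCatch(
            .rAutoCore(x@elements, x@frames[[f]], x@bonds, k, weights,
                       x@name),
            error = function(e) stop("frame ", f, ": ",
                                     conditionMessage(e), call. = FALSE))
        res@value
    }, numeric(1))
})

#' @describeIn r3m the k = 3, mass-weighted autocorrelation of one
#'   conformation.
#' @export
setMethod("r3m", "Molecule", function(x)
    rAutocorrelation(x, k = 3L, weights = "mass"))

#' @describeIn r3m numeric vector of R3m values, one per conformer frame.
#' @export
setMethod("r3m", "ConformerEnsemble", function(x)
    rAutocorrelation(x, k = 3L, weights = "mass"))

#' @export
#' @describeIn DescriptorResult the descriptor value.
#' @param x,object a DescriptorResult.
setMethod("descriptorValue", "DescriptorResult", function(x) x@value)

#' @export
#' @describeIn DescriptorResult per-atom contribution vector.
setMethod("perAtomContributions", "DescriptorResult", function(x) x@perAtom)

#' @export
#' @describeIn DescriptorResult leverages used in the computation.
setMethod("leverages", "DescriptorResult", function(x) x@leverages)

#' @export
#' @describeIn DescriptorResult element symbols.
setMethod("atomElements", "DescriptorResult", function(x) x@elements)

#' @export
#' @describeIn DescriptorResult molecule identifier.
setMethod("molName", "DescriptorResult", function(x) x@name)

#' Percentage contribution of selected elements to a descriptor value
#'
#' Sums the per-atom contributions of atoms whose element symbol is in
#' \code{selection} and expresses the sum as a percentage of the descriptor
#' value (e.g. the share carried by the heavy heteroatoms N, O and S). A
#' zero-valued descriptor contributes 0\% by definition.
#'
#' @param result a [DescriptorResult-class].
#' @param selection character vector of element symbols.
#' @return percentage in [0, 100].
#' @export
atomContributions <- function(result, selection = c("N", "O", "S")) {
    stopifnot(is(result, "DescriptorResult"))
    if (result@value == 0) return(0)
    sel <- .normalizeSymbol(result@elements) %in% .normalizeSymbol(selection)
    100 * sum(result@perAtom[sel]) / result@value
}

#' Per-atom contribution table
#'
#' @param result a [DescriptorResult-class].
#' @return data.frame with atom index, element, leverage, contribution and
#'   percent of the descriptor value (suitable for CSV export).
#' @export
contributionTable <- function(result) {
    stopifnot(is(result, "DescriptorResult"))
    A <- length(result@elements)
    data.frame(atom = seq_len(A), element = result@elements,
               leverage = result@leverages, contribution = result@perAtom,
               percent = if (result@value > 0)
                   100 * result@perAtom / result@value else rep(0, A))
}

#' Signed dihedral (torsion) angle of four points
#'
#' Standard atan2 construction about the axis through points 2 and 3; the
#' result lies in (-180, 180] degrees, with 180 for the planar trans (zig-zag)
#' arrangement and 0 for eclipsed cis.
#'
#' @param p 4 x 3 numeric matrix of Cartesian coordinates, in chain order.
#' @return angle in degrees.
#' @examples
#' dihedralAngle(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)))
#' @export
dihedralAngle <- function(p) {
    p <- as.matrix(p)
    stopifnot(nrow(p) == 4L, ncol(p) == 3L)
    cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                              a[3] * b[1] - a[1] * b[3],
                              a[1] * b[2] - a[2] * b[1])
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    scale <- max(sqrt(sum(b1^2)) * sqrt(sum(b2^2)),
                 sqrt(sum(b2^2)) * sqrt(sum(b3^2)))
    if (sqrt(sum(n1^2)) < 1e-10 * scale || sqrt(sum(n2^2)) < 1e-10 * scale)
        stop("undefined torsion: three consecutive points are collinear")
    m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
    ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
    if (ang <= -180) ang <- ang + 360
    ang
}
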