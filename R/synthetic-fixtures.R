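#' Chain molecule fixture with analytically known descriptor values
#'
#' Builds an n-atom bonded chain with uniform spacing, centered at the
#' origin. The "linear" geometry places all atoms on the x axis, for which
#' the leverages have the closed form x_i^2 / sum(x^2) and every R_k.w value
#' follows by hand (see [chainGroundTruth()]). The "zigzag" geometry is a
#' planar trans chain with tetrahedral-like backbone angles, useful as a
#' torsion-perturbation substrate (a linear chain has no torsional degrees of
#' freedom).
#'
#' @param nAtoms chain length, >= 2.
#' @param spacing bond length in Angstrom (> 0).
#' @param elements single symbol recycled, or length-n vector.
#' @param geometry "linear" or "zigzag".
#' @return a [Molecule-class].
#' @examples
#' descriptorValue(r3m(makeChainMolecule(4)))  # 0.15
#' @export
makeChainMolecule <- function(nAtoms, spacing = 1, elements = "C",
                              geometry = c("linear", "zigzag")) {
    geometry <- match.arg(geometry)
    nAtoms <- as.integer(nAtoms)
    if (nAtoms < 2L) stop("a chain needs at least 2 atoms")
    if (spacing <= 0) stop("'spacing' must be positive")
    elements <- rep_len(elements, nAtoms)
    if (geometry == "linear") {
        xyz <- cbind(spacing * (seq_len(nAtoms) - 1), 0, 0)
    } else {
        # planar trans zig-zag, backbone angle 109.47 deg, bond length
        # = spacing
        half <- (180 - 109.47) / 2 * pi / 180
        dx <- spacing * cos(half)
        dy <- spacing * sin(half)
        xyz <- cbind(dx * (seq_len(nAtoms) - 1),
                     dy * (seq_len(nAtoms) %% 2L), 0)
    }
    bonds <- cbind(seq_len(nAtoms - 1L), 2:nAtoms)
    Molecule(elements, centerCoordinates(xyz), bonds,
             name = sprintf("%s_chain_%d", geometry, nAtoms))
}

#' Closed-form ground truth for a linear chain
#'
#' For a collinear chain along x with uniform spacing, the centered influence
#' matrix has leverages h_i = x_i^2 / sum(x^2) and the only pairs at
#' topological lag k are (i, i + k) at Euclidean distance k * spacing, so
#' R_k.w = sum_i sqrt(h_i h_(i+k)) / (k * spacing) * w_i * w_(i+k).
#' Computed here directly from that closed form, independently of the
#' production descriptor path, so it can serve as an oracle.
#'
#' @param nAtoms chain length.
#' @param spacing bond length (Angstrom).
#' @param elements element symbol(s), recycled.
#' @param k topological lag.
#' @param weights "mass" or "unit".
#' @return list with \code{leverages} and \code{value}.
#' @examples
#' chainGroundTruth(5)$value  # 2/15
#' @export
chainGroundTruth <- function(nAtoms, spacing = 1, elements = "C", k = 3L,
                             weights = c("mass", "unit")) {
    weights <- match.arg(weights)
    nAtoms <- as.integer(nAtoms)
    elements <- rep_len(elements, nAtoms)
    x <- spacing * (seq_len(nAtoms) - 1)
    x <- x - mean(x)
    h <- x^2 / sum(x^2)
    w <- if (weights == "mass") normalizedMasses(elements)
         else rep(1, nAtoms)
    value <- 0
    if (nAtoms > k) {
        i <- seq_len(nAtoms - k)
        value <- sum(sqrt(h[i] * h[i + k]) / (k * spacing) * w[i] * w[i + k])
    }
    list(leverages = h, value = value)
}

.rotatableBonds <- function(elements, bonds) {
    A <- length(elements)
    g <- igraph::make_empty_graph(n = A, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(t(bonds)))
    deg <- igraph::degree(g)
    bridges <- igraph::bridges(g)
    rot <- vapply(seq_len(nrow(bonds)), function(e) {
        i <- bonds[e, 1L]; j <- bonds[e, 2L]
        eid <- igraph::get_edge_ids(g, c(i, j))
        (eid %in% bridges) && deg[i] >= 2L && deg[j] >= 2L
    }, logical(1))
    bonds[rot, , drop = FALSE]
}

.rodrigues <- function(v, axis, theta) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3L, 3L)
    R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
    v %*% t(R)
}

#' Torsion-perturbed conformer ensemble
#'
#' Emulates the conformational spread of a flexible molecule: every rotatable
#' bond (an acyclic bond whose two atoms both have further neighbours)
#' receives an independent uniform twist within +/- \code{maxTwist} degrees in
#' each conformer. One side of the bond is rotated rigidly about the bond
#' axis, so all bond lengths are preserved exactly. Twists are uniform, not
#' Boltzmann-weighted: these ensembles exercise descriptor plumbing and are
#' not molecular dynamics surrogates.
#'
#' @param molecule a [Molecule-class] with at least one rotatable bond.
#' @param nConformers number of frames to generate.
#' @param maxTwist maximum absolute twist per bond, degrees.
#' @param seed integer seed; the ensemble is deterministic given
#'   (molecule, nConformers, maxTwist, seed).
#' @return a [ConformerEnsemble-class] with \code{nConformers} frames.
#' @export
perturbTorsions <- function(molecule, nConformers, maxTwist, seed = 1L) {
    stopifnot(is(molecule, "Molecule"))
    rot <- .rotatableBonds(molecule@elements, molecule@bonds)
    if (nrow(rot) < 1L)
        stop("molecule has no rotatable (non-ring, non-terminal) bond")
    nConformers <- as.integer(nConformers)
    A <- nAtoms(molecule)
    g <- igraph::make_empty_graph(n = A, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(t(molecule@bonds)))
    # atoms on the j side of each rotatable bond, fixed topology
    sides <- lapply(seq_len(nrow(rot)), function(e) {
        i <- rot[e, 1L]; j <- rot[e, 2L]
        g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
        memb <- igraph::components(g2)$membership
        setdiff(which(memb == memb[j]), j)
    })
    old <- if (exists(".Random.seed", envir = globalenv()))
               get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
    twists <- matrix(stats::runif(nConformers * nrow(rot),
                                  -maxTwist, maxTwist) * pi / 180,
                     nConformers, nrow(rot))
    frames <- lapply(seq_len(nConformers), function(c_) {
        xyz <- molecule@coordinates
        for (e in seq_len(nrow(rot))) {
            i <- rot[e, 1L]; j <- rot[e, 2L]
            axis <- xyz[j, ] - xyz[i, ]
            side <- sides[[e]]
            if (length(side))
                xyz[side, ] <- .rodrigues(
                    sweep(xyz[side, , drop = FALSE], 2L, xyz[j, ], "-"),
                    axis, twists[c_, e]) +
                    matrix(xyz[j, ], length(side), 3L, byrow = TRUE)
        }
        xyz
    })
    ConformerEnsemble(molecule@elements, molecule@bonds, frames,
                      provenance = sprintf(
                          "torsion perturbation: %d conformers, +/-%g deg, seed %d",
                          nConformers, maxTwist, as.integer(seed)),
                      name = molecule@name)
}

#' Simulate a Bernoulli-logistic labeled descriptor dataset
#'
#' Descriptor values are drawn uniformly on \code{xRange} and labels from
#' Bernoulli(plogis(beta0 + beta1 * x)); the standard parameter-recovery
#' fixture for [fitLogistic()].
#'
#' @param beta0,beta1 true logistic coefficients.
#' @param n sample size, >= 2.
#' @param xRange length-2 numeric range for the descriptor values.
#' @param seed integer seed (deterministic output).
#' @return list with \code{values} and \code{labels}.
#' @export
simulateLabeledDataset <- function(beta0, beta1, n, xRange = c(0.55, 0.72),
                                   seed = 1L) {
    n <- as.integer(n)
    if (n < 2L) stop("need n >= 2")
    if (length(xRange) != 2L || xRange[2L] <= xRange[1L])
        stop("'xRange' must be an increasing length-2 range")
    old <- if (exists(".Random.seed", envir = globalenv()))
               get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
    x <- stats::runif(n, xRange[1L], xRange[2L])
    p <- stats::plogis(beta0 + beta1 * x)
    list(values = x, labels = stats::rbinom(n, 1L, p))
}
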