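#' @import methods
NULL

.canonicalBonds <- function(bonds) {
    bonds <- as.matrix(bonds)
    if (length(bonds) == 0L)
        return(matrix(integer(0), ncol = 2L,
                      dimnames = list(NULL, c("atom1", "atom2"))))
    storage.mode(bonds) <- "integer"
    swap <- bonds[, 1L] > bonds[, 2L]
    bonds[swap, ] <- bonds[swap, c(2L, 1L)]
    bonds <- unique(bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE])
    dimnames(bonds) <- list(NULL, c("atom1", "atom2"))
    bonds
}

#' Molecule: one 3D conformation of a small molecule
#'
#' Holds element symbols, Cartesian coordinates (Angstrom) and the covalent
#' bond graph for a single conformation. Atom indices are 1-based.
#'
#' @slot elements character vector of element symbols, one per atom.
#' @slot coordinates numeric A x 3 matrix of Cartesian coordinates (Angstrom).
#' @slot bonds integer matrix with two columns (\code{atom1 < atom2}), one row
#'   per covalent bond; no self-bonds or duplicates.
#' @slot name free-text identifier.
#' @aliases Molecule-class
#' @exportClass Molecule
setClass("Molecule",
    slots = c(elements = "character", coordinates = "matrix",
              bonds = "matrix", name = "character"))

setValidity("Molecule", function(object) {
    msgs <- character(0)
    A <- length(object@elements)
    xyz <- object@coordinates
    if (!is.numeric(xyz) || ncol(xyz) != 3L)
        msgs <- c(msgs, "'coordinates' must be a numeric A x 3 matrix")
    else if (nrow(xyz) != A)
        msgs <- c(msgs, sprintf(
            "coordinate rows (%d) must equal atom count (%d)", nrow(xyz), A))
    b <- object@bonds
    if (ncol(b) != 2L)
        msgs <- c(msgs, "'bonds' must have two columns")
    else if (nrow(b) > 0L) {
        if (any(b < 1L) || any(b > A))
            msgs <- c(msgs, "bond indices out of range")
        if (any(b[, 1L] == b[, 2L]))
            msgs <- c(msgs, "self-bonds are not allowed")
        key <- paste(pmin(b[, 1L], b[, 2L]), pmax(b[, 1L], b[, 2L]))
        if (anyDuplicated(key))
            msgs <- c(msgs, "duplicate bonds are not allowed")
    }
    if (length(object@name) != 1L)
        msgs <- c(msgs, "'name' must be a single string")
    if (length(msgs)) msgs else TRUE
})

#' Construct a Molecule
#'
#' @param elements character vector of element symbols.
#' @param coordinates numeric A x 3 matrix (Angstrom).
#' @param bonds two-column matrix of 1-based atom index pairs; unordered pairs
#'   are canonicalised (smaller index first) and de-duplicated.
#' @param name identifier string.
#' @return A [Molecule-class] object.
#' @examples
#' m <- Molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
#'               rbind(c(1, 2)), name = "ethane backbone")
#' nAtoms(m)
#' @export
Molecule <- function(elements, coordinates,
                     bonds = matrix(integer(0), ncol = 2L),
                     name = "molecule") {
    coordinates <- as.matrix(coordinates)
    storage.mode(coordinates) <- "double"
    dimnames(coordinates) <- list(NULL, c("x", "y", "z"))
    new("Molecule", elements = as.character(elements),
        coordinates = coordinates, bonds = .canonicalBonds(bonds),
        name = as.character(name))
}

#' ConformerEnsemble: one topology, many coordinate sets
#'
#' A shared set of elements and bonds plus an ordered list of A x 3 coordinate
#' frames (one per conformation), as produced e.g. by sampling an amorphous-cell
#' molecular dynamics trajectory or by synthetic torsion perturbation.
#'
#' @slot elements character vector of element symbols (shared topology).
#' @slot bonds integer bond matrix (shared topology).
#' @slot frames list of numeric A x 3 coordinate matrices, at least one.
#' @slot provenance free-text origin note (e.g. cell id, frame times).
#' @slot name identifier.
#' @aliases ConformerEnsemble-class
#' @exportClass ConformerEnsemble
setClass("ConformerEnsemble",
    slots = c(elements = "character", bonds = "matrix", frames = "list",
              provenance = "character", name = "character"))

setValidity("ConformerEnsemble", function(object) {
    A <- length(object@elements)
    if (length(object@frames) < 1L)
        return("an ensemble needs at least one frame")
    bad <- vapply(object@frames, function(f)
        !is.numeric(f) || !is.matrix(f) || nrow(f) != A || ncol(f) != 3L,
        logical(1))
    if (any(bad))
        return(sprintf("frame(s) %s are not %d x 3 numeric matrices",
                       paste(which(bad), collapse = ", "), A))
    TRUE
})

#' Construct a ConformerEnsemble
#'
#' @param elements character vector of element symbols.
#' @param bonds two-column bond index matrix (shared by all frames).
#' @param frames list of A x 3 coordinate matrices.
#' @param provenance free-text origin description.
#' @param name identifier string.
#' @return A [ConformerEnsemble-class] object.
#' @export
ConformerEnsemble <- function(elements, bonds, frames,
                              provenance = "", name = "ensemble") {
    frames <- lapply(frames, function(f) {
        f <- as.matrix(f)
        storage.mode(f) <- "double"
        dimnames(f) <- list(NULL, c("x", "y", "z"))
        f
    })
    new("ConformerEnsemble", elements = as.character(elements),
        bonds = .canonicalBonds(bonds), frames = frames,
        provenance = as.character(provenance), name = as.character(name))
}

#' InfluenceResult: molecular influence (leverage) matrix
#'
#' The projection matrix H = M (M'M)^- M' of the centered molecular matrix M
#' (A x 3 coordinates). Its diagonal holds the leverages h_ii, which measure
#' each atom's displacement from the molecular geometric center.
#'
#' @slot H numeric A x A symmetric idempotent matrix.
#' @slot leverages numeric vector diag(H), each in [0, 1].
#' @aliases InfluenceResult-class
#' @exportClass InfluenceResult
setClass("InfluenceResult",
    slots = c(H = "matrix", leverages = "numeric"))

setValidity("InfluenceResult", function(object) {
    H <- object@H
    if (nrow(H) != ncol(H)) return("'H' must be square")
    if (length(object@leverages) != nrow(H))
        return("'leverages' length must match dim(H)")
    if (max(abs(H - t(H))) > 1e-8) return("'H' must be symmetric")
    if (max(abs(H %*% H - H)) > 1e-8) return("'H' must be idempotent")
    if (any(object@leverages < -1e-10 | object@leverages > 1 + 1e-10))
        return("leverages must lie in [0, 1]")
    TRUE
})

#' DescriptorResult: an R-GETAWAY autocorrelation value with decomposition
#'
#' @slot value the descriptor value R_k.w (dimensionless, non-negative).
#' @slot k integer topological lag.
#' @slot weightScheme "mass" (atomic mass normalized to carbon) or "unit".
#' @slot perAtom numeric length-A vector; each contributing pair term is split
#'   half-and-half between its two atoms, so the vector sums to \code{value}.
#' @slot leverages numeric length-A leverage vector used in the computation.
#' @slot elements character length-A element symbols (for selections).
#' @slot name molecule identifier.
#' @aliases DescriptorResult-class
#' @exportClass DescriptorResult
setClass("DescriptorResult",
    slots = c(value = "numeric", k = "integer", weightScheme = "character",
              perAtom = "numeric", leverages = "numeric",
              elements = "character", name = "character"))

setValidity("DescriptorResult", function(object) {
    A <- length(object@elements)
    if (length(object@perAtom) != A || length(object@leverages) != A)
        return("'perAtom' and 'leverages' must have one entry per atom")
    if (object@value < 0) return("'value' must be non-negative")
    if (abs(sum(object@perAtom) - object@value) > 1e-10 * max(1, object@value))
        return("per-atom contributions must sum to 'value'")
    TRUE
})

#' DistributionSummary: box-plot statistics of a descriptor sample
#'
#' Quartiles use linear interpolation between order statistics (type 7);
#' whiskers extend to the most extreme sample points within 1.5 x IQR of the
#' quartiles; points beyond the whiskers are outliers.
#'
#' @slot n sample size.
#' @slot median,mean,q1,q3 numeric summary statistics.
#' @slot whiskerLow,whiskerHigh whisker end points.
#' @slot outliers numeric vector of points beyond the whiskers.
#' @slot values the raw sample.
#' @aliases DistributionSummary-class
#' @exportClass DistributionSummary
setClass("DistributionSummary",
    slots = c(n = "integer", median = "numeric", mean = "numeric",
              q1 = "numeric", q3 = "numeric", whiskerLow = "numeric",
              whiskerHigh = "numeric", outliers = "numeric",
              values = "numeric"))

setValidity("DistributionSummary", function(object) {
    if (!(object@q1 <= object@median && object@median <= object@q3))
        return("need q1 <= median <= q3")
    if (object@whiskerLow < min(object@values) ||
        object@whiskerHigh > max(object@values))
        return("whiskers must lie within the sample range")
    if (length(object@outliers) &&
        any(object@outliers >= object@whiskerLow &
            object@outliers <= object@whiskerHigh))
        return("outliers must fall outside the whiskers")
    TRUE
})

#' FitDiagnostics: likelihood-based diagnostics of a logistic fit
#'
#' @slot logLik fitted-model log-likelihood.
#' @slot nullLogLik intercept-only log-likelihood.
#' @slot pseudoR2 McFadden pseudo-R^2, 1 - logLik/nullLogLik.
#' @slot chiSquare likelihood-ratio statistic 2(logLik - nullLogLik), 1 df.
#' @slot pValue upper-tail chi-square p-value (1 df).
#' @slot n number of observations.
#' @slot stdErrors estimated standard errors of (intercept, slope).
#' @slot separated TRUE when complete separation was detected.
#' @aliases FitDiagnostics-class
#' @exportClass FitDiagnostics
setClass("FitDiagnostics",
    slots = c(logLik = "numeric", nullLogLik = "numeric",
              pseudoR2 = "numeric", chiSquare = "numeric",
              pValue = "numeric", n = "integer", stdErrors = "numeric",
              separated = "logical"))

setValidity("FitDiagnostics", function(object) {
    if (object@chiSquare < -1e-8)
        return("chi-square statistic must be non-negative")
    if (object@pseudoR2 < -1e-8 || object@pseudoR2 > 1 + 1e-8)
        return("pseudo-R^2 must lie in [0, 1]")
    TRUE
})

#' LogisticModel: logit P(disperse) = intercept + slope * R3m
#'
#' @slot intercept beta0 on the logit scale.
#' @slot slope beta1, logit units per unit R3m.
#' @slot fitted TRUE for maximum-likelihood fits, FALSE for fixed-coefficient
#'   models such as [publishedModel()].
#' @slot diagnostics a [FitDiagnostics-class] object, or NULL.
#' @aliases LogisticModel-class
#' @exportClass LogisticModel
setClass("LogisticModel",
    slots = c(intercept = "numeric", slope = "numeric", fitted = "logical",
              diagnostics = "ANY"))

setValidity("LogisticModel", function(object) {
    if (!is.finite(object@intercept) || !is.finite(object@slope))
        return("coefficients must be finite")
    if (object@slope == 0)
        return("slope must be nonzero for a usable boundary")
    TRUE
})

#' Construct a LogisticModel from coefficients
#'
#' @param intercept,slope coefficients on the logit scale.
#' @param fitted whether the coefficients come from a maximum-likelihood fit.
#' @param diagnostics optional [FitDiagnostics-class].
#' @return A [LogisticModel-class].
#' @export
LogisticModel <- function(intercept, slope, fitted = FALSE,
                          diagnostics = NULL) {
    new("LogisticModel", intercept = as.numeric(intercept),
        slope = as.numeric(slope), fitted = isTRUE(fitted),
        diagnostics = diagnostics)
}

setMethod("show", "Molecule", function(object) {
    cat(sprintf("Molecule '%s': %d atoms (%s), %d bonds\n", object@name,
                length(object@elements),
                paste(names(sort(-table(object@elements))), collapse = ","),
                nrow(object@bonds)))
})

setMethod("show", "ConformerEnsemble", function(object) {
    cat(sprintf("ConformerEnsemble '%s': %d atoms, %d bonds, %d frames\n",
                object@name, length(object@elements), nrow(object@bonds),
                length(object@frames)))
    if (nzchar(object@provenance))
        cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "DescriptorResult", function(object) {
    cat(sprintf("R%d%s = %.6g  ('%s', %d atoms)\n", object@k,
                if (object@weightScheme == "mass") "m" else "u",
                object@value, object@name, length(object@elements)))
})

setMethod("show", "DistributionSummary", function(object) {
    cat(sprintf(
        "DistributionSummary: n=%d median=%.4g mean=%.4g IQR=[%.4g, %.4g]\n",
        object@n, object@median, object@mean, object@q1, object@q3))
    cat(sprintf("  whiskers [%.4g, %.4g], %d outlier(s)\n",
                object@whiskerLow, object@whiskerHigh,
                length(object@outliers)))
})

setMethod("show", "LogisticModel", function(object) {
    cat(sprintf("LogisticModel: logit P(Y) = %.4g + %.4g * R3m  (%s)\n",
                object@intercept, object@slope,
                if (object@fitted) "fitted" else "fixed coefficients"))
    cat(sprintf("  50%% boundary at R3m = %.3f\n", decisionBoundary(object)))
    d <- object@diagnostics
    if (is(d, "FitDiagnostics"))
        cat(sprintf(
            "  n=%d logLik=%.4g pseudo-R2=%.3f chi2=%.4g p=%.3g%s\n",
            d@n, d@logLik, d@pseudoR2, d@chiSquare, d@pValue,
            if (d@separated) " [SEPARATED]" else ""))
})
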