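#' Equally spaced frame times inside a trajectory window
#'
#' Reproduces the frame-selection bookkeeping used when sampling an
#' equilibrated molecular dynamics window: \code{count} equally spaced times
#' inclusive of both endpoints (e.g. 7 frames over the final 300 ps of a
#' 500 ps run gives 200, 250, ..., 500 ps). With \code{count = 1} the window
#' end is returned.
#'
#' @param windowStart,windowEnd window limits (same time unit, end > start).
#' @param count number of frames, >= 1.
#' @return numeric vector of \code{count} frame times.
#' @examples
#' selectFrames(200, 500, 7)
#' @export
selectFrames <- function(windowStart, windowEnd, count) {
    if (windowEnd <= windowStart)
        stop("window must have positive extent (windowEnd > windowStart)")
    count <- as.integer(count)
    if (count < 1L) stop("'count' must be >= 1")
    if (count == 1L) return(windowEnd)
    seq(windowStart, windowEnd, length.out = count)
}

#' Split a multi-molecule simulation frame into per-molecule conformations
#'
#' An amorphous-cell frame stores \code{nMolecules} copies of one molecule as
#' consecutive atom blocks. Given the single-molecule topology, the frame is
#' cut into per-molecule coordinate sets.
#'
#' @param elements element symbols of ONE molecule (length A).
#' @param bonds bond matrix of one molecule (1-based within the molecule).
#' @param frameCoordinates (A * nMolecules) x 3 coordinate matrix.
#' @param nMolecules number of molecule copies in the frame.
#' @return a [ConformerEnsemble-class] with one frame per extracted molecule.
#' @export
extractMolecules <- function(elements, bonds, frameCoordinates, nMolecules) {
    A <- length(elements)
    frameCoordinates <- as.matrix(frameCoordinates)
    nMolecules <- as.integer(nMolecules)
    if (nrow(frameCoordinates) != A * nMolecules)
        stop("frame has ", nrow(frameCoordinates), " rows; expected ",
             A, " atoms x ", nMolecules, " molecules")
    frames <- lapply(seq_len(nMolecules), function(m)
        frameCoordinates[(m - 1L) * A + seq_len(A), , drop = FALSE])
    ConformerEnsemble(elements, bonds, frames,
                      provenance = sprintf("extracted %d molecules",
                                           nMolecules))
}

#' Descriptor values across a conformer ensemble
#'
#' One descriptor value per frame, in frame order; each equals the value
#' computed on the extracted single Molecule.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param k topological lag (default 3).
#' @param weights "mass" or "unit".
#' @return numeric vector, one value per frame.
#' @export
ensembleDescriptor <- function(ensemble, k = 3L,
                               weights = c("mass", "unit")) {
    stopifnot(is(ensemble, "ConformerEnsemble"))
    weights <- match.arg(weights)
    rAutocorrelation(ensemble, k = k, weights = weights)
}

#' Box-plot summary of a descriptor sample
#'
#' Quartiles by linear interpolation between order statistics
#' (\code{quantile} type 7); whiskers extend to the most extreme sample points
#' within 1.5 x IQR beyond the quartiles; points beyond the whiskers are
#' flagged as outliers.
#'
#' @param values numeric sample, n >= 1.
#' @return a [DistributionSummary-class].
#' @examples
#' summarizeDistribution(c(1, 1, 1, 1, 100))
#' @export
summarizeDistribution <- function(values) {
    values <- as.numeric(values)
    if (!length(values)) stop("empty sample")
    if (anyNA(values)) stop("sample contains NA")
    q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    loFence <- q[1] - 1.5 * iqr
    hiFence <- q[3] + 1.5 * iqr
    inside <- values >= loFence & values <= hiFence
    new("DistributionSummary", n = length(values), median = q[2],
        mean = mean(values), q1 = q[1], q3 = q[3],
        whiskerLow = min(values[inside]), whiskerHigh = max(values[inside]),
        outliers = values[!inside], values = values)
}

#' Fraction of a sample strictly above a threshold
#'
#' Used e.g. for the share of conformations whose R3m exceeds the
#' classification boundary.
#'
#' @param values numeric sample, n >= 1.
#' @param threshold the cut point (strict ">").
#' @return fraction in [0, 1].
#' @export
fractionAbove <- function(values, threshold) {
    values <- as.numeric(values)
    if (!length(values)) stop("empty sample")
    mean(values > threshold)
}

#' Compare two named descriptor value sets
#'
#' Matches the two sets by name and reports the mean absolute difference, the
#' per-name differences (b - a), the fraction of pairs with |difference| at or
#' below \code{deltaThreshold}, and an ordinary least-squares regression of b
#' on a (slope, intercept, R^2). This mirrors the standard check of one
#' coordinate source against another (e.g. generated conformations against
#' crystal structures).
#'
#' @param a,b named numeric vectors.
#' @param deltaThreshold cut for the "small difference" fraction
#'   (default 0.05).
#' @return list with \code{n}, \code{meanAbsDiff}, \code{differences} (named,
#'   b - a), \code{fractionWithin}, \code{deltaThreshold}, \code{slope},
#'   \code{intercept}, \code{r.squared}.
#' @export
compareValueSets <- function(a, b, deltaThreshold = 0.05) {
    common <- intersect(names(a), names(b))
    if (length(common) < 1L) stop("no matched names between the two sets")
    if (length(common) < 2L)
        stop("need at least 2 matched names for the regression")
    av <- as.numeric(a[common]); bv <- as.numeric(b[common])
    d <- bv - av
    names(d) <- common
    # identical sets are a legitimate input; silence the perfect-fit note
    fit <- suppressWarnings(stats::lm(bv ~ av))
    list(n = length(common),
         meanAbsDiff = mean(abs(d)),
         differences = d,
         fractionWithin = mean(abs(d) <= deltaThreshold + 1e-9),
         deltaThreshold = deltaThreshold,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r.squared = suppressWarnings(summary(fit)$r.squared))
}
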