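#' Amorphous density estimate from crystallographic density
#'
#' The rule of thumb that the amorphous form packs at 95\% of the
#' crystallographic density.
#'
#' @param crystalDensity crystallographic density in g/cm^3, > 0.
#' @return estimated amorphous density in g/cm^3 (unrounded; tables
#'   conventionally print 3 decimals).
#' @examples
#' round(amorphousDensityEstimate(1.252), 3)  # 1.189
#' @export
amorphousDensityEstimate <- function(crystalDensity) {
    if (any(!is.finite(crystalDensity) | crystalDensity <= 0))
        stop("crystallographic density must be positive")
    0.95 * crystalDensity
}

#' Signed percent error of a prediction
#'
#' 100 * (predicted - actual) / actual; positive for over-prediction.
#'
#' @param predicted,actual densities (or any positive quantities); actual
#'   must be nonzero.
#' @return signed percent error.
#' @examples
#' percentError(1.995, 1.9)  # +5
#' @export
percentError <- function(predicted, actual) {
    if (any(actual == 0)) stop("'actual' must be nonzero")
    100 * (predicted - actual) / actual
}

#' Density table in the style of a materials-properties summary
#'
#' Adds the 95\%-rule amorphous density estimate (rounded to 3 decimals for
#' presentation) and, where an experimental or simulated amorphous density is
#' present, the signed percent error of each against it.
#'
#' @param records data.frame with a \code{crystallographic_density} column
#'   and optionally \code{predicted_amorphous_density} and/or
#'   \code{experimental_amorphous_density} columns (g/cm^3; NA allowed).
#' @return the input data.frame with an \code{estimated_amorphous_density}
#'   column, plus percent-error columns where the inputs allow.
#' @export
densityTable <- function(records) {
    stopifnot(is.data.frame(records),
              "crystallographic_density" %in% names(records))
    cd <- records$crystallographic_density
    est <- rep(NA_real_, length(cd))
    ok <- !is.na(cd)
    est[ok] <- round(amorphousDensityEstimate(cd[ok]), 3)
    records$estimated_amorphous_density <- est
    if ("experimental_amorphous_density" %in% names(records)) {
        ea <- records$experimental_amorphous_density
        ok2 <- !is.na(ea) & ok
        pe <- rep(NA_real_, length(cd))
        pe[ok2] <- percentError(est[ok2], ea[ok2])
        records$estimate_percent_error <- pe
        if ("predicted_amorphous_density" %in% names(records)) {
            pa <- records$predicted_amorphous_density
            ok3 <- !is.na(pa) & !is.na(ea)
            pp <- rep(NA_real_, length(cd))
            pp[ok3] <- percentError(pa[ok3], ea[ok3])
            records$predicted_percent_error <- pp
        }
    }
    records
}
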