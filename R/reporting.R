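#' Default run configuration
#'
#' The defaults reproduce the reference workflow settings: lag k = 3, mass
#' weighting, the published 0.632 boundary, a 0.05 comparison threshold and
#' heavy-heteroatom selection N/O/S.
#'
#' @param k topological lag.
#' @param weights "mass" or "unit".
#' @param boundary decision boundary ("published" = model 50\% point, or a
#'   number such as 0.65 for the legacy midpoint model).
#' @param deltaThreshold comparison |difference| threshold.
#' @param selection element symbols for contribution percentages.
#' @param seed integer seed for any stochastic step.
#' @return named list, fully serialized into report headers.
#' @export
runConfig <- function(k = 3L, weights = "mass", boundary = "published",
                      deltaThreshold = 0.05, selection = c("N", "O", "S"),
                      seed = 1L) {
    list(k = as.integer(k), weights = weights, boundary = boundary,
         deltaThreshold = deltaThreshold, selection = selection,
         seed = as.integer(seed))
}

.configHeader <- function(config) {
    vals <- vapply(config, function(v) paste(format(v), collapse = ","),
                   character(1))
    c(sprintf("# RGetaway %s",
              as.character(utils::packageVersion("RGetaway"))),
      sprintf("# config %s=%s", names(config), vals))
}

#' Write a report data frame as CSV with a serialized config header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config a [runConfig()] list, embedded as '#'-prefixed header lines.
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(df, path, config = runConfig()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.configHeader(config), con)
    utils::write.csv(df, con, row.names = FALSE)
    invisible(path)
}

#' Per-molecule / per-conformer descriptor table
#'
#' One row per molecule or conformer frame: name, frame index, descriptor
#' value, the contribution percentage of the selected elements, and the
#' leverage trace (the rank of the centered coordinate matrix: 3 for generic
#' 3D geometries, 2 planar, 1 collinear).
#'
#' @param x a Molecule, ConformerEnsemble, list of either, or character
#'   vector of structure file paths.
#' @param config a [runConfig()] list.
#' @return data.frame with columns name, frame, value, selection_percent,
#'   leverage_trace.
#' @export
computeDescriptorTable <- function(x, config = runConfig()) {
    if (is.character(x)) {
        x <- lapply(x, readStructure)
    } else if (is(x, "Molecule") || is(x, "ConformerEnsemble")) {
        x <- list(x)
    }
    rows <- lapply(x, function(obj) {
        if (is(obj, "Molecule")) obj <- .molsToEnsemble(list(obj))
        do.call(rbind, lapply(seq_len(nFrames(obj)), function(f) {
            res <- rAutocorrelation(getFrame(obj, f), k = config$k,
                                    weights = config$weights)
            data.frame(name = molName(obj), frame = f,
                       value = descriptorValue(res),
                       selection_percent = atomContributions(
                           res, config$selection),
                       leverage_trace = sum(leverages(res)),
                       stringsAsFactors = FALSE)
        }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.resolveBoundary <- function(config, model) {
    if (identical(config$boundary, "published"))
        decisionBoundary(model)
    else as.numeric(config$boundary)
}

#' Dispersibility prediction report
#'
#' Per-value probability, class against the boundary (strict ">"), and a
#' probability band: "<1\%" for probabilities below 0.01, ">99\%" above 0.99,
#' "intermediate" otherwise. On the descriptor scale of the published model
#' the band cut points are R3m = 0.570 and 0.694 (the upper value recomputed
#' from the printed coefficients). When several values share a name they are
#' treated as a conformer distribution and a summary row block reports the
#' median-based class and the fraction of conformations above the boundary.
#'
#' @param values numeric R3m values.
#' @param names optional molecule names (recycled); values sharing a name
#'   form one distribution.
#' @param model a [LogisticModel-class].
#' @param config a [runConfig()] list.
#' @return list with \code{perValue} and \code{perMolecule} data.frames.
#' @export
predictDispersibility <- function(values, names = NULL,
                                  model = publishedModel(),
                                  config = runConfig()) {
    values <- as.numeric(values)
    if (!length(values)) stop("empty input: no descriptor values")
    if (is.null(names)) names <- sprintf("value_%d", seq_along(values))
    names <- rep_len(as.character(names), length(values))
    boundary <- .resolveBoundary(config, model)
    prob <- predictProbability(values, model)
    band <- ifelse(prob < 0.01, "<1%",
                   ifelse(prob > 0.99, ">99%", "intermediate"))
    perValue <- data.frame(name = names, r3m = values, probability = prob,
                           class = ifelse(values > boundary, "disperses",
                                          "fails"),
                           band = band, stringsAsFactors = FALSE)
    perMolecule <- do.call(rbind, lapply(split(values, names), function(v) {
        med <- stats::median(v)
        data.frame(n = length(v), median = med,
                   medianClass = ifelse(med > boundary, "disperses",
                                        "fails"),
                   fractionAboveBoundary = fractionAbove(v, boundary),
                   stringsAsFactors = FALSE)
    }))
    perMolecule <- cbind(name = rownames(perMolecule), perMolecule)
    rownames(perMolecule) <- NULL
    list(perValue = perValue, perMolecule = perMolecule,
         boundary = boundary)
}

#' Fit the dispersibility model from a labeled dataset and report
#'
#' Fits [fitLogistic()] on (r3m, label) data, reports the refit boundary to
#' 3 decimals and falls back to [midpointBoundary()] with a warning when the
#' data are completely separated.
#'
#' @param data data.frame with columns \code{r3m} and \code{label}, or a path
#'   to such a CSV.
#' @return list with \code{model}, \code{boundary} (numeric),
#'   \code{boundaryLabel} (3-decimal string), \code{separated}.
#' @export
fitDispersibilityModel <- function(data) {
    if (is.character(data)) data <- readLabeledData(data)
    if (!all(c("r3m", "label") %in% names(data)))
        stop("need columns 'r3m' and 'label'")
    model <- withCallingHandlers(
        fitLogistic(data$r3m, data$label),
        warning = function(w) invokeRestart("muffleWarning"))
    d <- fitDiagnostics(model)
    separated <- is(d, "FitDiagnostics") && d@separated
    boundary <- if (separated) midpointBoundary(data$r3m, data$label)
                else decisionBoundary(model)
    if (separated)
        warning("complete separation: reporting the midpoint boundary ",
                sprintf("%.3f", boundary),
                " instead of the diverging ML boundary")
    list(model = model, boundary = boundary,
         boundaryLabel = sprintf("%.3f", boundary), separated = separated)
}
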