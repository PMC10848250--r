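#' The published R3m dispersibility model for PVPVA
#'
#' Fixed-coefficient logistic model logit P(Y) = -46.79 + 74.01 * R3m for the
#' probability that a drug forms a persistent amorphous solid dispersion with
#' PVPVA by melt-quenching. Its 50\% boundary solves to R3m = 0.632; values
#' below 0.570 carry under 1\% probability and values above about 0.694 over
#' 99\%.
#'
#' @return a [LogisticModel-class] with \code{fitted = FALSE}.
#' @examples
#' predictProbability(0.654, publishedModel())
#' @export
publishedModel <- function() {
    LogisticModel(intercept = -46.79, slope = 74.01, fitted = FALSE)
}

#' @describeIn decisionBoundary \code{-intercept/slope} of the model.
#' @export
setMethod("decisionBoundary", "LogisticModel", function(model)
    -model@intercept / model@slope)

#' Dispersion probability at an R3m value
#'
#' Evaluates P = 1 / (1 + exp(-(intercept + slope * x))) with overflow-safe
#' arithmetic (\code{plogis}).
#'
#' @param x numeric R3m value(s), finite.
#' @param model a [LogisticModel-class]; default the published PVPVA model.
#' @return probabilities in (0, 1).
#' @export
predictProbability <- function(x, model = publishedModel()) {
    stopifnot(is(model, "LogisticModel"))
    if (!all(is.finite(x))) stop("descriptor values must be finite")
    stats::plogis(model@intercept + model@slope * x)
}

#' R3m value at a given dispersion probability
#'
#' Inverts the logistic model: x = (logit(p) - intercept) / slope. Exact
#' inverse of [predictProbability()].
#'
#' @param p probability strictly inside (0, 1).
#' @param model a [LogisticModel-class].
#' @return numeric R3m value(s).
#' @examples
#' r3mAtProbability(0.5)   # 0.632 to 3 decimals
#' r3mAtProbability(0.01)  # 0.570
#' @export
r3mAtProbability <- function(p, model = publishedModel()) {
    stopifnot(is(model, "LogisticModel"))
    if (any(p <= 0 | p >= 1))
        stop("probability must lie strictly inside (0, 1)")
    (stats::qlogis(p) - model@intercept) / model@slope
}

.isSeparated1D <- function(values, labels) {
    x0 <- values[labels == 0]; x1 <- values[labels == 1]
    max(x0) < min(x1) || max(x1) < min(x0)
}

#' Fit the logistic dispersibility model by maximum likelihood
#'
#' Binomial IRLS fit of labels on descriptor values (via \code{stats::glm},
#' log-likelihood convergence tolerance 1e-10, at most 100 iterations), with
#' likelihood-ratio diagnostics: McFadden pseudo-R^2 = 1 - LL/LL0, chi-square
#' = 2(LL - LL0) on 1 df and its upper-tail p-value. Complete separation
#' (a value threshold classifying the sample perfectly, or coefficients
#' diverging past 1e3 in norm) is flagged with a warning and
#' \code{separated = TRUE}; the coefficients of the last IRLS iteration are
#' returned, and [midpointBoundary()] is the appropriate boundary estimate in
#' that case.
#'
#' @param values numeric descriptor sample.
#' @param labels 0/1 dispersibility outcomes, both classes present.
#' @return a [LogisticModel-class] with [FitDiagnostics-class].
#' @examples
#' d <- simulateLabeledDataset(-46.79, 74.01, n = 500,
#'                             xRange = c(0.55, 0.72), seed = 1)
#' fitLogistic(d$values, d$labels)
#' @export
fitLogistic <- function(values, labels) {
    values <- as.numeric(values)
    labels <- as.integer(labels)
    if (length(values) != length(labels))
        stop("'values' and 'labels' must have equal length")
    if (length(values) < 2L) stop("need at least 2 observations")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
    if (length(unique(labels)) < 2L)
        stop("both outcome classes (0 and 1) must be present")
    sep <- .isSeparated1D(values, labels)
    fit <- suppressWarnings(
        stats::glm(labels ~ values, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)))
    co <- unname(stats::coef(fit))
    separated <- sep || max(abs(co)) > 1e3
    if (!fit$converged && !separated)
        stop("IRLS did not converge within 100 iterations")
    if (separated)
        warning("complete separation detected: maximum-likelihood ",
                "coefficients diverge; returning the last stable IRLS ",
                "iterate. Consider midpointBoundary().")
    ll <- as.numeric(stats::logLik(fit))
    p0 <- mean(labels)
    ll0 <- sum(stats::dbinom(labels, 1L, p0, log = TRUE))
    chi <- max(0, 2 * (ll - ll0))
    se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
    diag_ <- new("FitDiagnostics", logLik = ll, nullLogLik = ll0,
                 pseudoR2 = min(1, max(0, 1 - ll / ll0)), chiSquare = chi,
                 pValue = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 n = length(values), stdErrors = unname(se),
                 separated = separated)
    LogisticModel(co[1L], co[2L], fitted = TRUE, diagnostics = diag_)
}

#' Fit diagnostics of a fitted model
#' @param model a [LogisticModel-class].
#' @return the [FitDiagnostics-class], or NULL for fixed-coefficient models.
#' @export
fitDiagnostics <- function(model) {
    stopifnot(is(model, "LogisticModel"))
    model@diagnostics
}

#' Midpoint classification boundary for completely separated data
#'
#' When every failure value lies below every success value, logistic
#' maximum likelihood diverges; the phenomenological boundary is then the
#' midpoint between the largest failure value and the smallest success value.
#'
#' @param values numeric descriptor sample.
#' @param labels 0/1 outcomes; the classes must be completely separated with
#'   failures below successes.
#' @return the midpoint boundary value.
#' @examples
#' midpointBoundary(c(0.595, 0.687), c(0, 1))  # 0.641
#' @export
midpointBoundary <- function(values, labels) {
    values <- as.numeric(values)
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2L)
        stop("both outcome classes must be present")
    hiFail <- max(values[labels == 0])
    loPass <- min(values[labels == 1])
    if (hiFail >= loPass)
        stop("classes overlap (max failure ", format(hiFail),
             " >= min success ", format(loPass),
             "); use fitLogistic() instead")
    (hiFail + loPass) / 2
}

#' Classify R3m values against a dispersibility boundary
#'
#' A value is labeled "disperses" iff it lies strictly above the boundary
#' (ties classify as "fails"). The boundary defaults to the model's 50\%
#' point; pass \code{boundary = 0.65} for the legacy midpoint model.
#'
#' @param x numeric R3m value(s).
#' @param model optional [LogisticModel-class] used for the probability column
#'   and the default boundary.
#' @param boundary optional boundary override.
#' @return data.frame with columns \code{r3m}, \code{probability} (NA when no
#'   model is given), \code{class}.
#' @examples
#' classifyDispersibility(c(0.407, 0.687))
#' @export
classifyDispersibility <- function(x, model = publishedModel(),
                                   boundary = NULL) {
    if (is.null(boundary)) {
        if (is.null(model)) stop("need a model or an explicit boundary")
        boundary <- decisionBoundary(model)
    }
    prob <- if (is.null(model)) rep(NA_real_, length(x))
            else predictProbability(x, model)
    data.frame(r3m = as.numeric(x), probability = prob,
               class = ifelse(x > boundary, "disperses", "fails"),
               stringsAsFactors = FALSE)
}

#' Read a labeled descriptor dataset from delimited text
#'
#' Expects columns \code{name}, \code{r3m}, \code{label} (0/1); extra columns
#' are kept.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readLabeledData <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("r3m", "label")
    if (!all(need %in% names(df)))
        stop("labeled data must have columns 'r3m' and 'label'; found: ",
             paste(names(df), collapse = ", "))
    if (!is.numeric(df$r3m))
        stop("parse error: column 'r3m' is not numeric")
    if (anyNA(df$label) || !all(df$label %in% c(0, 1)))
        stop("parse error: column 'label' must contain only 0/1")
    df
}

#' Write / read a logistic model as JSON
#'
#' @param model a [LogisticModel-class].
#' @param path JSON file path.
#' @return \code{writeModel} returns \code{path} invisibly; \code{readModel}
#'   returns a [LogisticModel-class].
#' @export
writeModel <- function(model, path) {
    stopifnot(is(model, "LogisticModel"))
    d <- model@diagnostics
    obj <- list(intercept = model@intercept, slope = model@slope,
                fitted = model@fitted,
                boundary = decisionBoundary(model))
    if (is(d, "FitDiagnostics"))
        obj$diagnostics <- list(logLik = d@logLik, nullLogLik = d@nullLogLik,
                                pseudoR2 = d@pseudoR2,
                                chiSquare = d@chiSquare, pValue = d@pValue,
                                n = d@n, stdErrors = d@stdErrors,
                                separated = d@separated)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    d <- NULL
    if (!is.null(obj$diagnostics))
        d <- new("FitDiagnostics",
                 logLik = obj$diagnostics$logLik,
                 nullLogLik = obj$diagnostics$nullLogLik,
                 pseudoR2 = obj$diagnostics$pseudoR2,
                 chiSquare = obj$diagnostics$chiSquare,
                 pValue = obj$diagnostics$pValue,
                 n = as.integer(obj$diagnostics$n),
                 stdErrors = obj$diagnostics$stdErrors,
                 separated = obj$diagnostics$separated)
    LogisticModel(obj$intercept, obj$slope, fitted = isTRUE(obj$fitted),
                  diagnostics = d)
}
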