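test_that("the published model reproduces its printed probability anchors", {
    pm <- publishedModel()
    expect_equal(predictProbability(decisionBoundary(pm), pm), 0.5,
                 tolerance = 1e-12)
    expect_equal(round(decisionBoundary(pm), 3), 0.632)
    expect_lt(predictProbability(0.570, pm), 0.01)
    expect_equal(predictProbability(0.570, pm), 0.0099, tolerance = 1e-2)
    expect_gt(predictProbability(0.654, pm), 0.80)
    expect_equal(predictProbability(0.654, pm), 0.834, tolerance = 1e-3)
    expect_error(predictProbability(NaN, pm), "finite")
})

test_that("probability prediction is strictly increasing and exactly
           inverted by r3mAtProbability", {
    pm <- publishedModel()
    x <- seq(0.55, 0.72, by = 0.005)  # logits representable in double
    expect_true(all(diff(predictProbability(x, pm)) > 0))
    p <- c(1e-6, 0.01, 0.5, 0.99, 1 - 1e-6)
    expect_equal(predictProbability(r3mAtProbability(p, pm), pm), p,
                 tolerance = 1e-12)
    expect_equal(round(r3mAtProbability(0.5, pm), 3), 0.632)
    expect_equal(round(r3mAtProbability(0.01, pm), 3), 0.570)
    # the >99% cut recomputed from the printed coefficients
    expect_equal(round(r3mAtProbability(0.99, pm), 3), 0.694)
    expect_error(r3mAtProbability(0, pm), "strictly inside")
    expect_error(r3mAtProbability(1, pm), "strictly inside")
})

test_that("overflow-safe evaluation holds far outside the data range", {
    pm <- publishedModel()
    expect_equal(predictProbability(-100, pm), 0)
    expect_equal(predictProbability(100, pm), 1)
})

test_that("maximum-likelihood refit recovers known coefficients", {
    d <- simulateLabeledDataset(-46.79, 74.01, n = 5000,
                                xRange = c(0.55, 0.72), seed = 20)
    fit <- fitLogistic(d$values, d$labels)
    dg <- fitDiagnostics(fit)
    expect_false(dg@separated)
    expect_lt(abs(fit@intercept - (-46.79)), 3 * dg@stdErrors[1])
    expect_lt(abs(fit@slope - 74.01), 3 * dg@stdErrors[2])
    expect_equal(decisionBoundary(fit), 0.632, tolerance = 0.01)
    expect_lt(dg@pValue, 1e-10)
})

test_that("labels independent of the descriptor give a null fit", {
    set.seed(33)
    x <- runif(400, 0.5, 0.8)
    y <- rep_len(c(0L, 1L), 400)[order(order(x))]  # interleaved along x
    fit <- fitLogistic(x, y)
    dg <- fitDiagnostics(fit)
    expect_lt(dg@pseudoR2, 0.02)
    expect_gt(dg@pValue, 0.05)
})

test_that("IRLS matches a direct optimizer of the Bernoulli likelihood on
           small samples", {
    negll <- function(b, x, y)
        -sum(y * (b[1] + b[2] * x) - log1p(exp(b[1] + b[2] * x)))
    set.seed(44)
    for (rep in 1:5) {
        x <- runif(50, 0, 1)
        y <- rbinom(50, 1, plogis(-2 + 4 * x))
        if (length(unique(y)) < 2) next
        fit <- fitLogistic(x, y)
        if (fitDiagnostics(fit)@separated) next
        opt <- optim(c(0, 0), negll, x = x, y = y, method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 1000))
        expect_equal(unname(c(fit@intercept, fit@slope)), opt$par,
                     tolerance = 1e-5)
        expect_equal(fitDiagnostics(fit)@logLik, -opt$value,
                     tolerance = 1e-8)
    }
})

test_that("diagnostics respect the likelihood-ratio identity", {
    d <- simulateLabeledDataset(-10, 18, n = 600, xRange = c(0.3, 0.9),
                                seed = 5)
    dg <- fitDiagnostics(fitLogistic(d$values, d$labels))
    expect_equal(dg@chiSquare, 2 * (dg@logLik - dg@nullLogLik),
                 tolerance = 1e-10)
    expect_equal(dg@pseudoR2, 1 - dg@logLik / dg@nullLogLik,
                 tolerance = 1e-10)
    expect_gte(dg@pseudoR2, 0); expect_lte(dg@pseudoR2, 1)
})

test_that("complete separation is detected and reported, not hidden", {
    expect_warning(fit <- fitLogistic(c(0.5, 0.6, 0.7, 0.8), c(0, 0, 1, 1)),
                   "separation")
    expect_true(fitDiagnostics(fit)@separated)
    expect_error(fitLogistic(c(0.5, 0.6), c(1, 1)), "both outcome classes")
})

test_that("midpoint boundary is the center of the class gap", {
    expect_equal(midpointBoundary(c(0, 1), c(0, 1)), 0.5)
    expect_equal(midpointBoundary(c(0.595, 0.687), c(0, 1)), 0.641)
    expect_error(midpointBoundary(c(0.6, 0.58), c(0, 1)), "overlap")
})

test_that("classification uses a strict boundary with optional override", {
    cl <- classifyDispersibility(c(0.407, 0.687, 0.632))
    expect_equal(cl$class, c("fails", "disperses", "fails"))
    expect_lt(cl$probability[1], 1e-6)  # melatonin-like value
    legacy <- classifyDispersibility(0.64, boundary = 0.65)
    expect_equal(legacy$class, "fails")
    expect_equal(classifyDispersibility(0.64)$class, "disperses")
})

test_that("models round-trip through JSON with diagnostics", {
    d <- simulateLabeledDataset(-8, 14, n = 300, xRange = c(0.2, 1), seed = 3)
    fit <- fitLogistic(d$values, d$labels)
    tf <- withr::local_tempfile(fileext = ".json")
    writeModel(fit, tf)
    back <- readModel(tf)
    expect_equal(back@intercept, fit@intercept)
    expect_equal(back@slope, fit@slope)
    expect_equal(fitDiagnostics(back)@logLik, fitDiagnostics(fit)@logLik)
    expect_equal(fitDiagnostics(back)@stdErrors,
                 fitDiagnostics(fit)@stdErrors)
})

test_that("labeled-data ingestion validates the label column", {
    tf <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("name,r3m,label", "a,0.5,0", "b,0.7,2"), tf)
    expect_error(readLabeledData(tf), "0/1")
    writeLines(c("name,value", "a,1"), tf)
    expect_error(readLabeledData(tf), "r3m")
})
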