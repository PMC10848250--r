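test_that("frame selection spaces times inclusively across the window", {
    expect_equal(selectFrames(200, 500, 7), seq(200, 500, by = 50))
    expect_equal(selectFrames(0, 10, 2), c(0, 10))
    expect_equal(selectFrames(0, 10, 1), 10)
    expect_error(selectFrames(10, 10, 3), "positive extent")
})

test_that("ensemble descriptors match per-frame Molecule values, in order", {
    m <- makeChainMolecule(6, 1.5, geometry = "zigzag")
    ens <- perturbTorsions(m, 5, 45, seed = 9)
    v <- ensembleDescriptor(ens)
    expect_length(v, 5L)
    for (i in 1:5)
        expect_identical(v[i], descriptorValue(r3m(getFrame(ens, i))))
    # identical frames give identical values; a single frame matches the
    # Molecule-level value
    same <- ConformerEnsemble(atomElements(m), molBonds(m),
                              rep(list(atomCoordinates(m)), 3))
    expect_equal(ensembleDescriptor(same), rep(descriptorValue(r3m(m)), 3))
    one <- ConformerEnsemble(atomElements(m), molBonds(m),
                             list(atomCoordinates(m)))
    expect_equal(ensembleDescriptor(one), descriptorValue(r3m(m)))
})

test_that("descriptor errors propagate with the frame index attached", {
    bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 0, 0))
    good <- cbind(0:3, 0, 0)
    ens <- ConformerEnsemble(rep("C", 4), cbind(1:3, 2:4),
                             list(good, bad))
    expect_error(ensembleDescriptor(ens), "frame 2")
})

test_that("ensemble concatenation concatenates descriptor values", {
    m <- makeChainMolecule(5, 1.5, geometry = "zigzag")
    e1 <- perturbTorsions(m, 4, 30, seed = 1)
    e2 <- perturbTorsions(m, 3, 30, seed = 2)
    cat12 <- ConformerEnsemble(atomElements(m), molBonds(m),
                               c(e1@frames, e2@frames))
    expect_equal(ensembleDescriptor(cat12),
                 c(ensembleDescriptor(e1), ensembleDescriptor(e2)))
})

test_that("extractMolecules splits a packed frame into conformers", {
    m <- makeChainMolecule(4)
    packed <- rbind(atomCoordinates(m), atomCoordinates(m) + 5,
                    atomCoordinates(m) %*% randomRotation())
    ens <- extractMolecules(atomElements(m), molBonds(m), packed, 3)
    expect_equal(nFrames(ens), 3L)
    expect_equal(ensembleDescriptor(ens),
                 rep(descriptorValue(r3m(m)), 3), tolerance = 1e-10)
    expect_error(extractMolecules(atomElements(m), molBonds(m), packed, 4),
                 "expected")
})

test_that("box-plot summaries use type-7 quartiles and 1.5 IQR whiskers", {
    s <- summarizeDistribution(1:5)
    expect_equal(s@median, 3); expect_equal(s@q1, 2); expect_equal(s@q3, 4)
    expect_length(s@outliers, 0L)
    expect_equal(s@whiskerLow, 1); expect_equal(s@whiskerHigh, 5)

    const <- summarizeDistribution(rep(2.5, 8))
    expect_equal(const@median, 2.5)
    expect_equal(const@mean, 2.5)
    expect_equal(const@q3 - const@q1, 0)

    out <- summarizeDistribution(c(1, 1, 1, 1, 100))
    expect_equal(out@outliers, 100)
    expect_equal(out@whiskerHigh, 1)
    expect_error(summarizeDistribution(numeric(0)), "empty")
})

test_that("distribution summaries are permutation-invariant", {
    set.seed(17)
    x <- rnorm(101)
    a <- summarizeDistribution(x)
    b <- summarizeDistribution(sample(x))
    for (sl in c("median", "mean", "q1", "q3", "whiskerLow", "whiskerHigh"))
        expect_identical(slot(a, sl), slot(b, sl))
    expect_identical(sort(a@outliers), sort(b@outliers))
})

test_that("fractionAbove counts strict exceedances and is monotone in the
           threshold", {
    expect_equal(fractionAbove(c(0.6, 0.7), 0.65), 0.5)
    expect_equal(fractionAbove(c(0.6, 0.7), 0.7), 0)  # strict ">"
    expect_equal(fractionAbove(c(0.1, 0.2), 0.5), 0)
    set.seed(23)
    x <- runif(200)
    th <- sort(runif(20))
    fr <- vapply(th, function(t) fractionAbove(x, t), numeric(1))
    expect_true(all(diff(fr) <= 0))
    # binomial check against the normal tail probability
    set.seed(840)
    sample840 <- rnorm(840, 0.65, 0.02)
    expected <- 1 - pnorm((0.632 - 0.65) / 0.02)
    se <- sqrt(expected * (1 - expected) / 840)
    expect_lt(abs(fractionAbove(sample840, 0.632) - expected), 3 * se)
})

test_that("value-set comparison reports differences and the b-on-a
           regression", {
    a <- c(m1 = 0.4, m2 = 0.6, m3 = 0.9, m4 = 1.1)
    cmpSame <- compareValueSets(a, a)
    expect_equal(cmpSame$meanAbsDiff, 0)
    expect_equal(cmpSame$slope, 1)
    expect_equal(cmpSame$r.squared, 1)
    cmpShift <- compareValueSets(a, a + 0.05)
    expect_equal(cmpShift$meanAbsDiff, 0.05)
    expect_equal(cmpShift$slope, 1)
    expect_equal(cmpShift$fractionWithin, 1)
    expect_equal(compareValueSets(a, a + 0.06)$fractionWithin, 0)
    expect_error(compareValueSets(c(x = 1), c(y = 2)), "no matched names")
})

test_that("comparison regression recovers a known slope from noisy pairs", {
    set.seed(130)
    a <- runif(130, 0.3, 1.2)
    b <- 0.91 * a + rnorm(130, sd = 0.03)
    names(a) <- names(b) <- sprintf("api%03d", seq_along(a))
    cmp <- compareValueSets(a, b)
    fit <- lm(b ~ a)
    se <- summary(fit)$coefficients["a", "Std. Error"]
    expect_lt(abs(cmp$slope - 0.91), 3 * se)
    expect_gt(cmp$r.squared, 0.9)
})
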