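test_that("leverages of a collinear chain follow x^2 / sum(x^2)", {
    xyz <- centerCoordinates(cbind(0:3, 0, 0))
    res <- influenceMatrix(xyz)
    expect_equal(leverages(res), c(0.45, 0.05, 0.05, 0.45),
                 tolerance = 1e-10)
    expect_equal(sum(leverages(res)), 1, tolerance = 1e-8)  # rank 1
    H <- res@H
    expect_lt(max(abs(H %*% H - H)), 1e-8)
    expect_lt(max(abs(H - t(H))), 1e-10)
})

test_that("influence matrix has trace 3 for generic geometries and is
           rotation-invariant", {
    set.seed(101)
    xyz <- centerCoordinates(matrix(rnorm(36), ncol = 3))
    res <- influenceMatrix(xyz)
    expect_equal(sum(leverages(res)), 3, tolerance = 1e-8)
    for (rep in 1:100) {
        rot <- centerCoordinates(xyz %*% randomRotation())
        expect_equal(leverages(influenceMatrix(rot)), leverages(res),
                     tolerance = 1e-10)
    }
    expect_error(influenceMatrix(matrix(5, 4, 3)), "not centered")
})

test_that("topological distances are BFS path lengths", {
    chain <- cbind(1:3, 2:4)
    D <- topologicalDistances(chain, 4)
    expect_equal(D[1, 4], 3)
    ring <- cbind(1:6, c(2:6, 1))
    Dr <- topologicalDistances(ring, 6)
    for (i in 1:6) expect_equal(Dr[i, (i + 2) %% 6 + 1], 3)
    # disconnected fragments stay infinite
    Dd <- topologicalDistances(rbind(c(1, 2)), 4)
    expect_true(is.infinite(Dd[1, 3]))
    # independent all-pairs oracle on random trees
    set.seed(55)
    for (rep in 1:50) {
        m <- randomTreeMolecule(sample(4:20, 1))
        expect_identical(topologicalDistances(molBonds(m), nAtoms(m)),
                         floydWarshall(molBonds(m), nAtoms(m)))
    }
})

test_that("R_k.w matches hand computations on analytic chains", {
    expect_equal(descriptorValue(r3m(methaneMolecule())), 0)
    expect_equal(descriptorValue(r3m(makeChainMolecule(4))), 0.15,
                 tolerance = 1e-12)
    expect_equal(descriptorValue(r3m(makeChainMolecule(5))), 2 / 15,
                 tolerance = 1e-12)
    # unit weights on a heteroatom chain ignore the masses
    s <- makeChainMolecule(4, elements = c("C", "C", "C", "S"))
    expect_equal(descriptorValue(rAutocorrelation(s, 3, "unit")), 0.15,
                 tolerance = 1e-12)
    expect_equal(descriptorValue(r3m(s)), 0.15 * normalizedMasses("S"),
                 tolerance = 1e-12)
})

test_that("coincident atoms on a contributing pair are an error, not a skip", {
    xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 0, 0))
    m <- Molecule(rep("C", 4), xyz, cbind(1:3, 2:4))
    expect_error(r3m(m), "degenerate geometry")
    # the same coincidence off every contributing lag is harmless
    expect_silent(rAutocorrelation(m, k = 2, weights = "mass"))
})

test_that("R_k.w is invariant under rigid motion and atom relabeling,
           and scales as 1/s", {
    set.seed(202)
    for (rep in 1:25) {
        m <- randomTreeMolecule(sample(5:12, 1))
        ref <- descriptorValue(r3m(m))
        # rotation + translation
        moved <- sweep(atomCoordinates(m) %*% randomRotation(), 2,
                       rnorm(3, sd = 4), "+")
        expect_equal(descriptorValue(r3m(Molecule(atomElements(m), moved,
                                                  molBonds(m)))),
                     ref, tolerance = 1e-10)
        # permutation with remapped bonds
        perm <- sample(nAtoms(m))
        inv <- order(perm)
        pm <- Molecule(atomElements(m)[perm],
                       atomCoordinates(m)[perm, , drop = FALSE],
                       matrix(inv[molBonds(m)], ncol = 2))
        expect_equal(descriptorValue(r3m(pm)), ref, tolerance = 1e-10)
        # uniform scaling: leverages invariant, r_ij scales by s
        s <- runif(1, 0.5, 3)
        sm <- Molecule(atomElements(m), atomCoordinates(m) * s, molBonds(m))
        expect_equal(descriptorValue(r3m(sm)), ref / s, tolerance = 1e-10)
    }
})

test_that("production descriptor agrees with the naive pairwise oracle", {
    set.seed(303)
    for (rep in 1:40) {
        m <- randomTreeMolecule(sample(4:15, 1))
        k <- sample(1:4, 1)
        expect_equal(descriptorValue(rAutocorrelation(m, k, "mass")),
                     naiveRkw(m, k, "mass"), tolerance = 1e-12)
    }
})

test_that("per-atom contributions conserve the descriptor value", {
    set.seed(404)
    for (rep in 1:20) {
        m <- randomTreeMolecule(sample(5:15, 1))
        res <- r3m(m)
        expect_equal(sum(perAtomContributions(res)), descriptorValue(res),
                     tolerance = 1e-10)
        expect_equal(atomContributions(res, unique(atomElements(m))), 100)
    }
})

test_that("element-selection contributions split pair terms equally", {
    allc <- r3m(makeChainMolecule(6))
    expect_equal(atomContributions(allc, c("N", "O", "S")), 0)
    ccc_s <- r3m(makeChainMolecule(4, elements = c("C", "C", "C", "S")))
    expect_equal(atomContributions(ccc_s, "S"), 50, tolerance = 1e-10)
    expect_equal(atomContributions(r3m(methaneMolecule()), "C"), 0)  # value 0
})

test_that("a heavy atom at a peripheral (high-leverage) site does not lower
           R3m relative to a central site", {
    for (geom in c("linear", "zigzag")) {
        base <- makeChainMolecule(6, 1.5, geometry = geom)
        h <- leverages(r3m(base))
        hiSite <- which.max(h)
        loSite <- which.min(h)
        elHi <- replace(rep("C", 6), hiSite, "S")
        elLo <- replace(rep("C", 6), loSite, "S")
        vHi <- descriptorValue(r3m(Molecule(elHi, atomCoordinates(base),
                                            molBonds(base))))
        vLo <- descriptorValue(r3m(Molecule(elLo, atomCoordinates(base),
                                            molBonds(base))))
        expect_gte(vHi, vLo)
    }
})

test_that("dihedral angles follow the signed atan2 convention in
           (-180, 180]", {
    trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
    expect_equal(dihedralAngle(trans), 180)
    cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
    expect_equal(dihedralAngle(cis), 0)
    perp <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
    expect_equal(abs(dihedralAngle(perp)), 90)
    coll <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
    expect_error(dihedralAngle(coll), "collinear")
})

test_that("contribution tables expose atom, element, leverage and percent", {
    tab <- contributionTable(r3m(makeChainMolecule(5)))
    expect_named(tab, c("atom", "element", "leverage", "contribution",
                        "percent"))
    expect_equal(sum(tab$percent), 100, tolerance = 1e-8)
})
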