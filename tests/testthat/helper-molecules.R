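# Fixture builders and independent oracles, all generated in code.

methaneMolecule <- function() {
    xyz <- rbind(c(0, 0, 0), c(0.63, 0.63, 0.63), c(-0.63, -0.63, 0.63),
                 c(-0.63, 0.63, -0.63), c(0.63, -0.63, -0.63))
    Molecule(c("C", "H", "H", "H", "H"), xyz,
             rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)), name = "methane")
}

# random labelled tree over n atoms: node i > 1 attaches to a random earlier
# node; coordinates i.i.d. normal so geometries are generic (full rank)
randomTreeMolecule <- function(nAtoms, elements = NULL) {
    parents <- vapply(2:nAtoms, function(i) sample.int(i - 1L, 1L),
                      integer(1))
    bonds <- cbind(parents, 2:nAtoms)
    if (is.null(elements))
        elements <- sample(c("C", "N", "O", "S", "H"), nAtoms,
                           replace = TRUE)
    Molecule(elements, matrix(rnorm(nAtoms * 3, sd = 2), ncol = 3), bonds,
             name = sprintf("tree_%d", nAtoms))
}

randomRotation <- function() {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
}

# independent all-pairs shortest-path oracle (Floyd-Warshall triple loop)
floydWarshall <- function(bonds, nAtoms) {
    D <- matrix(Inf, nAtoms, nAtoms)
    diag(D) <- 0
    for (e in seq_len(nrow(bonds))) {
        D[bonds[e, 1], bonds[e, 2]] <- 1
        D[bonds[e, 2], bonds[e, 1]] <- 1
    }
    for (m in seq_len(nAtoms))
        for (i in seq_len(nAtoms))
            for (j in seq_len(nAtoms))
                if (D[i, m] + D[m, j] < D[i, j])
                    D[i, j] <- D[i, m] + D[m, j]
    D
}

# naive R_k.w oracle: explicit hat-matrix leverages (base solve, full-rank
# geometries only), Floyd-Warshall distances, triple loop over pairs
naiveRkw <- function(mol, k, weights = "mass") {
    M <- atomCoordinates(mol)
    M <- sweep(M, 2, colMeans(M), "-")
    H <- M %*% solve(t(M) %*% M) %*% t(M)
    h <- diag(H)
    A <- nAtoms(mol)
    w <- if (weights == "mass") normalizedMasses(atomElements(mol))
         else rep(1, A)
    D <- floydWarshall(molBonds(mol), A)
    val <- 0
    for (i in seq_len(A - 1))
        for (j in (i + 1):A)
            if (is.finite(D[i, j]) && D[i, j] == k) {
                rij <- sqrt(sum((M[i, ] - M[j, ])^2))
                val <- val + sqrt(h[i] * h[j]) / rij * w[i] * w[j]
            }
    val
}
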