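test_that("sliding-window profile covers steps 3..N-3 and pairs 4..N-3", {
    ps <- syntheticParams("DNA")
    sq <- "GCGCATTTACGGATCCAGTACGCAT"   # 25 bp
    prof <- predictProfile(sq, ps)
    expect_equal(length(prof@coveredSteps), 20L)
    expect_equal(length(prof@coveredPairs), 19L)
    expect_equal(range(prof@coveredSteps), c(3L, 22L))
    expect_equal(range(prof@coveredPairs), c(4L, 22L))
    ## uncovered entries are NA, never silently filled
    expect_true(all(is.na(prof@stepCoords[c(1, 2, 23, 24), ])))
    expect_true(all(is.na(prof@pairCoords[c(1:3, 23:25), ])))
    expect_true(all(is.na(prof@minorGroove[1:3])))
    ## fillEnds substitutes the sequence-averaged values
    filled <- predictProfile(sq, ps, fillEnds = TRUE)
    sa <- sequenceAveragedParameters(ps)
    expect_equal(unname(filled@stepCoords[1, ]), unname(sa$step))
    expect_equal(filled@minorGroove[1], sa$minorGroove)
    expect_error(predictProfile("ACGTA", ps), "shorter than 6")
    expect_warning(predictProfile("ACGTAC", ps), "no pair-level")
})

test_that("constant-context sequences give constant profiles", {
    ps <- syntheticParams("DNA")
    prof <- predictProfile(strrep("G", 12), ps)
    rec <- getHexamerRecord(ps, "GGGGGG")
    for (j in prof@coveredSteps) {
        expect_equal(unname(prof@stepCoords[j, ]), unname(rec@stepCoords[3, ]))
        expect_equal(prof@majorGroove[j], rec@majorGroove)
    }
})

test_that("profiles obey complement symmetry", {
    ps <- syntheticParams("DNA")
    sq <- "ATCGGACTATGCCAGTAAGC"
    n <- nchar(sq)
    a <- predictProfile(sq, ps)
    b <- predictProfile(reverseComplement(sq), ps)
    for (j in b@coveredSteps) {
        want <- a@stepCoords[n - j, ]
        want[c(1, 4)] <- -want[c(1, 4)]
        expect_equal(unname(b@stepCoords[j, ]), unname(want))
        expect_equal(b@majorGroove[j], a@majorGroove[n - j])
    }
    for (j in b@coveredPairs) {
        want <- a@pairCoords[n + 1 - j, ]
        want[c(1, 4)] <- -want[c(1, 4)]
        expect_equal(unname(b@pairCoords[j, ]), unname(want))
        expect_equal(b@minorGroove[j], a@minorGroove[n + 1 - j])
    }
})

test_that("stiffness assembly averages overlaps and stays banded", {
    ps <- syntheticParams("DNA")
    ## a single hexamer: the matrix is that hexamer's block
    K6 <- assembleStiffnessMatrix("CATGAC", ps)
    expect_equal(stiffnessMatrix(K6), getStiffnessBlock(ps, "CATGAC"))
    ## 7 bp: the 54x54 overlap is the entrywise mean of the two blocks
    K7 <- assembleStiffnessMatrix("CATGACT", ps)
    B1 <- getStiffnessBlock(ps, "CATGAC")
    B2 <- getStiffnessBlock(ps, "ATGACT")
    ov <- intersect(blockSlice(1), blockSlice(2))
    expect_equal(stiffnessMatrix(K7)[ov, ov],
                 (B1[13:66, 13:66] + B2[1:54, 1:54]) / 2)
    ## non-overlap corners come from single blocks
    expect_equal(stiffnessMatrix(K7)[1:12, 1:12], B1[1:12, 1:12])
    ## symmetric, banded, zero outside
    sq <- "ATCGGACTATGCCAGT"
    K <- assembleStiffnessMatrix(sq, ps)
    m <- stiffnessMatrix(K)
    expect_equal(m, t(m))
    expect_true(all(m[!bandPattern(nchar(sq))] == 0))
})

test_that("assembled matrices transform covariantly under complementation", {
    ps <- syntheticParams("DNA")
    sq <- "ATCGGACTATGCC"
    n <- nchar(sq)
    Ka <- stiffnessMatrix(assembleStiffnessMatrix(sq, ps))
    Kb <- stiffnessMatrix(assembleStiffnessMatrix(reverseComplement(sq), ps))
    ## signed permutation: group g -> 2n-g, odd offsets 1 and 4 flip sign
    g <- rep(seq_len(2 * n - 1), each = 6)
    off <- rep(1:6, 2 * n - 1)
    perm <- (2 * n - g - 1) * 6 + off
    sgn <- ifelse(off %in% c(1, 4), -1, 1)
    expect_equal(Kb, Ka[perm, perm] * tcrossprod(sgn), tolerance = 1e-12)
})

test_that("nondimensionalization scales entries by 1 A / 11 deg and inverts exactly", {
    ps <- syntheticParams("DNA")
    K <- assembleStiffnessMatrix("CATGAC", ps)
    Knd <- nondimensionalize(K)
    m <- stiffnessMatrix(K); mnd <- stiffnessMatrix(Knd)
    ## translation-translation entries unchanged (scale 1)
    expect_equal(mnd[1, 2], m[1, 2])
    ## rotation-rotation entries scale by 11^2 (e.g. 0.05 -> 6.05)
    expect_equal(mnd[6, 6], m[6, 6] * 121)
    ## translation-rotation cross terms scale by 11
    expect_equal(mnd[1, 6], m[1, 6] * 11)
    expect_true(Knd@dimensionless)
    back <- redimensionalize(Knd)
    expect_equal(stiffnessMatrix(back), m)
    expect_error(nondimensionalize(Knd), "already dimensionless")
    expect_error(redimensionalize(K), "not dimensionless")
})

test_that("eigenvalue cutoff clamps the spectrum and keeps eigenvectors", {
    ## construct a symmetric matrix with eigenvalues {-0.1, 0.2, 5.0}
    set.seed(8)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    M <- Q %*% diag(c(-0.1, 0.2, 5.0)) %*% t(Q)
    M <- (M + t(M)) / 2
    out <- applyEigenvalueCutoff(M, lambdaC = 0.48)
    ev <- eigen(out, symmetric = TRUE)
    expect_equal(sort(ev$values), c(0.48, 0.48, 5.0), tolerance = 1e-10)
    ## the unmodified mode keeps its eigenvector (up to sign)
    top <- eigen(M, symmetric = TRUE)$vectors[, 1]
    topOut <- ev$vectors[, which.max(ev$values)]
    expect_equal(abs(sum(top * topOut)), 1, tolerance = 1e-10)
    ## matrices already above the cutoff are unchanged
    P <- Q %*% diag(c(0.5, 1, 2)) %*% t(Q)
    expect_equal(applyEigenvalueCutoff((P + t(P)) / 2, lambdaC = 0.48),
                 (P + t(P)) / 2, tolerance = 1e-12)
    ## na-type defaults
    pc <- physicalConstants()
    expect_equal(unname(pc$lambdaC["DNA"]), 0.48)
    expect_equal(unname(pc$lambdaC["RNA"]), 0.44)
})

test_that("band trimming zeroes exactly the out-of-band entries", {
    ps <- syntheticParams("DNA")
    n <- 9
    sq <- "ACGGTCAAG"
    ## independent oracle for the band pattern: (i, j) is in-band iff some
    ## hexamer window contains both coordinate positions
    d <- coordinateVectorLength(n)
    oracle <- matrix(FALSE, d, d)
    for (h in 1:(n - 5)) {
        sl <- (12 * (h - 1) + 1):(12 * (h - 1) + 66)
        oracle[sl, sl] <- TRUE
    }
    expect_identical(bandPattern(n), oracle)
    dense <- .asDense <- randomSPD(d, seed = 13)
    Kd <- duplexmech:::.asStiffness(dense, n, "DNA", FALSE, FALSE)
    Kt <- trimToBand(Kd)
    mt <- stiffnessMatrix(Kt)
    expect_true(all(mt[!oracle] == 0))
    expect_equal(mt[oracle], dense[oracle])
    ## Frobenius difference equals the off-band norm
    expect_equal(norm(dense - mt, "F"), sqrt(sum(dense[!oracle]^2)))
    ## already-banded matrices are unchanged
    Kb <- assembleStiffnessMatrix(sq, ps)
    expect_equal(stiffnessMatrix(trimToBand(Kb)), stiffnessMatrix(Kb))
    expect_true(is.finite(attr(Kt, "minEigenvalue")))
})

test_that("truncating to a narrower band can break positive definiteness", {
    ## qualitative behaviour: restricting couplings to too short a range can
    ## destroy definiteness even though the full matrix is SPD; a strongly
    ## equicorrelated matrix truncated to two off-diagonals is indefinite
    d <- 30
    S <- matrix(0.9, d, d); diag(S) <- 1
    expect_gt(min(eigen(S, only.values = TRUE)$values), 0)
    narrow <- S
    narrow[abs(row(S) - col(S)) > 2] <- 0
    expect_lt(min(eigen(narrow, only.values = TRUE)$values), 0)
})

test_that("deformation energy is the quadratic form with SPD positivity", {
    expect_equal(deformationEnergy(1:5, 1:5, diag(5)), 0)
    expect_equal(deformationEnergy(5, 0, matrix(0.05)), 0.625)
    ## doubling the deviation quadruples the energy
    K <- randomSPD(8, seed = 14)
    w0 <- rnorm(8)
    dw <- rnorm(8)
    expect_equal(deformationEnergy(w0 + 2 * dw, w0, K),
                 4 * deformationEnergy(w0 + dw, w0, K))
    expect_gt(deformationEnergy(w0 + dw, w0, K), 0)
    expect_error(deformationEnergy(1:3, 1:3, diag(5)), "dimension mismatch")
})

test_that("Schur complement equals brute-force relaxation of free coordinates", {
    expect_equal(effectiveStiffnessForSubset(matrix(c(3, 1, 1, 2), 2), 1),
                 matrix(2.5))
    ## block-diagonal: the reduced matrix is just K_cc
    Kb <- matrix(0, 5, 5)
    Kb[1:3, 1:3] <- randomSPD(3, 15)
    Kb[4:5, 4:5] <- randomSPD(2, 16)
    expect_equal(effectiveStiffnessForSubset(Kb, 1:3),
                 Kb[1:3, 1:3], tolerance = 1e-12)
    ## full subset: K itself
    K <- randomSPD(5, seed = 17)
    expect_equal(effectiveStiffnessForSubset(K, 1:5), K)
    ## numeric minimization oracle: E(xc) = min over xf of the full quadratic
    constrained <- c(1, 3)
    Keff <- effectiveStiffnessForSubset(K, constrained)
    xc <- c(0.7, -0.4)
    oracle <- optim(c(0, 0, 0), function(xf) {
        w <- numeric(5); w[constrained] <- xc; w[-constrained] <- xf
        0.5 * crossprod(w, K %*% w)
    }, method = "BFGS")$value
    expect_equal(as.numeric(0.5 * crossprod(xc, Keff %*% xc)), oracle,
                 tolerance = 1e-6)
    expect_error(effectiveStiffnessForSubset(K, integer(0)), "non-empty")
})
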