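test_that("step rotations round-trip and agree with the axis-angle oracle", {
    set.seed(31)
    for (i in 1:10) {
        trt <- c(tilt = runif(1, -6, 6), roll = runif(1, -4, 12),
                 twist = runif(1, 20, 40))
        sr <- stepRotation(trt[1], trt[2], trt[3])
        ## proper rotation
        expect_equal(crossprod(sr$A), diag(3), tolerance = 1e-12)
        expect_equal(det(sr$A), 1, tolerance = 1e-12)
        ## mid-step triad squares to the full step rotation
        expect_equal(sr$M %*% sr$M, sr$A, tolerance = 1e-12)
        ## round trip
        expect_equal(stepFromRotation(sr$A), trt, tolerance = 1e-10)
        ## brute-force axis/angle from the rotation matrix
        th <- acos((sum(diag(sr$A)) - 1) / 2)
        ax <- c(sr$A[3, 2] - sr$A[2, 3], sr$A[1, 3] - sr$A[3, 1],
                sr$A[2, 1] - sr$A[1, 2]) / (2 * sin(th))
        expect_equal(sr$angle, th, tolerance = 1e-8)
        expect_equal(sr$axis, ax, tolerance = 1e-8)
    }
})

test_that("helical rise/twist have the right limits and match the rotation oracle", {
    h <- stepToHelical(c(0, 0, 3.3, 0, 0, 34))
    expect_equal(unname(h[1, ]), c(3.3, 34))
    ## zero-rotation limit: h-twist 0, h-rise = rise
    h0 <- stepToHelical(c(0.4, -0.2, 3.3, 0, 0, 0))
    expect_equal(unname(h0[1, ]), c(3.3, 0))
    ## general case: displacement projected on the rotation axis
    set.seed(32)
    for (i in 1:5) {
        st <- c(rnorm(2, 0, 0.4), 3.3 + rnorm(1, 0, 0.1),
                rnorm(2, 0, 4), 34 + rnorm(1, 0, 4))
        sr <- stepRotation(st[4], st[5], st[6])
        v <- as.vector(sr$M %*% st[1:3])
        expect_equal(stepToHelical(st)[1, "hRise"], abs(sum(v * sr$axis)),
                     tolerance = 1e-10, ignore_attr = TRUE)
        expect_equal(abs(stepToHelical(st)[1, "hTwist"]), sr$angle / pi * 180,
                     tolerance = 1e-10, ignore_attr = TRUE)
    }
})

test_that("frame reconstruction is exact and closes geometric figures", {
    ## straight twisted rod: all normals collinear
    rod <- rodEquilibrium(10)
    fr <- buildFrames(rod)
    expect_equal(fr$normals %*% c(0, 0, 1), matrix(1, 11, 1),
                 tolerance = 1e-12)
    ## constant roll 360/n with zero twist closes a planar circle
    circ <- matrix(rep(c(0, 0, 3.3, 0, 30, 0), 12), 12, 6, byrow = TRUE)
    frc <- buildFrames(circ)
    expect_equal(frc$normals[13, ], frc$normals[1, ], tolerance = 1e-10)
    ## round trip step -> frames -> step
    set.seed(33)
    steps <- cbind(rnorm(15, 0, 0.4), rnorm(15, 0, 0.4), rnorm(15, 3.3, 0.1),
                   rnorm(15, 0, 3), rnorm(15, 3, 3), rnorm(15, 34, 3))
    expect_equal(unname(extractSteps(buildFrames(steps))), unname(steps),
                 tolerance = 1e-8)
})

test_that("Gaussian ensemble sampling is deterministic and matches (what, kBT K^-1)", {
    K <- randomSPD(12, seed = 34, ridge = 2)
    what <- rnorm(12)
    X1 <- sampleEnsemble(what, K, 200, seed = 7)
    X2 <- sampleEnsemble(what, K, 200, seed = 7)
    expect_identical(X1, X2)
    X <- sampleEnsemble(what, K, 20000, seed = 8)
    SigmaTrue <- physicalConstants()$kBT * solve(K)
    expect_equal(colMeans(X), what, tolerance = 0.05, ignore_attr = TRUE)
    expect_lt(max(abs(diag(cov(X)) / diag(SigmaTrue) - 1)), 0.05)
})

test_that("material constants follow the fluctuation formulas", {
    pc <- physicalConstants()
    set.seed(35)
    ## samples with exactly unit sample variance, scaled to the target
    z <- as.vector(scale(rnorm(4000)))
    l <- 82.5 + sqrt(2.1) * z
    om0 <- as.vector(scale(rnorm(4000)))
    om <- 14.835 + sqrt(0.069) * om0
    rec <- materialConstants(l, om, l0 = 82.5)
    expect_equal(rec@Y, pc$kBT_pN_A * 82.5 / 2.1, tolerance = 1e-12)
    expect_equal(rec@Y, 1627.2, tolerance = 1e-4)
    expect_equal(rec@Ctw, 82.5 / 0.069 / 10, tolerance = 1e-12)
    expect_equal(rec@Ctw, 119.6, tolerance = 1e-3)
    ## diagonal covariance: no twist-stretch coupling
    lOrth <- 82.5 + as.vector(scale(resid(lm(l ~ om))))
    expect_equal(materialConstants(lOrth, om)@k, 0, tolerance = 1e-10)
    ## positive k means overtwisting lengthens: construct positive coupling
    lPos <- 82.5 + 2 * (om - mean(om)) + 0.05 * z
    expect_gt(materialConstants(lPos, om)@k, 0)
    ## pi/5 converts A/rad to nm/turn
    Sig <- cov(cbind(lPos, om))
    expect_equal(materialConstants(lPos, om)@k,
                 Sig[1, 2] / Sig[2, 2] * pi / 5)
    expect_error(materialConstants(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("global length and twist are sums of helical rises and twists", {
    rod <- rodEquilibrium(25)
    g <- globalLengthTwist(rod)
    expect_equal(unname(g["l"]), 82.5)
    expect_equal(unname(g["omega"]), 25 * 34 * pi / 180)
    expect_equal(unname(globalLengthTwist(NULL)), c(0, 0))
})

test_that("homogeneous-rod persistence lengths recover the closed forms", {
    ## lp = 2 h / <theta^2>: sd 0.05 rad in tilt and roll -> ld = 132 nm;
    ## sd 0.06 rad in twist -> ltw = 183.3 nm and C = ltw / 2
    sdBend <- 0.05 * 180 / pi
    sdTw <- 0.06 * 180 / pi
    arr <- rodEnsemble(30000, 25, sdBend, sdBend, sdTw, seed = 36)
    bend <- bendingPersistence(arr, rodEquilibrium(25))
    expect_equal(persistenceLength(bend), 2 * 3.3 / 0.005 / 10,
                 tolerance = 0.03)
    expect_equal(bend@alpha, 1, tolerance = 0.01)
    expect_gt(bend@r2, 0.999)
    tw <- twistPersistence(arr)
    expect_equal(persistenceLength(tw), 2 * 3.3 / 0.0036 / 10,
                 tolerance = 0.04)
    bt <- duplexmech:::.batchTrajectories(arr)
    rec <- materialConstants(rowSums(bt$hRise), rowSums(bt$hTwist))
    expect_equal(rec@Ctw / (persistenceLength(tw) / 2), 1, tolerance = 0.05)
    ## intrinsically bent but fluctuation-free rod: the static structure is
    ## factored out, the ratio is identically 1, the p.l. unbounded
    bent <- rodEquilibrium(25)
    bent[, 5] <- 4   # constant roll
    arrBent <- array(rep(bent, each = 50), c(50, 25, 6))
    fitBent <- bendingPersistence(arrBent, bent)
    expect_equal(fitBent@ordinate[1:24], rep(1, 24), tolerance = 1e-12)
    expect_true(is.infinite(persistenceLength(fitBent)))
    ## zero twist noise: unbounded twist p.l.
    arrQuiet <- rodEnsemble(50, 25, 0, 0, 0, seed = 37)
    expect_true(is.infinite(persistenceLength(twistPersistence(arrQuiet))))
})

test_that("static disorder persistence comes from sequence variability alone", {
    ps <- syntheticParams("DNA")
    ## uniform parameters: no static disorder, unbounded persistence lengths
    flat <- ps
    sa <- sequenceAveragedParameters(ps)
    flat@stepMeans <- matrix(rep(rep(sa$step, 5), each = nrow(ps@stepMeans)),
                             nrow(ps@stepMeans),
                             dimnames = dimnames(ps@stepMeans))
    st <- staticPersistence(flat, nSeq = 50, seqLen = 36, seed = 4)
    expect_true(is.infinite(persistenceLength(st$bend)))
    expect_true(is.infinite(persistenceLength(st$twist)))
    ## known per-step spread: static bend p.l. ~ 2h / (sd_t^2 + sd_r^2)
    noisy <- flat
    set.seed(41)
    sdDeg <- 2
    nH <- nrow(ps@stepMeans)
    noisy@stepMeans[, "step3.tilt"] <- rnorm(nH, 0, sdDeg)
    noisy@stepMeans[, "step3.roll"] <- sa$step["roll"] + rnorm(nH, 0, sdDeg)
    selfc <- vapply(rownames(ps@stepMeans), isSelfComplementary, logical(1))
    noisy@stepMeans[selfc, "step3.tilt"] <- 0
    stN <- staticPersistence(noisy, nSeq = 3000, seqLen = 40, seed = 5)
    sdRad <- sdDeg * pi / 180
    h <- sa$step["rise"]
    expected <- 2 * h / (2 * sdRad^2) / 10
    expect_equal(persistenceLength(stN$bend), unname(expected),
                 tolerance = 0.15)
    ## deterministic given seed
    stN2 <- staticPersistence(noisy, nSeq = 3000, seqLen = 40, seed = 5)
    expect_identical(persistenceLength(stN$bend),
                     persistenceLength(stN2$bend))
})

test_that("length profiles are flat for uncorrelated rods and end at the global value", {
    arr <- rodEnsemble(8000, 24, 2, 2, 3, seed = 38)
    lp <- lengthProfile(arr, lengths = c(2, 6, 12, 25))
    ## independent steps: variance scales with length, Y and C are flat
    expect_lt(diff(range(lp$Y)) / mean(lp$Y), 0.1)
    expect_lt(diff(range(lp$C)) / mean(lp$C), 0.1)
    ## the full-length entry equals materialConstants on the whole duplex
    bt <- duplexmech:::.batchTrajectories(arr)
    rec <- materialConstants(rowSums(bt$hRise), rowSums(bt$hTwist))
    full <- lp[lp$length == 25, ]
    expect_equal(full$Y, rec@Y)
    expect_equal(full$C, rec@Ctw)
    expect_equal(full$k, rec@k)
    ## a fragment needs at least one step: length 2 exists, length 1 cannot
    expect_true(2 %in% lengthProfile(arr, lengths = 2)$length)
    expect_error(lengthProfile(arr, lengths = 1))
})

test_that("template threading energy vanishes on the sequence's own shape", {
    ps <- syntheticParams("DNA")
    sq <- "GCGCATTTACGGATCCAGTACGCAT"
    prof <- predictProfile(sq, ps)
    templ <- prof@stepCoords[10:13, c("roll", "twist", "slide")]
    te <- threadTemplateEnergy(sq, templ, ps)
    expect_equal(te$energy[te$offset == 10], 0, tolerance = 1e-10)
    expect_true(all(te$energy >= -1e-10))
    expect_equal(te$offset[which.min(te$energy)], 10L)
    ## partially relaxed energy matches a brute-force numeric minimization
    sq2 <- "ATCGGACTATGC"
    prof2 <- predictProfile(sq2, ps)
    templ2 <- prof2@stepCoords[5:6, c("roll", "twist", "slide")] +
        c(2, -1.5, 1, 2, 0.3, -0.2)
    te2 <- threadTemplateEnergy(sq2, templ2, ps)
    K <- repairedStiffnessMatrix(sq2, ps)
    o <- 5L
    winIdx <- (12 * (o - 1) + 1):(12 * (o + 1) + 6)
    Kwin <- stiffnessMatrix(K)[winIdx, winIdx]
    subIdx <- match(c("roll", "twist", "slide"), duplexmech:::.STEP_COORDS)
    constr <- match(c(duplexmech:::stepIndices(5)[subIdx],
                      duplexmech:::stepIndices(6)[subIdx]), winIdx)
    delta <- as.vector(t(templ2)) -
        as.vector(t(prof2@stepCoords[5:6, c("roll", "twist", "slide")]))
    oracle <- optim(rep(0, length(winIdx) - 6), function(xf) {
        w <- numeric(length(winIdx))
        w[constr] <- delta
        w[-constr] <- xf
        0.5 * crossprod(w, Kwin %*% w)
    }, method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))$value
    expect_equal(te2$energy[te2$offset == 5], oracle, tolerance = 1e-5)
    expect_error(threadTemplateEnergy("ACGTACGTAC",
                                      matrix(0, 20, 3,
                                             dimnames = list(NULL, c("roll", "twist", "slide"))),
                                      ps),
                 "template longer")
})
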