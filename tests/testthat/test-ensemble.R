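test_that("snapshots are filtered by the 4-Angstrom rule on inner pairs only", {
    hb <- hbondSeries(rbind(c(3.0, 3.0, 3.0),
                            c(4.1, 3.0, 3.0),
                            c(3.9, 3.0, 3.0),
                            c(3.0, 3.0, 6.0)),
                      pair = c(2L, 3L, 5L))
    mask <- filterSnapshots(hb, centralRange = 2:4)
    ## inner bond at 4.1 excluded; 3.9 kept; outer pair 5 at 6.0 ignored
    expect_identical(as.logical(mask), c(TRUE, FALSE, TRUE, TRUE))
    expect_equal(attr(mask, "keptFraction"), 0.75)
    ## idempotent: filtering the kept snapshots removes nothing
    hb2 <- hbondSeries(hb@dist[mask, , drop = FALSE], hb@pair)
    mask2 <- filterSnapshots(hb2, centralRange = 2:4)
    expect_true(all(mask2))
})

test_that("ensemble estimators implement what = <w>, K = kBT Sigma^-1, kx = kBT/var", {
    kBT <- physicalConstants()$kBT
    ## a 1-coordinate series with sample variance exactly kBT (deg^2) has
    ## stiffness constant exactly 1 kcal/mol/deg^2
    set.seed(51)
    x <- matrix(34 + sqrt(kBT) * as.vector(scale(rnorm(500))), ncol = 1)
    est1 <- estimateMeanCov(x)
    expect_equal(unname(est1$kx), 1)
    ## whitened samples with cov exactly kBT I give K = I
    Z <- matrix(rnorm(400 * 6), 400)
    W <- sqrt(kBT) * Z %*% solve(chol(cov(Z)))
    estI <- estimateMeanCov(W)
    expect_equal(estI$K, diag(6), tolerance = 1e-10)
    ## Monte Carlo recovery of a known stiffness
    K <- randomSPD(10, seed = 52, ridge = 2)
    X <- sampleEnsemble(rnorm(10), K, 20000, seed = 53)
    est <- estimateMeanCov(X)
    expect_lt(max(abs(diag(est$K) / diag(K) - 1)), 0.05)
    ## mask support and minimum snapshot count
    expect_error(estimateMeanCov(X, mask = c(TRUE, rep(FALSE, 19999))),
                 "at least 2")
})

test_that("max-entropy banding reproduces the covariance inside the band", {
    pc <- physicalConstants()
    ## single hexamer: no overlaps, K = kBT Sigma^-1 exactly
    S6 <- randomSPD(66, seed = 54)
    K6 <- bandedMaxentStiffness(S6, 6)
    expect_equal(stiffnessMatrix(K6), pc$kBT * solve(S6), tolerance = 1e-9)
    ## random SPD covariances up to 10 bp: in-band reproduction to 1e-8,
    ## exact zeros outside the band
    for (nBp in c(7L, 10L)) {
        d <- coordinateVectorLength(nBp)
        S <- randomSPD(d, seed = 54 + nBp)
        Kb <- bandedMaxentStiffness(S, nBp)
        bp <- bandPattern(nBp)
        SigImp <- pc$kBT * solve(stiffnessMatrix(Kb))
        expect_lt(max(abs((SigImp - S)[bp])), 1e-8)
        expect_true(all(stiffnessMatrix(Kb)[!bp] == 0))
        ## the banded stiffness of an SPD covariance is SPD
        expect_gt(min(eigen(stiffnessMatrix(Kb), symmetric = TRUE,
                            only.values = TRUE)$values), 0)
    }
    ## covariance whose inverse is already banded: recovered exactly
    d8 <- coordinateVectorLength(8L)
    Kgen <- bandedMaxentStiffness(randomSPD(d8, seed = 77), 8L)
    Sgen <- pc$kBT * solve(stiffnessMatrix(Kgen))
    Kback <- bandedMaxentStiffness((Sgen + t(Sgen)) / 2, 8L)
    expect_equal(stiffnessMatrix(Kback), stiffnessMatrix(Kgen),
                 tolerance = 1e-8)
    expect_error(bandedMaxentStiffness(diag(10), 8), "must be")
})

test_that("block extraction round-trips through assembly and flags duplicates", {
    sq <- "ACGGTCAAG"   # no self-complementary hexamer windows
    d <- coordinateVectorLength(nchar(sq))
    Kb <- bandedMaxentStiffness(randomSPD(d, seed = 55), nchar(sq))
    ex <- extractHexamerBlocks(Kb, sq)
    expect_length(ex$blocks, 4L)
    expect_equal(nrow(ex$duplicates), 0L)
    Kre <- assembleFromBlocks(sq, ex$blocks)
    expect_equal(stiffnessMatrix(Kre), stiffnessMatrix(Kb), tolerance = 1e-12)
    ## single hexamer: one block equal to the whole matrix
    K1 <- bandedMaxentStiffness(randomSPD(66, seed = 56), 6)
    ex1 <- extractHexamerBlocks(K1, "CATGAC")
    expect_length(ex1$blocks, 1L)
    expect_equal(ex1$blocks[["CATGAC"]], stiffnessMatrix(K1))
    ## a duplicated window is reported with its deviation; first occurrence
    ## wins
    sqd <- "AAAAAAA"    # windows 1 and 2 are both AAAAAA
    Kd <- bandedMaxentStiffness(randomSPD(coordinateVectorLength(7), seed = 57), 7)
    exd <- extractHexamerBlocks(Kd, sqd)
    expect_equal(nrow(exd$duplicates), 1L)
    expect_equal(exd$duplicates$hexamer, "AAAAAA")
    expect_gt(exd$duplicates$maxDeviation, 0)
    expect_equal(exd$blocks[["AAAAAA"]],
                 stiffnessMatrix(Kd)[blockSlice(1), blockSlice(1)])
    expect_error(assembleFromBlocks("CATGAC", list()), "missing block")
})

test_that("convergence errors follow the half-trajectory formula", {
    expect_equal(unname(convergenceError(1, 3, 2)), c(1, 0.5))
    expect_equal(unname(convergenceError(2, 2, 2)), c(0, 0))
    expect_true(is.na(convergenceError(1, -1, 0)["er"]))
    ## halves of a stationary series converge on the full-series mean
    set.seed(58)
    x <- rnorm(20000, 5, 1)
    ce <- convergenceError(mean(x[1:10000]), mean(x[10001:20000]), mean(x))
    expect_lt(ce["er"], 0.01)
})

test_that("opening events are maximal runs above the cutoff", {
    d <- matrix(3, 10, 2)
    d[2, 1] <- 4.5          # single-snapshot event
    d[5:7, 2] <- 4.2        # three-snapshot event
    hb <- hbondSeries(d, pair = c(4L, 4L), times = seq(0, 90, by = 10))
    ev <- openingEvents(hb, 4)
    expect_equal(sort(ev), c(10, 30))
    expect_error(openingEvents(hb, 9), "no bonds")
})

test_that("survival fits recover exponential opening rates", {
    set.seed(59)
    dur <- rexp(10000, rate = 0.5)
    sf <- survivalFit(dur)
    ## tau_open = 2 ns within 3 standard errors of an efficient estimator
    expect_lt(abs(sf@tauOpen - 2), 3 * 2 / sqrt(length(dur)) + 1e-12)
    expect_gt(sf@r2, 0.99)
    expect_true(sf@auto)
    ## explicit window
    sf2 <- survivalFit(dur, fitWindow = c(0.5, 6))
    expect_lt(abs(sf2@tauOpen - 2), 0.15)
    ## degenerate inputs are refused
    expect_error(survivalFit(numeric(0)), "empty event set")
    expect_error(survivalFit(rep(2, 10)), "durations equal")
    expect_error(survivalFit(c(1, 2), fitWindow = c(10, 20)),
                 "fewer than 3 support points")
})

test_that("synthetic trajectories are deterministic and recover injected openings", {
    ps <- syntheticParams("DNA")
    sq <- "GCGCATTTACGG"
    model <- buildDuplexModel(sq, ps, trim = FALSE)
    tr1 <- syntheticTrajectory(model, n = 200, seed = 6)
    tr2 <- syntheticTrajectory(model, n = 200, seed = 6)
    expect_identical(tr1$coords@data, tr2$coords@data)
    expect_identical(tr1$hbonds@dist, tr2$hbonds@dist)
    ## opening rate 0: the filter keeps every snapshot
    mask <- filterSnapshots(tr1$hbonds, 3:(nchar(sq) - 2))
    expect_equal(attr(mask, "keptFraction"), 1)
    ## injected exponential openings: recovered mean opening time within CI
    tr <- syntheticTrajectory(model, n = 30000, seed = 7, dt = 0.01,
                              openingRate = 0.4, meanOpenTime = 1)
    durations <- unlist(lapply(3:(nchar(sq) - 2),
                               function(p) openingEvents(tr$hbonds, p)))
    durations <- durations / 1000       # ps -> ns
    expect_gt(length(durations), 200)
    sf <- survivalFit(durations)
    expect_lt(abs(sf@tauOpen - 1), 4 / sqrt(length(durations)))
    ## filtering now removes the open snapshots
    kept <- attr(filterSnapshots(tr$hbonds, 3:(nchar(sq) - 2)), "keptFraction")
    expect_lt(kept, 1)
})

test_that("generate -> estimate -> band -> extract -> assemble recovers the model", {
    ps <- syntheticParams("DNA")
    sq <- "ACGGTCAA"    # 8 bp, no self-complementary windows
    model <- buildDuplexModel(sq, ps, trim = TRUE)
    Kgen <- stiffnessMatrix(model@K)
    expect_gt(min(eigen(Kgen, symmetric = TRUE, only.values = TRUE)$values), 0)
    tr <- syntheticTrajectory(model, n = 50000, seed = 8)
    mask <- filterSnapshots(tr$hbonds, 3:6)
    est <- estimateMeanCov(tr$coords, mask)
    expect_equal(est$what, model@what, tolerance = 0.02, ignore_attr = TRUE)
    Khat <- bandedMaxentStiffness(est$Sigma, nchar(sq))
    ex <- extractHexamerBlocks(Khat, sq)
    Kre <- assembleFromBlocks(sq, ex$blocks)
    ## assembly reproduces the banded estimate exactly
    expect_equal(stiffnessMatrix(Kre), stiffnessMatrix(Khat),
                 tolerance = 1e-10)
    ## and the estimate recovers the generating banded stiffness within
    ## Monte Carlo error (compared on the dimensionless scale)
    s <- duplexmech:::coordinateScales(nchar(sq))
    rel <- norm((stiffnessMatrix(Khat) - Kgen) * tcrossprod(s), "F") /
        norm(Kgen * tcrossprod(s), "F")
    expect_lt(rel, 0.1)
})

test_that("coordinate and H-bond series round-trip through CSV", {
    ps <- syntheticParams("DNA")
    model <- buildDuplexModel("GCGCATTTACGG", ps, trim = FALSE)
    tr <- syntheticTrajectory(model, n = 50, seed = 9, openingRate = 0.5,
                              meanOpenTime = 0.5)
    fc <- tempfile(fileext = ".csv")
    writeCoordinateSeries(tr$coords, fc)
    back <- readCoordinateSeries(fc, "GCGCATTTACGG")
    expect_equal(unname(back@data), unname(tr$coords@data), tolerance = 1e-10)
    expect_equal(back@times, tr$coords@times)
    fh <- tempfile(fileext = ".csv")
    writeHBondSeries(tr$hbonds, fh)
    hback <- readHBondSeries(fh)
    expect_equal(unname(hback@dist), unname(tr$hbonds@dist), tolerance = 1e-10)
    expect_identical(hback@pair, tr$hbonds@pair)
})
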