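## Rigid-base mechanics: step <-> frame conversions (mid-step triad
## convention), helical rise/twist, Gaussian ensemble sampling, global
## elastic constants, bending/twist persistence lengths, static disorder,
## length-scale profiles and template threading energies.

.deg2rad <- pi / 180

## quaternion of the step rotation Rz(w/2 - phi) Ry(Gamma) Rz(w/2 + phi),
## vectorized over steps; tilt/roll/twist in degrees
.stepQuaternion <- function(tilt, roll, twist) {
    gam <- sqrt(tilt^2 + roll^2) * .deg2rad
    phi <- atan2(tilt, roll)
    om <- twist * .deg2rad
    cg <- cos(gam / 2); sg <- sin(gam / 2)
    cw <- cos(om / 2); sw <- sin(om / 2)
    cbind(w = cg * cw,
          x = sg * sin(phi),
          y = sg * cos(phi),
          z = cg * sw)
}

.quatMultiply <- function(a, b) {
    cbind(w = a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
          x = a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
          y = a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
          z = a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1])
}

.quatToMatrix <- function(q) {
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3L, 3L)
}

#' Rotation matrix of a base-pair step
#'
#' Composes the step rotation from (tilt, roll, twist) using the mid-step
#' triad convention: with the roll-tilt angle Gamma = sqrt(tilt^2 + roll^2)
#' and phase phi = atan2(tilt, roll), the rotation is
#' Rz(twist/2 - phi) Ry(Gamma) Rz(twist/2 + phi). The mid-step triad is the
#' half-rotation about the same axis.
#'
#' @param tilt,roll,twist Step rotations in degrees.
#' @return List with `A` (3x3 step rotation), `M` (3x3 mid-step rotation),
#'   `angle` (total rotation angle, radians) and `axis` (unit vector).
#' @export
stepRotation <- function(tilt, roll, twist) {
    q <- unname(.stepQuaternion(tilt, roll, twist)[1L, ])
    A <- .quatToMatrix(q)
    vn <- sqrt(sum(q[2:4]^2))
    angle <- 2 * atan2(vn, q[1])
    axis <- if (vn > 1e-12) q[2:4] / vn else c(0, 0, 1)
    half <- c(cos(angle / 4), axis * sin(angle / 4))
    list(A = A, M = .quatToMatrix(half), angle = angle, axis = axis)
}

#' Step coordinates from a step rotation and displacement
#'
#' Inverse of the mid-step triad composition: recovers (tilt, roll, twist)
#' from the rotation matrix (a ZYZ Euler decomposition) and (shift, slide,
#' rise) from the displacement expressed in the mid-step frame.
#'
#' @param A 3x3 step rotation (in the frame of the first pair).
#' @param d Displacement of the second origin in the first pair's frame
#'   (optional).
#' @return Named numeric: tilt, roll, twist (degrees) and, when `d` is given,
#'   shift, slide, rise (Angstrom).
#' @export
stepFromRotation <- function(A, d = NULL) {
    cg <- max(min(A[3, 3], 1), -1)
    gam <- acos(cg)
    if (abs(gam) < 1e-10) {
        om <- atan2(A[2, 1], A[1, 1])
        tilt <- roll <- 0
        phi <- 0
    } else {
        a <- atan2(A[2, 3], A[1, 3])
        b <- atan2(A[3, 2], -A[3, 1])
        om <- a + b
        phi <- (b - a) / 2
        tilt <- gam * sin(phi)
        roll <- gam * cos(phi)
    }
    out <- c(tilt = tilt / .deg2rad, roll = roll / .deg2rad,
             twist = om / .deg2rad)
    if (!is.null(d)) {
        sr <- stepRotation(out["tilt"], out["roll"], out["twist"])
        v <- crossprod(sr$M, d)
        out <- c(shift = v[1], slide = v[2], rise = v[3], out)
    }
    out
}

#' Helical rise and twist of a base-pair step
#'
#' The helical twist is the total rotation angle of the step rotation and the
#' helical rise is the displacement projected onto the rotation axis. When
#' the rotation angle is (near) zero the axis is undefined; the documented
#' limit assigns h-twist = 0 and h-rise = the displacement along the mid-step
#' normal. Vectorized over steps.
#'
#' @param steps Matrix (or 6-vector) of step coordinates, columns shift,
#'   slide, rise, tilt, roll, twist.
#' @return Matrix with columns `hRise` (Angstrom) and `hTwist` (degrees).
#' @examples
#' stepToHelical(c(0, 0, 3.3, 0, 0, 34))
#' @export
stepToHelical <- function(steps) {
    if (is.null(dim(steps))) steps <- matrix(steps, nrow = 1L)
    q <- .stepQuaternion(steps[, 4L], steps[, 5L], steps[, 6L])
    vn <- sqrt(q[, 2]^2 + q[, 3]^2 + q[, 4]^2)
    theta <- 2 * atan2(vn, q[, 1])
    ok <- vn > 1e-12
    ux <- ifelse(ok, q[, 2] / vn, 0)
    uy <- ifelse(ok, q[, 3] / vn, 0)
    uz <- ifelse(ok, q[, 4] / vn, 1)
    hRise <- steps[, 1L] * ux + steps[, 2L] * uy + steps[, 3L] * uz
    hTwist <- theta
    flip <- hRise < 0
    hRise[flip] <- -hRise[flip]
    hTwist[flip] <- -hTwist[flip]
    hTwist[!ok] <- 0
    hRise[!ok] <- steps[!ok, 3L]
    cbind(hRise = hRise, hTwist = hTwist / .deg2rad)
}

#' Reconstruct base-pair frames from step coordinates
#'
#' Composes frames along the duplex: T_(i+1) = T_i A_i with the step rotation
#' A_i of [stepRotation()], and origins advanced by the displacement expressed
#' in the mid-step triad. Pair 0 carries the identity frame at the origin.
#'
#' @param steps m x 6 matrix of step coordinates.
#' @return List with `triads` (3 x 3 x (m+1) array), `origins` ((m+1) x 3),
#'   and `normals` ((m+1) x 3, the triad z axes).
#' @export
buildFrames <- function(steps) {
    if (is.null(dim(steps))) steps <- matrix(steps, nrow = 1L)
    m <- nrow(steps)
    triads <- array(0, c(3L, 3L, m + 1L))
    origins <- matrix(0, m + 1L, 3L)
    triads[, , 1L] <- diag(3)
    for (i in seq_len(m)) {
        sr <- stepRotation(steps[i, 4L], steps[i, 5L], steps[i, 6L])
        Ti <- triads[, , i]
        origins[i + 1L, ] <- origins[i, ] +
            as.vector(Ti %*% sr$M %*% steps[i, 1:3])
        triads[, , i + 1L] <- Ti %*% sr$A
    }
    list(triads = triads, origins = origins, normals = t(triads[, 3L, ]))
}

#' @describeIn buildFrames recover the step coordinates from a frame series
#'   (round-trip inverse)
#' @param frames Output of `buildFrames`.
#' @export
extractSteps <- function(frames) {
    m <- dim(frames$triads)[3L] - 1L
    out <- matrix(0, m, 6L, dimnames = list(NULL, .STEP_COORDS))
    for (i in seq_len(m)) {
        Ti <- frames$triads[, , i]
        A <- crossprod(Ti, frames$triads[, , i + 1L])
        d <- crossprod(Ti, frames$origins[i + 1L, ] - frames$origins[i, ])
        v <- stepFromRotation(A, d)
        out[i, ] <- v[c("shift", "slide", "rise", "tilt", "roll", "twist")]
    }
    out
}

## cumulative normals dot t0 and cumulative helical series, vectorized over
## snapshots; stepArray is n x m x 6
.batchTrajectories <- function(stepArray) {
    n <- dim(stepArray)[1L]; m <- dim(stepArray)[2L]
    q <- cbind(w = rep(1, n), x = 0, y = 0, z = 0)
    tz <- matrix(0, n, m)       # t_i . t_0 for i = 1..m
    hr <- matrix(0, n, m)       # helical rise per step
    ht <- matrix(0, n, m)       # helical twist per step (radians)
    for (i in seq_len(m)) {
        st <- stepArray[, i, , drop = FALSE]
        dim(st) <- c(n, 6L)
        qs <- .stepQuaternion(st[, 4L], st[, 5L], st[, 6L])
        q <- .quatMultiply(q, qs)
        tz[, i] <- 1 - 2 * (q[, 2]^2 + q[, 3]^2)
        hel <- stepToHelical(st)
        hr[, i] <- hel[, 1L]
        ht[, i] <- hel[, 2L] * .deg2rad
    }
    list(normalDot = tz, hRise = hr, hTwist = ht)
}

## column-wise cumulative sum, vectorized over rows
.rowCumsum <- function(x) {
    for (j in seq_len(ncol(x))[-1L]) x[, j] <- x[, j - 1L] + x[, j]
    x
}

#' Sample a Gaussian coordinate ensemble from a model
#'
#' Draws snapshots from the multivariate normal with mean `what` and
#' covariance kBT K^-1 (the canonical ensemble of the quadratic model).
#'
#' @param what Equilibrium coordinate vector.
#' @param K SPD stiffness (`DuplexStiffness` or matrix), same dimension.
#' @param n Number of snapshots.
#' @param seed Integer seed (deterministic output).
#' @return n x length(what) matrix of coordinate snapshots.
#' @export
sampleEnsemble <- function(what, K, n, seed = 1L) {
    m <- if (is(K, "DuplexStiffness")) K@mat else K
    stopifnot(length(what) == nrow(m), n >= 1)
    kBT <- physicalConstants()$kBT
    Sigma <- kBT * tryCatch(solve((m + t(m)) / 2),
                            error = function(e) stop("stiffness matrix is singular"))
    R <- tryCatch(chol((Sigma + t(Sigma)) / 2),
                  error = function(e) stop("stiffness matrix is not positive definite"))
    set.seed(as.integer(seed))
    z <- matrix(stats::rnorm(n * length(what)), n)
    sweep(z %*% R, 2L, what, `+`)
}

#' @describeIn sampleEnsemble sample from a [buildDuplexModel()] object
#' @param model A `DuplexModel`.
#' @export
sampleModelEnsemble <- function(model, n, seed = 1L)
    sampleEnsemble(model@what, model@K, n, seed)

#' Extract the per-step coordinate array from coordinate-vector samples
#'
#' @param samples n x (12 nBp - 6) matrix of coordinate snapshots.
#' @param nBp Number of base pairs.
#' @return n x (nBp - 1) x 6 array of step coordinates.
#' @export
stepCoordinateArray <- function(samples, nBp) {
    n <- nrow(samples)
    m <- nBp - 1L
    out <- array(0, c(n, m, 6L))
    for (s in seq_len(m)) out[, s, ] <- samples[, stepIndices(s)]
    out
}

#' Global length and twist of a fragment
#'
#' The global length is the sum of helical rises and the global twist the sum
#' of helical twists (in radians) over the steps of the fragment.
#'
#' @param steps m x 6 step-coordinate matrix (one snapshot).
#' @return Named numeric `l` (Angstrom) and `omega` (radians).
#' @examples
#' globalLengthTwist(matrix(rep(c(0, 0, 3.3, 0, 0, 34), 25), 25, byrow = TRUE))
#' @export
globalLengthTwist <- function(steps) {
    if (is.null(steps) || NROW(steps) == 0L) return(c(l = 0, omega = 0))
    hel <- stepToHelical(steps)
    c(l = sum(hel[, 1L]), omega = sum(hel[, 2L]) * .deg2rad)
}

setClass("GlobalElasticRecord",
    representation(l0 = "numeric", omega0 = "numeric", Sigma = "matrix",
                   Krod = "matrix", Y = "numeric", Ctw = "numeric",
                   k = "numeric", n = "integer"))

setMethod("show", "GlobalElasticRecord", function(object) {
    cat(sprintf("GlobalElasticRecord (n = %d snapshots)\n", object@n))
    cat(sprintf("  l0 = %.2f A, omega0 = %.4f rad\n", object@l0, object@omega0))
    cat(sprintf("  stretch modulus Y = %.0f pN\n", object@Y))
    cat(sprintf("  twist stiffness C = %.1f nm\n", object@Ctw))
    cat(sprintf("  twist-stretch coupling k = %.3f nm/turn\n", object@k))
})

#' Global material constants from length/twist fluctuations
#'
#' From snapshots of the global length l (Angstrom) and global twist omega
#' (radians): the 1D stretch modulus Y = kBT l0 / var(l) (reported in pN),
#' the 1D twist stiffness C = l0 / var(omega) (reported in nm), the
#' twist-stretch coupling k = cov(l, omega) / var(omega) (Angstrom/radian,
#' reported in nm/turn via the factor pi/5), and the 2x2 material stiffness
#' Krod = kBT l0 Sigma^-1. Positive k means overtwisting lengthens the helix.
#'
#' @param l Numeric vector of global lengths (Angstrom).
#' @param omega Numeric vector of global twists (radians).
#' @param l0 Equilibrium length; defaults to mean(l).
#' @return A `GlobalElasticRecord`.
#' @export
materialConstants <- function(l, omega, l0 = mean(l)) {
    stopifnot(length(l) == length(omega), length(l) >= 2)
    pc <- physicalConstants()
    Sigma <- stats::cov(cbind(l, omega))
    if (any(diag(Sigma) <= 0)) stop("zero variance in global coordinates")
    Y <- pc$kBT_pN_A * l0 / Sigma[1L, 1L]
    C <- l0 / Sigma[2L, 2L] / 10          # Angstrom -> nm
    k <- Sigma[1L, 2L] / Sigma[2L, 2L] * pi / 5
    Krod <- pc$kBT * l0 * solve(Sigma)
    new("GlobalElasticRecord", l0 = l0, omega0 = mean(omega), Sigma = Sigma,
        Krod = Krod, Y = Y, Ctw = C, k = k, n = length(l))
}

setClass("PersistenceFit",
    representation(kind = "character", li0 = "numeric", ordinate = "numeric",
                   fitRange = "integer", persistenceLength = "numeric",
                   alpha = "numeric", r2 = "numeric", slope = "numeric"))

setMethod("show", "PersistenceFit", function(object) {
    pl <- if (is.finite(object@persistenceLength))
        sprintf("%.1f nm", object@persistenceLength) else "unbounded"
    cat(sprintf("PersistenceFit (%s): %s, alpha = %.4f, R^2 = %.4f\n",
                object@kind, pl, object@alpha, object@r2))
})

#' @describeIn bendingPersistence persistence length in nm (Inf when the
#'   correlation does not decay)
#' @param fit A `PersistenceFit`.
#' @export
persistenceLength <- function(fit) fit@persistenceLength

## semilog straight-line fit of ordinate vs li0; Inf persistence length when
## the decay is absent (slope >= 0 within numerical noise)
.persistenceFit <- function(kind, li0, ordinate, fitRange) {
    fitRange <- fitRange[fitRange <= length(ordinate)]
    usable <- fitRange[ordinate[fitRange] > 0 & is.finite(ordinate[fitRange])]
    if (length(usable) < length(fitRange))
        warning("non-positive ordinate values excluded from the ",
                kind, " persistence fit")
    if (length(usable) < 3L)
        stop("fewer than 3 usable separations for the persistence fit")
    x <- li0[usable]
    y <- log(ordinate[usable])
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2L])
    alpha <- exp(unname(stats::coef(fit)[1L]))
    r2 <- summary(fit)$r.squared
    pl <- if (slope < -1e-12) -1 / slope / 10 else Inf   # Angstrom -> nm
    new("PersistenceFit", kind = kind, li0 = li0, ordinate = ordinate,
        fitRange = as.integer(usable), persistenceLength = pl,
        alpha = alpha, r2 = r2, slope = slope)
}

#' Dynamic bending persistence length
#'
#' Directional correlations of the base-pair normals with the static
#' structure factored out: the ratio <t_i . t_0> / (that_i . that_0) is
#' fitted as alpha_d exp(-l_i0 / l_d) on a semilog plot against the mean
#' contour distance l_i0 (sum of helical rises between pairs 0 and i).
#'
#' @param stepSamples n x m x 6 array of step-coordinate snapshots (see
#'   [stepCoordinateArray()]).
#' @param eqSteps m x 6 matrix of equilibrium step coordinates (defines the
#'   equilibrium normals that are factored out).
#' @param fitRange Pair separations used in the fit (default 1..min(24, m)).
#' @return A `PersistenceFit` with the persistence length in nm and the
#'   prefactor alpha.
#' @export
bendingPersistence <- function(stepSamples, eqSteps,
                               fitRange = seq_len(min(24L, dim(stepSamples)[2L]))) {
    bt <- .batchTrajectories(stepSamples)
    corr <- colMeans(bt$normalDot)
    eq <- .batchTrajectories(array(eqSteps, c(1L, dim(eqSteps))))
    ratio <- corr / as.vector(eq$normalDot)
    li0 <- colMeans(.rowCumsum(bt$hRise))
    .persistenceFit("dynamic-bend", li0, ratio, fitRange)
}

#' Twist persistence length
#'
#' Correlations of the global twist: <cos(omega_i - <omega_i>)> fitted as
#' alpha_tw exp(-l_i0 / l_tw). The equilibrium twist is subtracted, so the
#' twist persistence length is the analog of the dynamic bending persistence
#' length.
#'
#' @inheritParams bendingPersistence
#' @return A `PersistenceFit`.
#' @export
twistPersistence <- function(stepSamples,
                             fitRange = seq_len(min(24L, dim(stepSamples)[2L]))) {
    bt <- .batchTrajectories(stepSamples)
    om <- .rowCumsum(bt$hTwist)
    dOm <- sweep(om, 2L, colMeans(om))
    ordinate <- colMeans(cos(dOm))
    li0 <- colMeans(.rowCumsum(bt$hRise))
    .persistenceFit("twist", li0, ordinate, fitRange)
}

## fast central-step lookup for all 4^6 hexamers of the alphabet
.centralStepLookup <- function(ps) {
    allHex <- names(.allKmersNamed(6L, ps@naType))
    canon <- canonicalClass(allHex, naType = ps@naType)
    r <- match(canon, ps@hexamers)
    v <- ps@stepMeans[r, 12L + 1:6, drop = FALSE]
    flip <- canon != allHex
    v[flip, c(1L, 4L)] <- -v[flip, c(1L, 4L)]
    rownames(v) <- allHex
    v
}

.allKmersNamed <- function(k, naType) {
    alpha <- if (naType == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
    grid <- do.call(expand.grid, c(rep(list(alpha), k), stringsAsFactors = FALSE))
    all <- do.call(paste0, grid)
    stats::setNames(seq_along(all), all)
}

#' Static persistence lengths from sequence disorder
#'
#' Generates random sequences, treats the model-predicted equilibrium
#' structure of each as one snapshot of a virtual ensemble, and applies the
#' bending and twist persistence analysis with the sequence-averaged static
#' structure as the reference. This isolates the disorder contributed by
#' sequence-dependent equilibrium structure, as opposed to thermal motion.
#'
#' @param ps A `ParameterSet`.
#' @param nSeq Number of random sequences (virtual snapshots).
#' @param seqLen Sequence length in bp; the covered steps 3..seqLen-3 are
#'   used.
#' @param seed Integer seed.
#' @param fitRange Pair separations for the fits.
#' @return List with elements `bend` and `twist`, both `PersistenceFit`s.
#' @export
staticPersistence <- function(ps, nSeq = 2000L, seqLen = 40L, seed = 1L,
                              fitRange = 1:24) {
    stopifnot(seqLen >= 12L)
    set.seed(as.integer(seed))
    alpha <- if (ps@naType == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
    lut <- .centralStepLookup(ps)
    m <- seqLen - 5L                    # covered steps 3..seqLen-3
    arr <- array(0, c(nSeq, m, 6L))
    for (i in seq_len(nSeq)) {
        sq <- paste(sample(alpha, seqLen, replace = TRUE), collapse = "")
        hexes <- substring(sq, 1:(seqLen - 5L), 6:seqLen)
        arr[i, , ] <- lut[hexes, , drop = FALSE]
    }
    sa <- sequenceAveragedParameters(ps)
    eq <- matrix(rep(sa$centralStep, each = m), m, 6L)
    list(bend = bendingPersistence(arr, eq, fitRange = fitRange),
         twist = twistPersistence(arr, fitRange = fitRange))
}

#' Length-scale profile of the global elastic constants
#'
#' For every contiguous fragment (2 bp up to the full length) of every
#' snapshot, computes the stretch modulus, twist stiffness and twist-stretch
#' coupling from the fragment's length/twist fluctuations, then averages
#' values of fragments with equal length over all start offsets.
#'
#' @param stepSamples n x m x 6 array of step-coordinate snapshots.
#' @param lengths Fragment lengths in bp to include (default 2..m+1).
#' @return data.frame with columns `length`, `Y` (pN), `C` (nm), `k`
#'   (nm/turn).
#' @export
lengthProfile <- function(stepSamples, lengths = NULL) {
    bt <- .batchTrajectories(stepSamples)
    m <- ncol(bt$hRise)
    cumL <- cbind(0, .rowCumsum(bt$hRise))
    cumW <- cbind(0, .rowCumsum(bt$hTwist))
    if (is.null(lengths)) lengths <- 2:(m + 1L)
    if (any(lengths < 2L) || any(lengths > m + 1L))
        stop("fragment lengths must be between 2 bp and the duplex length")
    pc <- physicalConstants()
    out <- lapply(lengths, function(f) {
        s <- f - 1L                     # steps in the fragment
        offs <- seq_len(m - s + 1L)
        Yv <- Cv <- kv <- numeric(length(offs))
        for (ii in seq_along(offs)) {
            o <- offs[ii]
            lfrag <- cumL[, o + s] - cumL[, o]
            wfrag <- cumW[, o + s] - cumW[, o]
            l0 <- mean(lfrag)
            vl <- stats::var(lfrag); vw <- stats::var(wfrag)
            Yv[ii] <- pc$kBT_pN_A * l0 / vl
            Cv[ii] <- l0 / vw / 10
            kv[ii] <- stats::cov(lfrag, wfrag) / vw * pi / 5
        }
        data.frame(length = f, Y = mean(Yv), C = mean(Cv), k = mean(kv))
    })
    do.call(rbind, out)
}

#' Threading energy of a per-step template along a sequence
#'
#' Slides a per-step coordinate template (by default over the highly
#' conserved roll, twist and slide) along the covered region of a duplex.
#' At each offset the model's stiffness is reduced to the template subset by
#' the partially relaxed (Schur complement) scheme - all other coordinates
#' adopt energy-optimal values - and the deformation energy of imposing the
#' template on the predicted means is recorded.
#'
#' @param seq Sequence (character or `DuplexSequence`).
#' @param template Matrix with one row per template step; columns named by
#'   the constrained step coordinates.
#' @param ps A `ParameterSet`.
#' @param subset Constrained step coordinates (column order of `template`).
#' @param lambdaC Eigenvalue cutoff for the model stiffness.
#' @param trim Trim the repaired stiffness to the hexameric band.
#' @return data.frame with columns `offset` (duplex step index of the first
#'   template step) and `energy` (kcal/mol).
#' @export
threadTemplateEnergy <- function(seq, template, ps,
                                 subset = c("roll", "twist", "slide"),
                                 lambdaC = NULL, trim = TRUE) {
    ds <- duplexSequence(seq, ps@naType)
    n <- nchar(ds@seq)
    template <- as.matrix(template)
    if (is.null(colnames(template))) colnames(template) <- subset
    template <- template[, subset, drop = FALSE]
    tSteps <- nrow(template)
    stopifnot(all(subset %in% .STEP_COORDS))
    if (tSteps > n - 5L - 2L)
        stop("template longer than the covered part of the sequence")
    prof <- predictProfile(ds, ps)
    K <- repairedStiffnessMatrix(ds, ps, lambdaC = lambdaC, trim = trim)
    subOff <- match(subset, .STEP_COORDS)
    offsets <- 3:(n - 3L - tSteps + 1L)
    energy <- numeric(length(offsets))
    for (ii in seq_along(offsets)) {
        o <- offsets[ii]
        stepsIdx <- o:(o + tSteps - 1L)
        winIdx <- (12L * (o - 1L) + 1L):(12L * (o + tSteps - 1L) + 6L)
        constrGlobal <- as.vector(vapply(stepsIdx,
                                         function(s) stepIndices(s)[subOff],
                                         integer(length(subOff))))
        constrLocal <- match(constrGlobal, winIdx)
        Keff <- effectiveStiffnessForSubset(K@mat[winIdx, winIdx], constrLocal)
        pred <- as.vector(t(prof@stepCoords[stepsIdx, subset, drop = FALSE]))
        delta <- as.vector(t(template)) - pred
        energy[ii] <- as.numeric(0.5 * crossprod(delta, Keff %*% delta))
    }
    data.frame(offset = offsets, energy = energy)
}
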