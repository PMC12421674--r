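## shared fixtures: cached synthetic parameter sets and random test objects

.paramCache <- new.env(parent = emptyenv())

syntheticParams <- function(naType = "DNA", seed = 42L) {
    key <- paste(naType, seed)
    if (is.null(.paramCache[[key]]))
        .paramCache[[key]] <- generateSyntheticParameters(seed, naType)
    .paramCache[[key]]
}

## random symmetric positive definite matrix
randomSPD <- function(d, seed = 1L, ridge = 0.5) {
    set.seed(seed)
    A <- matrix(rnorm(d * d), d)
    crossprod(A) / d + ridge * diag(d)
}

## a hexamer record with arbitrary (but valid) values
randomHexamerRecord <- function(sequence, seed = 1L) {
    set.seed(seed)
    hexamerRecord(
        sequence = sequence,
        pairCoords = matrix(rnorm(36), 6, 6),
        stepCoords = matrix(rnorm(30, 0, 2) + rep(c(0, 0, 3.3, 0, 3, 34), each = 5), 5, 6),
        majorGroove = 18 + rnorm(1),
        minorGroove = 12 + rnorm(2),
        pairK = matrix(rexp(36) + 0.01, 6, 6),
        stepK = matrix(rexp(30) + 0.01, 5, 6),
        majorGrooveK = 0.2 + rexp(1, 10),
        minorGrooveK = 0.3 + rexp(2, 10),
        block = randomSPD(66, seed + 1))
}

## homogeneous-rod step-coordinate snapshots: n x m x 6 array with Gaussian
## tilt/roll/twist noise (sd in degrees) around a straight twisted rod
rodEnsemble <- function(n, m, sdTilt, sdRoll, sdTwist, rise = 3.3,
                        twist = 34, seed = 1L) {
    set.seed(seed)
    arr <- array(0, c(n, m, 6L))
    arr[, , 3L] <- rise
    arr[, , 4L] <- rnorm(n * m, 0, sdTilt)
    arr[, , 5L] <- rnorm(n * m, 0, sdRoll)
    arr[, , 6L] <- twist + rnorm(n * m, 0, sdTwist)
    arr
}

rodEquilibrium <- function(m, rise = 3.3, twist = 34)
    matrix(rep(c(0, 0, rise, 0, 0, twist), each = m), m, 6L)
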