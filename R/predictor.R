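## Sequence -> shape, per-coordinate stiffness, groove profiles and the
## assembled nonlocal banded stiffness matrix.

setClass("ShapeProfile",
    representation(
        sequence = "character", naType = "character", nBp = "integer",
        pairCoords = "matrix",    # nBp x 6, NA where uncovered
        stepCoords = "matrix",    # (nBp-1) x 6
        minorGroove = "numeric",  # per pair
        majorGroove = "numeric",  # per step
        pairK = "matrix", stepK = "matrix",
        minorGrooveK = "numeric", majorGrooveK = "numeric",
        coveredPairs = "integer", coveredSteps = "integer",
        filled = "logical"))

setMethod("show", "ShapeProfile", function(object) {
    cat(sprintf("ShapeProfile (%s, %d bp): steps %d..%d and pairs %d..%d covered%s\n",
                object@naType, object@nBp,
                min(object@coveredSteps), max(object@coveredSteps),
                min(object@coveredPairs), max(object@coveredPairs),
                if (object@filled) "; uncovered ends filled with sequence-averaged values" else ""))
})

#' @describeIn predictProfile per-step coordinate means (rows steps, columns
#'   shift..twist; NA outside coverage)
#' @export
stepProfile <- function(profile) profile@stepCoords

#' @describeIn predictProfile per-pair coordinate means
#' @export
pairProfile <- function(profile) profile@pairCoords

#' @describeIn predictProfile groove-width profiles as a list
#' @export
grooveProfile <- function(profile)
    list(minor = profile@minorGroove, major = profile@majorGroove)

#' Predict shape and coordinate stiffness profiles of a sequence
#'
#' Applies the hexameric/heptameric sliding window: step j takes the
#' central-step values of the hexamer spanning pairs j-2..j+3, pair j takes
#' the central-pair values of the heptamer spanning pairs j-3..j+3 (the mean
#' of its two overlapping hexamers). The major groove width is assigned per
#' hexamer to its central step, the minor groove per heptamer to its central
#' pair. For an N-bp duplex, steps 3..N-3 and pairs 4..N-3 are covered; three
#' pairs at each end are not. Uncovered positions are NA unless
#' `fillEnds = TRUE`, which fills them with the sequence-averaged values of
#' the parameter set.
#'
#' @param seq Sequence (character or [duplexSequence()]), length >= 7 for
#'   pair-level output (>= 6 gives step-level output only, with a warning).
#' @param ps A `ParameterSet` of matching `naType`.
#' @param fillEnds Fill uncovered positions with sequence-averaged values.
#' @return A `ShapeProfile`.
#' @export
predictProfile <- function(seq, ps, fillEnds = FALSE) {
    ds <- duplexSequence(seq, ps@naType)
    s <- ds@seq
    n <- nchar(s)
    if (n < 6L) stop("sequence shorter than 6 bp: no hexameric window fits")
    if (n < 7L) warning("sequence shorter than 7 bp: no pair-level (heptameric) output")

    pairCoords <- matrix(NA_real_, n, 6L, dimnames = list(NULL, .PAIR_COORDS))
    stepCoords <- matrix(NA_real_, n - 1L, 6L, dimnames = list(NULL, .STEP_COORDS))
    pairK <- pairCoords; stepK <- stepCoords
    minorGroove <- rep(NA_real_, n); minorGrooveK <- minorGroove
    majorGroove <- rep(NA_real_, n - 1L); majorGrooveK <- majorGroove

    ## hexameric windows -> central step (position h+2) and major groove
    for (h in seq_len(max(n - 5L, 0L))) {
        rec <- getHexamerRecord(ps, substr(s, h, h + 5L))
        j <- h + 2L
        stepCoords[j, ] <- rec@stepCoords[3L, ]
        stepK[j, ] <- rec@stepK[3L, ]
        majorGroove[j] <- rec@majorGroove
        majorGrooveK[j] <- rec@majorGrooveK
    }
    ## heptameric windows -> central pair (position h+3) and minor groove
    if (n >= 7L) {
        for (h in seq_len(n - 6L)) {
            rec <- getHeptamerRecord(ps, substr(s, h, h + 6L))
            j <- h + 3L
            pairCoords[j, ] <- rec@centralPair
            pairK[j, ] <- rec@pairK
            minorGroove[j] <- rec@minorGroove
            minorGrooveK[j] <- rec@minorGrooveK
        }
    }
    coveredSteps <- which(!is.na(stepCoords[, 1L]))
    coveredPairs <- which(!is.na(pairCoords[, 1L]))
    if (fillEnds) {
        sa <- sequenceAveragedParameters(ps)
        for (j in setdiff(seq_len(n - 1L), coveredSteps))
            stepCoords[j, ] <- sa$step
        for (j in setdiff(seq_len(n), coveredPairs))
            pairCoords[j, ] <- sa$pair
        minorGroove[is.na(minorGroove)] <- sa$minorGroove
        majorGroove[is.na(majorGroove)] <- sa$majorGroove
    }
    new("ShapeProfile", sequence = s, naType = ps@naType, nBp = as.integer(n),
        pairCoords = pairCoords, stepCoords = stepCoords,
        minorGroove = minorGroove, majorGroove = majorGroove,
        pairK = pairK, stepK = stepK,
        minorGrooveK = minorGrooveK, majorGrooveK = majorGrooveK,
        coveredPairs = coveredPairs, coveredSteps = coveredSteps,
        filled = fillEnds)
}

## ---------------------------------------------------------------------------

setClass("DuplexStiffness",
    representation(mat = "matrix", nBp = "integer", naType = "character",
                   dimensionless = "logical", banded = "logical"),
    validity = function(object) {
        n <- coordinateVectorLength(object@nBp)
        if (!all(dim(object@mat) == c(n, n)))
            return(sprintf("matrix must be %d x %d for %d bp", n, n, object@nBp))
        TRUE
    })

setMethod("show", "DuplexStiffness", function(object) {
    cat(sprintf("DuplexStiffness: %d bp (%d coordinates), %s, %s\n",
                object@nBp, nrow(object@mat),
                if (object@dimensionless) "dimensionless" else "mixed units (kcal/mol/A^2, /deg^2, /deg A)",
                if (object@banded) "banded" else "dense"))
})

#' @describeIn assembleStiffnessMatrix the raw matrix of a `DuplexStiffness`
#' @param K A `DuplexStiffness`.
#' @export
stiffnessMatrix <- function(K) K@mat

.asStiffness <- function(mat, nBp, naType, dimensionless, banded)
    new("DuplexStiffness", mat = unname(mat), nBp = as.integer(nBp),
        naType = naType, dimensionless = dimensionless, banded = banded)

#' Logical band pattern of the hexameric block union
#'
#' TRUE where a coordinate-vector entry pair (i, j) lies inside at least one
#' hexameric 66x66 block of an `nBp`-bp duplex.
#'
#' @param nBp Number of base pairs (>= 6).
#' @return Logical matrix of dimension 12 nBp - 6.
#' @export
bandPattern <- function(nBp) {
    n <- coordinateVectorLength(nBp)
    out <- matrix(FALSE, n, n)
    for (h in seq_len(nBp - 5L)) {
        sl <- blockSlice(h)
        out[sl, sl] <- TRUE
    }
    out
}

#' Assemble the banded stiffness matrix of a sequence
#'
#' Places the 66x66 stiffness block of every hexameric window at its position
#' along the diagonal; entries covered by several blocks (up to six) are the
#' arithmetic means of the contributing block entries; entries outside the
#' hexameric band are exactly zero. Blocks for reverse-complement windows are
#' derived by the complement transform.
#'
#' @param seq Sequence (>= 6 bp).
#' @param ps A `ParameterSet`.
#' @return A `DuplexStiffness` (mixed units, banded).
#' @export
assembleStiffnessMatrix <- function(seq, ps) {
    ds <- duplexSequence(seq, ps@naType)
    s <- ds@seq
    n <- nchar(s)
    if (n < 6L) stop("sequence shorter than 6 bp")
    dim <- coordinateVectorLength(n)
    acc <- matrix(0, dim, dim)
    cnt <- matrix(0L, dim, dim)
    for (h in seq_len(n - 5L)) {
        sl <- blockSlice(h)
        acc[sl, sl] <- acc[sl, sl] + getStiffnessBlock(ps, substr(s, h, h + 5L))
        cnt[sl, sl] <- cnt[sl, sl] + 1L
    }
    keep <- cnt > 0L
    acc[keep] <- acc[keep] / cnt[keep]
    .asStiffness(acc, n, ps@naType, dimensionless = FALSE, banded = TRUE)
}

#' Nondimensionalize or redimensionalize a stiffness matrix
#'
#' Mixed-unit stiffness entries are made dimensionless by multiplying entry
#' (i, j) with the coordinate scales s_i s_j, where s is 1 Angstrom for
#' translations and 11 degrees for rotations; all entries are then in
#' kcal/mol. `redimensionalize` is the exact inverse.
#'
#' @param K A `DuplexStiffness`.
#' @param angleScale Rotation scale in degrees.
#' @return A `DuplexStiffness` with the `dimensionless` flag toggled.
#' @export
nondimensionalize <- function(K, angleScale = physicalConstants()$angleScale) {
    stopifnot(is(K, "DuplexStiffness"))
    if (K@dimensionless) stop("matrix is already dimensionless")
    s <- coordinateScales(K@nBp, angleScale)
    .asStiffness(K@mat * tcrossprod(s), K@nBp, K@naType,
                 dimensionless = TRUE, banded = K@banded)
}

#' @rdname nondimensionalize
#' @export
redimensionalize <- function(K, angleScale = physicalConstants()$angleScale) {
    stopifnot(is(K, "DuplexStiffness"))
    if (!K@dimensionless) stop("matrix is not dimensionless")
    s <- coordinateScales(K@nBp, angleScale)
    .asStiffness(K@mat / tcrossprod(s), K@nBp, K@naType,
                 dimensionless = FALSE, banded = K@banded)
}

#' Eigenvalue-cutoff repair of a stiffness matrix
#'
#' Spectral decomposition K = P D P^T of the (dimensionless) matrix; all
#' eigenvalues below the cutoff are replaced by the cutoff and the matrix is
#' reassembled with unchanged eigenvectors. This is the minimal perturbation
#' making the matrix safely positive definite; defaults are 0.48 for DNA and
#' 0.44 for RNA.
#'
#' @param K A dimensionless `DuplexStiffness` (see [nondimensionalize()]), or
#'   a plain symmetric matrix.
#' @param lambdaC Eigenvalue cutoff; when NULL the default for the matrix's
#'   nucleic-acid type.
#' @return Repaired matrix of the same class as the input (dense).
#' @export
applyEigenvalueCutoff <- function(K, lambdaC = NULL) {
    isObj <- is(K, "DuplexStiffness")
    m <- if (isObj) K@mat else K
    if (isObj && !K@dimensionless)
        stop("apply the cutoff to the nondimensionalized matrix")
    if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
    if (is.null(lambdaC)) {
        if (!isObj) stop("lambdaC required for a plain matrix")
        lambdaC <- physicalConstants()$lambdaC[[K@naType]]
    }
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    d <- pmax(e$values, lambdaC)
    out <- e$vectors %*% (d * t(e$vectors))
    out <- (out + t(out)) / 2
    if (isObj) .asStiffness(out, K@nBp, K@naType, TRUE, banded = FALSE) else out
}

#' Trim a stiffness matrix to the hexameric band
#'
#' Sets all entries outside the union of hexameric block slices to zero.
#' Positive definiteness is re-checked and reported via the returned
#' attribute `minEigenvalue`.
#'
#' @param K A `DuplexStiffness`.
#' @return A banded `DuplexStiffness`; `attr(, "minEigenvalue")` carries the
#'   smallest eigenvalue after trimming.
#' @export
trimToBand <- function(K) {
    stopifnot(is(K, "DuplexStiffness"))
    m <- K@mat
    m[!bandPattern(K@nBp)] <- 0
    out <- .asStiffness(m, K@nBp, K@naType, K@dimensionless, banded = TRUE)
    attr(out, "minEigenvalue") <- min(eigen((m + t(m)) / 2, symmetric = TRUE,
                                            only.values = TRUE)$values)
    out
}

#' Assemble, repair and trim the stiffness matrix of a sequence
#'
#' Convenience pipeline: [assembleStiffnessMatrix()], [nondimensionalize()],
#' [applyEigenvalueCutoff()], [redimensionalize()], and by default
#' [trimToBand()] (trimming after the cutoff slightly improves agreement with
#' validation data; disable with `trim = FALSE`).
#'
#' @param seq Sequence.
#' @param ps A `ParameterSet`.
#' @param lambdaC Cutoff; NULL for the na-type default.
#' @param trim Re-trim to the hexameric band after the repair.
#' @return A `DuplexStiffness` in mixed units.
#' @export
repairedStiffnessMatrix <- function(seq, ps, lambdaC = NULL, trim = TRUE) {
    K <- assembleStiffnessMatrix(seq, ps)
    Knd <- applyEigenvalueCutoff(nondimensionalize(K), lambdaC)
    K <- redimensionalize(Knd)
    if (trim) K <- trimToBand(K)
    K
}

#' Quadratic deformation energy
#'
#' E = 1/2 (w - what)^T K (w - what), in kcal/mol for a mixed-unit K with raw
#' coordinates (or a nondimensional pair).
#'
#' @param w Coordinate vector.
#' @param what Equilibrium coordinate vector.
#' @param K `DuplexStiffness` or matrix.
#' @return Energy in kcal/mol.
#' @examples
#' deformationEnergy(5, 0, matrix(0.05))  # 0.625
#' @export
deformationEnergy <- function(w, what, K) {
    m <- if (is(K, "DuplexStiffness")) K@mat else K
    d <- as.numeric(w) - as.numeric(what)
    if (length(d) != nrow(m)) stop("dimension mismatch between coordinates and K")
    as.numeric(0.5 * crossprod(d, m %*% d))
}

#' Effective stiffness of a constrained coordinate subset
#'
#' The stiffness governing a subset of coordinates when all remaining
#' coordinates relax to their energy-optimal values: the Schur complement
#' K_cc - K_cf K_ff^{-1} K_fc.
#'
#' @param K `DuplexStiffness` or SPD matrix.
#' @param constrained Indices of the constrained coordinates.
#' @return Reduced matrix over the constrained coordinates.
#' @examples
#' effectiveStiffnessForSubset(matrix(c(3, 1, 1, 2), 2), 1)  # 2.5
#' @export
effectiveStiffnessForSubset <- function(K, constrained) {
    m <- if (is(K, "DuplexStiffness")) K@mat else K
    constrained <- as.integer(constrained)
    if (!length(constrained)) stop("constrained subset must be non-empty")
    free <- setdiff(seq_len(nrow(m)), constrained)
    if (!length(free)) return(m[constrained, constrained, drop = FALSE])
    Kcc <- m[constrained, constrained, drop = FALSE]
    Kcf <- m[constrained, free, drop = FALSE]
    Kff <- m[free, free, drop = FALSE]
    sol <- tryCatch(solve(Kff, t(Kcf)),
                    error = function(e) stop("free-coordinate block is singular"))
    Kcc - Kcf %*% sol
}

## ---------------------------------------------------------------------------

setClass("DuplexModel",
    representation(sequence = "character", naType = "character",
                   profile = "ShapeProfile", what = "numeric",
                   K = "DuplexStiffness"))

setMethod("show", "DuplexModel", function(object) {
    cat(sprintf("DuplexModel (%s, %d bp)\n", object@naType,
                nchar(object@sequence)))
    show(object@profile)
    show(object@K)
})

#' Full shape + stiffness model of a duplex
#'
#' Combines the predicted shape profile (with sequence-averaged fill of the
#' uncovered three pairs at each end, so the equilibrium coordinate vector is
#' complete) and the repaired stiffness matrix into one object usable for
#' energies and ensemble sampling.
#'
#' @param seq Sequence (>= 7 bp).
#' @param ps A `ParameterSet`.
#' @param lambdaC Eigenvalue cutoff (NULL: na-type default).
#' @param trim Trim the repaired matrix to the hexameric band.
#' @return A `DuplexModel` with slots `profile`, `what` (equilibrium
#'   coordinate vector, length 12 nBp - 6) and `K`.
#' @export
buildDuplexModel <- function(seq, ps, lambdaC = NULL, trim = TRUE) {
    ds <- duplexSequence(seq, ps@naType)
    prof <- predictProfile(ds, ps, fillEnds = TRUE)
    n <- prof@nBp
    what <- numeric(coordinateVectorLength(n))
    for (p in seq_len(n)) what[pairIndices(p)] <- prof@pairCoords[p, ]
    for (st in seq_len(n - 1L)) what[stepIndices(st)] <- prof@stepCoords[st, ]
    K <- repairedStiffnessMatrix(ds, ps, lambdaC = lambdaC, trim = trim)
    new("DuplexModel", sequence = ds@seq, naType = ps@naType,
        profile = prof, what = what, K = K)
}

#' @describeIn buildDuplexModel equilibrium coordinate vector
#' @param model A `DuplexModel`.
#' @export
equilibriumCoordinates <- function(model) model@what

#' @describeIn buildDuplexModel the repaired stiffness matrix
#' @export
modelStiffness <- function(model) model@K
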