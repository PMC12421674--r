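## The per-hexamer parameter store: equilibrium coordinates, groove widths,
## per-coordinate stiffness constants and 66x66 stiffness blocks for all
## canonical hexamer classes. Only canonical classes are stored; records for
## their reverse complements are always derived through the core transforms.

.pairColNames <- function()
    paste0(rep(paste0("pair", 1:6), each = 6L), ".", rep(.PAIR_COORDS, 6L))
.stepColNames <- function()
    paste0(rep(paste0("step", 1:5), each = 6L), ".", rep(.STEP_COORDS, 5L))

setClass("ParameterSet",
    representation(
        naType = "character",
        hexamers = "character",       # canonical classes, sorted
        pairMeans = "matrix",         # nHex x 36
        stepMeans = "matrix",         # nHex x 30
        pairK = "matrix",
        stepK = "matrix",
        majorGroove = "numeric",
        majorGrooveK = "numeric",
        minorGroove = "matrix",       # nHex x 2 (pair3, pair4)
        minorGrooveK = "matrix",
        blocks = "list",              # named 66x66 matrices
        metadata = "list"
    ),
    validity = function(object) {
        n <- length(object@hexamers)
        if (nrow(object@pairMeans) != n || nrow(object@stepMeans) != n)
            return("coordinate tables must have one row per hexamer class")
        if (length(object@blocks) != n)
            return("one stiffness block per hexamer class required")
        TRUE
    })

setMethod("show", "ParameterSet", function(object) {
    cat(sprintf("ParameterSet (%s): %d canonical hexamer classes\n",
                object@naType, length(object@hexamers)))
    md <- object@metadata
    if (!is.null(md$source)) cat("  source:", md$source, "\n")
    if (!is.null(md$seed)) cat("  seed:", md$seed, "\n")
})

#' @describeIn generateSyntheticParameters canonical hexamer classes in the set
#' @export
hexamerClasses <- function(ps) ps@hexamers

#' Nucleic-acid type of an object
#'
#' @param x A `DuplexSequence`, `ParameterSet` or other object carrying an
#'   `naType` slot; plain characters are interpreted as sequences.
#' @return "DNA" or "RNA".
#' @export
naTypeOf <- function(x) {
    if (isVirtualClass(class(x)) || !isS4(x)) return(naType(x))
    if ("naType" %in% slotNames(class(x))) slot(x, "naType") else naType(x)
}

## internal: row index of the canonical class of `hex`, plus flip flag
.lookupHexamer <- function(ps, hex) {
    canon <- canonicalClass(hex, naType = ps@naType)
    r <- match(canon, ps@hexamers)
    if (is.na(r)) stop("hexamer class missing from parameter set: ", canon)
    list(row = r, flip = !identical(canon, hex))
}

#' Retrieve the parameter record of a hexamer
#'
#' Looks up the canonical class and, when the query is the reverse complement
#' of the stored representative, applies the complement transform so that the
#' returned record always describes the queried strand.
#'
#' @param ps A `ParameterSet`.
#' @param hex 6-letter sequence (character or `DuplexSequence`).
#' @return A [hexamerRecord()].
#' @export
getHexamerRecord <- function(ps, hex) {
    hex <- sequenceLetters(hex)
    lk <- .lookupHexamer(ps, hex)
    r <- lk$row
    rec <- hexamerRecord(
        sequence = ps@hexamers[r],
        pairCoords = matrix(ps@pairMeans[r, ], 6L, 6L, byrow = TRUE),
        stepCoords = matrix(ps@stepMeans[r, ], 5L, 6L, byrow = TRUE),
        majorGroove = ps@majorGroove[r],
        minorGroove = ps@minorGroove[r, ],
        pairK = matrix(ps@pairK[r, ], 6L, 6L, byrow = TRUE),
        stepK = matrix(ps@stepK[r, ], 5L, 6L, byrow = TRUE),
        majorGrooveK = ps@majorGrooveK[r],
        minorGrooveK = ps@minorGrooveK[r, ],
        block = ps@blocks[[r]],
        naType = ps@naType)
    if (lk$flip) complementHexamerRecord(rec) else rec
}

#' @describeIn getHexamerRecord the 66x66 stiffness block of a hexamer (with
#'   the complement transform applied when needed)
#' @export
getStiffnessBlock <- function(ps, hex) {
    hex <- sequenceLetters(hex)
    lk <- .lookupHexamer(ps, hex)
    b <- ps@blocks[[lk$row]]
    if (lk$flip) complementStiffnessBlock(b) else b
}

#' @describeIn getHexamerRecord heptamer record from its two overlapping
#'   hexamers
#' @param hept 7-letter sequence.
#' @export
getHeptamerRecord <- function(ps, hept) {
    hept <- sequenceLetters(hept)
    stopifnot(nchar(hept) == 7L)
    heptamerFromHexamers(getHexamerRecord(ps, substr(hept, 1L, 6L)),
                         getHexamerRecord(ps, substr(hept, 2L, 7L)))
}

#' Sequence-averaged structural parameters of a parameter set
#'
#' Means over all hexamer (step coordinates, major groove) and heptamer
#' (intra-basepair coordinates, minor groove) contexts, counting both a class
#' and its complement, which forces the odd coordinates to average to exactly
#' zero.
#'
#' @param ps A `ParameterSet`.
#' @return List with `pair`, `step` (named 6-vectors), `minorGroove`,
#'   `majorGroove`.
#' @export
sequenceAveragedParameters <- function(ps) {
    oddP <- c(1L, 4L)
    ## weight 2 for classes whose complement is distinct, 1 for
    ## self-complementary ones, so the average runs over all 4096 hexamers
    selfc <- vapply(ps@hexamers, isSelfComplementary, logical(1),
                    naType = ps@naType)
    w <- ifelse(selfc, 1, 2)
    wMean <- function(m) colSums(m * w) / sum(w)
    pair <- colMeans(matrix(wMean(ps@pairMeans), 6L, 6L, byrow = TRUE))
    step3 <- wMean(ps@stepMeans[, 12L + 1:6, drop = FALSE])  # central step
    stepAll <- colMeans(matrix(wMean(ps@stepMeans), 5L, 6L, byrow = TRUE))
    ## averaging over class + complement zeroes the odd coordinates
    pair[oddP] <- 0
    stepAll[oddP] <- 0
    step3[oddP] <- 0
    names(pair) <- .PAIR_COORDS
    names(stepAll) <- .STEP_COORDS
    names(step3) <- .STEP_COORDS
    list(pair = pair, step = stepAll, centralStep = step3,
         minorGroove = sum(w * rowMeans(ps@minorGroove)) / sum(w),
         majorGroove = sum(w * ps@majorGroove) / sum(w))
}

## ---------------------------------------------------------------------------
## anchor tables

#' Dinucleotide anchor table for the synthetic generator
#'
#' Equilibrium central-step coordinates (and their context variability) for
#' the ten canonical dinucleotides, used to anchor the synthetic parameter
#' generator. The DNA values are MD-derived dinucleotide means; the RNA table
#' is the DNA one shifted by the difference of the sequence-averaged step
#' coordinates between A-RNA and B-DNA helices, with odd coordinates and all
#' spreads scaled by the corresponding variability ratio.
#'
#' @param naType "DNA" or "RNA".
#' @return List of two 10x6 matrices `mean` and `sd` with dinucleotide row
#'   names and step-coordinate column names.
#' @export
dimerAnchorTable <- function(naType = c("DNA", "RNA")) {
    naType <- match.arg(naType)
    dimers <- c("CG", "CA", "TA", "AG", "GG", "AA", "GA", "AT", "AC", "GC")
    m <- rbind(
        CG = c( 0.00,  0.24, 3.33,  0.00,  6.16, 34.31),
        CA = c(-0.23,  0.15, 3.29, -0.11,  6.70, 33.13),
        TA = c( 0.00,  0.29, 3.25,  0.00,  5.26, 34.51),
        AG = c(-0.32, -0.37, 3.37, -2.70,  3.93, 33.46),
        GG = c(-0.20, -0.25, 3.45, -0.06,  4.85, 34.90),
        AA = c(-0.36, -0.06, 3.31, -2.27,  1.63, 35.99),
        GA = c(-0.45,  0.23, 3.32, -1.08,  2.22, 37.74),
        AT = c( 0.00, -0.71, 3.24,  0.00, -0.53, 30.70),
        AC = c( 0.19, -0.49, 3.29, -0.40,  0.22, 32.69),
        GC = c( 0.00, -0.28, 3.35,  0.00,  0.20, 36.60))
    s <- rbind(
        CG = c(0.20, 0.12, 0.12, 1.00, 1.04, 3.11),
        CA = c(0.20, 0.17, 0.12, 1.13, 0.98, 3.28),
        TA = c(0.20, 0.17, 0.10, 1.00, 0.87, 2.46),
        AG = c(0.19, 0.21, 0.09, 0.62, 1.09, 1.83),
        GG = c(0.24, 0.31, 0.10, 1.08, 0.76, 1.65),
        AA = c(0.19, 0.16, 0.05, 0.54, 0.80, 1.44),
        GA = c(0.17, 0.17, 0.06, 0.95, 0.75, 1.81),
        AT = c(0.20, 0.06, 0.05, 1.00, 0.71, 1.36),
        AC = c(0.17, 0.13, 0.08, 0.77, 0.58, 1.88),
        GC = c(0.20, 0.17, 0.08, 1.00, 0.39, 1.80))
    colnames(m) <- colnames(s) <- .STEP_COORDS
    if (naType == "RNA") {
        ## sequence-averaged A-RNA minus B-DNA step means and sd ratios
        shiftBy <- c(shift = 0, slide = -1.51, rise = -0.03,
                     tilt = 0, roll = 5.69, twist = -4.41)
        oddScale <- c(shift = 0.09 / 0.33, slide = 1, rise = 1,
                      tilt = 0.72 / 1.61, roll = 1, twist = 1)
        sdScale <- c(shift = 0.09 / 0.33, slide = 0.14 / 0.36, rise = 1,
                     tilt = 0.72 / 1.61, roll = 2.95 / 2.53, twist = 1.01 / 2.84)
        m <- sweep(m, 2L, oddScale, `*`)
        m <- sweep(m, 2L, shiftBy, `+`)
        s <- sweep(s, 2L, sdScale, `*`)
        rownames(m) <- rownames(s) <- chartr("T", "U", dimers)
    }
    list(mean = m, sd = s)
}

## Table-1-style sequence-averaged intra-basepair and groove anchors
.pairAnchors <- function(naType) {
    if (naType == "DNA") {
        list(mean = c(0, -0.02, 0.03, 0, -11.03, 0.24),
             sd = c(0.12, 0.04, 0.10, 5.86, 3.70, 0.84),
             minor = c(12.04, 0.89), major = c(18.36, 0.61))
    } else {
        list(mean = c(0, -0.02, -0.07, 0, -12.61, 0.28),
             sd = c(0.12, 0.05, 0.10, 4.79, 1.75, 0.83),
             minor = c(17.11, 0.22), major = c(18.11, 0.31))
    }
}

## baseline per-coordinate stiffness constants (kcal/mol/A^2 or /deg^2)
.stiffnessBaselines <- function() {
    list(pair = c(shear = 4, stretch = 25, stagger = 4,
                  buckle = 0.008, propeller = 0.018, opening = 0.09),
         step = c(shift = 1.8, slide = 3.0, rise = 7.5,
                  tilt = 0.04, roll = 0.025, twist = 0.055),
         minor = 0.35, major = 0.22)
}

## parity transforms on flattened 36/30-vectors (reverse groups, negate odd)
.flipPair36 <- function(v, negate = TRUE) {
    m <- matrix(v, 6L, 6L, byrow = TRUE)[6:1, , drop = FALSE]
    if (negate) m[, c(1L, 4L)] <- -m[, c(1L, 4L)]
    as.vector(t(m))
}
.flipStep30 <- function(v, negate = TRUE) {
    m <- matrix(v, 5L, 6L, byrow = TRUE)[5:1, , drop = FALSE]
    if (negate) m[, c(1L, 4L)] <- -m[, c(1L, 4L)]
    as.vector(t(m))
}

#' Generate a complete synthetic parameter set
#'
#' Produces a schema-complete `ParameterSet` covering all 2080 canonical
#' hexamer classes without any external data. Central-step means are anchored
#' to dinucleotide equilibrium values plus a bounded, hexamer-specific context
#' perturbation at the printed variability scale; intra-basepair coordinates
#' and groove widths are anchored to sequence-averaged helix values; stiffness
#' blocks are built symmetric positive definite with a banded correlation
#' structure and physically sensible diagonal magnitudes. Records for
#' self-complementary hexamers are exactly symmetrized (odd central-step
#' coordinates are literal zeros); complements are never drawn independently.
#' The output is deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param naType "DNA" or "RNA".
#' @param dimerAnchors Optional anchor table as returned by
#'   [dimerAnchorTable()].
#' @return A `ParameterSet`.
#' @examples
#' \donttest{ps <- generateSyntheticParameters(1)}
#' @export
generateSyntheticParameters <- function(seed = 1L, naType = c("DNA", "RNA"),
                                        dimerAnchors = NULL) {
    naType <- match.arg(naType)
    if (is.null(dimerAnchors)) dimerAnchors <- dimerAnchorTable(naType)
    set.seed(as.integer(seed))
    hexes <- allCanonicalKmers(6L, naType)
    nHex <- length(hexes)
    pa <- .pairAnchors(naType)
    kb <- .stiffnessBaselines()

    anchorsM <- dimerAnchors$mean
    anchorsS <- dimerAnchors$sd
    ## orientations of all 16 dimers in terms of the 10 canonical rows
    alpha <- if (naType == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
    dimAll <- as.vector(outer(alpha, alpha, function(a, b) paste0(a, b)))
    anchorFor <- function(d) {
        if (d %in% rownames(anchorsM))
            return(list(mean = anchorsM[d, ], sd = anchorsS[d, ]))
        rc <- reverseComplement(d, naType)
        if (!rc %in% rownames(anchorsM))
            stop("anchor table covers neither ", d, " nor ", rc)
        m <- anchorsM[rc, ]
        m[c(1L, 4L)] <- -m[c(1L, 4L)]   # odd coordinates flip
        list(mean = m, sd = anchorsS[rc, ])
    }
    dimerCache <- lapply(dimAll, anchorFor)
    names(dimerCache) <- dimAll

    trunc2 <- function(n) pmax(pmin(stats::rnorm(n), 2), -2)

    pairMeans <- matrix(0, nHex, 36L, dimnames = list(hexes, .pairColNames()))
    stepMeans <- matrix(0, nHex, 30L, dimnames = list(hexes, .stepColNames()))
    pairK <- pairMeans
    stepK <- stepMeans
    majorGroove <- numeric(nHex)
    majorGrooveK <- numeric(nHex)
    minorGroove <- matrix(0, nHex, 2L, dimnames = list(hexes, c("pair3", "pair4")))
    minorGrooveK <- minorGroove
    blocks <- vector("list", nHex)
    names(blocks) <- hexes

    ## diagonal scale of the 66x66 block (constrained stiffnesses exceed the
    ## marginal per-coordinate constants by roughly this factor)
    diagBase <- rep(c(kb$pair, kb$step), length.out = 66L) * 2.5
    bandIdx <- which(row(diag(66)) > col(diag(66)) &
                     row(diag(66)) - col(diag(66)) <= 12L)
    bandDecay <- exp(-(row(diag(66)) - col(diag(66)))[bandIdx] / 8)

    for (r in seq_len(nHex)) {
        hex <- hexes[r]
        ## step coordinates: dimer anchor + bounded context perturbation
        sm <- matrix(0, 5L, 6L)
        for (s in 1:5) {
            an <- dimerCache[[substr(hex, s, s + 1L)]]
            sm[s, ] <- an$mean + an$sd * trunc2(6L)
        }
        pm <- matrix(rep(pa$mean, each = 6L), 6L, 6L) +
            matrix(rep(pa$sd, each = 6L), 6L, 6L) * trunc2(36L)
        majorGroove[r] <- pa$major[1] + pa$major[2] * trunc2(1L)
        minorGroove[r, ] <- pa$minor[1] + pa$minor[2] * trunc2(2L)
        ## per-coordinate stiffness constants: lognormal context variability
        pairK[r, ] <- rep(kb$pair, 6L) * exp(0.2 * trunc2(36L))
        stepK[r, ] <- rep(kb$step, 5L) * exp(0.2 * trunc2(30L))
        majorGrooveK[r] <- kb$major * exp(0.2 * trunc2(1L))
        minorGrooveK[r, ] <- kb$minor * exp(0.2 * trunc2(2L))

        ## SPD block: banded unit-diagonal factor -> correlation -> scale
        L <- diag(66)
        L[bandIdx] <- 0.12 * bandDecay * stats::rnorm(length(bandIdx))
        C <- tcrossprod(L)
        dC <- 1 / sqrt(diag(C))
        C <- C * tcrossprod(dC)
        d <- diagBase * exp(0.15 * trunc2(66L))
        B <- C * tcrossprod(sqrt(d))
        B <- (B + t(B)) / 2

        if (isSelfComplementary(hex, naType)) {
            pmv <- as.vector(t(pm)); smv <- as.vector(t(sm))
            pmv <- (pmv + .flipPair36(pmv)) / 2
            smv <- (smv + .flipStep30(smv)) / 2
            pm <- matrix(pmv, 6L, 6L, byrow = TRUE)
            sm <- matrix(smv, 5L, 6L, byrow = TRUE)
            minorGroove[r, ] <- mean(minorGroove[r, ])
            pairK[r, ] <- (pairK[r, ] + .flipPair36(pairK[r, ], negate = FALSE)) / 2
            stepK[r, ] <- (stepK[r, ] + .flipStep30(stepK[r, ], negate = FALSE)) / 2
            minorGrooveK[r, ] <- mean(minorGrooveK[r, ])
            B <- (B + complementStiffnessBlock(B)) / 2
        }
        pairMeans[r, ] <- as.vector(t(pm))
        stepMeans[r, ] <- as.vector(t(sm))
        blocks[[r]] <- B
    }
    new("ParameterSet", naType = naType, hexamers = hexes,
        pairMeans = pairMeans, stepMeans = stepMeans,
        pairK = pairK, stepK = stepK,
        majorGroove = majorGroove, majorGrooveK = majorGrooveK,
        minorGroove = minorGroove, minorGrooveK = minorGrooveK,
        blocks = blocks,
        metadata = list(source = "synthetic", seed = as.integer(seed),
                        naType = naType))
}

#' Validate a parameter set
#'
#' Checks completeness (all canonical hexamer classes present), symmetry and
#' positive definiteness of every stiffness block, positivity of stiffness
#' constants and groove widths, and the exact symmetry rules for
#' self-complementary hexamers (zero odd central-step coordinates; stiffness
#' block invariant under the complement transform).
#'
#' @param ps A `ParameterSet`.
#' @param tol Numeric tolerance for the symmetry checks.
#' @return A list with `pass` (logical) and `issues` (character vector of
#'   human-readable findings, empty when the set is valid).
#' @export
validateParameterSet <- function(ps, tol = 1e-8) {
    issues <- character(0)
    expected <- allCanonicalKmers(6L, ps@naType)
    missing <- setdiff(expected, ps@hexamers)
    if (length(missing))
        issues <- c(issues, sprintf("missing %d hexamer class(es), e.g. %s",
                                    length(missing),
                                    paste(utils::head(missing, 5), collapse = ", ")))
    extra <- setdiff(ps@hexamers, expected)
    if (length(extra))
        issues <- c(issues, sprintf("non-canonical keys present: %s",
                                    paste(utils::head(extra, 5), collapse = ", ")))
    if (any(!is.finite(ps@pairMeans)) || any(!is.finite(ps@stepMeans)))
        issues <- c(issues, "non-finite coordinate means")
    if (any(ps@pairK <= 0) || any(ps@stepK <= 0) ||
        any(ps@majorGrooveK <= 0) || any(ps@minorGrooveK <= 0))
        issues <- c(issues, "non-positive stiffness constants")
    if (any(ps@majorGroove <= 0) || any(ps@minorGroove <= 0))
        issues <- c(issues, "non-positive groove widths")
    centralOdd <- c(12L + 1L, 12L + 4L)   # step3 shift, tilt in the 30-vector
    for (r in seq_along(ps@hexamers)) {
        hex <- ps@hexamers[r]
        B <- ps@blocks[[r]]
        if (max(abs(B - t(B))) > tol) {
            issues <- c(issues, sprintf("%s: stiffness block not symmetric", hex))
            next
        }
        ev <- tryCatch({ chol(B); TRUE }, error = function(e) FALSE)
        if (!ev) {
            mn <- min(eigen((B + t(B)) / 2, symmetric = TRUE,
                            only.values = TRUE)$values)
            issues <- c(issues,
                        sprintf("%s: block not positive definite (min eigenvalue %.3g)",
                                hex, mn))
        }
        if (isSelfComplementary(hex, ps@naType)) {
            if (any(ps@stepMeans[r, centralOdd] != 0))
                issues <- c(issues,
                            sprintf("%s: self-complementary but odd central-step coordinates not zero", hex))
            if (max(abs(B - complementStiffnessBlock(B))) > tol)
                issues <- c(issues,
                            sprintf("%s: self-complementary block not complement-invariant", hex))
        }
    }
    list(pass = length(issues) == 0L, issues = issues)
}
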