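## Per-context parameter records and their transformation under
## complementation (reference-strand flip).

setClass("HexamerRecord",
    representation(
        sequence = "character",       # 6 letters
        naType = "character",
        pairCoords = "matrix",        # 6 pairs x 6 coords
        stepCoords = "matrix",        # 5 steps x 6 coords
        majorGroove = "numeric",      # width at the central step (Angstrom)
        minorGroove = "numeric",      # widths at pairs 3 and 4 (the hexamer's
                                      # two pentamer centres)
        pairK = "matrix",             # per-coordinate stiffness, same layout
        stepK = "matrix",
        majorGrooveK = "numeric",
        minorGrooveK = "numeric",
        block = "matrix"              # 66 x 66 symmetric stiffness block
    ),
    validity = function(object) {
        if (nchar(object@sequence) != 6L) return("sequence must have 6 letters")
        if (!all(dim(object@pairCoords) == c(6L, 6L))) return("pairCoords must be 6x6")
        if (!all(dim(object@stepCoords) == c(5L, 6L))) return("stepCoords must be 5x6")
        if (length(object@minorGroove) != 2L) return("minorGroove must hold pairs 3 and 4")
        if (!all(dim(object@block) == c(66L, 66L))) return("block must be 66x66")
        if (max(abs(object@block - t(object@block))) > 1e-8)
            return("stiffness block must be symmetric")
        TRUE
    })

setClass("HeptamerRecord",
    representation(
        sequence = "character",       # 7 letters
        naType = "character",
        centralPair = "numeric",      # 6 intra-basepair coordinates of pair 4
        minorGroove = "numeric",      # width at the central pair
        pairK = "numeric",
        minorGrooveK = "numeric"
    ),
    validity = function(object) {
        if (nchar(object@sequence) != 7L) return("sequence must have 7 letters")
        if (length(object@centralPair) != 6L) return("centralPair must have 6 values")
        TRUE
    })

#' Construct a hexamer parameter record
#'
#' Holds the equilibrium coordinates of the six pairs and five steps of a
#' hexameric context, its groove widths, per-coordinate stiffness constants,
#' and the 66x66 symmetric stiffness block (coordinates ordered first pair,
#' first step, second pair, ..., last pair).
#'
#' @param sequence 6-letter sequence.
#' @param pairCoords 6x6 matrix (rows pairs 1..6, columns
#'   shear..opening).
#' @param stepCoords 5x6 matrix (rows steps 1..5, columns shift..twist).
#' @param majorGroove Major groove width at the central step (Angstrom).
#' @param minorGroove Widths at pairs 3 and 4 (length-2, Angstrom).
#' @param pairK,stepK Per-coordinate stiffness constants, same layout as the
#'   coordinate matrices.
#' @param majorGrooveK,minorGrooveK Groove stiffness constants.
#' @param block 66x66 symmetric stiffness block.
#' @param naType "DNA" or "RNA".
#' @return A `HexamerRecord`.
#' @export
hexamerRecord <- function(sequence, pairCoords, stepCoords, majorGroove,
                          minorGroove, pairK, stepK, majorGrooveK,
                          minorGrooveK, block, naType = NULL) {
    ds <- duplexSequence(sequence, naType)
    dimnames(pairCoords) <- list(paste0("pair", 1:6), .PAIR_COORDS)
    dimnames(stepCoords) <- list(paste0("step", 1:5), .STEP_COORDS)
    dimnames(pairK) <- dimnames(pairCoords)
    dimnames(stepK) <- dimnames(stepCoords)
    names(minorGroove) <- names(minorGrooveK) <- c("pair3", "pair4")
    new("HexamerRecord", sequence = ds@seq, naType = ds@naType,
        pairCoords = pairCoords, stepCoords = stepCoords,
        majorGroove = unname(majorGroove), minorGroove = minorGroove,
        pairK = pairK, stepK = stepK, majorGrooveK = unname(majorGrooveK),
        minorGrooveK = minorGrooveK, block = block)
}

setMethod("show", "HexamerRecord", function(object) {
    cat(sprintf("HexamerRecord %s (%s)\n", object@sequence, object@naType))
    cat("  central step:",
        paste(sprintf("%s=%.2f", .STEP_COORDS, object@stepCoords[3, ]),
              collapse = " "), "\n")
    cat(sprintf("  major groove %.2f A, minor grooves %.2f / %.2f A\n",
                object@majorGroove, object@minorGroove[1], object@minorGroove[2]))
})

setMethod("show", "HeptamerRecord", function(object) {
    cat(sprintf("HeptamerRecord %s (%s)\n", object@sequence, object@naType))
    cat("  central pair:",
        paste(sprintf("%s=%.2f", .PAIR_COORDS, object@centralPair),
              collapse = " "), "\n")
    cat(sprintf("  minor groove %.2f A\n", object@minorGroove))
})

## signed permutation implementing the complement transform on a 66-vector:
## group g (1..11, alternating pair/step) maps to group 12-g; within each
## sextet the odd coordinates (offsets 1 and 4) change sign
.blockPermutation <- function() {
    g <- rep(1:11, each = 6L)
    off <- rep(1:6, times = 11L)
    perm <- (12L - g - 1L) * 6L + off
    sign <- ifelse(off %in% c(1L, 4L), -1, 1)
    list(perm = perm, sign = sign)
}

#' Complement transform of a 66x66 stiffness block
#'
#' Rearranges a hexameric stiffness block to describe the reverse-complement
#' hexamer: pair i becomes pair 7-i, step i becomes step 6-i, and entries
#' coupling an odd with an even coordinate change sign. The transform is a
#' signed permutation (orthogonal), so symmetry and the eigenvalue spectrum
#' are preserved, and applying it twice returns the original block.
#'
#' @param block 66x66 symmetric matrix.
#' @return The transformed 66x66 symmetric matrix.
#' @examples
#' complementStiffnessBlock(diag(66))[1, 1]
#' @export
complementStiffnessBlock <- function(block) {
    stopifnot(all(dim(block) == c(66L, 66L)))
    if (max(abs(block - t(block))) > 1e-8)
        stop("stiffness block must be symmetric")
    bp <- .blockPermutation()
    out <- block[bp$perm, bp$perm] * tcrossprod(bp$sign)
    dimnames(out) <- NULL
    out
}

#' Complement transform of a hexamer record
#'
#' Produces the parameter record of the reverse-complement hexamer: the pair
#' order is reversed (pair i -> pair 7-i), the step order is reversed
#' (step i -> step 6-i), odd coordinates (shear, buckle, shift, tilt) change
#' sign, even coordinates and groove widths are unchanged, and the stiffness
#' constants - even quantities - are only re-indexed. The stiffness block is
#' transformed with [complementStiffnessBlock()]. For a self-complementary
#' hexamer the odd coordinates of the central step are forced to exactly zero.
#'
#' @param rec A `HexamerRecord`.
#' @return The complementary `HexamerRecord`.
#' @export
complementHexamerRecord <- function(rec) {
    stopifnot(is(rec, "HexamerRecord"))
    oddPair <- c(1L, 4L)   # shear, buckle
    oddStep <- c(1L, 4L)   # shift, tilt
    pc <- rec@pairCoords[6:1, , drop = FALSE]
    pc[, oddPair] <- -pc[, oddPair]
    sc <- rec@stepCoords[5:1, , drop = FALSE]
    sc[, oddStep] <- -sc[, oddStep]
    selfc <- isSelfComplementary(rec@sequence, rec@naType)
    if (selfc) sc[3L, oddStep] <- 0
    hexamerRecord(
        sequence = reverseComplement(rec@sequence, rec@naType),
        pairCoords = pc, stepCoords = sc,
        majorGroove = rec@majorGroove,
        minorGroove = rev(rec@minorGroove),
        pairK = rec@pairK[6:1, , drop = FALSE],
        stepK = rec@stepK[5:1, , drop = FALSE],
        majorGrooveK = rec@majorGrooveK,
        minorGrooveK = rev(rec@minorGrooveK),
        block = complementStiffnessBlock(rec@block),
        naType = rec@naType)
}

#' Complement transform of a heptamer record
#'
#' Odd central-pair coordinates (shear, buckle) change sign; the minor groove
#' width and the stiffness constants are even and unchanged. Self-complementary
#' heptamers get exactly-zero odd central coordinates.
#'
#' @param rec A `HeptamerRecord`.
#' @return The complementary `HeptamerRecord`.
#' @export
complementHeptamerRecord <- function(rec) {
    stopifnot(is(rec, "HeptamerRecord"))
    cp <- rec@centralPair
    cp[c(1L, 4L)] <- -cp[c(1L, 4L)]
    if (isSelfComplementary(rec@sequence, rec@naType)) cp[c(1L, 4L)] <- 0
    new("HeptamerRecord",
        sequence = reverseComplement(rec@sequence, rec@naType),
        naType = rec@naType, centralPair = cp,
        minorGroove = rec@minorGroove, pairK = rec@pairK,
        minorGrooveK = rec@minorGrooveK)
}

#' Heptamer parameters from two overlapping hexamers
#'
#' A heptamer consists of two hexamers overlapping in five letters; the
#' parameters of its central pair are the arithmetic means of the values
#' stored in the two hexamers (4th pair of the first, 3rd pair of the
#' second), and likewise for the minor groove width and the stiffness
#' constants.
#'
#' @param recA,recB `HexamerRecord`s with `recA` sequence positions 2..6 equal
#'   to `recB` positions 1..5.
#' @return A `HeptamerRecord` for the combined 7-letter sequence.
#' @examples
#' ## heptamer CATGACT = hexamers CATGAC + ATGACT
#' @export
heptamerFromHexamers <- function(recA, recB) {
    stopifnot(is(recA, "HexamerRecord"), is(recB, "HexamerRecord"))
    if (substr(recA@sequence, 2L, 6L) != substr(recB@sequence, 1L, 5L))
        stop("hexamers do not overlap in 5 letters: ",
             recA@sequence, " / ", recB@sequence)
    sequence <- paste0(recA@sequence, substr(recB@sequence, 6L, 6L))
    cp <- (recA@pairCoords[4L, ] + recB@pairCoords[3L, ]) / 2
    if (isSelfComplementary(sequence, recA@naType)) cp[c(1L, 4L)] <- 0
    new("HeptamerRecord",
        sequence = sequence, naType = recA@naType,
        centralPair = cp,
        minorGroove = unname((recA@minorGroove["pair4"] +
                              recB@minorGroove["pair3"]) / 2),
        pairK = (recA@pairK[4L, ] + recB@pairK[3L, ]) / 2,
        minorGrooveK = unname((recA@minorGrooveK["pair4"] +
                               recB@minorGrooveK["pair3"]) / 2))
}
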