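## Rigid-base coordinate conventions: names, parity, units, and the indexing
## of the per-duplex coordinate vector (pair1, step1, pair2, ..., pairN).

.PAIR_COORDS <- c("shear", "stretch", "stagger", "buckle", "propeller", "opening")
.STEP_COORDS <- c("shift", "slide", "rise", "tilt", "roll", "twist")
.HELICAL_COORDS <- c("X-disp", "Y-disp", "h-rise", "inclination", "tip", "h-twist")
.GROOVE_COORDS <- c("minor-groove", "major-groove")

## odd coordinates flip sign when the reference strand is changed
.ODD_COORDS <- c("shear", "buckle", "shift", "tilt", "Y-disp", "tip")

## within each 6-coordinate group the first three are translations (Angstrom),
## the last three rotations (degrees); grooves are distances (Angstrom)
.COORD_UNIT <- c(
    shear = "A", stretch = "A", stagger = "A",
    buckle = "deg", propeller = "deg", opening = "deg",
    shift = "A", slide = "A", rise = "A",
    tilt = "deg", roll = "deg", twist = "deg",
    `X-disp` = "A", `Y-disp` = "A", `h-rise` = "A",
    inclination = "deg", tip = "deg", `h-twist` = "deg",
    `minor-groove` = "A", `major-groove` = "A"
)

#' The rigid-base coordinate catalog
#'
#' The 18 named rigid-base coordinates (6 intra-basepair, 6 step, 6 helical)
#' plus the two groove widths, with their group, parity under reference-strand
#' change, and unit class. The ordering within the pair and step groups is
#' fixed and shared by all stiffness blocks and coordinate vectors.
#'
#' @return A data.frame with columns `name`, `group` (pair/step/helical/groove),
#'   `parity` (odd/even) and `unit` ("A" or "deg").
#' @examples
#' coordinateCatalog()
#' @export
coordinateCatalog <- function() {
    name <- c(.PAIR_COORDS, .STEP_COORDS, .HELICAL_COORDS, .GROOVE_COORDS)
    group <- rep(c("pair", "step", "helical", "groove"), c(6L, 6L, 6L, 2L))
    data.frame(
        name = name,
        group = group,
        parity = ifelse(name %in% .ODD_COORDS, "odd", "even"),
        unit = unname(.COORD_UNIT[name]),
        stringsAsFactors = FALSE
    )
}

#' Parity of a coordinate under reference-strand change
#'
#' Odd coordinates (shear, buckle, shift, tilt, Y-disp, tip) change sign when
#' the reading strand is flipped; all others, including the groove widths and
#' all stiffness constants, are even.
#'
#' @param name Coordinate name(s) from [coordinateCatalog()].
#' @return Character vector, "odd" or "even".
#' @examples
#' parity("shift")
#' parity(c("buckle", "rise"))
#' @export
parity <- function(name) {
    cat <- coordinateCatalog()
    bad <- setdiff(name, cat$name)
    if (length(bad))
        stop("unknown coordinate name(s): ", paste(bad, collapse = ", "))
    ifelse(name %in% .ODD_COORDS, "odd", "even")
}

#' Length of the duplex coordinate vector
#'
#' A duplex of `nBp` base pairs has `nBp` intra-basepair sextets interleaved
#' with `nBp - 1` step sextets: 12 nBp - 6 coordinates, ordered pair 1,
#' step 1, pair 2, ..., pair nBp.
#'
#' @param nBp Number of base pairs.
#' @return Integer vector length.
#' @examples
#' coordinateVectorLength(25)
#' @export
coordinateVectorLength <- function(nBp) {
    stopifnot(nBp >= 1)
    as.integer(12 * nBp - 6)
}

#' Index into the duplex coordinate vector
#'
#' Maps a (position, coordinate) pair to its 1-based index in the coordinate
#' vector of a duplex. Pairs occupy positions 1..nBp, steps 1..nBp-1.
#'
#' @param nBp Number of base pairs.
#' @param position 1-based pair or step index.
#' @param coordinate Coordinate name (determines pair vs step group), or an
#'   integer 1..6 combined with `type`.
#' @param type "pair" or "step"; inferred from `coordinate` when it is a name.
#' @return 1-based integer index.
#' @examples
#' vectorIndex(25, 1, "shear")       # 1
#' vectorIndex(25, 1, "shift")       # 7
#' vectorIndex(25, 25, "opening")    # 294
#' @export
vectorIndex <- function(nBp, position, coordinate, type = NULL) {
    if (is.character(coordinate)) {
        if (coordinate %in% .PAIR_COORDS) {
            type <- "pair"
            offset <- match(coordinate, .PAIR_COORDS)
        } else if (coordinate %in% .STEP_COORDS) {
            type <- "step"
            offset <- match(coordinate, .STEP_COORDS)
        } else {
            stop("coordinate must be an intra-basepair or step coordinate name")
        }
    } else {
        stopifnot(!is.null(type), coordinate %in% 1:6)
        type <- match.arg(type, c("pair", "step"))
        offset <- as.integer(coordinate)
    }
    maxPos <- if (type == "pair") nBp else nBp - 1L
    if (position < 1 || position > maxPos)
        stop(sprintf("%s position %d out of range 1..%d", type, position, maxPos))
    base <- if (type == "pair") 12L * (position - 1L) else 12L * (position - 1L) + 6L
    as.integer(base + offset)
}

#' Coordinate-vector indices of a hexameric block
#'
#' The 66 consecutive coordinates (6 pairs, 5 steps) of the hexamer starting
#' at base pair `start`. Adjacent blocks overlap in exactly 54 indices
#' (5 pairs + 4 steps).
#'
#' @param start 1-based first base pair of the hexamer.
#' @param nBp Total number of base pairs (for range checking); optional.
#' @return Integer vector of 66 indices.
#' @examples
#' length(blockSlice(1))
#' length(intersect(blockSlice(1), blockSlice(2)))
#' @export
blockSlice <- function(start, nBp = NULL) {
    stopifnot(start >= 1)
    if (!is.null(nBp) && start + 5L > nBp)
        stop("hexamer starting at ", start, " does not fit in ", nBp, " bp")
    (12L * (start - 1L) + 1L):(12L * (start - 1L) + 66L)
}

## labels ("pair3.buckle", "step2.twist", ...) for a coordinate vector
coordinateLabels <- function(nBp) {
    labs <- character(coordinateVectorLength(nBp))
    for (p in seq_len(nBp))
        labs[12L * (p - 1L) + 1:6] <- paste0("pair", p, ".", .PAIR_COORDS)
    for (s in seq_len(nBp - 1L))
        labs[12L * (s - 1L) + 7:12] <- paste0("step", s, ".", .STEP_COORDS)
    labs
}

## nondimensionalization scales for a duplex coordinate vector:
## 1 (Angstrom) for translations, angleScale (deg) for rotations
coordinateScales <- function(nBp, angleScale = physicalConstants()$angleScale) {
    n <- coordinateVectorLength(nBp)
    grp <- rep(c(1, 1, 1, angleScale, angleScale, angleScale),
               length.out = n)
    grp
}

## TRUE where the coordinate is odd, over a duplex coordinate vector
coordinateOddMask <- function(nBp) {
    ## within both pair and step sextets the odd coordinates sit at
    ## offsets 1 (shear/shift) and 4 (buckle/tilt)
    n <- coordinateVectorLength(nBp)
    rep(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE), length.out = n)
}

## indices of step `s` (1-based) coordinates in the duplex vector
stepIndices <- function(s) 12L * (s - 1L) + 7:12

## indices of pair `p` coordinates
pairIndices <- function(p) 12L * (p - 1L) + 1:6
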