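#' Physical constants and model defaults
#'
#' Returns the constants used throughout the package: the Boltzmann constant
#' in kcal/mol/K, the reference temperature, their product \eqn{k_B T}, the
#' nondimensionalization scales (1 Angstrom for translations, 11 degrees for
#' rotations), the default eigenvalue cutoffs for repairing assembled
#' stiffness matrices (applied on the nondimensionalized matrix), and the
#' conversion factor from kcal/(mol Angstrom) to piconewtons.
#'
#' @return A named list with elements `kB` (kcal/mol/K), `temperature` (K),
#'   `kBT` (kcal/mol), `kBT_pN_A` (pN Angstrom), `lengthScale` (Angstrom),
#'   `angleScale` (degrees), `lambdaC` (named vector, DNA and RNA defaults),
#'   and `pN_per_kcal_mol_A`.
#' @examples
#' physicalConstants()$kBT
#' @export
physicalConstants <- function() {
    kB <- 1.987204e-3
    temperature <- 300
    pN <- 69.479
    list(
        kB = kB,
        temperature = temperature,
        kBT = kB * temperature,
        pN_per_kcal_mol_A = pN,
        kBT_pN_A = kB * temperature * pN,
        lengthScale = 1,
        angleScale = 11,
        lambdaC = c(DNA = 0.48, RNA = 0.44)
    )
}

#' Twist density of a helix from its pitch
#'
#' The twist density (degrees of rotation per Angstrom of axial rise) is
#' 360 divided by the helical pitch. The pitch can be given directly or as
#' base pairs per turn times the inter-basepair distance. The B-DNA value
#' (10.5 bp/turn, 3.23 Angstrom) gives about 10.6 deg/A; an A-RNA pitch of
#' 32 Angstrom gives about 11.3 deg/A. These motivate the common 11-degree
#' angle scale used for nondimensionalization.
#'
#' @param pitch Helical pitch in Angstrom. Either supply `pitch`, or both
#'   `bpPerTurn` and `rise`.
#' @param bpPerTurn Base pairs per helical turn.
#' @param rise Inter-basepair distance along the axis (Angstrom).
#' @return Twist density in degrees per Angstrom.
#' @examples
#' twistDensity(bpPerTurn = 10.5, rise = 3.23)
#' twistDensity(pitch = 32)
#' @export
twistDensity <- function(pitch = NULL, bpPerTurn = NULL, rise = NULL) {
    if (is.null(pitch)) {
        if (is.null(bpPerTurn) || is.null(rise))
            stop("supply 'pitch' or both 'bpPerTurn' and 'rise'")
        pitch <- bpPerTurn * rise
    }
    stopifnot(pitch > 0)
    360 / pitch
}

#' Helical repeat from a twist angle
#'
#' Converts a mean twist per step (degrees) into the helical repeat in base
#' pairs per turn, `360 / twist`.
#'
#' @param twistDeg Mean twist per base-pair step in degrees.
#' @return Helical repeat in bp/turn.
#' @examples
#' helicalRepeat(34.49)
#' @export
helicalRepeat <- function(twistDeg) {
    stopifnot(all(twistDeg > 0))
    360 / twistDeg
}
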