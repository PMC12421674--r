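## Duplex sequence algebra: alphabet checks, reverse complement, canonical
## reverse-complement classes. DNA uses ACGT, RNA uses ACGU; the reading
## strand is the strand whose 5'->3' order matches the input string.

#' @importClassesFrom Biostrings DNAString RNAString
#' @import methods
NULL

setClass("DuplexSequence",
    representation(seq = "character", naType = "character"),
    validity = function(object) {
        if (length(object@seq) != 1L || nchar(object@seq) < 1L)
            return("sequence must be a single non-empty string")
        if (!object@naType %in% c("DNA", "RNA"))
            return("naType must be 'DNA' or 'RNA'")
        alpha <- if (object@naType == "DNA") "ACGT" else "ACGU"
        if (grepl(sprintf("[^%s]", alpha), object@seq))
            return(sprintf("invalid letters for %s (alphabet %s)",
                           object@naType, alpha))
        TRUE
    })

#' Construct a duplex sequence
#'
#' A validated double-helix sequence: the given strand read 5' to 3', over
#' ACGT (DNA) or ACGU (RNA). If `naType` is missing it is inferred from the
#' presence of U/T (defaulting to DNA when ambiguous).
#'
#' @param seq Character string (case-insensitive).
#' @param naType "DNA" or "RNA".
#' @return A `DuplexSequence` object.
#' @examples
#' duplexSequence("CATGAC")
#' duplexSequence("ACGU")
#' @export
duplexSequence <- function(seq, naType = NULL) {
    if (is(seq, "DuplexSequence")) return(seq)
    seq <- toupper(as.character(seq))
    if (is.null(naType))
        naType <- if (grepl("U", seq, fixed = TRUE)) "RNA" else "DNA"
    new("DuplexSequence", seq = seq, naType = naType)
}

#' @describeIn duplexSequence the plain character sequence
#' @param x A `DuplexSequence`.
#' @export
sequenceLetters <- function(x) {
    if (is(x, "DuplexSequence")) x@seq else toupper(as.character(x))
}

#' @describeIn duplexSequence the nucleic-acid type ("DNA" or "RNA")
#' @export
naType <- function(x) {
    if (is(x, "DuplexSequence")) x@naType
    else duplexSequence(x)@naType
}

setMethod("show", "DuplexSequence", function(object) {
    s <- object@seq
    disp <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
    cat(sprintf("DuplexSequence (%s, %d bp): %s\n",
                object@naType, nchar(s), disp))
})

setMethod("length", "DuplexSequence", function(x) nchar(x@seq))

#' Reverse complement of a duplex sequence
#'
#' Watson-Crick complement (A-T or A-U, C-G) read in reverse, in the same
#' alphabet as the input.
#'
#' @param seq A `DuplexSequence` or character string.
#' @param naType Optional override of the alphabet.
#' @return Same type as the input (`DuplexSequence` in, `DuplexSequence` out;
#'   character in, character out).
#' @examples
#' reverseComplement("CATGAC")
#' reverseComplement("ATATAT")  # self-complementary
#' @export
reverseComplement <- function(seq, naType = NULL) {
    wasChar <- !is(seq, "DuplexSequence")
    ds <- duplexSequence(seq, naType)
    rc <- if (ds@naType == "DNA") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(ds@seq)))
    } else {
        as.character(Biostrings::reverseComplement(Biostrings::RNAString(ds@seq)))
    }
    if (wasChar) rc else duplexSequence(rc, ds@naType)
}

#' Self-complementarity and canonical reverse-complement classes
#'
#' On a double helix a k-mer and its reverse complement describe the same
#' duplex context. `isSelfComplementary` tests whether a k-mer equals its own
#' reverse complement; `canonicalClass` returns the lexicographically smaller
#' of the two, a class representative stable under complementation.
#'
#' @param seq A k-mer (`DuplexSequence` or character, vectorized for
#'   `canonicalClass` on character input).
#' @param naType Optional alphabet override.
#' @return Logical, or the canonical representative(s).
#' @examples
#' isSelfComplementary("AAGCTT")
#' canonicalClass("TTTTTT")
#' @export
isSelfComplementary <- function(seq, naType = NULL) {
    s <- sequenceLetters(seq)
    identical(s, reverseComplement(s, naType))
}

#' @rdname isSelfComplementary
#' @export
canonicalClass <- function(seq, naType = NULL) {
    if (is(seq, "DuplexSequence")) {
        rc <- reverseComplement(seq)
        return(if (rc@seq < seq@seq) rc else seq)
    }
    s <- toupper(as.character(seq))
    rna <- if (is.null(naType)) grepl("U", paste(s, collapse = "")) else naType == "RNA"
    rc <- .revcompVec(s, rna)
    ifelse(rc < s, rc, s)
}

## fast vectorized reverse complement on plain characters
.revcompVec <- function(s, rna = FALSE) {
    comp <- if (rna) chartr("ACGU", "UGCA", s) else chartr("ACGT", "TGCA", s)
    vapply(strsplit(comp, "", fixed = TRUE),
           function(x) paste(rev(x), collapse = ""), character(1))
}

#' All canonical k-mer classes
#'
#' Enumerates the canonical representatives of all reverse-complement k-mer
#' classes, in lexicographic order.
#'
#' @param k k-mer length.
#' @param naType "DNA" or "RNA".
#' @return Character vector of length [countKmerClasses(k)].
#' @examples
#' allCanonicalKmers(2)
#' @export
allCanonicalKmers <- function(k, naType = "DNA") {
    stopifnot(k >= 1)
    alpha <- if (naType == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
    grid <- do.call(expand.grid, c(rep(list(alpha), k), stringsAsFactors = FALSE))
    ## vary the last position slowest so output is lexicographically sorted
    all <- apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
    all <- sort(all)
    keep <- all == canonicalClass(all, naType = naType)
    all[keep]
}

## integer k-mer coding used by the sequence designer: A,C,G,T/U = 0..3
.lettersToCode <- function(letters) {
    m <- match(letters, c("A", "C", "G", "T"))
    m2 <- match(letters, c("A", "C", "G", "U"))
    code <- ifelse(is.na(m), m2, m)
    if (anyNA(code)) stop("invalid letters")
    as.integer(code - 1L)
}

.codeToLetters <- function(code, rna = FALSE) {
    alpha <- if (rna) c("A", "C", "G", "U") else c("A", "C", "G", "T")
    alpha[code + 1L]
}
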