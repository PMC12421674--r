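## Design of minimal sequences containing every reverse-complement k-mer
## class, partitioning into capped oligomers, and k-mer coverage audits.

#' Number of reverse-complement k-mer classes
#'
#' On a double helix a k-mer and its reverse complement are the same context,
#' so the number of distinct classes is 4^k/2 for odd k (no k-mer is
#' self-complementary) and (4^k + 4^(k/2))/2 for even k.
#'
#' @param k k-mer length (>= 1).
#' @return Integer count of classes.
#' @examples
#' countKmerClasses(5)  # 512
#' countKmerClasses(6)  # 2080
#' @export
countKmerClasses <- function(k) {
    if (k < 1) stop("k must be >= 1")
    k <- as.integer(k)
    if (k %% 2L == 1L) as.integer(4^k / 2)
    else as.integer((4^k + 4^(k / 2)) / 2)
}

## reverse-complement code table for all 4^k k-mers (codes 0..4^k-1,
## first letter most significant); returns 0-based class codes
.classCodes <- function(k) {
    n <- 4L^k
    codes <- 0:(n - 1L)
    rc <- integer(n)
    rest <- codes
    for (i in seq_len(k)) {       # peel digits from least significant end
        d <- rest %% 4L
        rc <- rc * 4L + (3L - d)  # complement; building reverses the order
        rest <- rest %/% 4L
    }
    pmin(codes, rc)
}

#' Minimal sequence covering every k-mer class
#'
#' Depth-first search for a sequence in which every reverse-complement k-mer
#' class appears exactly once, counting both strands. For odd k the search
#' finds an optimal sequence of length `countKmerClasses(k) + k - 1`. For
#' even k optimality is generally unattainable by this search; a best-effort
#' sequence covering every class at least once is produced and the duplicated
#' classes are reported.
#'
#' @param k k-mer length.
#' @param seed Integer seed; the traversal order is randomized by the seed
#'   with deterministic tie-breaking, so results are reproducible.
#' @param naType "DNA" or "RNA".
#' @param maxSteps Search-step budget per restart.
#' @param restarts Number of restarts from random start nodes.
#' @return A list with elements `sequence` (a [duplexSequence()]), `length`,
#'   `census` (named counts per canonical class), `duplicated` (classes seen
#'   more than once), and `optimal` (TRUE when every class occurs exactly
#'   once).
#' @examples
#' d <- minimalCoveringSequence(3, seed = 1)
#' d$length  # 34
#' @export
minimalCoveringSequence <- function(k, seed = 1L, naType = "DNA",
                                    maxSteps = 2e6, restarts = 25L) {
    stopifnot(k >= 1)
    k <- as.integer(k)
    set.seed(as.integer(seed))
    target <- countKmerClasses(k)
    cls <- .classCodes(k)
    nodeMod <- 4L^(k - 1L)

    letters <- NULL
    for (r in seq_len(restarts)) {
        res <- .dfsCover(k, cls, nodeMod, target, maxSteps)
        if (!is.null(res)) { letters <- res; break }
    }
    if (is.null(letters)) {
        if (k %% 2L == 1L)
            stop("DFS failed to find an optimal covering sequence for odd k = ", k)
        letters <- .greedyCover(k, cls, nodeMod, target, maxSteps)
    }
    seqChar <- paste(.codeToLetters(letters, rna = naType == "RNA"),
                     collapse = "")
    census <- kmerCensus(seqChar, k, collapseComplement = TRUE)
    dup <- names(census)[census > 1L]
    list(sequence = duplexSequence(seqChar, naType),
         length = nchar(seqChar),
         census = census,
         duplicated = dup,
         optimal = length(dup) == 0L && length(census) == target &&
             all(census == 1L))
}

## backtracking DFS for an exactly-once covering walk; returns 0..3 letter
## codes or NULL on failure
.dfsCover <- function(k, cls, nodeMod, target, maxSteps) {
    maxDepth <- target + 1L
    usedCls <- logical(4L^k)      # indexed by class code + 1
    usedCount <- 0L
    letters <- integer(target + k - 1L)
    startNode <- sample.int(nodeMod, 1L) - 1L
    if (k > 1L) {                 # start node digits become the first letters
        rest <- startNode
        for (i in (k - 1L):1L) {
            letters[i] <- rest %% 4L
            rest <- rest %/% 4L
        }
    }
    pos <- k - 1L
    node <- integer(maxDepth); node[1L] <- startNode
    perms <- matrix(0L, 4L, maxDepth)
    ptrs <- integer(maxDepth)
    chosen <- integer(maxDepth)
    depth <- 1L
    perms[, 1L] <- sample.int(4L) - 1L
    steps <- 0L
    while (depth >= 1L) {
        steps <- steps + 1L
        if (steps > maxSteps) return(NULL)
        if (usedCount == target) return(letters[seq_len(pos)])
        ptrs[depth] <- ptrs[depth] + 1L
        if (ptrs[depth] > 4L) {
            depth <- depth - 1L
            if (depth >= 1L) {    # undo the parent's accepted choice
                usedCls[chosen[depth]] <- FALSE
                usedCount <- usedCount - 1L
                pos <- pos - 1L
            }
            next
        }
        c0 <- perms[ptrs[depth], depth]
        km <- node[depth] * 4L + c0
        cl <- cls[km + 1L] + 1L
        if (usedCls[cl]) next
        usedCls[cl] <- TRUE
        usedCount <- usedCount + 1L
        pos <- pos + 1L
        letters[pos] <- c0
        chosen[depth] <- cl
        depth <- depth + 1L
        node[depth] <- km %% nodeMod
        perms[, depth] <- sample.int(4L) - 1L
        ptrs[depth] <- 0L
        chosen[depth] <- 0L
    }
    NULL
}

## duplication-tolerant greedy walk: prefer edges whose class is unused,
## otherwise take a random edge; stops when every class has been seen
.greedyCover <- function(k, cls, nodeMod, target, maxSteps) {
    usedCls <- logical(4L^k)
    usedCount <- 0L
    letters <- integer(0)
    node <- sample.int(nodeMod, 1L) - 1L
    if (k > 1L) {
        rest <- node
        pre <- integer(k - 1L)
        for (i in (k - 1L):1L) { pre[i] <- rest %% 4L; rest <- rest %/% 4L }
        letters <- pre
    }
    steps <- 0L
    while (usedCount < target && steps < maxSteps) {
        steps <- steps + 1L
        cand <- sample.int(4L) - 1L
        kms <- node * 4L + cand
        cl <- cls[kms + 1L] + 1L
        fresh <- which(!usedCls[cl])
        pick <- if (length(fresh)) fresh[1L] else 1L
        if (!usedCls[cl[pick]]) {
            usedCls[cl[pick]] <- TRUE
            usedCount <- usedCount + 1L
        }
        letters <- c(letters, cand[pick])
        node <- kms[pick] %% nodeMod
    }
    if (usedCount < target)
        warning("greedy cover stopped before covering all classes (",
                usedCount, "/", target, ")")
    letters
}

#' k-mer census of one or more sequences
#'
#' Counts every k-letter window. With `collapseComplement = TRUE` windows are
#' counted per canonical reverse-complement class (i.e., both strands).
#'
#' @param seqs Character vector or list of `DuplexSequence`s.
#' @param k Window length.
#' @param collapseComplement Count per canonical class instead of per literal
#'   window.
#' @return Named integer vector of counts, sorted by class.
#' @examples
#' kmerCensus("AAA", 2)
#' kmerCensus("AT", 2, collapseComplement = TRUE)
#' @export
kmerCensus <- function(seqs, k, collapseComplement = FALSE) {
    if (is(seqs, "DuplexSequence")) seqs <- list(seqs)
    chars <- vapply(seqs, sequenceLetters, character(1))
    wins <- unlist(lapply(chars, function(s) {
        n <- nchar(s)
        if (n < k) return(character(0))
        substring(s, 1:(n - k + 1L), k:n)
    }), use.names = FALSE)
    if (collapseComplement) wins <- canonicalClass(wins)
    tab <- table(wins)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[order(names(out))]
}

setClass("OligomerSet",
    representation(oligomers = "character", cores = "character",
                   coreLen = "integer", k = "integer", cap = "character",
                   naType = "character"))

setMethod("show", "OligomerSet", function(object) {
    cat(sprintf("OligomerSet: %d oligomers of %d bp (core %d bp + %s caps), k = %d\n",
                length(object@oligomers), nchar(object@oligomers[1]),
                object@coreLen, object@cap, object@k))
})

#' Partition a designed sequence into capped oligomers
#'
#' Tiles the sequence with cores of `coreLen` base pairs overlapping by
#' k - 1, so that every interior k-mer window of the source sequence is
#' preserved inside some core. The last core is right-aligned to the sequence
#' end (a larger overlap) so no window is lost. Each core is capped with a
#' GCGC tetramer at both ends to isolate end fraying; caps are excluded from
#' census and model fitting.
#'
#' @param seq The designed sequence (character or `DuplexSequence`).
#' @param coreLen Core length in bp (>= k).
#' @param k The k-mer length whose windows must be preserved.
#' @param cap Cap sequence added at both ends.
#' @return An `OligomerSet`.
#' @examples
#' d <- minimalCoveringSequence(3, seed = 1)
#' partitionIntoOligomers(d$sequence, coreLen = 10, k = 3)
#' @export
partitionIntoOligomers <- function(seq, coreLen, k, cap = "GCGC") {
    ds <- duplexSequence(seq)
    s <- ds@seq
    n <- nchar(s)
    coreLen <- as.integer(coreLen)
    if (coreLen < k) stop("coreLen must be >= k")
    if (coreLen > n) stop("coreLen exceeds the sequence length")
    stride <- coreLen - (k - 1L)
    starts <- seq.int(1L, n - coreLen + 1L, by = stride)
    if (starts[length(starts)] + coreLen - 1L < n)
        starts <- c(starts, n - coreLen + 1L)
    cores <- substring(s, starts, starts + coreLen - 1L)
    new("OligomerSet",
        oligomers = paste0(cap, cores, cap),
        cores = cores, coreLen = coreLen, k = as.integer(k),
        cap = cap, naType = ds@naType)
}

#' @describeIn partitionIntoOligomers core sequences without caps
#' @param x An `OligomerSet`.
#' @export
oligomerCores <- function(x) x@cores

#' @describeIn partitionIntoOligomers capped oligomer sequences
#' @export
oligomerSequences <- function(x) x@oligomers

#' Write sequences to FASTA
#'
#' @param seqs Character vector, `DuplexSequence`, or `OligomerSet` (capped
#'   oligomers are written).
#' @param path Output file.
#' @param names Optional sequence names.
#' @return Invisibly, the path.
#' @export
writeFasta <- function(seqs, path, names = NULL) {
    if (is(seqs, "OligomerSet")) {
        rna <- seqs@naType == "RNA"
        seqs <- seqs@oligomers
    } else if (is(seqs, "DuplexSequence")) {
        rna <- seqs@naType == "RNA"
        seqs <- seqs@seq
    } else {
        rna <- grepl("U", paste(seqs, collapse = ""))
    }
    if (is.null(names)) names <- sprintf("seq%03d", seq_along(seqs))
    xss <- if (rna) Biostrings::RNAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
    names(xss) <- names
    Biostrings::writeXStringSet(xss, filepath = path)
    invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param naType "DNA" or "RNA"; inferred from the content when NULL.
#' @return A list of [duplexSequence()] objects, named by FASTA headers.
#' @export
readFasta <- function(path, naType = NULL) {
    raw <- Biostrings::readBStringSet(path)
    out <- lapply(as.character(raw), duplexSequence, naType = naType)
    out
}
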