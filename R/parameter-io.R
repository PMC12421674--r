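## Deposit-style CSV serialization of parameter sets. Layout (documented in
## the README): shape.csv holds one row per (hexamer, position, coordinate)
## with the equilibrium mean and the per-coordinate stiffness constant;
## grooves.csv holds groove widths and stiffnesses; blocks.csv holds the
## upper triangle of every 66x66 stiffness block in long format; metadata.json
## records na_type, seed and provenance. Units are Angstrom, degrees and
## kcal/mol throughout; only canonical classes are stored.

#' Write a parameter set to a directory of CSV tables
#'
#' @param ps A `ParameterSet`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @seealso [loadParameterSet()]
#' @export
writeParameterSet <- function(ps, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    hexes <- ps@hexamers
    nHex <- length(hexes)

    longShape <- function(m, k, cols) {
        key <- do.call(rbind, strsplit(cols, ".", fixed = TRUE))
        data.table::data.table(
            sequence = rep(hexes, times = length(cols)),
            postype = rep(key[, 1L], each = nHex),
            coordinate = rep(key[, 2L], each = nHex),
            mean = as.vector(m),
            kx = as.vector(k))
    }
    shape <- rbind(longShape(ps@pairMeans, ps@pairK, .pairColNames()),
                   longShape(ps@stepMeans, ps@stepK, .stepColNames()))
    data.table::setorder(shape, sequence, postype, coordinate)
    data.table::fwrite(shape, file.path(dir, "shape.csv"))

    grooves <- rbind(
        data.table::data.table(sequence = hexes, groove = "major",
                               position = "step3",
                               width = ps@majorGroove, kx = ps@majorGrooveK),
        data.table::data.table(sequence = rep(hexes, 2L), groove = "minor",
                               position = rep(c("pair3", "pair4"), each = nHex),
                               width = as.vector(ps@minorGroove),
                               kx = as.vector(ps@minorGrooveK)))
    data.table::setorder(grooves, sequence, groove, position)
    data.table::fwrite(grooves, file.path(dir, "grooves.csv"))

    ut <- upper.tri(diag(66L), diag = TRUE)
    iIdx <- row(diag(66L))[ut]
    jIdx <- col(diag(66L))[ut]
    vals <- vapply(ps@blocks, function(B) B[ut], numeric(sum(ut)))
    blocks <- data.table::data.table(
        sequence = rep(hexes, each = sum(ut)),
        i = rep(iIdx, times = nHex),
        j = rep(jIdx, times = nHex),
        value = as.vector(vals))
    data.table::fwrite(blocks, file.path(dir, "blocks.csv"))

    meta <- ps@metadata
    meta$na_type <- ps@naType
    jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

## parity fold of one stored orientation onto its canonical class
.foldToCanonical <- function(entry) {
    list(pairMean = .flipPair36(entry$pairMean),
         stepMean = .flipStep30(entry$stepMean),
         pairK = .flipPair36(entry$pairK, negate = FALSE),
         stepK = .flipStep30(entry$stepK, negate = FALSE),
         major = entry$major, majorK = entry$majorK,
         minor = rev(entry$minor), minorK = rev(entry$minorK),
         block = complementStiffnessBlock(entry$block))
}

#' Load a parameter set from CSV tables
#'
#' Reads the layout written by [writeParameterSet()]. Keys are canonicalized:
#' records stored under a non-canonical orientation are folded onto the
#' canonical class through the complement transforms. When both a hexamer and
#' its reverse complement are present, their records must agree after the
#' parity transform; an inconsistency is a validation error. Missing classes
#' and malformed rows are reported by name.
#'
#' @param dir Directory containing `shape.csv`, `grooves.csv`, `blocks.csv`
#'   and optionally `metadata.json`.
#' @param naType "DNA" or "RNA"; read from the metadata sidecar when NULL.
#' @param validate Run [validateParameterSet()] and stop on failure.
#' @param tol Tolerance for the complement-consistency comparison.
#' @return A `ParameterSet`.
#' @export
loadParameterSet <- function(dir, naType = NULL, validate = TRUE, tol = 1e-6) {
    shapePath <- file.path(dir, "shape.csv")
    groovePath <- file.path(dir, "grooves.csv")
    blockPath <- file.path(dir, "blocks.csv")
    metaPath <- file.path(dir, "metadata.json")
    for (p in c(shapePath, groovePath, blockPath))
        if (!file.exists(p)) stop("missing parameter table: ", p)
    meta <- if (file.exists(metaPath)) jsonlite::read_json(metaPath) else list()
    if (is.null(naType))
        naType <- if (!is.null(meta$na_type)) meta$na_type else "DNA"

    shape <- data.table::fread(shapePath)
    need <- c("sequence", "postype", "coordinate", "mean", "kx")
    if (!all(need %in% names(shape)))
        stop("shape.csv must have columns: ", paste(need, collapse = ", "))
    allCols <- c(.pairColNames(), .stepColNames())
    key <- paste0(shape$postype, ".", shape$coordinate)
    bad <- which(!key %in% allCols)
    if (length(bad))
        stop(sprintf("shape.csv row %d: unknown position/coordinate '%s'",
                     bad[1], key[bad[1]]))
    seqs <- sort(unique(shape$sequence))
    if (any(nchar(seqs) != 6L))
        stop("shape.csv: sequences must have 6 letters, found ",
             seqs[which(nchar(seqs) != 6L)[1]])
    M <- matrix(NA_real_, length(seqs), 66L, dimnames = list(seqs, allCols))
    K <- M
    ridx <- match(shape$sequence, seqs)
    cidx <- match(key, allCols)
    M[cbind(ridx, cidx)] <- shape$mean
    K[cbind(ridx, cidx)] <- shape$kx
    if (anyNA(M)) {
        miss <- which(is.na(M), arr.ind = TRUE)[1L, ]
        stop(sprintf("shape.csv: %s is missing entry %s",
                     seqs[miss[1]], allCols[miss[2]]))
    }

    grooves <- data.table::fread(groovePath)
    unknown <- setdiff(grooves$sequence, seqs)
    if (length(unknown))
        stop("grooves.csv: sequences absent from shape.csv: ",
             paste(utils::head(unknown, 5), collapse = ", "))
    majorG <- stats::setNames(rep(NA_real_, length(seqs)), seqs)
    majorGK <- majorG
    minorG <- matrix(NA_real_, length(seqs), 2L,
                     dimnames = list(seqs, c("pair3", "pair4")))
    minorGK <- minorG
    gmaj <- grooves[grooves$groove == "major", ]
    majorG[gmaj$sequence] <- gmaj$width
    majorGK[gmaj$sequence] <- gmaj$kx
    gmin <- grooves[grooves$groove == "minor", ]
    minorG[cbind(match(gmin$sequence, seqs), match(gmin$position, c("pair3", "pair4")))] <- gmin$width
    minorGK[cbind(match(gmin$sequence, seqs), match(gmin$position, c("pair3", "pair4")))] <- gmin$kx
    if (anyNA(majorG) || anyNA(minorG))
        stop("grooves.csv: incomplete groove data for ",
             seqs[which(is.na(majorG) | is.na(minorG[, 1L]))[1]])

    blk <- data.table::fread(blockPath)
    if (!all(c("sequence", "i", "j", "value") %in% names(blk)))
        stop("blocks.csv must have columns sequence, i, j, value")
    blkList <- lapply(split(blk, by = "sequence", keep.by = FALSE), function(d) {
        B <- matrix(NA_real_, 66L, 66L)
        B[cbind(d$i, d$j)] <- d$value
        B[cbind(d$j, d$i)] <- d$value
        B
    })
    blkList <- blkList[seqs]
    for (s in seqs) {
        B <- blkList[[s]]
        if (is.null(B) || anyNA(B))
            stop("blocks.csv: incomplete 66x66 block for ", s)
        if (max(abs(B - t(B))) > tol)
            stop("blocks.csv: asymmetric block for ", s)
        blkList[[s]] <- (B + t(B)) / 2
    }

    entryFor <- function(s) list(
        pairMean = M[s, 1:36], stepMean = M[s, 37:66],
        pairK = K[s, 1:36], stepK = K[s, 37:66],
        major = majorG[[s]], majorK = majorGK[[s]],
        minor = minorG[s, ], minorK = minorGK[s, ],
        block = blkList[[s]])

    expected <- allCanonicalKmers(6L, naType)
    missing <- character(0)
    nHex <- length(expected)
    pairMeans <- matrix(0, nHex, 36L, dimnames = list(expected, .pairColNames()))
    stepMeans <- matrix(0, nHex, 30L, dimnames = list(expected, .stepColNames()))
    pairK <- pairMeans; stepK <- stepMeans
    majorGroove <- numeric(nHex); majorGrooveK <- numeric(nHex)
    minorGroove <- matrix(0, nHex, 2L, dimnames = list(expected, c("pair3", "pair4")))
    minorGrooveK <- minorGroove
    blocks <- vector("list", nHex); names(blocks) <- expected

    for (r in seq_len(nHex)) {
        cls <- expected[r]
        rc <- reverseComplement(cls, naType)
        hasC <- cls %in% seqs
        hasR <- !identical(rc, cls) && rc %in% seqs
        if (!hasC && !hasR) { missing <- c(missing, cls); next }
        e <- if (hasC) entryFor(cls) else .foldToCanonical(entryFor(rc))
        if (hasC && hasR) {
            f <- .foldToCanonical(entryFor(rc))
            dev <- max(abs(e$pairMean - f$pairMean),
                       abs(e$stepMean - f$stepMean),
                       abs(e$block - f$block))
            if (dev > tol)
                stop("inconsistent parity signs between ", cls, " and its ",
                     "complement ", rc, " (max deviation ", signif(dev, 3), ")")
        }
        pairMeans[r, ] <- e$pairMean; stepMeans[r, ] <- e$stepMean
        pairK[r, ] <- e$pairK; stepK[r, ] <- e$stepK
        majorGroove[r] <- e$major; majorGrooveK[r] <- e$majorK
        minorGroove[r, ] <- e$minor; minorGrooveK[r, ] <- e$minorK
        blocks[[r]] <- e$block
    }
    if (length(missing))
        stop(sprintf("parameter set is missing %d hexamer class(es): %s%s",
                     length(missing),
                     paste(utils::head(missing, 10), collapse = ", "),
                     if (length(missing) > 10) ", ..." else ""))

    ps <- new("ParameterSet", naType = naType, hexamers = expected,
              pairMeans = pairMeans, stepMeans = stepMeans,
              pairK = pairK, stepK = stepK,
              majorGroove = majorGroove, majorGrooveK = majorGrooveK,
              minorGroove = minorGroove, minorGrooveK = minorGrooveK,
              blocks = blocks,
              metadata = c(meta[setdiff(names(meta), "na_type")],
                           list(path = dir)))
    if (validate) {
        v <- validateParameterSet(ps)
        if (!v$pass)
            stop("parameter set failed validation:\n  ",
                 paste(utils::head(v$issues, 10), collapse = "\n  "))
    }
    ps
}
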