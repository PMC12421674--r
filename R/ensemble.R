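## Parameter estimation from coordinate ensembles: snapshot filtering by the
## hydrogen-bond rule, mean/covariance/stiffness estimation, maximum-
## absolute-entropy banded stiffness, hexameric block extraction, convergence
## diagnostics, base-pair opening survival analysis, and a synthetic
## trajectory generator for parameter-recovery tests.

setClass("CoordinateTimeSeries",
    representation(data = "matrix", times = "numeric",
                   sequence = "character", naType = "character"),
    validity = function(object) {
        if (length(object@times) != nrow(object@data))
            return("one timestamp per snapshot required")
        if (is.unsorted(object@times, strictly = FALSE))
            return("timestamps must be monotone")
        if (nzchar(object@sequence) &&
            ncol(object@data) != coordinateVectorLength(nchar(object@sequence)))
            return("data dimension does not match 12 nBp - 6")
        TRUE
    })

setMethod("show", "CoordinateTimeSeries", function(object) {
    cat(sprintf("CoordinateTimeSeries: %d snapshots x %d coordinates (%s, %d bp)\n",
                nrow(object@data), ncol(object@data), object@naType,
                nchar(object@sequence)))
})

#' Coordinate time series container
#'
#' Snapshots of the duplex coordinate vector (pair 1, step 1, ..., pair N),
#' one row per snapshot, with timestamps in picoseconds.
#'
#' @param data n x (12 nBp - 6) numeric matrix.
#' @param sequence The duplex sequence.
#' @param times Snapshot timestamps (ps); defaults to 10-ps spacing.
#' @param naType "DNA" or "RNA".
#' @return A `CoordinateTimeSeries`.
#' @export
coordinateTimeSeries <- function(data, sequence, times = NULL, naType = NULL) {
    ds <- duplexSequence(sequence, naType)
    if (is.null(times)) times <- seq(0, by = 10, length.out = nrow(data))
    new("CoordinateTimeSeries", data = as.matrix(data), times = times,
        sequence = ds@seq, naType = ds@naType)
}

setClass("HBondSeries",
    representation(dist = "matrix", pair = "integer", label = "character",
                   times = "numeric"),
    validity = function(object) {
        if (ncol(object@dist) != length(object@pair))
            return("one pair index per bond column required")
        if (any(object@dist <= 0)) return("distances must be positive")
        TRUE
    })

setMethod("show", "HBondSeries", function(object) {
    cat(sprintf("HBondSeries: %d snapshots x %d bonds over %d pairs\n",
                nrow(object@dist), ncol(object@dist),
                length(unique(object@pair))))
})

#' Hydrogen-bond distance series container
#'
#' Heavy-atom donor-acceptor distances of the Watson-Crick hydrogen bonds,
#' one row per snapshot and one column per bond.
#'
#' @param dist n x nBonds matrix of distances (Angstrom).
#' @param pair Integer base-pair index of each bond column.
#' @param label Optional bond labels.
#' @param times Snapshot timestamps (ps).
#' @return An `HBondSeries`.
#' @export
hbondSeries <- function(dist, pair, label = NULL, times = NULL) {
    dist <- as.matrix(dist)
    if (is.null(label)) label <- sprintf("pair%d.hb%d", pair,
                                         stats::ave(pair, pair, FUN = seq_along))
    if (is.null(times)) times <- seq(0, by = 10, length.out = nrow(dist))
    new("HBondSeries", dist = dist, pair = as.integer(pair),
        label = label, times = times)
}

#' Filter snapshots by the broken hydrogen-bond rule
#'
#' A hydrogen bond is broken when its heavy-atom distance exceeds 4 Angstrom.
#' A snapshot is excluded when at least one bond of a pair inside
#' `centralRange` is broken; bonds of pairs outside the range (the outer cap
#' pairs) are ignored.
#'
#' @param hb An `HBondSeries`.
#' @param centralRange Integer range of pair indices to monitor.
#' @param cutoff Breaking distance (Angstrom).
#' @return Logical keep-mask over snapshots, with attribute `keptFraction`.
#' @export
filterSnapshots <- function(hb, centralRange, cutoff = 4) {
    stopifnot(is(hb, "HBondSeries"))
    inner <- hb@pair %in% centralRange
    broken <- if (any(inner))
        rowSums(hb@dist[, inner, drop = FALSE] > cutoff) > 0L
    else rep(FALSE, nrow(hb@dist))
    mask <- !broken
    attr(mask, "keptFraction") <- mean(mask)
    mask
}

#' Mean, covariance and stiffness from a coordinate ensemble
#'
#' The equilibrium coordinates are the ensemble mean over kept snapshots, the
#' stiffness matrix is K = kBT Sigma^-1 with the sample covariance Sigma, and
#' the per-coordinate stiffness constants are kx = kBT / var(x) (all other
#' coordinates unconstrained).
#'
#' @param ts A `CoordinateTimeSeries` or plain snapshot matrix.
#' @param mask Optional logical keep-mask (from [filterSnapshots()]).
#' @return List with `what`, `Sigma`, `K` (NULL when Sigma is singular, with
#'   a warning), `kx`, and `nKept`.
#' @export
estimateMeanCov <- function(ts, mask = NULL) {
    x <- if (is(ts, "CoordinateTimeSeries")) ts@data else as.matrix(ts)
    if (!is.null(mask)) x <- x[mask, , drop = FALSE]
    if (nrow(x) < 2L) stop("need at least 2 kept snapshots")
    kBT <- physicalConstants()$kBT
    what <- colMeans(x)
    Sigma <- stats::cov(x)
    K <- tryCatch(kBT * solve(Sigma), error = function(e) {
        warning("singular covariance; full stiffness matrix not computed")
        NULL
    })
    list(what = what, Sigma = Sigma, K = K,
         kx = kBT / diag(Sigma), nKept = nrow(x))
}

#' Maximum-absolute-entropy banded stiffness matrix
#'
#' Constructs the stiffness matrix that is exactly zero outside the union of
#' hexameric 66x66 blocks and whose implied covariance reproduces the sample
#' covariance on every in-band entry: each diagonal hexameric block of the
#' covariance is inverted and added at its position, then the covariance
#' blocks of the 54-coordinate overlaps between adjacent hexamers are
#' inverted and subtracted, and the result is multiplied by kBT.
#'
#' @param Sigma SPD covariance matrix over the duplex coordinate vector.
#' @param nBp Number of base pairs (>= 6).
#' @return A banded `DuplexStiffness`.
#' @export
bandedMaxentStiffness <- function(Sigma, nBp) {
    nBp <- as.integer(nBp)
    stopifnot(nBp >= 6L)
    n <- coordinateVectorLength(nBp)
    if (!all(dim(Sigma) == c(n, n)))
        stop("Sigma must be ", n, " x ", n, " for ", nBp, " bp")
    if (max(abs(Sigma - t(Sigma))) > 1e-8) stop("Sigma must be symmetric")
    J <- matrix(0, n, n)
    invBlock <- function(idx) {
        tryCatch(solve(Sigma[idx, idx]),
                 error = function(e)
                     stop("singular covariance sub-block at indices ",
                          idx[1], "..", idx[length(idx)]))
    }
    for (h in seq_len(nBp - 5L)) {
        sl <- blockSlice(h)
        J[sl, sl] <- J[sl, sl] + invBlock(sl)
    }
    for (h in seq_len(nBp - 6L)) {
        ov <- intersect(blockSlice(h), blockSlice(h + 1L))
        J[ov, ov] <- J[ov, ov] - invBlock(ov)
    }
    kBT <- physicalConstants()$kBT
    .asStiffness(kBT * (J + t(J)) / 2, nBp, "DNA", dimensionless = FALSE,
                 banded = TRUE)
}

#' Extract hexameric stiffness blocks from a banded matrix
#'
#' Cuts the 66x66 block of every hexameric window out of a banded stiffness
#' matrix and keys it by the canonical reverse-complement class (applying the
#' complement transform when the canonical representative is the reverse
#' complement of the window). For duplicate windows the first occurrence
#' wins; the deviation between duplicates is reported.
#'
#' @param K Banded `DuplexStiffness` (or plain matrix with `nBp` implied by
#'   `seq`).
#' @param seq The sequence the matrix belongs to.
#' @param naType Alphabet override for plain-character input.
#' @return List with `blocks` (named list of 66x66 matrices) and `duplicates`
#'   (data.frame with columns `hexamer`, `maxDeviation`).
#' @export
extractHexamerBlocks <- function(K, seq, naType = NULL) {
    ds <- duplexSequence(seq, naType)
    m <- if (is(K, "DuplexStiffness")) K@mat else as.matrix(K)
    n <- nchar(ds@seq)
    stopifnot(nrow(m) == coordinateVectorLength(n))
    blocks <- list()
    dup <- data.frame(hexamer = character(0), maxDeviation = numeric(0))
    for (h in seq_len(n - 5L)) {
        hex <- substr(ds@seq, h, h + 5L)
        canon <- canonicalClass(hex, naType = ds@naType)
        B <- m[blockSlice(h), blockSlice(h)]
        if (!identical(canon, hex)) B <- complementStiffnessBlock(B)
        if (isSelfComplementary(canon, ds@naType))
            B <- (B + complementStiffnessBlock(B)) / 2
        if (is.null(blocks[[canon]])) {
            blocks[[canon]] <- B
        } else {
            dup <- rbind(dup, data.frame(
                hexamer = canon,
                maxDeviation = max(abs(blocks[[canon]] - B))))
        }
    }
    list(blocks = blocks, duplicates = dup)
}

#' Assemble a stiffness matrix from an explicit block map
#'
#' Same assembly as [assembleStiffnessMatrix()] (arithmetic means on
#' overlaps, zero outside the band) but using a named map of canonical-class
#' blocks, e.g. from [extractHexamerBlocks()]. Blocks for reverse-complement
#' windows are derived by the complement transform.
#'
#' @param seq Sequence.
#' @param blocks Named list of 66x66 blocks keyed by canonical hexamer class.
#' @param naType Alphabet override.
#' @return A banded `DuplexStiffness`.
#' @export
assembleFromBlocks <- function(seq, blocks, naType = NULL) {
    ds <- duplexSequence(seq, naType)
    s <- ds@seq
    n <- nchar(s)
    if (n < 6L) stop("sequence shorter than 6 bp")
    dim <- coordinateVectorLength(n)
    acc <- matrix(0, dim, dim)
    cnt <- matrix(0L, dim, dim)
    for (h in seq_len(n - 5L)) {
        hex <- substr(s, h, h + 5L)
        canon <- canonicalClass(hex, naType = ds@naType)
        B <- blocks[[canon]]
        if (is.null(B)) stop("missing block for class ", canon)
        if (!identical(canon, hex)) B <- complementStiffnessBlock(B)
        sl <- blockSlice(h)
        acc[sl, sl] <- acc[sl, sl] + B
        cnt[sl, sl] <- cnt[sl, sl] + 1L
    }
    keep <- cnt > 0L
    acc[keep] <- acc[keep] / cnt[keep]
    .asStiffness(acc, n, ds@naType, dimensionless = FALSE, banded = TRUE)
}

#' Half-trajectory convergence error
#'
#' The absolute convergence error of a quantity is the mean deviation of its
#' half-trajectory estimates from the full-trajectory value,
#' eps_a = 0.5 (|x1 - xfull| + |x2 - xfull|); the relative error is
#' eps_r = eps_a / |xfull|.
#'
#' @param x1,x2 Estimates from the two trajectory halves.
#' @param xfull Estimate from the full trajectory.
#' @return Named numeric `ea` and `er` (`er` is NA when `xfull` is 0).
#' @examples
#' convergenceError(1, 3, 2)
#' @export
convergenceError <- function(x1, x2, xfull) {
    stopifnot(is.finite(x1), is.finite(x2), is.finite(xfull))
    ea <- 0.5 * (abs(x1 - xfull) + abs(x2 - xfull))
    er <- if (xfull != 0) ea / abs(xfull) else NA_real_
    c(ea = ea, er = er)
}

#' Base-pair opening events
#'
#' A pair is open while at least one of its hydrogen bonds exceeds the
#' 4-Angstrom cutoff. Events are maximal runs of consecutive open snapshots;
#' single-snapshot events count. Durations are run lengths times the
#' snapshot spacing.
#'
#' @param hb An `HBondSeries`.
#' @param pair Base-pair index.
#' @param cutoff Breaking distance (Angstrom).
#' @return Numeric vector of event durations (time units of `hb@times`).
#' @export
openingEvents <- function(hb, pair, cutoff = 4) {
    stopifnot(is(hb, "HBondSeries"))
    cols <- which(hb@pair == pair)
    if (!length(cols)) stop("no bonds recorded for pair ", pair)
    open <- rowSums(hb@dist[, cols, drop = FALSE] > cutoff) > 0L
    r <- rle(open)
    dt <- if (length(hb@times) > 1L) stats::median(diff(hb@times)) else 1
    r$lengths[r$values] * dt
}

setClass("SurvivalFit",
    representation(t = "numeric", S = "numeric", window = "numeric",
                   lambda = "numeric", tauOpen = "numeric",
                   tauSE = "numeric", r2 = "numeric", auto = "logical"))

setMethod("show", "SurvivalFit", function(object) {
    cat(sprintf("SurvivalFit: tau_open = %.3f (SE %.3f), lambda = %.4f, R^2 = %.4f%s\n",
                object@tauOpen, object@tauSE, object@lambda, object@r2,
                if (object@auto) " [auto-selected fit window]" else ""))
})

#' Exponential fit of the opening-time survival function
#'
#' The survival function S(t) is the fraction of opening events lasting
#' longer than t. For exponentially distributed opening times
#' S(t) = exp(-lambda t) and the mean opening time is tau_open = -1/slope of
#' a straight-line fit to ln S(t). The fit window is user-specified or
#' auto-selected as the widest time interval (at least 5 support points)
#' whose linear fit reaches the R^2 threshold; auto-selection is a heuristic
#' and is flagged in the result.
#'
#' @param durations Event durations.
#' @param fitWindow Numeric length-2 time window for the fit, or NULL for
#'   auto-selection.
#' @param r2Threshold Minimum R^2 for the auto-selected window.
#' @param maxPoints Thinning grid size for large event sets.
#' @return A `SurvivalFit` with `tauOpen`, its delta-method standard error,
#'   the fitted `lambda`, and the evaluated survival curve.
#' @export
survivalFit <- function(durations, fitWindow = NULL, r2Threshold = 0.99,
                        maxPoints = 200L) {
    durations <- durations[is.finite(durations) & durations > 0]
    if (!length(durations)) stop("empty event set")
    tU <- sort(unique(durations))
    if (length(tU) < 2L)
        stop("all event durations equal; survival slope undefined")
    ## evaluate S strictly below the maximum so S > 0 everywhere
    tGrid <- tU[-length(tU)]
    if (length(tGrid) > maxPoints)
        tGrid <- unique(stats::quantile(tGrid, probs = seq(0, 1, length.out = maxPoints),
                                        names = FALSE, type = 1))
    tGrid <- c(0, tGrid)
    S <- vapply(tGrid, function(tt) mean(durations > tt), numeric(1))
    keep <- S > 0 & S < 1
    tGrid <- tGrid[keep]; S <- S[keep]
    auto <- is.null(fitWindow)
    x <- tGrid; y <- log(S)
    ## the empirical ln S(t) has variance ~ (1 - S) / (N S); weight by its
    ## inverse so the noisy tail does not dominate the straight-line fit
    wt <- S / (1 - S)
    cw <- cumsum(c(0, wt))
    cx <- cumsum(c(0, wt * x)); cy <- cumsum(c(0, wt * y))
    cxx <- cumsum(c(0, wt * x^2)); cyy <- cumsum(c(0, wt * y^2))
    cxy <- cumsum(c(0, wt * x * y))
    fitStats <- function(idx) {        # closed-form weighted regression
        i <- idx[1L]; j <- idx[length(idx)]; nn <- j - i + 1L
        sw <- cw[j + 1L] - cw[i]
        sx <- cx[j + 1L] - cx[i]; sy <- cy[j + 1L] - cy[i]
        sxx <- cxx[j + 1L] - cxx[i]; syy <- cyy[j + 1L] - cyy[i]
        sxy <- cxy[j + 1L] - cxy[i]
        Sxx <- sxx - sx^2 / sw; Syy <- syy - sy^2 / sw; Sxy <- sxy - sx * sy / sw
        slope <- Sxy / Sxx
        sse <- max(Syy - slope * Sxy, 0)
        se <- if (nn > 2L) sqrt(sse / (nn - 2L) / Sxx) else NA_real_
        r2 <- if (Syy > 0) 1 - sse / Syy else 1
        c(slope = slope, se = se, r2 = r2)
    }
    if (auto) {
        nP <- length(tGrid)
        if (nP < 5L) stop("fewer than 5 support points for the survival fit")
        best <- NULL; bestSpan <- -Inf
        for (i in seq_len(nP - 4L)) {
            for (j in seq.int(i + 4L, nP)) {
                fs <- fitStats(i:j)
                if (fs["r2"] >= r2Threshold &&
                    tGrid[j] - tGrid[i] > bestSpan) {
                    bestSpan <- tGrid[j] - tGrid[i]
                    best <- list(idx = i:j, fs = fs)
                }
            }
        }
        if (is.null(best)) {      # fall back to the full range
            best <- list(idx = seq_len(nP), fs = fitStats(seq_len(nP)))
            warning("no window reached the R^2 threshold; fitted the full range")
        }
        idx <- best$idx; fs <- best$fs
        window <- range(tGrid[idx])
    } else {
        idx <- which(tGrid >= fitWindow[1L] & tGrid <= fitWindow[2L])
        if (length(idx) < 3L)
            stop("fit window contains fewer than 3 support points")
        fs <- fitStats(idx)
        window <- as.numeric(fitWindow)
    }
    slope <- fs[["slope"]]
    if (slope >= 0) stop("survival function does not decay on the fit window")
    lambda <- -slope
    new("SurvivalFit", t = tGrid, S = S, window = window,
        lambda = lambda, tauOpen = 1 / lambda,
        tauSE = fs[["se"]] / lambda^2, r2 = fs[["r2"]], auto = auto)
}

#' Synthetic trajectory generator
#'
#' Draws Gaussian coordinate snapshots from a duplex model (mean = predicted
#' equilibrium coordinates, covariance = kBT K^-1) and generates hydrogen-
#' bond distance series with a quiet baseline plus exponential-duration
#' opening excursions beyond the 4-Angstrom cutoff injected at a configured
#' rate per pair. Deterministic given the seed.
#'
#' @param model A `DuplexModel` (see [buildDuplexModel()]; use `trim = FALSE`
#'   to guarantee a positive definite sampling stiffness).
#' @param n Number of snapshots.
#' @param seed Integer seed.
#' @param dt Snapshot spacing (ns).
#' @param openingRate Opening events per ns per pair (0 disables openings).
#' @param meanOpenTime Mean opening duration (ns).
#' @param pairs Pairs eligible for openings (default: all but the two outer
#'   pairs at each end).
#' @return List with `coords` (a `CoordinateTimeSeries`, times in ps) and
#'   `hbonds` (an `HBondSeries`).
#' @export
syntheticTrajectory <- function(model, n, seed = 1L, dt = 0.01,
                                openingRate = 0, meanOpenTime = 1,
                                pairs = NULL) {
    stopifnot(is(model, "DuplexModel"))
    set.seed(as.integer(seed))
    nBp <- nchar(model@sequence)
    X <- .gaussianSamples(model@what, model@K@mat, n)
    timesPs <- (seq_len(n) - 1L) * dt * 1000
    coords <- coordinateTimeSeries(X, model@sequence, times = timesPs,
                                   naType = model@naType)
    letters <- strsplit(model@sequence, "")[[1L]]
    nBonds <- ifelse(letters %in% c("G", "C"), 3L, 2L)
    pairIdx <- rep(seq_len(nBp), nBonds)
    D <- matrix(stats::rnorm(n * length(pairIdx), 2.9, 0.08), n)
    D[D < 2.4] <- 2.4
    if (openingRate > 0) {
        if (is.null(pairs)) pairs <- 3:(nBp - 2L)
        total <- n * dt
        for (p in pairs) {
            col <- which(pairIdx == p)[1L]
            tPos <- 0
            repeat {
                tPos <- tPos + stats::rexp(1L, rate = openingRate)
                if (tPos >= total) break
                dur <- stats::rexp(1L, rate = 1 / meanOpenTime)
                i0 <- floor(tPos / dt) + 1L
                i1 <- min(n, i0 + max(1L, round(dur / dt)) - 1L)
                D[i0:i1, col] <- 4.6 + abs(stats::rnorm(i1 - i0 + 1L, 0, 0.25))
                tPos <- tPos + dur
            }
        }
    }
    hb <- hbondSeries(D, pairIdx, times = timesPs)
    list(coords = coords, hbonds = hb)
}

## Gaussian sampling without touching the RNG seed (callers manage it)
.gaussianSamples <- function(what, K, n) {
    kBT <- physicalConstants()$kBT
    Sigma <- kBT * solve((K + t(K)) / 2)
    R <- chol((Sigma + t(Sigma)) / 2)
    z <- matrix(stats::rnorm(n * length(what)), n)
    sweep(z %*% R, 2L, what, `+`)
}

## ---------------------------------------------------------------------------
## CSV readers/writers for external ensembles

#' Read and write coordinate time series CSV
#'
#' Long format with columns `snapshot`, `position` (e.g. "pair1", "step1"),
#' `coordinate`, `value`, and optionally `time` (ps).
#'
#' @param path CSV file.
#' @param sequence Duplex sequence the series belongs to.
#' @param naType Alphabet override.
#' @return A `CoordinateTimeSeries`.
#' @export
readCoordinateSeries <- function(path, sequence, naType = NULL) {
    d <- data.table::fread(path)
    need <- c("snapshot", "position", "coordinate", "value")
    if (!all(need %in% names(d)))
        stop("coordinate series must have columns: ", paste(need, collapse = ", "))
    ds <- duplexSequence(sequence, naType)
    n <- nchar(ds@seq)
    labs <- coordinateLabels(n)
    key <- paste0(d$position, ".", d$coordinate)
    cidx <- match(key, labs)
    if (anyNA(cidx))
        stop("unknown position/coordinate: ", key[which(is.na(cidx))[1L]])
    snaps <- sort(unique(d$snapshot))
    X <- matrix(NA_real_, length(snaps), length(labs),
                dimnames = list(NULL, labs))
    X[cbind(match(d$snapshot, snaps), cidx)] <- d$value
    if (anyNA(X)) stop("incomplete coordinate series (missing entries)")
    times <- if ("time" %in% names(d))
        d$time[!duplicated(d$snapshot)][order(unique(d$snapshot))]
    else NULL
    coordinateTimeSeries(X, ds, times = times)
}

#' @rdname readCoordinateSeries
#' @param ts A `CoordinateTimeSeries` to write.
#' @export
writeCoordinateSeries <- function(ts, path) {
    stopifnot(is(ts, "CoordinateTimeSeries"))
    labs <- coordinateLabels(nchar(ts@sequence))
    pc <- do.call(rbind, strsplit(labs, ".", fixed = TRUE))
    n <- nrow(ts@data)
    d <- data.table::data.table(
        snapshot = rep(seq_len(n), times = length(labs)),
        time = rep(ts@times, times = length(labs)),
        position = rep(pc[, 1L], each = n),
        coordinate = rep(pc[, 2L], each = n),
        value = as.vector(ts@data))
    data.table::fwrite(d, path)
    invisible(path)
}

#' Read and write hydrogen-bond distance series CSV
#'
#' Long format with columns `snapshot`, `pair`, `bond`, `distance`, and
#' optionally `time`.
#'
#' @param path CSV file.
#' @return An `HBondSeries`.
#' @export
readHBondSeries <- function(path) {
    d <- data.table::fread(path)
    need <- c("snapshot", "pair", "bond", "distance")
    if (!all(need %in% names(d)))
        stop("H-bond series must have columns: ", paste(need, collapse = ", "))
    key <- paste0("pair", d$pair, ".hb", d$bond)
    cols <- unique(key[order(d$pair, d$bond)])
    snaps <- sort(unique(d$snapshot))
    D <- matrix(NA_real_, length(snaps), length(cols),
                dimnames = list(NULL, cols))
    D[cbind(match(d$snapshot, snaps), match(key, cols))] <- d$distance
    if (anyNA(D)) stop("incomplete H-bond series (missing entries)")
    pair <- as.integer(sub("^pair(\\d+)\\..*$", "\\1", cols))
    times <- if ("time" %in% names(d))
        d$time[!duplicated(d$snapshot)][order(unique(d$snapshot))]
    else NULL
    hbondSeries(D, pair, label = cols, times = times)
}

#' @rdname readHBondSeries
#' @param hb An `HBondSeries` to write.
#' @export
writeHBondSeries <- function(hb, path) {
    stopifnot(is(hb, "HBondSeries"))
    n <- nrow(hb@dist)
    d <- data.table::data.table(
        snapshot = rep(seq_len(n), times = ncol(hb@dist)),
        time = rep(hb@times, times = ncol(hb@dist)),
        pair = rep(hb@pair, each = n),
        bond = rep(stats::ave(hb@pair, hb@pair, FUN = seq_along), each = n),
        distance = as.vector(hb@dist))
    data.table::fwrite(d, path)
    invisible(path)
}
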