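#' Preprocess a calcium video
#'
#' Standard conditioning before spot detection: subtract a static
#' background (per-pixel median of the first few frames), divide by the
#' flat-field, Gaussian-smooth each frame and clamp at zero.
#'
#' @param video a [TirfVideo-class] calcium stack.
#' @param flatfield optional (y, x) matrix of relative illumination; must
#'   be positive everywhere. It is normalised to mean 1 before division.
#' @param backgroundFrames number of initial frames whose per-pixel median
#'   is taken as static background (0 disables subtraction).
#' @param smoothSigma spatial Gaussian sigma in pixels.
#' @return corrected [TirfVideo-class].
#' @export
preprocessCalciumVideo <- function(video, flatfield = NULL,
                                   backgroundFrames = 5, smoothSigma = 1) {
    stopifnot(is(video, "TirfVideo"))
    arr <- videoData(video)
    nt <- dim(arr)[1L]
    if (backgroundFrames > 0) {
        nb <- min(backgroundFrames, nt)
        bg <- apply(arr[seq_len(nb), , , drop = FALSE], c(2L, 3L), median)
        arr <- sweep(arr, c(2L, 3L), bg, `-`)
    }
    if (!is.null(flatfield)) {
        if (any(flatfield <= 0))
            stop("flat-field must be positive everywhere")
        ff <- flatfield / mean(flatfield)
        arr <- sweep(arr, c(2L, 3L), ff, `/`)
    }
    if (smoothSigma > 0) arr <- .gaussXY(arr, smoothSigma)
    arr[arr < 0] <- 0
    TirfVideo(arr, pixelSize(video), frameInterval(video), video@channel)
}

# 8-connected local maxima of a matrix above a threshold. Plateaus are
# collapsed to their centroid. Returns a matrix (y, x) of pixel indices.
.localMaxima <- function(m, threshold) {
    ny <- nrow(m); nx <- ncol(m)
    if (ny < 3L || nx < 3L) return(matrix(0, 0, 2))
    ge <- matrix(TRUE, ny, nx)
    for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        sh <- matrix(-Inf, ny, nx)
        ys <- max(1, 1 + dy):min(ny, ny + dy)
        xs <- max(1, 1 + dx):min(nx, nx + dx)
        sh[ys, xs] <- m[ys - dy, xs - dx]
        ge <- ge & (m >= sh)
    }
    cand <- ge & (m > threshold)
    if (!any(cand)) return(matrix(0, 0, 2))
    lab <- EBImage::bwlabel(cand)
    ids <- seq_len(max(lab))
    out <- t(vapply(ids, function(i) {
        w <- which(lab == i, arr.ind = TRUE)
        colMeans(w)
    }, numeric(2)))
    colnames(out) <- c("y", "x")
    out
}

#' Track cells as linked calcium maxima
#'
#' Detects local intensity maxima per frame and links them across frames
#' with a greedy nearest-neighbour rule: candidate links are sorted by
#' distance and accepted while each maximum and each open track is used at
#' most once and the distance stays below \code{maxLinkDistance}.
#' Unmatched maxima open new tracks; tracks are never gap-closed.
#'
#' @param video preprocessed [TirfVideo-class].
#' @param detectionThreshold intensity threshold for maxima.
#' @param maxLinkDistance maximum frame-to-frame link distance in um.
#' @return list of tracks; each has \code{id}, \code{frames} (1-based
#'   indices), \code{pos} (um, columns y/x), \code{intensity} (mean over
#'   the 3x3 neighbourhood of the maximum), \code{startTime} (s).
#' @export
trackCells <- function(video, detectionThreshold, maxLinkDistance = 10) {
    stopifnot(is(video, "TirfVideo"))
    px_um <- pixelSize(video) / 1000
    nt <- nFrames(video)
    tracks <- list()
    open <- integer()      # track indices still linkable
    for (t in seq_len(nt)) {
        fr <- frameData(video, t)
        mx <- .localMaxima(fr, detectionThreshold)
        used <- rep(FALSE, nrow(mx))
        matched <- rep(FALSE, length(open))
        if (nrow(mx) && length(open)) {
            heads <- t(vapply(tracks[open], function(tr)
                tr$pos[nrow(tr$pos), ], numeric(2)))
            dmat <- sqrt(outer(heads[, 1], mx[, 1] * px_um, `-`)^2 +
                         outer(heads[, 2], mx[, 2] * px_um, `-`)^2)
            ord <- order(dmat)
            for (k in ord) {
                if (dmat[k] > maxLinkDistance) break
                i <- (k - 1L) %% nrow(dmat) + 1L
                j <- (k - 1L) %/% nrow(dmat) + 1L
                if (matched[i] || used[j]) next
                matched[i] <- TRUE; used[j] <- TRUE
                ti <- open[i]
                tracks[[ti]]$frames <- c(tracks[[ti]]$frames, t)
                tracks[[ti]]$pos <- rbind(tracks[[ti]]$pos,
                                          mx[j, ] * px_um)
                tracks[[ti]]$intensity <- c(tracks[[ti]]$intensity,
                                            .meanAt(fr, mx[j, ]))
            }
        }
        for (j in which(!used)) {
            tracks[[length(tracks) + 1L]] <- list(
                id = length(tracks) + 1L,
                frames = t,
                pos = matrix(mx[j, ] * px_um, 1, 2,
                             dimnames = list(NULL, c("y", "x"))),
                intensity = .meanAt(fr, mx[j, ]),
                startTime = (t - 1) * frameInterval(video))
        }
        open <- which(vapply(tracks, function(tr)
            tail(tr$frames, 1L) == t, logical(1)))
    }
    tracks
}

.meanAt <- function(fr, yx) {
    y <- round(yx[1]); x <- round(yx[2])
    ys <- max(1, y - 1):min(nrow(fr), y + 1)
    xs <- max(1, x - 1):min(ncol(fr), x + 1)
    mean(fr[ys, xs])
}

#' Classify cell adhesion from a position track
#'
#' A cell is adhered once its frame-to-frame speed drops below
#' \code{speedThreshold} and stays there for the remainder of the track.
#' The default 0.2 um/s reflects the essentially immobile interaction of
#' Jurkat cells with unblocked glass.
#'
#' @param track a track from [trackCells()] (needs \code{pos},
#'   \code{frames}) or a bare (n, 2) position matrix in um.
#' @param speedThreshold um/s.
#' @param frameInterval seconds between track samples (taken from
#'   consecutive frame indices when the track carries them).
#' @return list with \code{adhered}, \code{adhesionTime} (s, relative to
#'   track start; NA when never adhered) and \code{speed} (um/s, one value
#'   per step).
#' @export
classifyAdhesion <- function(track, speedThreshold = 0.2,
                             frameInterval = 1) {
    pos <- if (is.list(track)) track$pos else track
    if (nrow(pos) < 2L)
        stop("track must span at least 2 frames")
    dt <- frameInterval
    steps <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
    speed <- steps / dt
    below <- rev(cumprod(rev(speed < speedThreshold))) > 0
    if (!any(below))
        return(list(adhered = FALSE, adhesionTime = NA_real_,
                    speed = speed))
    k <- which(below)[1L]
    list(adhered = TRUE, adhesionTime = (k - 1) * dt, speed = speed)
}

#' Detect calcium triggering in a single-cell trace
#'
#' The baseline is the mean of the lowest decile of intensities within the
#' first \code{baselineWindow} seconds of the track; the trace is
#' normalised so that baseline = 1. A trigger is the first upward crossing
#' of \code{foldChange} that stays at or above it for at least
#' \code{minDuration} seconds. Cells whose trigger falls within
#' \code{earlyExclusion} seconds of track start are flagged
#' \code{excludedEarly}: their apparent response is typically a settling
#' artefact, and they are removed from population denominators.
#'
#' @param trace numeric intensity vector, or a track from [trackCells()].
#' @param frameInterval seconds per sample.
#' @param foldChange trigger threshold as a multiple of baseline.
#' @param minDuration seconds the trace must stay above threshold.
#' @param earlyExclusion seconds; triggers earlier than this are excluded.
#' @param baselineWindow seconds of initial track used for the baseline.
#' @param smooth logical; measure the fold change on a 3-sample running
#'   mean of the normalised trace (the default) rather than the raw one.
#' @return list with \code{triggered}, \code{triggerTime} (s, relative to
#'   track start; NA if none), \code{excludedEarly}, \code{baseline},
#'   \code{normalized}.
#' @export
detectTrigger <- function(trace, frameInterval = 1, foldChange = 3,
                          minDuration = 10, earlyExclusion = 40,
                          baselineWindow = 60, smooth = TRUE) {
    if (is.list(trace)) {
        frameInterval <- if (!is.null(trace$frameInterval))
            trace$frameInterval else frameInterval
        trace <- trace$intensity
    }
    n <- length(trace)
    dt <- frameInterval
    if (n * dt < minDuration)
        stop("trace shorter than the minimum trigger duration")
    nb <- max(1L, min(n, ceiling(baselineWindow / dt)))
    early <- trace[seq_len(nb)]
    lowest <- sort(early)[seq_len(max(1L, floor(0.1 * nb)))]
    baseline <- mean(lowest)
    if (!is.finite(baseline) || baseline <= 0)
        stop("cannot establish a positive baseline (all-zero trace?)")
    norm <- trace / baseline
    work <- if (smooth && n >= 3L) {
        w <- norm
        w[2:(n - 1L)] <- (norm[1:(n - 2L)] + norm[2:(n - 1L)] +
                          norm[3:n]) / 3
        w
    } else norm
    need <- max(1L, ceiling(minDuration / dt))
    above <- work >= foldChange
    trig <- NA_integer_
    run <- rle(above)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (k in seq_along(run$values)) {
        if (run$values[k] && run$lengths[k] >= need) {
            trig <- starts[k]
            break
        }
    }
    if (is.na(trig))
        return(list(triggered = FALSE, triggerTime = NA_real_,
                    excludedEarly = FALSE, baseline = baseline,
                    normalized = norm))
    tt <- (trig - 1L) * dt
    if (tt < earlyExclusion)
        return(list(triggered = FALSE, triggerTime = tt,
                    excludedEarly = TRUE, baseline = baseline,
                    normalized = norm))
    list(triggered = TRUE, triggerTime = tt, excludedEarly = FALSE,
         baseline = baseline, normalized = norm)
}

#' Summarise adhesion and signalling over a cell population
#'
#' Builds cumulative fraction-versus-time curves for adhesion and calcium
#' triggering and fits a logistic curve with the lower asymptote fixed at
#' 0 and the upper asymptote fixed at the configured plateau (1.0 for
#' adhesion; 0.8 for signalling, the empirical ceiling of responding
#' cells). The time at which half of all cells have responded is read
#' from the fit, falling back to the empirical crossing of 0.5 when the
#' fit cannot converge.
#'
#' @param cellTable data.frame with columns \code{triggerTime},
#'   \code{excludedEarly}, \code{adhesionTime} (seconds; NA = no event).
#' @param plateauSignal,plateauAdhesion fixed upper asymptotes.
#' @return list with \code{fractionSignaling}, \code{fractionAdhered},
#'   \code{timeTo50Signal}, \code{timeTo50Adhesion} (s; NA when fewer than
#'   half the cells respond), the fitted curves, and the per-cell table.
#' @export
summarizePopulation <- function(cellTable, plateauSignal = 0.8,
                                plateauAdhesion = 1.0) {
    stopifnot(is.data.frame(cellTable))
    keep <- !isTRUE0(cellTable$excludedEarly)
    tab <- cellTable[keep, , drop = FALSE]
    if (nrow(tab) < 1L) stop("no non-excluded cells")
    sig <- .cdfSummary(tab$triggerTime, nrow(tab), plateauSignal)
    adh <- .cdfSummary(tab$adhesionTime, nrow(tab), plateauAdhesion)
    list(fractionSignaling = sig$fraction, fractionAdhered = adh$fraction,
         timeTo50Signal = sig$t50, timeTo50Adhesion = adh$t50,
         signalCurve = sig$curve, adhesionCurve = adh$curve,
         cells = tab)
}

isTRUE0 <- function(x) if (is.null(x)) FALSE else x %in% TRUE

# Cumulative-fraction curve, constrained sigmoid fit and time-to-50%.
# Two families with lower asymptote 0 and upper asymptote fixed at the
# plateau are tried -- a logistic in time and a delayed saturating
# exponential (the natural shape for settle-and-trigger kinetics) -- and
# the better-fitting one (residual sum of squares) supplies the curve
# from which the 50%-of-all-cells time is read.
.cdfSummary <- function(times, nTotal, plateau) {
    ev <- sort(times[!is.na(times)])
    frac <- length(ev) / nTotal
    if (!length(ev))
        return(list(fraction = 0, t50 = NA_real_, curve = NULL))
    tt <- ev
    ff <- seq_along(ev) / nTotal
    curve <- data.frame(time_s = tt, fraction = ff)
    fit <- NULL
    t50 <- NA_real_
    if (length(unique(tt)) >= 3L) {
        fitLog <- tryCatch(minpack.lm::nlsLM(
            ff ~ plateau / (1 + exp(-(tt - m) / s)),
            start = list(m = median(tt), s = max(sd(tt) / 2, 1e-3)),
            lower = c(m = 0, s = 1e-6),
            control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL)
        fitExp <- tryCatch(minpack.lm::nlsLM(
            ff ~ plateau * (1 - exp(-pmax(tt - t0, 0) / tau)),
            start = list(t0 = max(min(tt) / 2, 1e-3),
                         tau = max(median(tt), 1e-3)),
            lower = c(t0 = 0, tau = 1e-6),
            control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL)
        rss <- function(f) if (is.null(f)) Inf else
            sum(stats::residuals(f)^2)
        fit <- if (rss(fitExp) < rss(fitLog)) fitExp else fitLog
    }
    if (!is.null(fit) && plateau > 0.5) {
        p <- coef(fit)
        t50 <- if ("m" %in% names(p)) {
            p[["m"]] - p[["s"]] * log(plateau / 0.5 - 1)
        } else {
            p[["t0"]] - p[["tau"]] * log(1 - 0.5 / plateau)
        }
        if (t50 < 0) t50 <- 0
    } else if (frac >= 0.5) {
        t50 <- tt[which(ff >= 0.5)[1L]]
    }
    if (frac < 0.5) t50 <- NA_real_
    list(fraction = frac, t50 = t50, curve = curve, fit = fit)
}
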