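#' Build inside/outside region pairs around close contacts
#'
#' For each close contact and frame, the "inside" region is the contact
#' mask and the "outside" region is the ring obtained by dilating the
#' inside by \code{dilation_px} pixels and removing the inside itself.
#' Rings are refined by removing every other contact's inside region and,
#' when the protein of interest sits on the cell, restricted to the
#' segmented cell area so that the dark bilayer beyond the membrane edge
#' cannot fake a depletion.
#'
#' @param contactLabels [LabelVolume-class] of kind \code{"close_contact"}.
#' @param dilation_px ring width in pixels (default 10).
#' @param cellMask optional logical (time, y, x) array (or
#'   [LabelVolume-class]) of segmented cell area.
#' @param proteinOnCell logical; restrict rings to the cell mask.
#' @return list of region pairs: \code{contactId}, \code{frame},
#'   \code{inside}, \code{outside} (linear pixel indices into the frame
#'   matrix) and \code{dim}. Pairs whose refined ring is empty are
#'   dropped with a warning.
#' @export
buildRegionPairs <- function(contactLabels, dilation_px = 10,
                             cellMask = NULL, proteinOnCell = FALSE) {
    stopifnot(is(contactLabels, "LabelVolume"))
    lab <- labelData(contactLabels)
    nt <- dim(lab)[1L]
    if (proteinOnCell && is.null(cellMask))
        stop("proteinOnCell = TRUE requires a cellMask")
    cm <- if (is(cellMask, "LabelVolume")) labelData(cellMask) > 0L else
        cellMask
    brush <- EBImage::makeBrush(2L * dilation_px + 1L, "disc")
    pairs <- list()
    for (t in seq_len(nt)) {
        fr <- lab[t, , ]
        ids <- setdiff(unique(as.vector(fr)), 0L)
        if (!length(ids)) next
        anyInside <- fr > 0L
        for (id in sort(ids)) {
            inside <- fr == id
            ring <- EBImage::dilate(EBImage::Image(inside * 1),
                                    brush) > 0.5
            ring <- as.matrix(ring) & !anyInside
            if (proteinOnCell) ring <- ring & cm[t, , ]
            if (!any(ring)) {
                warning("contact ", id, " frame ", t,
                        ": refined ring is empty; pair dropped")
                next
            }
            pairs[[length(pairs) + 1L]] <- list(
                contactId = id, frame = t,
                inside = which(inside), outside = which(ring),
                dim = dim(fr))
        }
    }
    pairs
}

#' Protein enrichment at a close contact
#'
#' Ratio of the mean protein intensity inside the contact to the mean in
#' the surrounding ring: values above 1 indicate enrichment, below 1
#' depletion.
#'
#' @param image (y, x) protein-channel frame (flat-field corrected).
#' @param pair one region pair from [buildRegionPairs()].
#' @return the ratio, or NA (with a warning) when the outside mean is 0.
#' @export
enrichment <- function(image, pair) {
    mi <- mean(image[pair$inside])
    mo <- mean(image[pair$outside])
    if (!is.finite(mo) || mo == 0) {
        warning("outside mean is zero; enrichment undefined")
        return(NA_real_)
    }
    mi / mo
}

#' CD45-style exclusion at a close contact
#'
#' \code{1 - perc10(I_inside) / mean(I_outside)}: the 10th percentile of
#' intensities inside the contact relative to the mean of the ring
#' region. Positive values indicate exclusion; negative values indicate
#' enrichment.
#'
#' @inheritParams enrichment
#' @return the exclusion fraction, or NA when the outside mean is 0.
#' @export
cd45Exclusion <- function(image, pair) {
    p10 <- quantile(image[pair$inside], 0.1, names = FALSE, type = 7)
    mo <- mean(image[pair$outside])
    if (!is.finite(mo) || mo == 0) {
        warning("outside mean is zero; exclusion undefined")
        return(NA_real_)
    }
    1 - p10 / mo
}

# shared preprocessing for single-molecule counting: 5-frame temporal
# running mean followed by a 1-px Gaussian blur
.smProcess <- function(video, window = 5, sigma = 1) {
    arr <- .runningMeanT(videoData(video), window)
    .gaussXY(arr, sigma)
}

#' Calibrate the single-molecule detection threshold
#'
#' The threshold for counting bound ligands is set on an image stack
#' acquired before cells are added: after the standard processing
#' (5-frame running mean, 1-px Gaussian blur) the returned threshold is
#' the smallest value at which fewer than 2 local maxima are detected in
#' the whole stack.
#'
#' @param preCellStack [TirfVideo-class] acquired without cells.
#' @param window,sigma processing parameters.
#' @return the threshold (a.u.).
#' @export
calibrateSmThreshold <- function(preCellStack, window = 5, sigma = 1) {
    stopifnot(is(preCellStack, "TirfVideo"))
    proc <- .smProcess(preCellStack, window, sigma)
    if (diff(range(proc)) <= 1e-10 * max(abs(proc), 1))
        stop("cannot calibrate: stack is constant (saturated?)")
    vals <- numeric()
    for (t in seq_len(dim(proc)[1L])) {
        mx <- .localMaxima(proc[t, , ], -Inf)
        if (nrow(mx))
            vals <- c(vals, proc[t, , ][cbind(round(mx[, 1]),
                                              round(mx[, 2]))])
    }
    if (length(vals) < 2L)
        stop("cannot calibrate: fewer than 2 local maxima in the stack")
    sort(vals, decreasing = TRUE)[2L]
}

#' Count single bound ligands at close contacts
#'
#' Processes the stack like [calibrateSmThreshold()], detects local
#' maxima strictly above the threshold per frame, and assigns each
#' detection to the close contact (if any) containing it. Diffusing
#' molecules are motion-blurred below threshold by the long exposure, so
#' only bound (immobile) molecules are counted. The signalling timepoint
#' is the maximum of the central-difference gradient of the (smoothed)
#' calcium trace.
#'
#' @param video single-molecule channel [TirfVideo-class].
#' @param contactLabels optional [LabelVolume-class] of close contacts.
#' @param calciumTrace optional numeric per-frame calcium trace.
#' @param threshold detection threshold from [calibrateSmThreshold()].
#' @param window,sigma processing parameters.
#' @return list with \code{perFrame} (data.frame: frame, time_s, n_total,
#'   n_in_contacts), \code{detections} (data.frame: frame, y_px, x_px,
#'   contactId), \code{perContact} (named vector: maximum simultaneous
#'   count per contact) and \code{signalingFrame} (NA without a trace).
#' @export
countBoundMolecules <- function(video, contactLabels = NULL,
                                calciumTrace = NULL, threshold,
                                window = 5, sigma = 1) {
    stopifnot(is(video, "TirfVideo"))
    proc <- .smProcess(video, window, sigma)
    nt <- dim(proc)[1L]
    dt <- frameInterval(video)
    clab <- if (!is.null(contactLabels)) labelData(contactLabels) else NULL
    det <- list()
    perFrame <- data.frame(frame = seq_len(nt),
                           time_s = (seq_len(nt) - 1) * dt,
                           n_total = 0L, n_in_contacts = 0L)
    for (t in seq_len(nt)) {
        mx <- .localMaxima(proc[t, , ], threshold)
        if (!nrow(mx)) next
        cid <- rep(NA_integer_, nrow(mx))
        if (!is.null(clab)) {
            cid <- clab[cbind(t, round(mx[, 1]), round(mx[, 2]))]
            cid[cid == 0L] <- NA_integer_
        }
        perFrame$n_total[t] <- nrow(mx)
        perFrame$n_in_contacts[t] <- sum(!is.na(cid))
        det[[length(det) + 1L]] <- data.frame(
            frame = t, y_px = mx[, 1], x_px = mx[, 2], contactId = cid)
    }
    detections <- if (length(det)) do.call(rbind, det) else
        data.frame(frame = integer(), y_px = numeric(), x_px = numeric(),
                   contactId = integer())
    perContact <- integer()
    hit <- detections[!is.na(detections$contactId), ]
    if (nrow(hit)) {
        counts <- table(hit$contactId, hit$frame)
        perContact <- apply(counts, 1L, max)
    }
    sigFrame <- NA_integer_
    if (!is.null(calciumTrace) && length(calciumTrace) >= 3L) {
        n <- length(calciumTrace)
        sm <- calciumTrace
        sm[2:(n - 1L)] <- (calciumTrace[1:(n - 2L)] +
                           calciumTrace[2:(n - 1L)] +
                           calciumTrace[3:n]) / 3
        grad <- c(sm[2L] - sm[1L],
                  (sm[3:n] - sm[1:(n - 2L)]) / 2,
                  sm[n] - sm[n - 1L])
        sigFrame <- which.max(grad)
    }
    list(perFrame = perFrame, detections = detections,
         perContact = perContact, signalingFrame = sigFrame)
}
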