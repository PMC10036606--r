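#' Segmentation configuration
#'
#' All tunable parameters of the membrane and close-contact segmentation.
#' Hysteresis bounds and the late-contact threshold are expressed as
#' multiples of the SD of the filtered image computed over pixels outside
#' segmented cell areas ("notCZ" statistics, recomputed per frame).
#'
#' @param h_low,h_high lower/upper hysteresis bounds for the LoG-filtered
#'   glycocalyx image, in SD multiples (defaults 3 and 5.5, calibrated on
#'   rendered fixtures for zero false positives on contact-free videos).
#' @param h2 late-contact threshold in SD multiples below the notCZ mean
#'   of the Gaussian-filtered image (default 3).
#' @param dog_sigma_small small sigma (px) of the membrane DoG filter.
#' @param dog_sigma_large large sigma (px); default \code{cellRadius/2}
#'   in pixels, also used for seed detection.
#' @param gauss_sigma_xy spatial Gaussian sigma (px) for the glycocalyx
#'   channel.
#' @param rolling_ball_radius_t temporal running-mean window in frames.
#' @param cell_radius expected cell radius in um (seed separation).
#' @param min_cell_area minimum cell mask area in um^2.
#' @param min_contact_area_px minimum close-contact area in pixels
#'   (default 4; with the temporal filtering this suppresses residual
#'   noise blobs while keeping sub-diffraction contacts).
#' @param erosion_radius_px structuring-disc radius for the late-contact
#'   erosion.
#' @param global_threshold custom global threshold on the membrane DoG
#'   image; \code{NULL} uses the Otsu threshold alone.
#' @return list of class \code{SegmentationConfig}.
#' @examples
#' cfg <- segmentationConfig()
#' cfg$h_high
#' @export
segmentationConfig <- function(h_low = 3, h_high = 5.5, h2 = 3,
                               dog_sigma_small = 1, dog_sigma_large = NULL,
                               gauss_sigma_xy = 2,
                               rolling_ball_radius_t = 5,
                               cell_radius = 5, min_cell_area = 20,
                               min_contact_area_px = 4,
                               erosion_radius_px = 2,
                               global_threshold = NULL) {
    stopifnot(h_low < h_high, h_low > 0, gauss_sigma_xy > 0,
              dog_sigma_small > 0, min_contact_area_px >= 1)
    structure(list(
        h_low = h_low, h_high = h_high, h2 = h2,
        dog_sigma_small = dog_sigma_small,
        dog_sigma_large = dog_sigma_large,
        gauss_sigma_xy = gauss_sigma_xy,
        rolling_ball_radius_t = rolling_ball_radius_t,
        cell_radius = cell_radius, min_cell_area = min_cell_area,
        min_contact_area_px = min_contact_area_px,
        erosion_radius_px = erosion_radius_px,
        global_threshold = global_threshold),
        class = "SegmentationConfig")
}

#' Minimum reportable close-contact area
#'
#' Segmentation is pixel-based, so the smallest detectable contact is one
#' camera pixel.
#'
#' @param pixelSize_nm pixel edge length in nm (default 107).
#' @return area of one pixel in um^2 (0.011 um^2 at 107 nm).
#' @export
minContactArea <- function(pixelSize_nm = 107) (pixelSize_nm / 1000)^2

#' Remove a linearly increasing background from the membrane channel
#'
#' Membrane dye progressively stains the bilayer itself, producing a
#' background that grows linearly in time. The background level of each
#' frame is estimated from its dimmest pixels (assumed cell-free), a line
#' is fitted over frames, and the fitted increase relative to the
#' intercept is subtracted, leaving cell contrast untouched.
#'
#' @param video a [TirfVideo-class] membrane stack with >= 3 frames.
#' @param dimFraction fraction of dimmest pixels per frame used to
#'   estimate the background level.
#' @return corrected [TirfVideo-class].
#' @export
correctMembraneBackground <- function(video, dimFraction = 0.2) {
    stopifnot(is(video, "TirfVideo"))
    arr <- videoData(video)
    nt <- dim(arr)[1L]
    if (nt < 3L) stop("need at least 3 frames to fit a linear background")
    lev <- vapply(seq_len(nt), function(t) {
        v <- sort(as.vector(arr[t, , ]))
        mean(v[seq_len(max(1L, floor(dimFraction * length(v))))])
    }, numeric(1))
    tt <- seq_len(nt)
    fit <- lm(lev ~ tt)
    trend <- predict(fit) - coef(fit)[1L] - coef(fit)[2L]
    # subtract the increase relative to the first frame's fitted level
    for (t in seq_len(nt)) arr[t, , ] <- arr[t, , ] - trend[t]
    TirfVideo(arr, pixelSize(video), frameInterval(video), video@channel)
}

# Otsu threshold of a numeric vector (256-bin histogram).
.otsu <- function(v, nbins = 256L) {
    r <- range(v)
    if (diff(r) == 0) return(r[1])
    h <- tabulate(pmin(nbins, 1L + floor((v - r[1]) / diff(r) * nbins)),
                  nbins)
    p <- h / sum(h)
    mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
    w0 <- cumsum(p)
    mu <- cumsum(p * mids)
    muT <- mu[nbins]
    between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
    between[!is.finite(between)] <- 0
    mids[which.max(between)]
}

# per-frame DoG filter of a (time, y, x) array
.dog <- function(arr, sSmall, sLarge)
    .gaussXY(arr, sSmall) - .gaussXY(arr, sLarge)

#' Segment the cell membrane channel
#'
#' Each frame is band-passed with a difference-of-Gaussians filter and
#' thresholded with the union of a custom global threshold and the Otsu
#' threshold of the filtered frame; components smaller than
#' \code{min_cell_area} are dropped.
#'
#' @param video background-corrected membrane [TirfVideo-class].
#' @param config a [segmentationConfig()].
#' @return logical (time, y, x) mask array.
#' @export
segmentMembrane <- function(video, config = segmentationConfig()) {
    stopifnot(is(video, "TirfVideo"))
    arr <- videoData(video)
    px_um <- pixelSize(video) / 1000
    sLarge <- if (is.null(config$dog_sigma_large))
        config$cell_radius / px_um / 2 else config$dog_sigma_large
    d <- .dog(arr, config$dog_sigma_small, sLarge)
    minpx <- max(1L, round(config$min_cell_area / px_um^2))
    mask <- array(FALSE, dim(arr))
    nt <- dim(arr)[1L]
    for (t in seq_len(nt)) {
        fr <- d[t, , ]
        # Otsu assumes a bimodal histogram; on a cell-free noise frame it
        # would split the noise itself. It is therefore floored at a
        # noise bound whose scale comes from the temporal frame
        # difference (static structure cancels there), falling back to
        # the spatial MAD for single-frame stacks.
        sigma <- if (nt > 1L) {
            tn <- if (t < nt) t + 1L else t - 1L
            stats::mad(fr - d[tn, , ]) / sqrt(2)
        } else stats::mad(fr)
        thr <- max(.otsu(as.vector(fr)), median(fr) + 5 * sigma)
        if (!is.null(config$global_threshold))
            thr <- min(thr, config$global_threshold)
        m <- fr > thr
        if (any(m)) {
            lab <- EBImage::bwlabel(m)
            sz <- tabulate(lab[lab > 0L])
            drop <- which(sz < minpx)
            if (length(drop)) m[lab %in% drop] <- FALSE
        }
        mask[t, , ] <- m
    }
    mask
}

# 26-connected label propagation of seed labels through a 3-d mask:
# a geodesic watershed on the binary mask. Ties go to the lowest label.
.propagateLabels <- function(labels, mask) {
    off <- .offsets3d("full")
    dims <- dim(mask)
    repeat {
        best <- array(.Machine$integer.max, dims)
        for (o in off) {
            dt <- o[1L]; dy <- o[2L]; dx <- o[3L]
            src_t <- max(1, 1 - dt):min(dims[1], dims[1] - dt)
            src_y <- max(1, 1 - dy):min(dims[2], dims[2] - dy)
            src_x <- max(1, 1 - dx):min(dims[3], dims[3] - dx)
            sh <- array(.Machine$integer.max, dims)
            sh[src_t + dt, src_y + dy, src_x + dx] <-
                labels[src_t, src_y, src_x]
            sh[sh == 0L] <- .Machine$integer.max
            best <- pmin(best, sh)
        }
        # fill only still-unlabelled mask voxels; seeds never change
        upd <- mask & labels == 0L & best < .Machine$integer.max
        if (!any(upd)) break
        labels[upd] <- best[upd]
    }
    labels
}

#' Label cells with a spatiotemporal watershed
#'
#' Seeds are the local maxima of the large-sigma DoG filter on the last
#' membrane frame, thinned to a minimum separation of one cell radius
#' (optionally overridden or supplemented by explicit seeds). Labels are
#' grown through the 3-d (time, y, x) mask by geodesic propagation, so a
#' cell keeps one label across its whole history. Mask components not
#' reached from any seed are attached to the nearest labelled region
#' within twice the cell radius (Euclidean distance in (x, y, t), pixels
#' and frames), else dropped.
#'
#' @param mask logical (time, y, x) array from [segmentMembrane()].
#' @param video the membrane [TirfVideo-class] (for seed detection and
#'   calibration).
#' @param config a [segmentationConfig()].
#' @param seedOverrides optional data.frame (t, y, x, label) of manual
#'   seed pixels (1-based indices) replacing the automatic ones.
#' @return a [LabelVolume-class] of kind \code{"cell"}.
#' @export
labelCells <- function(mask, video, config = segmentationConfig(),
                       seedOverrides = NULL) {
    stopifnot(is(video, "TirfVideo"))
    dims <- dim(mask)
    nt <- dims[1L]
    px_um <- pixelSize(video) / 1000
    rad_px <- config$cell_radius / px_um
    labels <- array(0L, dims)
    if (!is.null(seedOverrides)) {
        for (i in seq_len(nrow(seedOverrides)))
            labels[seedOverrides$t[i], seedOverrides$y[i],
                   seedOverrides$x[i]] <- as.integer(seedOverrides$label[i])
    } else {
        sLarge <- if (is.null(config$dog_sigma_large))
            rad_px / 2 else config$dog_sigma_large
        last <- .gaussXY(videoData(video)[nt, , , drop = FALSE],
                         sLarge)[1L, , ]
        mx <- .localMaxima(last, -Inf)
        if (nrow(mx)) {
            mx <- mx[mask[cbind(nt, round(mx[, 1]), round(mx[, 2]))], ,
                     drop = FALSE]
        }
        if (nrow(mx)) {
            # thin by intensity: strongest first, drop closer than radius
            ints <- last[cbind(round(mx[, 1]), round(mx[, 2]))]
            mx <- mx[order(-ints), , drop = FALSE]
            keep <- rep(TRUE, nrow(mx))
            for (i in seq_len(nrow(mx))) {
                if (!keep[i]) next
                if (i < nrow(mx)) {
                    d <- sqrt((mx[-(1:i), 1] - mx[i, 1])^2 +
                              (mx[-(1:i), 2] - mx[i, 2])^2)
                    keep[-(1:i)][d < rad_px] <- FALSE
                }
            }
            mx <- mx[keep, , drop = FALSE]
        }
        if (!nrow(mx))
            stop("no cell seeds found on the last frame (frame ", nt,
                 "); provide seedOverrides")
        # deterministic label order: top-left first
        mx <- mx[order(mx[, 1], mx[, 2]), , drop = FALSE]
        for (i in seq_len(nrow(mx)))
            labels[nt, round(mx[i, 1]), round(mx[i, 2])] <- i
    }
    labels[!mask] <- 0L
    if (!any(labels > 0L))
        stop("no seed lies inside the mask; provide seedOverrides")
    labels <- .propagateLabels(labels, mask)

    # orphan components: nearest labelled voxel within 2 * radius
    orphan <- mask & labels == 0L
    if (any(orphan)) {
        lv <- which(labels > 0L, arr.ind = TRUE)
        lvals <- labels[lv]
        comp <- .label3d(orphan)
        for (id in seq_len(max(comp))) {
            vox <- which(comp == id, arr.ind = TRUE)
            best <- Inf; bestLab <- 0L
            for (r in seq_len(nrow(vox))) {
                d2 <- (lv[, 1] - vox[r, 1])^2 + (lv[, 2] - vox[r, 2])^2 +
                      (lv[, 3] - vox[r, 3])^2
                j <- which.min(d2)
                if (d2[j] < best) { best <- d2[j]; bestLab <- lvals[j] }
            }
            if (sqrt(best) <= 2 * rad_px)
                labels[comp == id] <- bestLab
        }
    }
    LabelVolume(labels, "cell", pixelSize(video), frameInterval(video))
}

# Neighbourhood offset sets for 3-d labelling. "full" is 26-connectivity;
# "overlap" connects 8-neighbours in-plane plus voxels at the same (y, x)
# in consecutive frames (the temporal-overlap rule for contact tracking).
.offsets3d <- function(type = c("full", "overlap")) {
    type <- match.arg(type)
    off <- list()
    for (dt in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dt == 0 && dy == 0 && dx == 0) next
        if (type == "overlap" && dt != 0 && (dy != 0 || dx != 0)) next
        off[[length(off) + 1L]] <- c(dt, dy, dx)
    }
    off
}

# 3-d connected components via iterative min-label propagation; adequate
# for the modest volumes handled here.
.label3d <- function(mask, connectivity = "full") {
    off <- .offsets3d(connectivity)
    labels <- array(0L, dim(mask))
    labels[mask] <- seq_len(sum(mask))
    repeat {
        prev <- labels
        labels <- .minNeighbor(labels, mask, off)
        if (identical(labels, prev)) break
    }
    # compact to 1..n by first appearance
    u <- unique(labels[labels > 0L])
    out <- labels
    out[labels > 0L] <- match(labels[labels > 0L], sort(u))
    out
}

.minNeighbor <- function(labels, mask, off) {
    dims <- dim(labels)
    out <- labels
    for (o in off) {
        dt <- o[1L]; dy <- o[2L]; dx <- o[3L]
        src_t <- max(1, 1 - dt):min(dims[1], dims[1] - dt)
        src_y <- max(1, 1 - dy):min(dims[2], dims[2] - dy)
        src_x <- max(1, 1 - dx):min(dims[3], dims[3] - dx)
        sh <- array(.Machine$integer.max, dims)
        sh[src_t + dt, src_y + dy, src_x + dx] <- labels[src_t, src_y, src_x]
        sh[sh == 0L] <- .Machine$integer.max
        upd <- mask & sh < out
        out[upd] <- sh[upd]
    }
    out
}

#' Flat-field correct a video
#'
#' The flat-field is the time-sum of a cell-free reference stack,
#' normalised to mean 1; every frame of the input is divided by it.
#'
#' @param video a [TirfVideo-class].
#' @param flatfieldStack a [TirfVideo-class] reference stack (no cells)
#'   or a (y, x) matrix.
#' @return corrected [TirfVideo-class].
#' @export
flatfieldCorrect <- function(video, flatfieldStack) {
    stopifnot(is(video, "TirfVideo"))
    ff <- if (is(flatfieldStack, "TirfVideo")) {
        apply(videoData(flatfieldStack), c(2L, 3L), sum)
    } else flatfieldStack
    if (any(ff <= 0)) stop("flat-field contains non-positive pixels")
    ff <- ff / mean(ff)
    arr <- sweep(videoData(video), c(2L, 3L), ff, `/`)
    TirfVideo(arr, pixelSize(video), frameInterval(video), video@channel)
}

#' Segment close contacts in the glycocalyx channel
#'
#' The flat-field-corrected glycocalyx stack is smoothed with a temporal
#' running mean and a spatial Gaussian; the Laplacian of the result gives
#' a LoG filter whose response is positive inside dark exclusion spots.
#' Two detectors are combined: (i) a hysteresis threshold on the LoG image
#' with bounds \code{h_low} / \code{h_high} notCZ SDs, and (ii) a
#' late-contact detector thresholding the edge-enhanced image (Gaussian +
#' LoG) at \code{mean - h2 * SD} of the notCZ statistics, followed by a
#' morphological erosion. notCZ statistics are computed per frame over
#' pixels outside segmented cell areas. Components below
#' \code{min_contact_area_px} are removed; detections overlapping in
#' consecutive frames share one contact label, and each contact is mapped
#' to the cell label it overlaps most.
#'
#' @param video flat-field-corrected glycocalyx [TirfVideo-class].
#' @param cellLabels optional [LabelVolume-class] of kind "cell".
#' @param config a [segmentationConfig()].
#' @param restrict logical; clip contacts to their owning cell's mask
#'   (requires \code{cellLabels}).
#' @return a [LabelVolume-class] of kind \code{"close_contact"} whose
#'   \code{owners} slot maps contact labels to cell labels.
#' @export
segmentCloseContacts <- function(video, cellLabels = NULL,
                                 config = segmentationConfig(),
                                 restrict = !is.null(cellLabels)) {
    stopifnot(is(video, "TirfVideo"))
    if (restrict && is.null(cellLabels)) {
        warning("restriction requested but no cell labels given; ",
                "returning an empty result")
        return(LabelVolume(array(0L, dim(videoData(video))),
                           "close_contact", pixelSize(video),
                           frameInterval(video)))
    }
    arr <- videoData(video)
    dims <- dim(arr)
    nt <- dims[1L]
    sm <- .runningMeanT(arr, config$rolling_ball_radius_t)
    G <- .gaussXY(sm, config$gauss_sigma_xy)
    cellMask <- if (!is.null(cellLabels)) labelData(cellLabels) > 0L else
        array(FALSE, dims)

    brush <- EBImage::makeBrush(2L * config$erosion_radius_px + 1L, "disc")
    weak <- array(FALSE, dims)
    strong <- array(FALSE, dims)
    lateAll <- array(FALSE, dims)
    for (t in seq_len(nt)) {
        g <- G[t, , ]
        L <- .laplacian(g)
        not <- !cellMask[t, , ]
        if (!any(not)) not[] <- TRUE
        sdL <- sd(L[not])
        strong[t, , ] <- L > config$h_high * sdL
        weak[t, , ] <- L > config$h_low * sdL
        thr2 <- mean(g[not]) - config$h2 * sd(g[not])
        late <- (g + L) < thr2
        late <- EBImage::erode(EBImage::Image(late * 1), brush) > 0
        lateAll[t, , ] <- as.matrix(late)
    }
    # hysteresis over the spatiotemporal volume: a weak component (8-conn
    # in-plane, overlap-connected in time) survives if it contains at
    # least one strong voxel anywhere in its lifetime
    det <- array(FALSE, dims)
    if (any(strong)) {
        labw <- .label3d(weak, "overlap")
        keep <- unique(labw[strong])
        keep <- keep[keep > 0L]
        det <- array(labw %in% keep, dims)
    }
    det <- det | lateAll
    if (restrict) det <- det & cellMask

    # per-frame small-component removal
    for (t in seq_len(nt)) {
        m <- det[t, , ]
        if (!any(m)) next
        lab <- EBImage::bwlabel(m)
        sz <- tabulate(lab[lab > 0L])
        drop <- which(sz < config$min_contact_area_px)
        if (length(drop)) m[lab %in% drop] <- FALSE
        det[t, , ] <- m
    }

    labels <- .label3d(det, "overlap")
    owners <- integer()
    if (max(labels) > 0L && !is.null(cellLabels)) {
        cl <- labelData(cellLabels)
        owners <- vapply(seq_len(max(labels)), function(i) {
            v <- cl[labels == i]
            v <- v[v > 0L]
            if (!length(v)) NA_integer_ else
                as.integer(names(sort(table(v), decreasing = TRUE))[1L])
        }, integer(1))
        names(owners) <- seq_len(max(labels))
    } else if (max(labels) > 0L) {
        owners <- setNames(rep(NA_integer_, max(labels)),
                           seq_len(max(labels)))
    }
    LabelVolume(labels, "close_contact", pixelSize(video),
                frameInterval(video), owners = owners)
}
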