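#' Measure per-cell calcium traces at the contact centroid
#'
#' For every cell label, the mean calcium intensity inside a circle
#' centred on the cell's per-frame centroid is extracted. Frames in which
#' the cell mask is missing between two detections are filled by linear
#' interpolation of the neighbouring centroids and flagged. Trigger
#' analysis is applied to each trace with [detectTrigger()].
#'
#' @param video registered calcium [TirfVideo-class].
#' @param cellLabels [LabelVolume-class] of kind \code{"cell"}.
#' @param circleRadius_um measurement circle radius in um (default 5).
#' @param ... passed on to [detectTrigger()] (fold change, durations...).
#' @return list of per-cell traces; each has \code{cellId}, \code{frames},
#'   \code{time_s}, \code{centroid} (um), \code{intensity},
#'   \code{interpolated} flags and \code{trigger} (a [detectTrigger()]
#'   result). Cells absent from every frame are skipped with a warning.
#' @export
measureCellCalcium <- function(video, cellLabels, circleRadius_um = 5,
                               ...) {
    stopifnot(is(video, "TirfVideo"), is(cellLabels, "LabelVolume"))
    lab <- labelData(cellLabels)
    nt <- nFrames(video)
    px_um <- pixelSize(video) / 1000
    dt <- frameInterval(video)
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    out <- list()
    dims <- dim(lab)
    yy <- (seq_len(dims[2L]) - 0.5) * px_um
    xx <- (seq_len(dims[3L]) - 0.5) * px_um
    for (id in ids) {
        cen <- matrix(NA_real_, nt, 2)
        for (t in seq_len(nt)) {
            w <- which(lab[t, , ] == id, arr.ind = TRUE)
            if (nrow(w))
                cen[t, ] <- c(mean((w[, 1] - 0.5) * px_um),
                              mean((w[, 2] - 0.5) * px_um))
        }
        present <- which(!is.na(cen[, 1]))
        if (!length(present)) {
            warning("cell ", id, " absent from all frames; skipped")
            next
        }
        span <- present[1L]:present[length(present)]
        interp <- setdiff(span, present)
        if (length(interp)) {
            cen[span, 1] <- approx(present, cen[present, 1], xout = span)$y
            cen[span, 2] <- approx(present, cen[present, 2], xout = span)$y
        }
        ints <- vapply(span, function(t) {
            d2 <- outer((yy - cen[t, 1])^2, (xx - cen[t, 2])^2, `+`)
            mean(frameData(video, t)[d2 <= circleRadius_um^2])
        }, numeric(1))
        trig <- tryCatch(detectTrigger(ints, frameInterval = dt, ...),
                         error = function(e) NULL)
        out[[as.character(id)]] <- list(
            cellId = id, frames = span, time_s = (span - 1) * dt,
            centroid = cen[span, , drop = FALSE], intensity = ints,
            interpolated = span %in% interp, trigger = trig)
    }
    out
}

#' Quality control: exclude cells that touch the field edge
#'
#' Cells touching the field-of-view border in the membrane channel are
#' unreliable: their footprint and contacts are clipped. A cell is
#' excluded when it touches the edge before it triggers or, if it never
#' triggers, within \code{window_s} seconds after its first close
#' contact. Cells without contacts and without triggers are kept unless
#' they touch the edge at any time.
#'
#' @param cellLabels [LabelVolume-class] of kind \code{"cell"}.
#' @param triggerTimes named numeric vector, seconds (NA = no trigger);
#'   names are cell labels.
#' @param firstContactTimes named numeric vector, seconds (NA = none).
#' @param margin_px border width in pixels counted as "edge".
#' @param window_s grace window after the first contact for
#'   non-triggering cells.
#' @return data.frame with \code{cellId}, \code{edgeTime_s} (first
#'   edge-touch time, NA if never) and \code{kept}.
#' @export
qcEdgeExclusion <- function(cellLabels, triggerTimes, firstContactTimes,
                            margin_px = 1, window_s = 300) {
    stopifnot(is(cellLabels, "LabelVolume"))
    lab <- labelData(cellLabels)
    dims <- dim(lab)
    dt <- frameInterval(cellLabels)
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    edge <- array(FALSE, dims[2:3])
    m <- margin_px
    edge[c(seq_len(m), dims[2L] - seq_len(m) + 1L), ] <- TRUE
    edge[, c(seq_len(m), dims[3L] - seq_len(m) + 1L)] <- TRUE
    res <- lapply(ids, function(id) {
        et <- NA_real_
        for (t in seq_len(dims[1L])) {
            if (any(lab[t, , ][edge] == id)) {
                et <- (t - 1) * dt
                break
            }
        }
        trig <- triggerTimes[as.character(id)]
        fc <- firstContactTimes[as.character(id)]
        kept <- TRUE
        if (!is.na(et)) {
            if (length(trig) && !is.na(trig)) {
                kept <- et >= trig
            } else if (length(fc) && !is.na(fc)) {
                kept <- et > fc + window_s
            } else {
                kept <- FALSE
            }
        }
        data.frame(cellId = id, edgeTime_s = et, kept = kept)
    })
    do.call(rbind, res)
}

#' Detect per-cell interaction events
#'
#' Computes the five per-cell event times that anchor the four
#' interaction stages: first membrane detection (searching), adhesion,
#' first close contact (scanning), calcium triggering (spreading) and the
#' time of maximum membrane footprint (synapsing). The footprint-area
#' trace is smoothed with a running mean before taking its maximum.
#'
#' @param cellLabels [LabelVolume-class] of kind \code{"cell"}.
#' @param contactLabels [LabelVolume-class] of kind \code{"close_contact"}
#'   (owners map contacts to cells), or NULL.
#' @param traces output of [measureCellCalcium()] (for trigger times), or
#'   NULL.
#' @param speedThreshold adhesion speed threshold, um/s.
#' @param areaSmoothFrames running-mean window for the membrane-area
#'   trace.
#' @return data.frame, one row per cell: \code{cellId},
#'   \code{time_CZ_first_s}, \code{time_adhesion_s},
#'   \code{time_CCZ_first_s}, \code{time_Ca_s}, \code{time_to_CZ_max_s}.
#'   Absent events are NA.
#' @export
detectEvents <- function(cellLabels, contactLabels = NULL, traces = NULL,
                         speedThreshold = 0.2, areaSmoothFrames = 5) {
    stopifnot(is(cellLabels, "LabelVolume"))
    lab <- labelData(cellLabels)
    nt <- dim(lab)[1L]
    dt <- frameInterval(cellLabels)
    px_um <- pixelSize(cellLabels) / 1000
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    owners <- if (!is.null(contactLabels)) contactOwners(contactLabels)
              else integer()
    clab <- if (!is.null(contactLabels)) labelData(contactLabels) else NULL

    rows <- lapply(ids, function(id) {
        inFrame <- vapply(seq_len(nt), function(t)
            sum(lab[t, , ] == id), integer(1))
        present <- which(inFrame > 0L)
        t_cz <- (present[1L] - 1L) * dt

        # adhesion from the centroid track
        cen <- t(vapply(present, function(t) {
            w <- which(lab[t, , ] == id, arr.ind = TRUE)
            c(mean(w[, 1]), mean(w[, 2])) * px_um
        }, numeric(2)))
        t_adh <- NA_real_
        if (nrow(cen) >= 2L) {
            a <- classifyAdhesion(cen, speedThreshold, frameInterval = dt)
            if (a$adhered) t_adh <- t_cz + a$adhesionTime
        }

        # first close contact owned by this cell
        t_ccz <- NA_real_
        if (!is.null(clab)) {
            mine <- as.integer(names(owners))[!is.na(owners) &
                                              owners == id]
            if (length(mine)) {
                for (t in seq_len(nt)) {
                    if (any(clab[t, , ] %in% mine)) {
                        t_ccz <- (t - 1L) * dt
                        break
                    }
                }
            }
        }

        # calcium trigger (absolute time = track start + relative time)
        t_ca <- NA_real_
        if (!is.null(traces)) {
            tr <- traces[[as.character(id)]]
            if (!is.null(tr) && !is.null(tr$trigger) &&
                isTRUE(tr$trigger$triggered))
                t_ca <- tr$time_s[1L] + tr$trigger$triggerTime
        }

        # maximum of the smoothed membrane-area trace
        area <- inFrame * px_um^2
        sm <- as.vector(stats::filter(area,
            rep(1 / areaSmoothFrames, areaSmoothFrames), sides = 2))
        sm[is.na(sm)] <- area[is.na(sm)]
        t_max <- (which.max(sm) - 1L) * dt

        data.frame(cellId = id, time_CZ_first_s = t_cz,
                   time_adhesion_s = t_adh, time_CCZ_first_s = t_ccz,
                   time_Ca_s = t_ca, time_to_CZ_max_s = t_max)
    })
    do.call(rbind, rows)
}

#' Assign the four interaction stages to every timepoint
#'
#' Stage I (searching) runs from the first membrane detection, stage II
#' (scanning) from the first close contact, stage III (spreading) from
#' calcium triggering and stage IV (synapsing) from the maximum membrane
#' footprint. Intervals are half-open \code{[event, next_event)}; stages
#' III and IV are absent for non-triggering cells, and an out-of-order
#' event is clipped to the previous stage boundary with a warning.
#'
#' @param events data.frame from [detectEvents()].
#' @param nFrames number of frames to label.
#' @param frameInterval seconds per frame.
#' @return character matrix (cells x frames) with values "I".."IV" or NA
#'   before the cell appears; rownames are cell ids.
#' @export
assignStages <- function(events, nFrames, frameInterval = 1) {
    dt <- frameInterval
    out <- matrix(NA_character_, nrow(events), nFrames,
                  dimnames = list(events$cellId, NULL))
    tf <- (seq_len(nFrames) - 1L) * dt
    for (i in seq_len(nrow(events))) {
        ev <- events[i, ]
        b1 <- ev$time_CZ_first_s
        b2 <- ev$time_CCZ_first_s
        b3 <- if (!is.na(ev$time_Ca_s)) ev$time_Ca_s else NA_real_
        b4 <- if (!is.na(b3)) ev$time_to_CZ_max_s else NA_real_
        if (!is.na(b2) && !is.na(b1) && b2 < b1) {
            warning("cell ", ev$cellId,
                    ": first contact precedes first membrane; clipped")
            b2 <- b1
        }
        if (!is.na(b3) && !is.na(b2) && b3 < b2) {
            warning("cell ", ev$cellId,
                    ": trigger precedes first contact; clipped")
            b3 <- b2
        }
        if (!is.na(b4) && !is.na(b3) && b4 < b3) b4 <- b3
        st <- rep(NA_character_, nFrames)
        if (!is.na(b1)) st[tf >= b1] <- "I"
        if (!is.na(b2)) st[tf >= b2] <- "II"
        if (!is.na(b3)) st[tf >= b3] <- "III"
        if (!is.na(b4)) st[tf >= b4] <- "IV"
        out[i, ] <- st
    }
    out
}

# 1-px inner outline of a logical mask (pixels with a 4-neighbour outside)
.maskOutline <- function(mask) {
    ny <- nrow(mask); nx <- ncol(mask)
    pad <- matrix(FALSE, ny + 2L, nx + 2L)
    pad[2:(ny + 1L), 2:(nx + 1L)] <- mask
    core <- pad[2:(ny + 1L), 2:(nx + 1L)] &
        pad[1:ny, 2:(nx + 1L)] & pad[3:(ny + 2L), 2:(nx + 1L)] &
        pad[2:(ny + 1L), 1:nx] & pad[2:(ny + 1L), 3:(nx + 2L)]
    mask & !core
}

#' Extract per-contact feature records
#'
#' For every close contact and every frame it is detected in, reports the
#' pixel-based area, the glycocalyx exclusion statistic
#' \code{exclusion_10 = 1 - perc10(I_inside) / mean(I_outside)} (10th
#' percentile inside the contact over the mean of the 1-px outline of the
#' owning cell's membrane mask, both on flat-field-corrected intensities),
#' the accumulated contact time, and the owning cell's interaction stage.
#'
#' @param contactLabels [LabelVolume-class] of kind \code{"close_contact"}.
#' @param video flat-field-corrected glycocalyx [TirfVideo-class].
#' @param cellLabels optional [LabelVolume-class] of kind \code{"cell"}
#'   providing the outline for \code{mean(I_outside)}.
#' @param stages optional stage matrix from [assignStages()].
#' @return data.frame with columns \code{contactId}, \code{cellId},
#'   \code{frame}, \code{time_s}, \code{area_um2}, \code{exclusion_10},
#'   \code{contact_time_s}, \code{stage}, \code{valid} (FALSE when no
#'   outline pixels were available).
#' @export
contactFeatures <- function(contactLabels, video, cellLabels = NULL,
                            stages = NULL) {
    stopifnot(is(contactLabels, "LabelVolume"), is(video, "TirfVideo"))
    lab <- labelData(contactLabels)
    nt <- dim(lab)[1L]
    dt <- frameInterval(contactLabels)
    pxArea <- (pixelSize(contactLabels) / 1000)^2
    owners <- contactOwners(contactLabels)
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    clab <- if (!is.null(cellLabels)) labelData(cellLabels) else NULL
    rows <- list()
    for (id in ids) {
        owner <- if (length(owners)) owners[as.character(id)] else
            NA_integer_
        seen <- 0L
        for (t in seq_len(nt)) {
            inside <- lab[t, , ] == id
            if (!any(inside)) next
            seen <- seen + 1L
            img <- frameData(video, t)
            outline <- NULL
            if (!is.null(clab)) {
                cm <- if (!is.na(owner)) clab[t, , ] == owner else
                    clab[t, , ] > 0L
                if (any(cm)) outline <- .maskOutline(cm)
            }
            valid <- !is.null(outline) && any(outline)
            excl <- if (valid) {
                1 - quantile(img[inside], 0.1, names = FALSE, type = 7) /
                    mean(img[outline])
            } else NA_real_
            stg <- if (!is.null(stages) && !is.na(owner) &&
                       as.character(owner) %in% rownames(stages))
                stages[as.character(owner), t] else NA_character_
            rows[[length(rows) + 1L]] <- data.frame(
                contactId = id, cellId = owner, frame = t,
                time_s = (t - 1L) * dt,
                area_um2 = sum(inside) * pxArea,
                exclusion_10 = excl,
                contact_time_s = seen * dt,
                stage = stg, valid = valid)
        }
    }
    if (!length(rows))
        return(data.frame(contactId = integer(), cellId = integer(),
                          frame = integer(), time_s = numeric(),
                          area_um2 = numeric(), exclusion_10 = numeric(),
                          contact_time_s = numeric(), stage = character(),
                          valid = logical()))
    do.call(rbind, rows)
}

#' Close-contact area as a fraction of total membrane area
#'
#' Divides the summed close-contact area at the moment of calcium
#' triggering by the cell's total surface area measured in solution
#' (e.g. ~525 um^2 for Jurkat-derived reporter cells, ~300 um^2 for
#' primary CD8+ T cells).
#'
#' @param records contact feature table from [contactFeatures()].
#' @param timeCa_s trigger time in seconds (NA returns NA).
#' @param cellSurfaceArea_um2 total membrane surface area, um^2 (> 0).
#' @param cellId optional cell id to restrict the sum to.
#' @return fraction (unitless); 0 when no contacts exist at trigger.
#' @examples
#' rec <- data.frame(contactId = 1, cellId = 1, frame = 1, time_s = 0,
#'                   area_um2 = 1.0)
#' contactAreaFraction(rec, 0, 500)   # 0.002
#' @export
contactAreaFraction <- function(records, timeCa_s, cellSurfaceArea_um2,
                                cellId = NULL) {
    stopifnot(cellSurfaceArea_um2 > 0)
    if (is.na(timeCa_s)) return(NA_real_)
    r <- records
    if (!is.null(cellId)) r <- r[!is.na(r$cellId) & r$cellId == cellId, ]
    if (!nrow(r)) return(0)
    # frame whose time is closest to the trigger time
    tgt <- r$time_s[which.min(abs(r$time_s - timeCa_s))]
    if (abs(tgt - timeCa_s) > max(diff(sort(unique(r$time_s))), 0, na.rm = TRUE))
        return(0)
    sum(r$area_um2[r$time_s == tgt]) / cellSurfaceArea_um2
}

#' Write the per-cell event table and per-contact feature table
#'
#' CSV export using the conventional output strings
#' (\code{time_CZ_first (s)}, ..., \code{Area (um^2)}, ...).
#'
#' @param events data.frame from [detectEvents()].
#' @param records data.frame from [contactFeatures()].
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
writeFeatureTables <- function(events, records, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ev <- events
    names(ev) <- c("cell_id", "time_CZ_first (s)", "time_adhesion (s)",
                   "time_CCZ_first (s)", "time_Ca (s)",
                   "time_to_CZ_max (s)")
    f1 <- file.path(dir, "events.csv")
    write.csv(ev, f1, row.names = FALSE)
    rec <- records[, c("contactId", "cellId", "time_s", "area_um2",
                       "exclusion_10", "contact_time_s", "stage")]
    names(rec) <- c("contact_id", "cell_id", "time (s)", "Area (um^2)",
                    "exclusion_10", "contact_time (s)", "stage")
    f2 <- file.path(dir, "contacts.csv")
    write.csv(rec, f2, row.names = FALSE)
    invisible(c(f1, f2))
}
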