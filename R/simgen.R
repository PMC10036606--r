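#' Describe ground-truth close contacts
#'
#' Builds rows of the contact-truth table used by [groundTruthScene()].
#' A close contact is a circular disc in which the glycocalyx intensity is
#' reduced to \code{background * (1 - exclusion_depth)}; depth 1 means full
#' exclusion (intensity 0), depth 0 no exclusion.
#'
#' @param center_y_um,center_x_um disc centre in um (vectorised).
#' @param diameter disc diameter in um.
#' @param exclusion_depth fraction of background removed inside the disc,
#'   in [0, 1].
#' @param birth_s,death_s time window (seconds) during which the contact
#'   exists; a contact is live at time t when \code{birth_s <= t < death_s}.
#' @return data.frame with one row per contact.
#' @examples
#' contactTruth(1.5, 1.5, diameter = 0.25, exclusion_depth = 0.5)
#' @export
contactTruth <- function(center_y_um, center_x_um, diameter,
                         exclusion_depth, birth_s = 0, death_s = Inf) {
    data.frame(center_y_um = center_y_um, center_x_um = center_x_um,
               diameter_um = diameter, exclusion_depth = exclusion_depth,
               birth_s = birth_s, death_s = death_s)
}

#' Describe a ground-truth cell
#'
#' A cell is a circular membrane footprint with a per-frame centre
#' trajectory, footprint radius and calcium-reporter intensity. Scalars are
#' recycled over \code{nFrames}.
#'
#' @param center_y_um,center_x_um per-frame centre (um), scalar or vector.
#' @param radius_um per-frame footprint radius (um); 0 means not yet spread.
#' @param calcium per-frame calcium intensity (a.u.).
#' @param trigger_time_s true calcium-trigger time in seconds, or NA.
#' @param nFrames number of frames to recycle scalars over.
#' @return list describing the cell, for [groundTruthScene()].
#' @export
cellTruth <- function(center_y_um, center_x_um, radius_um, calcium = 100,
                      trigger_time_s = NA_real_, nFrames = NULL) {
    n <- max(length(center_y_um), length(center_x_um), length(radius_um),
             length(calcium))
    if (!is.null(nFrames)) n <- max(n, nFrames)
    list(center = cbind(y = rep_len(center_y_um, n),
                        x = rep_len(center_x_um, n)),
         radius = rep_len(radius_um, n),
         calcium = rep_len(calcium, n),
         trigger_time_s = trigger_time_s)
}

#' Describe a ground-truth point emitter
#'
#' Point emitters model single fluorescent ligands: immobile (bound)
#' emitters render as diffraction-limited spots, diffusing (unbound) ones
#' are motion-blurred by averaging sub-frame positions over the exposure.
#'
#' @param y_um,x_um initial position in um.
#' @param mobility \code{"immobile"} or \code{"diffusing"}.
#' @param D_um2_s diffusion coefficient (um^2/s) for diffusing emitters.
#' @param brightness expected photons per frame.
#' @return list describing the emitter.
#' @export
emitterTruth <- function(y_um, x_um, mobility = c("immobile", "diffusing"),
                         D_um2_s = 1, brightness = 300) {
    mobility <- match.arg(mobility)
    stopifnot(brightness > 0)
    list(y = y_um, x = x_um, mobility = mobility, D = D_um2_s,
         brightness = brightness)
}

#' Rasterise the ground-truth glycocalyx field at one timepoint
#'
#' Renders the scene's idealised glycocalyx at a fine sub-pixel resolution:
#' uniform background with each live contact drawn as a disc of intensity
#' \code{background * (1 - exclusion_depth)}. Membership is by distance
#' from the disc centre; sub-pixel centres sit at half-integer multiples of
#' \code{resolution}.
#'
#' @param scene a [GroundTruthScene-class].
#' @param t time in seconds (a contact is live when
#'   \code{birth_s <= t < death_s}).
#' @param resolution sub-pixel edge length in nm; must divide the camera
#'   pixel size used later by [renderFrame()]. Default 10.7 nm (one tenth
#'   of a 107 nm camera pixel).
#' @return numeric (y, x) matrix of intensities at \code{resolution}.
#' @examples
#' sc <- groundTruthScene(fieldSize = c(2, 2),
#'     contacts = contactTruth(1, 1, 0.4, 0.4))
#' gt <- makeGroundTruthFrame(sc, t = 0)
#' range(gt)    # 60 inside the disc, 100 outside
#' @export
makeGroundTruthFrame <- function(scene, t = 0, resolution = 10.7) {
    stopifnot(is(scene, "GroundTruthScene"))
    tmax <- scene@nFrames * scene@frameInterval
    if (t < 0 || t > tmax)
        stop("t = ", t, " s outside the scene's time span [0, ", tmax, "]")
    ny <- round(scene@fieldSize[1] * 1000 / resolution)
    nx <- round(scene@fieldSize[2] * 1000 / resolution)
    field <- matrix(scene@background, ny, nx)
    ct <- scene@contacts
    if (!nrow(ct)) return(field)
    yy <- (seq_len(ny) - 0.5) * resolution / 1000
    xx <- (seq_len(nx) - 0.5) * resolution / 1000
    for (i in seq_len(nrow(ct))) {
        if (!(ct$birth_s[i] <= t && t < ct$death_s[i])) next
        r <- ct$diameter_um[i] / 2
        dy <- yy - ct$center_y_um[i]
        dx <- xx - ct$center_x_um[i]
        inside <- outer(dy^2, dx^2, `+`) <= r^2
        field[inside] <- scene@background * (1 - ct$exclusion_depth[i])
    }
    field
}

#' Render a fine ground-truth field through the optical + camera geometry
#'
#' Applies the Gaussian PSF in physical units to a fine-resolution field
#' and mean-bins the result onto the camera pixel grid. The blur kernel is
#' normalised with reflective boundary handling, so constant fields pass
#' through unchanged and total intensity is conserved.
#'
#' @param field fine-resolution (y, x) matrix from [makeGroundTruthFrame()].
#' @param psf a [PSFModel-class].
#' @param camera a [CameraModel-class]; its \code{pixelSize} sets the
#'   output grid.
#' @param resolution the field's sub-pixel size in nm; the camera pixel
#'   size must be an integer multiple of it.
#' @return (y, x) matrix at camera resolution, same intensity units as the
#'   input (no gain or noise applied).
#' @export
renderFrame <- function(field, psf = psfModel(), camera = cameraModel(),
                        resolution = 10.7) {
    stopifnot(is(psf, "PSFModel"), is(camera, "CameraModel"))
    if (psf@sigma <= 0) stop("PSF sigma must be > 0")
    factor <- camera@pixelSize / resolution
    if (abs(factor - round(factor)) > 1e-9)
        stop("resolution (", resolution, " nm) must divide the camera ",
             "pixel size (", camera@pixelSize, " nm)")
    factor <- as.integer(round(factor))
    if (nrow(field) < factor || ncol(field) < factor)
        stop("field is smaller than one camera pixel")
    blurred <- .blurField(field, psf@sigma / resolution)
    .binField(blurred, factor)
}

#' Apply EMCCD camera noise to an ideal image
#'
#' Stochastic camera model for an electron-multiplying CCD: Poisson photon
#' shot noise, Gamma-distributed electron multiplication (excess-noise
#' factor 2), Gaussian read noise, and a fixed offset. For a pixel with
#' expectation \code{mu} photoelectrons the output has mean
#' \code{emGain * mu + offset} and variance
#' \code{2 * emGain^2 * mu + readNoiseSD^2}.
#'
#' @param ideal matrix or array of expected photoelectrons per pixel
#'   (i.e. after quantum-efficiency scaling); must be non-negative.
#' @param camera a [CameraModel-class].
#' @param seed optional integer; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return noisy image in ADU, same shape as \code{ideal}.
#' @examples
#' img <- applyCameraNoise(matrix(10, 64, 64), cameraModel(), seed = 1)
#' mean(img)    # ~ 250 * 10 + offset
#' @export
applyCameraNoise <- function(ideal, camera = cameraModel(), seed = NULL) {
    stopifnot(is(camera, "CameraModel"))
    if (any(ideal < 0))
        stop("expected photon counts must be non-negative")
    .withSeed(seed, {
        n <- rpois(length(ideal), as.vector(ideal))
        adu <- numeric(length(n))
        pos <- n > 0L
        adu[pos] <- rgamma(sum(pos), shape = n[pos], scale = camera@emGain)
        adu <- adu + rnorm(length(n), sd = camera@readNoiseSD) +
            camera@offset
        out <- ideal
        out[] <- adu
        out
    })
}

# Render all emitters of one frame directly onto the camera grid.
# positions: matrix (n_emitters, 2) in um; returns photons/pixel.
.renderEmitters <- function(positions, brightness, ny, nx, px_um, sigma_um) {
    img <- matrix(0, ny, nx)
    if (is.null(positions) || nrow(positions) == 0L) return(img)
    yy <- (seq_len(ny) - 0.5) * px_um
    xx <- (seq_len(nx) - 0.5) * px_um
    norm <- px_um^2 / (2 * pi * sigma_um^2)
    for (i in seq_len(nrow(positions))) {
        gy <- exp(-(yy - positions[i, 1])^2 / (2 * sigma_um^2))
        gx <- exp(-(xx - positions[i, 2])^2 / (2 * sigma_um^2))
        img <- img + brightness[i] * norm * outer(gy, gx)
    }
    img
}

#' Simulate a registered multi-channel TIRFM video
#'
#' End-to-end synthesis: the glycocalyx channel renders the scene's
#' exclusion discs through [makeGroundTruthFrame()] and [renderFrame()];
#' the membrane channel draws each cell's footprint disc; the calcium
#' channel paints each cell's calcium trace into its footprint; the
#' optional emitter channel draws point emitters with sub-frame motion
#' blur for diffusing molecules. Photon expectations are scaled by the
#' camera quantum efficiency and passed through [applyCameraNoise()]
#' unless \code{noise = FALSE}.
#'
#' @param scene a [GroundTruthScene-class].
#' @param psf a [PSFModel-class].
#' @param camera a [CameraModel-class].
#' @param seed integer seed; the same seed reproduces the video bit for
#'   bit.
#' @param resolution ground-truth rasterisation resolution in nm.
#' @param noise logical; apply the EMCCD model (default TRUE).
#' @param photonScale expected photons per scene intensity unit. The
#'   default 2.5 maps the standard background of 100 a.u. to ~225
#'   photoelectrons per pixel per frame, which at EM gain 250 fills a
#'   16-bit dynamic range the way a typical glycocalyx channel does.
#' @param membraneIntensity,calciumBackground,membraneBackground photon
#'   levels used for the membrane and calcium channels.
#' @param emitterSubsteps sub-frame positions averaged per frame to model
#'   motion blur of diffusing emitters.
#' @return A list with components \code{glycocalyx}, \code{membrane},
#'   \code{calcium} (each a [TirfVideo-class]), \code{emitter} (present
#'   when the scene has emitters), \code{emitterTracks} (list of per-frame
#'   mean positions, um), and \code{scene} (the input echoed back).
#' @examples
#' sc <- groundTruthScene(fieldSize = c(3, 3), nFrames = 4,
#'     contacts = contactTruth(1.5, 1.5, 0.4, 0.6))
#' vid <- simulateVideo(sc, seed = 1)
#' vid$glycocalyx
#' @export
simulateVideo <- function(scene, psf = psfModel(), camera = cameraModel(),
                          seed = NULL, resolution = 10.7, noise = TRUE,
                          photonScale = 2.5, membraneIntensity = 80,
                          calciumBackground = 5, membraneBackground = 5,
                          emitterSubsteps = 10L) {
    stopifnot(is(scene, "GroundTruthScene"))
    .withSeed(seed, {
        nt <- scene@nFrames
        dt <- scene@frameInterval
        px_um <- camera@pixelSize / 1000
        ny <- round(scene@fieldSize[1] * 1000 / resolution) %/%
            as.integer(round(camera@pixelSize / resolution))
        nx <- round(scene@fieldSize[2] * 1000 / resolution) %/%
            as.integer(round(camera@pixelSize / resolution))
        qe <- camera@quantumEfficiency * photonScale

        glyco <- array(0, c(nt, ny, nx))
        memb <- array(0, c(nt, ny, nx))
        calc <- array(0, c(nt, ny, nx))
        yy <- (seq_len(ny) - 0.5) * px_um
        xx <- (seq_len(nx) - 0.5) * px_um

        # glyco frames repeat while the live-contact set is unchanged
        cache <- list()
        for (t in seq_len(nt)) {
            tsec <- (t - 1) * dt
            live <- which(scene@contacts$birth_s <= tsec &
                          tsec < scene@contacts$death_s)
            key <- paste0("k", paste(live, collapse = ","))
            if (is.null(cache[[key]])) {
                gt <- makeGroundTruthFrame(scene, tsec, resolution)
                cache[[key]] <- renderFrame(gt, psf, camera, resolution)
            }
            glyco[t, , ] <- cache[[key]]

            for (cl in scene@cells) {
                r <- cl$radius[t]
                if (r <= 0) next
                disc <- outer((yy - cl$center[t, 1])^2,
                              (xx - cl$center[t, 2])^2, `+`) <= r^2
                m <- memb[t, , ]
                m[disc] <- m[disc] + membraneIntensity
                memb[t, , ] <- m
                ca <- calc[t, , ]
                ca[disc] <- ca[disc] + cl$calcium[t]
                calc[t, , ] <- ca
            }
        }
        memb <- memb + membraneBackground
        calc <- calc + calciumBackground
        # light optical blur of the cell channels (PSF at camera scale)
        sig_px <- psf@sigma / camera@pixelSize
        memb <- .gaussXY(memb, sig_px)
        calc <- .gaussXY(calc, sig_px)

        out <- list()
        emTracks <- list()
        if (length(scene@emitters)) {
            sigma_um <- psf@sigma / 1000
            emit <- array(0, c(nt, ny, nx))
            pos <- lapply(scene@emitters, function(e) c(e$y, e$x))
            for (t in seq_len(nt)) {
                means <- matrix(0, length(pos), 2)
                for (i in seq_along(pos)) {
                    e <- scene@emitters[[i]]
                    if (e$mobility == "immobile") {
                        sub <- matrix(pos[[i]], emitterSubsteps, 2,
                                      byrow = TRUE)
                    } else {
                        step_sd <- sqrt(2 * e$D * dt / emitterSubsteps)
                        steps <- matrix(rnorm(2L * emitterSubsteps,
                                              sd = step_sd),
                                        emitterSubsteps, 2)
                        sub <- sweep(apply(steps, 2, cumsum), 2,
                                     pos[[i]], `+`)
                        pos[[i]] <- sub[emitterSubsteps, ]
                    }
                    means[i, ] <- colMeans(sub)
                    # motion blur: spread the frame budget over sub-positions
                    emit[t, , ] <- emit[t, , ] +
                        .renderEmitters(sub, rep(e$brightness /
                                                 emitterSubsteps,
                                                 emitterSubsteps),
                                        ny, nx, px_um, sigma_um)
                }
                emTracks[[t]] <- means
            }
            emit <- emit + membraneBackground
            if (noise) emit <- applyCameraNoise(qe * emit, camera)
            out$emitter <- TirfVideo(emit, camera@pixelSize, dt, "emitter")
        }

        if (noise) {
            glyco <- applyCameraNoise(qe * glyco, camera)
            memb <- applyCameraNoise(qe * memb, camera)
            calc <- applyCameraNoise(qe * calc, camera)
        }
        out$glycocalyx <- TirfVideo(glyco, camera@pixelSize, dt,
                                    "glycocalyx")
        out$membrane <- TirfVideo(memb, camera@pixelSize, dt, "membrane")
        out$calcium <- TirfVideo(calc, camera@pixelSize, dt, "calcium")
        if (length(emTracks)) {
            # reorganise per emitter: n_frames x 2 matrices
            nE <- length(scene@emitters)
            out$emitterTracks <- lapply(seq_len(nE), function(i)
                do.call(rbind, lapply(emTracks, function(m) m[i, ])))
        }
        out$scene <- scene
        out
    })
}

#' Write a video as a 16-bit multi-page TIFF
#'
#' Intensities are rounded to integers and stored as 16-bit pages, the
#' native format of EMCCD acquisitions; values outside [0, maxValue] are
#' clipped the way a saturating camera would. [readVideoTiff()] restores
#' the stack on the original ADU scale.
#'
#' @param video a [TirfVideo-class].
#' @param path output file path.
#' @param maxValue full-scale value (default 65535, 16-bit).
#' @return \code{path}, invisibly.
#' @export
writeVideoTiff <- function(video, path, maxValue = 65535) {
    stopifnot(is(video, "TirfVideo"))
    pages <- lapply(seq_len(nFrames(video)), function(t) {
        fr <- round(frameData(video, t))
        pmin(pmax(fr, 0), maxValue) / maxValue
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
    invisible(path)
}

#' Read a multi-page TIFF into a TirfVideo
#'
#' @param path TIFF file path.
#' @param pixelSize,frameInterval,channel calibration metadata (TIFF pages
#'   do not carry it).
#' @param maxValue full-scale value used at write time.
#' @return A [TirfVideo-class].
#' @export
readVideoTiff <- function(path, pixelSize = 107, frameInterval = 1,
                          channel = "unknown", maxValue = 65535) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (t in seq_along(pages)) arr[t, , ] <- pages[[t]] * maxValue
    TirfVideo(arr, pixelSize, frameInterval, channel)
}

#' Export a scene's ground truth to disk
#'
#' Writes the contact-truth table as CSV and the full scene description
#' (field, background, timing, cells, emitters) as JSON.
#'
#' @param scene a [GroundTruthScene-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeScene <- function(scene, dir) {
    stopifnot(is(scene, "GroundTruthScene"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(dir, "contacts_truth.csv")
    ct <- scene@contacts
    if (nrow(ct)) ct <- cbind(contact_id = seq_len(nrow(ct)), ct)
    write.csv(ct, csv, row.names = FALSE)
    js <- file.path(dir, "scene.json")
    jsonlite::write_json(list(
        field_size_um = scene@fieldSize,
        background_intensity = scene@background,
        frame_interval_s = scene@frameInterval,
        n_frames = scene@nFrames,
        contacts = scene@contacts,
        cells = lapply(scene@cells, function(cl) list(
            center_um = unname(cl$center), radius_um = cl$radius,
            calcium = cl$calcium, trigger_time_s = cl$trigger_time_s)),
        emitters = scene@emitters
    ), js, auto_unbox = TRUE, digits = NA)
    invisible(c(csv, js))
}
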