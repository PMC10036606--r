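#' @import methods
#' @importFrom stats approx coef convolve dist lm median nls optim
#'   pchisq predict quantile rgamma rnorm rpois runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
NULL

#' TirfVideo: a single-channel fluorescence time-lapse stack
#'
#' Container for one channel of a TIRF microscopy time lapse. The pixel
#' array is ordered \code{(time, y, x)}; physical calibration is carried in
#' the \code{pixelSize} (nm) and \code{frameInterval} (seconds) slots.
#' Pixel centres sit at half-integer multiples of the pixel size, so pixel
#' \code{j} (1-based) is centred at \code{(j - 0.5) * pixelSize/1000} um.
#'
#' @slot data numeric array \code{(time, y, x)} of intensities.
#' @slot pixelSize numeric(1), pixel edge length in nm.
#' @slot frameInterval numeric(1), time between frames in seconds.
#' @slot channel character(1) free-text channel tag (e.g. "glycocalyx").
#'
#' @seealso [TirfVideo()] for construction, [simulateVideo()] for synthesis.
#' @exportClass TirfVideo
setClass("TirfVideo",
    representation(
        data = "array",
        pixelSize = "numeric",
        frameInterval = "numeric",
        channel = "character"
    ),
    prototype(
        pixelSize = 107,
        frameInterval = 1,
        channel = "unknown"
    )
)

setValidity("TirfVideo", function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "'data' must be a 3-d (time, y, x) array")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be a single positive number (nm)")
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
        msg <- c(msg, "'frameInterval' must be a single positive number (s)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a TirfVideo
#'
#' @param data numeric array ordered \code{(time, y, x)}. A matrix is
#'   promoted to a single-frame stack.
#' @param pixelSize pixel edge length in nm (default 107, the effective
#'   EMCCD pixel of the reference instrument).
#' @param frameInterval frame spacing in seconds.
#' @param channel channel tag.
#' @return A [TirfVideo-class] object.
#' @examples
#' v <- TirfVideo(array(100, c(5, 16, 16)), channel = "glycocalyx")
#' nFrames(v)
#' @export
TirfVideo <- function(data, pixelSize = 107, frameInterval = 1,
                      channel = "unknown") {
    if (is.matrix(data))
        data <- array(data, c(1L, nrow(data), ncol(data)))
    new("TirfVideo", data = data, pixelSize = pixelSize,
        frameInterval = frameInterval, channel = channel)
}

#' PSF model (Gaussian approximation)
#'
#' The microscope point spread function is approximated by an isotropic
#' 2-d Gaussian; the default sigma of 131 nm corresponds to a bead-derived
#' calibration of a NA 1.49 TIRF objective.
#'
#' @slot sigma numeric(1), Gaussian sigma in nm.
#' @exportClass PSFModel
setClass("PSFModel", representation(sigma = "numeric"),
         prototype(sigma = 131))

setValidity("PSFModel", function(object) {
    if (length(object@sigma) != 1L || object@sigma <= 0)
        "'sigma' must be a single positive number (nm)" else TRUE
})

#' @param sigma Gaussian sigma in nm.
#' @return A [PSFModel-class].
#' @rdname PSFModel-class
#' @examples
#' psfModel()          # default 131 nm
#' @export
psfModel <- function(sigma = 131) new("PSFModel", sigma = sigma)

#' EMCCD camera model
#'
#' Parameters of the electron-multiplying CCD used to render and to
#' noise-corrupt simulated images. The EM register multiplies each
#' photoelectron by a stochastic gain whose excess-noise factor is 2, so a
#' pixel receiving on average \code{mu} photoelectrons has output mean
#' \code{gain * mu + offset} and variance \code{2 * gain^2 * mu +
#' readNoiseSD^2}.
#'
#' @slot emGain numeric(1), ADU per photoelectron (default 250).
#' @slot readNoiseSD numeric(1), Gaussian read noise SD in ADU.
#' @slot offset numeric(1), fixed camera offset in ADU.
#' @slot quantumEfficiency numeric(1) in (0, 1].
#' @slot pixelSize numeric(1), effective pixel size in nm (default 107).
#' @exportClass CameraModel
setClass("CameraModel",
    representation(
        emGain = "numeric",
        readNoiseSD = "numeric",
        offset = "numeric",
        quantumEfficiency = "numeric",
        pixelSize = "numeric"
    ),
    prototype(emGain = 250, readNoiseSD = 20, offset = 100,
              quantumEfficiency = 0.9, pixelSize = 107)
)

setValidity("CameraModel", function(object) {
    msg <- NULL
    if (object@emGain <= 0) msg <- c(msg, "'emGain' must be > 0")
    if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
    if (object@quantumEfficiency <= 0 || object@quantumEfficiency > 1)
        msg <- c(msg, "'quantumEfficiency' must be in (0, 1]")
    if (object@readNoiseSD < 0) msg <- c(msg, "'readNoiseSD' must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @param emGain ADU/photoelectron.
#' @param readNoiseSD read noise SD in ADU.
#' @param offset camera offset in ADU.
#' @param quantumEfficiency photon-to-electron conversion fraction.
#' @param pixelSize effective pixel size in nm.
#' @return A [CameraModel-class].
#' @rdname CameraModel-class
#' @examples
#' cameraModel()       # Evolve-512-like defaults: gain 250, 107 nm pixels
#' @export
cameraModel <- function(emGain = 250, readNoiseSD = 20, offset = 100,
                        quantumEfficiency = 0.9, pixelSize = 107) {
    new("CameraModel", emGain = emGain, readNoiseSD = readNoiseSD,
        offset = offset, quantumEfficiency = quantumEfficiency,
        pixelSize = pixelSize)
}

#' GroundTruthScene: the simulator's ground truth
#'
#' Describes everything the synthetic-video generator knows about a scene:
#' the physical field, the uniform glycocalyx background, a set of circular
#' close contacts (dark exclusion discs), cell footprints with calcium
#' traces, and point emitters for single-molecule channels.
#'
#' Contacts are rows of a data.frame with columns \code{center_y_um,
#' center_x_um, diameter_um, exclusion_depth, birth_s, death_s}. Cells and
#' emitters are lists created by [cellTruth()] and [emitterTruth()].
#'
#' @slot fieldSize numeric(2), physical extent in um, (y, x).
#' @slot background numeric(1), uniform glycocalyx intensity (a.u.).
#' @slot contacts data.frame of contact truth rows.
#' @slot cells list of cell truth descriptions.
#' @slot emitters list of emitter truth descriptions.
#' @slot frameInterval numeric(1), seconds.
#' @slot nFrames integer(1).
#' @exportClass GroundTruthScene
setClass("GroundTruthScene",
    representation(
        fieldSize = "numeric",
        background = "numeric",
        contacts = "data.frame",
        cells = "list",
        emitters = "list",
        frameInterval = "numeric",
        nFrames = "integer"
    ),
    prototype(
        fieldSize = c(5, 5),
        background = 100,
        contacts = data.frame(),
        cells = list(),
        emitters = list(),
        frameInterval = 1,
        nFrames = 1L
    )
)

setValidity("GroundTruthScene", function(object) {
    msg <- NULL
    if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0))
        msg <- c(msg, "'fieldSize' must be two positive numbers (um)")
    if (object@background <= 0)
        msg <- c(msg, "'background' must be > 0")
    if (object@nFrames < 1L)
        msg <- c(msg, "'nFrames' must be >= 1")
    ct <- object@contacts
    if (nrow(ct)) {
        need <- c("center_y_um", "center_x_um", "diameter_um",
                  "exclusion_depth", "birth_s", "death_s")
        if (!all(need %in% names(ct))) {
            msg <- c(msg, paste("contacts need columns:",
                                paste(need, collapse = ", ")))
        } else {
            if (any(ct$exclusion_depth < 0 | ct$exclusion_depth > 1))
                msg <- c(msg, "exclusion_depth must be in [0, 1]")
            if (any(ct$diameter_um <= 0))
                msg <- c(msg, "contact diameters must be > 0")
            if (any(ct$birth_s >= ct$death_s))
                msg <- c(msg, "contact birth_s must precede death_s")
            out <- ct$center_y_um < 0 | ct$center_y_um > object@fieldSize[1] |
                   ct$center_x_um < 0 | ct$center_x_um > object@fieldSize[2]
            if (any(out))
                msg <- c(msg, paste0("contact(s) outside field: ",
                                     paste(which(out), collapse = ", ")))
        }
    }
    for (cl in object@cells) {
        if (nrow(cl$center) != object@nFrames)
            msg <- c(msg, "cell trajectory length must equal nFrames")
        if (any(cl$radius < 0))
            msg <- c(msg, "cell footprint radii must be >= 0")
    }
    for (em in object@emitters)
        if (em$brightness <= 0)
            msg <- c(msg, "emitter brightness must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' @param fieldSize physical field extent in um, \code{c(y, x)}.
#' @param background uniform glycocalyx intensity (a.u., default 100).
#' @param contacts data.frame of contact truth rows (see
#'   [contactTruth()]), or NULL.
#' @param cells list of [cellTruth()] descriptions.
#' @param emitters list of [emitterTruth()] descriptions.
#' @param frameInterval seconds between frames.
#' @param nFrames number of frames.
#' @return A [GroundTruthScene-class].
#' @rdname GroundTruthScene-class
#' @examples
#' sc <- groundTruthScene(fieldSize = c(3, 3),
#'     contacts = contactTruth(1.5, 1.5, diameter = 0.4,
#'                             exclusion_depth = 0.6))
#' sc
#' @export
groundTruthScene <- function(fieldSize = c(5, 5), background = 100,
                             contacts = NULL, cells = list(),
                             emitters = list(), frameInterval = 1,
                             nFrames = 1L) {
    if (is.null(contacts)) contacts <- data.frame()
    new("GroundTruthScene", fieldSize = as.numeric(fieldSize),
        background = background, contacts = contacts, cells = cells,
        emitters = emitters, frameInterval = frameInterval,
        nFrames = as.integer(nFrames))
}

#' LabelVolume: integer labels over (time, y, x)
#'
#' Segmentation output for either cell footprints or close contacts.
#' Label 0 is background. For close-contact volumes, \code{owners} maps
#' each contact label to the label of the cell that owns it (NA when
#' unrestricted segmentation was used).
#'
#' @slot labels integer array \code{(time, y, x)}; 0 = background.
#' @slot kind character(1), \code{"cell"} or \code{"close_contact"}.
#' @slot pixelSize numeric(1) nm.
#' @slot frameInterval numeric(1) s.
#' @slot owners named integer vector: contact label -> cell label.
#' @exportClass LabelVolume
setClass("LabelVolume",
    representation(
        labels = "array",
        kind = "character",
        pixelSize = "numeric",
        frameInterval = "numeric",
        owners = "integer"
    ),
    prototype(kind = "cell", pixelSize = 107, frameInterval = 1,
              owners = integer())
)

setValidity("LabelVolume", function(object) {
    msg <- NULL
    if (length(dim(object@labels)) != 3L)
        msg <- c(msg, "'labels' must be a 3-d (time, y, x) array")
    if (!object@kind %in% c("cell", "close_contact"))
        msg <- c(msg, "'kind' must be 'cell' or 'close_contact'")
    if (any(object@labels < 0))
        msg <- c(msg, "labels must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' @param labels integer (time, y, x) array; 0 = background.
#' @param kind \code{"cell"} or \code{"close_contact"}.
#' @param pixelSize,frameInterval calibration (nm, s).
#' @param owners named integer vector mapping contact labels to cell
#'   labels (close-contact volumes only).
#' @return A [LabelVolume-class].
#' @rdname LabelVolume-class
#' @export
LabelVolume <- function(labels, kind = c("cell", "close_contact"),
                        pixelSize = 107, frameInterval = 1,
                        owners = integer()) {
    kind <- match.arg(kind)
    storage.mode(labels) <- "integer"
    new("LabelVolume", labels = labels, kind = kind, pixelSize = pixelSize,
        frameInterval = frameInterval, owners = owners)
}
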