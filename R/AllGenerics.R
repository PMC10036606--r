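#' Accessors for closecontacts containers
#'
#' Small accessor family shared by [TirfVideo-class], [LabelVolume-class]
#' and [GroundTruthScene-class]: physical calibration, frame count and the
#' underlying arrays.
#'
#' @param x a container object.
#' @param t 1-based frame index.
#' @return \code{pixelSize} nm; \code{frameInterval} s; \code{nFrames} an
#'   integer; \code{frameData} the (y, x) matrix of frame \code{t};
#'   \code{videoData}/\code{labelData} the full \code{(time, y, x)} array.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameData", function(x, t) standardGeneric("frameData"))
#' @rdname accessors
#' @export
setGeneric("videoData", function(x) standardGeneric("videoData"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setGeneric("labelKind", function(x) standardGeneric("labelKind"))
#' @rdname accessors
#' @export
setGeneric("contactOwners", function(x) standardGeneric("contactOwners"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "TirfVideo", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("frameInterval", "TirfVideo", function(x) x@frameInterval)
#' @rdname accessors
#' @export
setMethod("nFrames", "TirfVideo", function(x) dim(x@data)[1L])
#' @rdname accessors
#' @export
setMethod("frameData", "TirfVideo", function(x, t) x@data[t, , , drop = TRUE])
#' @rdname accessors
#' @export
setMethod("videoData", "TirfVideo", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("pixelSize", "LabelVolume", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("frameInterval", "LabelVolume", function(x) x@frameInterval)
#' @rdname accessors
#' @export
setMethod("nFrames", "LabelVolume", function(x) dim(x@labels)[1L])
#' @rdname accessors
#' @export
setMethod("frameData", "LabelVolume", function(x, t) x@labels[t, , , drop = TRUE])
#' @rdname accessors
#' @export
setMethod("labelData", "LabelVolume", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("labelKind", "LabelVolume", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("contactOwners", "LabelVolume", function(x) x@owners)

#' @rdname accessors
#' @export
setMethod("frameInterval", "GroundTruthScene", function(x) x@frameInterval)
#' @rdname accessors
#' @export
setMethod("nFrames", "GroundTruthScene", function(x) x@nFrames)

setMethod("show", "TirfVideo", function(object) {
    d <- dim(object@data)
    cat("TirfVideo [", object@channel, "]: ", d[1], " frame(s), ",
        d[2], " x ", d[3], " px @ ", object@pixelSize, " nm, dt = ",
        object@frameInterval, " s\n", sep = "")
    cat("  intensity range: [",
        signif(min(object@data), 4), ", ",
        signif(max(object@data), 4), "]\n", sep = "")
})

setMethod("show", "GroundTruthScene", function(object) {
    cat("GroundTruthScene: ", object@fieldSize[1], " x ",
        object@fieldSize[2], " um, ", object@nFrames, " frame(s), dt = ",
        object@frameInterval, " s\n", sep = "")
    cat("  background ", object@background, " a.u.; ",
        nrow(object@contacts), " contact(s), ", length(object@cells),
        " cell(s), ", length(object@emitters), " emitter(s)\n", sep = "")
})

setMethod("show", "LabelVolume", function(object) {
    d <- dim(object@labels)
    n <- length(setdiff(unique(as.vector(object@labels)), 0L))
    cat("LabelVolume [", object@kind, "]: ", d[1], " frame(s), ",
        d[2], " x ", d[3], " px, ", n, " label(s)\n", sep = "")
})

setMethod("show", "PSFModel", function(object)
    cat("PSFModel: Gaussian sigma =", object@sigma, "nm\n"))

setMethod("show", "CameraModel", function(object)
    cat("CameraModel: EM gain ", object@emGain, " ADU/e-, read noise ",
        object@readNoiseSD, " ADU, offset ", object@offset, " ADU, QE ",
        object@quantumEfficiency, ", pixel ", object@pixelSize, " nm\n",
        sep = ""))
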