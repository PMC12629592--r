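#' @import methods
#' @importFrom stats coef dgamma dnorm lm mad median pgamma pnorm qnorm
#'   quantile residuals rexp rgamma rnorm rpois runif sd uniroot var IQR
#' @importFrom utils head read.csv tail write.csv
NULL

#' Simulation and acquisition configuration
#'
#' Calibration and camera parameters shared by the synthetic generator and
#' the analysis stages.  All lengths are in nanometres, times in seconds and
#' intensities in arbitrary camera units (A.U.).
#'
#' @slot pixelSize physical pixel size, nm per pixel.
#' @slot frameInterval time between frame starts, s.
#' @slot exposure exposure time per frame, s; must not exceed
#'   \code{frameInterval}.
#' @slot nFrames number of frames in a rendered movie.
#' @slot imageShape integer vector \code{c(rows, cols)} of the field.
#' @slot psfSigma named numeric, PSF Gaussian sigma (nm) per channel.
#' @slot background constant background level, A.U. per pixel.
#' @slot shotNoiseScale photons per A.U.; Poisson shot noise is applied on
#'   the photon scale and converted back.  Zero disables shot noise.
#' @slot readNoiseSD SD of additive Gaussian read noise, A.U.  Zero disables.
#' @slot seed integer RNG seed giving bit-identical output for an identical
#'   configuration.
#'
#' @export
setClass("SimulationConfig",
  representation(
    pixelSize = "numeric",
    frameInterval = "numeric",
    exposure = "numeric",
    nFrames = "integer",
    imageShape = "integer",
    psfSigma = "numeric",
    background = "numeric",
    shotNoiseScale = "numeric",
    readNoiseSD = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@exposure <= 0) msg <- c(msg, "exposure must be > 0")
  if (object@frameInterval < object@exposure)
    msg <- c(msg, "frameInterval must be >= exposure")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
    msg <- c(msg, "imageShape must be two positive integers")
  if (any(object@psfSigma <= 0)) msg <- c(msg, "psfSigma must be > 0")
  if (is.null(names(object@psfSigma)) || any(!nzchar(names(object@psfSigma))))
    msg <- c(msg, "psfSigma must be named by channel")
  if (object@background < 0) msg <- c(msg, "background must be >= 0")
  if (object@shotNoiseScale < 0) msg <- c(msg, "shotNoiseScale must be >= 0")
  if (object@readNoiseSD < 0) msg <- c(msg, "readNoiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults mirror a single-molecule TIRF acquisition on an EMCCD at 100x:
#' 160 nm pixels, frames every 100 ms with a 50 ms exposure, and a 120 nm
#' PSF sigma in each channel.
#'
#' @param pixelSize nm per pixel.
#' @param frameInterval s between frames.
#' @param exposure s exposure per frame.
#' @param nFrames number of frames.
#' @param imageShape c(rows, cols).
#' @param psfSigma named numeric of per-channel PSF sigmas (nm).
#' @param background background level (A.U.).
#' @param shotNoiseScale photons per A.U. (0 = no shot noise).
#' @param readNoiseSD read-noise SD (A.U., 0 = none).
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nFrames = 10, seed = 1)
#' pixelSize(cfg)
#' @export
simulationConfig <- function(pixelSize = 160, frameInterval = 0.1,
                             exposure = 0.05, nFrames = 100L,
                             imageShape = c(64L, 256L),
                             psfSigma = c(microtubule = 120, molecule = 120),
                             background = 100, shotNoiseScale = 1,
                             readNoiseSD = 5, seed = 1L) {
  new("SimulationConfig",
    pixelSize = as.numeric(pixelSize),
    frameInterval = as.numeric(frameInterval),
    exposure = as.numeric(exposure),
    nFrames = as.integer(nFrames),
    imageShape = as.integer(imageShape),
    psfSigma = psfSigma,
    background = as.numeric(background),
    shotNoiseScale = as.numeric(shotNoiseScale),
    readNoiseSD = as.numeric(readNoiseSD),
    seed = as.integer(seed)
  )
}

#' Multi-channel fluorescence movie stack
#'
#' Pixel data for one or more channels sharing shape and calibration.  Each
#' channel is a \code{rows x cols x frames} array of intensities (A.U.).
#' Channel names carry their role (e.g. \code{"microtubule"},
#' \code{"molecule"}, \code{"second_molecule"}, \code{"seed"}).
#'
#' @slot channels named list of 3D numeric arrays, identical dimensions.
#' @slot pixelSize nm per pixel.
#' @slot frameInterval s per frame.
#' @slot metadata free-form list (seed, truth provenance, config hash).
#' @export
setClass("MovieStack",
  representation(
    channels = "list",
    pixelSize = "numeric",
    frameInterval = "numeric",
    metadata = "list"
  )
)

setValidity("MovieStack", function(object) {
  msg <- character()
  if (!length(object@channels)) msg <- c(msg, "at least one channel required")
  if (is.null(names(object@channels)) ||
      any(!nzchar(names(object@channels))))
    msg <- c(msg, "channels must be named by role")
  dims <- lapply(object@channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msg <- c(msg, "each channel must be a rows x cols x frames array")
  else if (length(dims) > 1L &&
           !all(vapply(dims[-1], identical, TRUE, dims[[1]])))
    msg <- c(msg, "all channels must share dimensions")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname MovieStack-class
#' @param channels named list of arrays (rows x cols x frames).
#' @param pixelSize nm per pixel.
#' @param frameInterval s per frame.
#' @param metadata optional list of provenance metadata.
#' @export
movieStack <- function(channels, pixelSize, frameInterval,
                       metadata = list()) {
  new("MovieStack", channels = channels, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval), metadata = metadata)
}

#' Kymograph: time x axial-position intensities per channel
#'
#' Rows are frames (time = row index x frameInterval, starting at 0); columns
#' are positions along the sampling polyline in pixel steps from its first
#' vertex.
#'
#' @slot channels named list of matrices (frames x positions).
#' @slot pixelSize nm per pixel along the axial axis.
#' @slot frameInterval s per frame.
#' @slot axialOrigin pixel coordinates (x, y) of the polyline's first vertex.
#' @slot metadata list.
#' @export
setClass("Kymograph",
  representation(
    channels = "list",
    pixelSize = "numeric",
    frameInterval = "numeric",
    axialOrigin = "numeric",
    metadata = "list"
  )
)

setValidity("Kymograph", function(object) {
  msg <- character()
  if (!length(object@channels)) msg <- c(msg, "at least one channel required")
  dims <- lapply(object@channels, dim)
  if (any(vapply(dims, length, 1L) != 2L))
    msg <- c(msg, "each channel must be a frames x positions matrix")
  else if (length(dims) > 1L &&
           !all(vapply(dims[-1], identical, TRUE, dims[[1]])))
    msg <- c(msg, "all channels must share dimensions")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (length(msg)) msg else TRUE
})

## ---- generics & accessors ----

#' @rdname SimulationConfig-class
#' @param object,x an object with calibration.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname SimulationConfig-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname MovieStack-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname MovieStack-class
#' @param name channel role name.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))
#' @rdname MovieStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setMethod("pixelSize", "SimulationConfig", function(x) x@pixelSize)
#' @export
setMethod("pixelSize", "MovieStack", function(x) x@pixelSize)
#' @export
setMethod("pixelSize", "Kymograph", function(x) x@pixelSize)
#' @export
setMethod("frameInterval", "SimulationConfig", function(x) x@frameInterval)
#' @export
setMethod("frameInterval", "MovieStack", function(x) x@frameInterval)
#' @export
setMethod("frameInterval", "Kymograph", function(x) x@frameInterval)
#' @export
setMethod("channelNames", "MovieStack", function(x) names(x@channels))
#' @export
setMethod("channelNames", "Kymograph", function(x) names(x@channels))

#' @export
setMethod("getChannel", "MovieStack", function(x, name) {
  if (!name %in% names(x@channels))
    stop("channel role '", name, "' not present; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[name]]
})
#' @export
setMethod("getChannel", "Kymograph", function(x, name) {
  if (!name %in% names(x@channels))
    stop("channel role '", name, "' not present; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[name]]
})

#' @export
setMethod("nFrames", "MovieStack", function(x) dim(x@channels[[1]])[3])
#' @export
setMethod("nFrames", "Kymograph", function(x) nrow(x@channels[[1]]))

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@imageShape[1], "x", object@imageShape[2],
      "px,", object@nFrames, "frames\n")
  cat("  pixel ", object@pixelSize, " nm, interval ", object@frameInterval,
      " s (exposure ", object@exposure, " s)\n", sep = "")
  cat("  PSF sigma (nm):",
      paste(names(object@psfSigma), signif(object@psfSigma, 4),
            sep = "=", collapse = ", "), "\n")
  cat("  background", object@background, "A.U., read noise SD",
      object@readNoiseSD, "A.U., seed", object@seed, "\n")
})

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@channels[[1]])
  cat("MovieStack:", d[1], "x", d[2], "px,", d[3], "frames,",
      length(object@channels), "channel(s):",
      paste(names(object@channels), collapse = ", "), "\n")
  cat("  pixel", object@pixelSize, "nm, interval", object@frameInterval,
      "s\n")
})

setMethod("show", "Kymograph", function(object) {
  d <- dim(object@channels[[1]])
  cat("Kymograph:", d[1], "frames x", d[2], "positions,",
      length(object@channels), "channel(s):",
      paste(names(object@channels), collapse = ", "), "\n")
  cat("  pixel", object@pixelSize, "nm, interval", object@frameInterval,
      "s\n")
})
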