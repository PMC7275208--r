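#' @title Generics
#' @name aortamark-generics
#' @description Accessor and backend generics for the package's S4 classes.
#' @param object,x an object.
#' @param backend a [DetectorBackend-class].
#' @param volume a normalised [CTVolume-class].
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname aortamark-generics
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname aortamark-generics
#' @export
setGeneric("gridShape", function(object) standardGeneric("gridShape"))

#' @rdname aortamark-generics
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname aortamark-generics
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

#' @rdname aortamark-generics
#' @export
setGeneric("direction", function(object) standardGeneric("direction"))

#' @rdname aortamark-generics
#' @export
setGeneric("voxelUnit", function(object) standardGeneric("voxelUnit"))

#' @rdname aortamark-generics
#' @export
setGeneric("voxelValues", function(object) standardGeneric("voxelValues"))

#' @rdname aortamark-generics
#' @export
setGeneric("landmarkPoints", function(object) standardGeneric("landmarkPoints"))

#' @rdname aortamark-generics
#' @export
setGeneric("classMap", function(object, ...) standardGeneric("classMap"))

#' Run a detector backend over a normalised volume
#'
#' Maps a window-normalised [CTVolume-class] to per-class probabilities on
#' the same grid. Every backend must return a [ProbabilityMaps-class] whose
#' per-voxel class probabilities sum to 1.
#'
#' @param backend a [DetectorBackend-class].
#' @param volume a [CTVolume-class] with unit \code{"normalized"} (or
#'   \code{"probability"}).
#' @param ... passed to methods.
#' @return a [ProbabilityMaps-class] on \code{geometry(volume)}.
#' @export
setGeneric("predictProbabilities",
    function(backend, volume, ...) standardGeneric("predictProbabilities"))
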