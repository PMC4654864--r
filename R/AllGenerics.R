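# Accessor generics. Slot access from user code is discouraged; these are the
# supported interface.

#' Number of segmented nuclei
#' @param object a \linkS4class{NucleusSet} or \linkS4class{FociCount}.
#' @return an integer count.
#' @export
setGeneric("nucleusCount", function(object) standardGeneric("nucleusCount"))

#' Label matrix of a NucleusSet
#' @param object a \linkS4class{NucleusSet}.
#' @return integer matrix, 0 = background.
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' Per-nucleus records (label, area, bounding box, centroid)
#' @param object a \linkS4class{NucleusSet}.
#' @return a data.frame with one row per nucleus.
#' @export
setGeneric("nucleusRecords", function(object) standardGeneric("nucleusRecords"))

#' Per-nucleus foci counts
#' @param object a \linkS4class{FociCount}.
#' @return named integer vector (names = nucleus labels).
#' @export
setGeneric("fociPerNucleus", function(object) standardGeneric("fociPerNucleus"))

#' Focus detections
#' @param object a \linkS4class{FociCount}.
#' @return data.frame with centroid, nucleus label, peak intensity and area
#'   of every detected focus.
#' @export
setGeneric("detections", function(object) standardGeneric("detections"))

#' Mean foci per nucleus
#' @param object a \linkS4class{FociCount}.
#' @return numeric mean (NA when the image has no nuclei).
#' @export
setGeneric("meanFoci", function(object) standardGeneric("meanFoci"))

#' Standard error of the mean foci count
#' @param object a \linkS4class{FociCount}.
#' @return numeric SEM; 0 for a single nucleus, NA without nuclei.
#' @export
setGeneric("semFoci", function(object) standardGeneric("semFoci"))

#' Ground-truth focus coordinates of a simulated image
#' @param object a \linkS4class{SimulatedFoci}.
#' @return n x 2 matrix of (row, col) positions.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' True number of foci in a simulated image
#' @param object a \linkS4class{SimulatedFoci}.
#' @return integer count.
#' @export
setGeneric("trueFociCount", function(object) standardGeneric("trueFociCount"))

#' Pixel matrix of an object carrying an image
#' @param object a \linkS4class{SimulatedFoci}.
#' @return numeric intensity matrix in [0,1].
#' @export
setGeneric("pixelMatrix", function(object) standardGeneric("pixelMatrix"))

#' @rdname nucleusCount
#' @export
setMethod("nucleusCount", "NucleusSet", function(object) nrow(object@records))

#' @rdname nucleusCount
#' @export
setMethod("nucleusCount", "FociCount", function(object) object@nNuclei)

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "NucleusSet", function(object) object@labels)

#' @rdname nucleusRecords
#' @export
setMethod("nucleusRecords", "NucleusSet", function(object) object@records)

#' @rdname fociPerNucleus
#' @export
setMethod("fociPerNucleus", "FociCount", function(object) object@perNucleusCounts)

#' @rdname detections
#' @export
setMethod("detections", "FociCount", function(object) object@detections)

#' @rdname meanFoci
#' @export
setMethod("meanFoci", "FociCount", function(object)
  if (object@nNuclei > 0) object@meanPerNucleus else NA_real_)

#' @rdname semFoci
#' @export
setMethod("semFoci", "FociCount", function(object)
  if (object@nNuclei > 0) object@sem else NA_real_)

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SimulatedFoci", function(object) object@gtCoordinates)

#' @rdname trueFociCount
#' @export
setMethod("trueFociCount", "SimulatedFoci", function(object) object@nFociTrue)

#' @rdname pixelMatrix
#' @export
setMethod("pixelMatrix", "SimulatedFoci", function(object) object@image)
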