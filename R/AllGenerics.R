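#' Extract the bars of a persistence barcode
#'
#' @param x a [PersistenceBarcode-class].
#' @param dim optional homology dimension (0 or 1) to restrict to.
#' @param dropZero drop zero-lifetime bars (topological noise created and
#'   destroyed at the same level)?
#' @return data.frame with columns `dim`, `birth`, `death`, `essential`,
#'   `lifetime`.
#' @export
setGeneric("bars", function(x, dim = NULL, dropZero = FALSE)
    standardGeneric("bars"))

#' Per-class prediction scores of a fitted window classifier
#'
#' @param object a [TopoClassifier-class].
#' @param newdata matrix (windows x features) or [TopoFeatureSet-class].
#' @return numeric matrix, one column per training class, higher = more
#'   confident. Probabilities for DTC/RF/NBC, posteriors for LDA, signed
#'   one-vs-rest decision values for SVM.
#' @export
setGeneric("predictScores", function(object, newdata)
    standardGeneric("predictScores"))

#' Accessors for TopoFeatureSet window metadata
#'
#' `featureMatrix` returns the windows x features numeric matrix
#' (transposed assay, ready for the classifiers); `classLabels`,
#' `glandIds` and `imageIds` return the per-window class label, the
#' globally unique gland identifier (`image_id/gland_id`) and the source
#' image identifier.
#'
#' @param x a [TopoFeatureSet-class].
#' @name TopoFeatureSet-accessors
#' @rdname TopoFeatureSet-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname TopoFeatureSet-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname TopoFeatureSet-accessors
#' @export
setGeneric("glandIds", function(x) standardGeneric("glandIds"))

#' @rdname TopoFeatureSet-accessors
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))
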