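#' @import methods
NULL

## Canonical order of the per-window descriptors. Everything downstream
## (feature tables, classifiers, CSV export) relies on this ordering.
.FEATURE_NAMES <- c("mean_life_dim0", "std_life_dim0",
                    "mean_life_dim1", "std_life_dim1",
                    "entropy_dim0", "entropy_dim1",
                    "pixel_mean", "pixel_std")

#' Filtered cubical complex of a grayscale image
#'
#' The V-construction over an \eqn{r \times c} intensity grid: pixels are
#' vertices, edges join horizontal/vertical neighbours, unit squares are
#' bounded by four edges. A cell's filtration value is the maximum intensity
#' over its vertices, so every sublevel set of cells is a subcomplex. Cells
#' are stored in filtration order: ascending value, ties broken by ascending
#' dimension, then anchor row, column and orientation. Facets therefore
#' always precede their cofaces.
#'
#' @slot nrow,ncol image dimensions (pixels).
#' @slot dim integer cell dimensions (0, 1 or 2), in filtration order.
#' @slot value numeric filtration value per cell.
#' @slot anchor integer matrix of 0-based (row, col) anchors per cell.
#' @slot orientation integer; 0 for vertices/squares, 1 horizontal edge,
#'   2 vertical edge.
#' @slot boundary list of integer vectors; for each cell the (sorted,
#'   1-based) filtration indices of its facets.
#' @slot levels sorted distinct filtration values.
#'
#' @seealso [cubicalComplex()], [computePersistence()], [sublevelCells()]
#' @export
setClass("CubicalComplex",
    representation(nrow = "integer", ncol = "integer",
                   dim = "integer", value = "numeric",
                   anchor = "matrix", orientation = "integer",
                   boundary = "list", levels = "numeric"))

setValidity("CubicalComplex", function(object) {
    r <- object@nrow; cc <- object@ncol
    n <- length(object@dim)
    msg <- character()
    if (r < 1L || cc < 1L)
        msg <- c(msg, "image must have at least one row and one column")
    expected <- r * cc + r * (cc - 1L) + (r - 1L) * cc + (r - 1L) * (cc - 1L)
    if (n != expected)
        msg <- c(msg, sprintf("cell count %d != closed form %d", n, expected))
    if (length(object@value) != n || length(object@boundary) != n ||
        nrow(object@anchor) != n || length(object@orientation) != n)
        msg <- c(msg, "slot lengths disagree")
    if (any(!is.finite(object@value)))
        msg <- c(msg, "non-finite filtration values")
    tab <- tabulate(object@dim + 1L, nbins = 3L)
    if (tab[1L] != r * cc ||
        tab[2L] != r * (cc - 1L) + (r - 1L) * cc ||
        tab[3L] != (r - 1L) * (cc - 1L))
        msg <- c(msg, "per-dimension cell counts violate the grid formulas")
    ## facets precede cofaces and never exceed their coface's value
    fl <- unlist(object@boundary, use.names = FALSE)
    coface <- rep.int(seq_len(n), lengths(object@boundary))
    if (length(fl)) {
        if (any(fl >= coface)) msg <- c(msg, "facet after coface")
        if (any(object@value[fl] > object@value[coface] + 1e-12))
            msg <- c(msg, "filtration monotonicity violated")
    }
    if (length(msg)) msg else TRUE
})

#' Persistence barcode
#'
#' Multiset of (birth, death) intervals per homology dimension produced by
#' [computePersistence()]. Essential classes (alive at the top of the
#' filtration) have their infinite death replaced by
#' \eqn{m = \max F + 1}, one more than the largest filtration level, and are
#' flagged. Zero-lifetime pairs (birth = death) are retained and flagged
#' implicitly by their lifetime; feature extraction drops them.
#'
#' @slot dim integer homology dimension per bar (0 or 1).
#' @slot birth,death numeric filtration values; `death >= birth`.
#' @slot essential logical; `TRUE` for classes that never die.
#' @slot m the substitution level `max(F) + 1`.
#'
#' @seealso [bars()], [persistentEntropy()], [writeBarcode()]
#' @export
setClass("PersistenceBarcode",
    representation(dim = "integer", birth = "numeric", death = "numeric",
                   essential = "logical", m = "numeric"))

setValidity("PersistenceBarcode", function(object) {
    n <- length(object@dim)
    msg <- character()
    if (length(object@birth) != n || length(object@death) != n ||
        length(object@essential) != n)
        msg <- c(msg, "slot lengths disagree")
    if (length(object@m) != 1L) msg <- c(msg, "m must be a single value")
    if (n && any(object@death < object@birth - 1e-12))
        msg <- c(msg, "death before birth")
    if (n && any(object@essential & abs(object@death - object@m) > 1e-12))
        msg <- c(msg, "essential bars must die at m = max(F) + 1")
    if (n && !all(object@dim %in% c(0L, 1L)))
        msg <- c(msg, "only dimensions 0 and 1 are recorded")
    if (length(msg)) msg else TRUE
})

#' Window-level topological feature container
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay,
#' `"features"`, is the 8 x n matrix of per-window descriptors (rows in the
#' canonical order `mean_life_dim0, std_life_dim0, mean_life_dim1,
#' std_life_dim1, entropy_dim0, entropy_dim1, pixel_mean, pixel_std`) and
#' whose `colData` carries `image_id`, `gland_id`, `class_label`,
#' `window_row`, `window_col` per window.
#'
#' @seealso [extractGlandFeatures()], [extractDatasetFeatures()],
#'   [kfoldEvaluate()]
#' @export
setClass("TopoFeatureSet",
    contains = "SummarizedExperiment")

setValidity("TopoFeatureSet", function(object) {
    msg <- character()
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'features' is required")
    else if (!identical(rownames(object), .FEATURE_NAMES))
        msg <- c(msg, paste("assay rows must be the 8 canonical features:",
                            paste(.FEATURE_NAMES, collapse = ", ")))
    need <- c("image_id", "gland_id", "class_label",
              "window_row", "window_col")
    miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
    if (length(miss))
        msg <- c(msg, paste("missing colData columns:",
                            paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Fitted window classifier
#'
#' Thin S4 wrapper around one of the five supported learners so that all of
#' them expose the same `predict`/[predictScores()] surface. The SVM variant
#' holds one binary machine per class (one-against-all).
#'
#' @slot method one of `"DTC"`, `"RF"`, `"SVM"`, `"NBC"`, `"LDA"`.
#' @slot fit the underlying fitted model (a list of binary fits for SVM).
#' @slot levels class labels seen at training, in sort order.
#' @slot featureNames column names the model expects.
#' @slot standardize logical; whether features were centred/scaled (kept
#'   with the means/sds needed to transform new data).
#' @slot center,scale numeric transforms applied when `standardize = TRUE`.
#' @export
setClass("TopoClassifier",
    representation(method = "character", fit = "ANY", levels = "character",
                   featureNames = "character", standardize = "logical",
                   center = "numeric", scale = "numeric"))

#' Cross-validation evaluation report
#'
#' Result of [kfoldEvaluate()]: repeated stratified k-fold cross-validation
#' of one classifier, reported at window, gland (majority vote) and image
#' level, with aggregated confusion matrices and one-vs-rest ROC AUC.
#'
#' @slot method classifier name.
#' @slot k,repeats CV geometry.
#' @slot splitLevel `"gland"` (leakage-safe default) or `"window"`.
#' @slot accuracy named numeric (percent): `window`, `gland`, `image`.
#' @slot aucClass per-class one-vs-rest AUC, averaged over folds/repeats.
#' @slot aucMacro macro-averaged AUC.
#' @slot perFold data.frame with one row per (repeat, fold).
#' @slot perRepeat data.frame with one row per repeat.
#' @slot confusionWindow,confusionGland count matrices (true x predicted)
#'   accumulated over all folds and repeats.
#' @slot hyperparameters list recording the learner settings used.
#' @export
setClass("EvaluationReport",
    representation(method = "character", k = "integer", repeats = "integer",
                   splitLevel = "character", accuracy = "numeric",
                   aucClass = "numeric", aucMacro = "numeric",
                   perFold = "data.frame", perRepeat = "data.frame",
                   confusionWindow = "matrix", confusionGland = "matrix",
                   hyperparameters = "list"))

setValidity("EvaluationReport", function(object) {
    msg <- character()
    if (!all(c("window", "gland", "image") %in% names(object@accuracy)))
        msg <- c(msg, "accuracy must be named window/gland/image")
    if (any(object@accuracy < -1e-9 | object@accuracy > 100 + 1e-9))
        msg <- c(msg, "accuracies are percentages in [0, 100]")
    ok <- is.na(object@aucMacro) ||
        (object@aucMacro >= -1e-9 && object@aucMacro <= 1 + 1e-9)
    if (!ok) msg <- c(msg, "macro AUC outside [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Synthetic gland image generator configuration
#'
#' Class-conditional parameters of the generator in [simulateGland()] /
#' [simulateDataset()]. Each class draws a Poisson number of lumens
#' (dark annular rims around near-body-intensity interiors) and a smoothed
#' background texture field whose amplitude is class-dependent; all glands
#' of one synthetic image share a class, mirroring whole-slide structure.
#'
#' @slot classes class labels, one per class.
#' @slot lumenMean expected lumens per gland, one per class (strictly
#'   increasing across classes).
#' @slot lumenRadiusRange 2-row matrix (min, max ring radius in px), one
#'   column per class.
#' @slot textureAmplitude intensity sd of the smoothed background field,
#'   one per class.
#' @slot textureScale half-width (px) of the box kernel smoothing the
#'   background field.
#' @slot noiseSd per-pixel additive Gaussian noise sd (intensity units).
#' @slot bodyValue,lumenValue gland body and lumen-rim intensities (8-bit
#'   scale).
#' @slot ringWidth lumen rim thickness in px.
#' @slot glandSize side length of a gland image in px.
#' @slot glandsPerImage,imagesPerClass dataset geometry.
#' @slot seed RNG seed used by [simulateDataset()].
#' @export
setClass("SyntheticGlandConfig",
    representation(classes = "character", lumenMean = "numeric",
                   lumenRadiusRange = "matrix", textureAmplitude = "numeric",
                   textureScale = "numeric", noiseSd = "numeric",
                   bodyValue = "numeric", lumenValue = "numeric",
                   ringWidth = "numeric", glandSize = "integer",
                   glandsPerImage = "integer", imagesPerClass = "integer",
                   seed = "integer"))

setValidity("SyntheticGlandConfig", function(object) {
    k <- length(object@classes)
    msg <- character()
    if (k < 1L) msg <- c(msg, "at least one class")
    if (length(object@lumenMean) != k ||
        length(object@textureAmplitude) != k ||
        ncol(object@lumenRadiusRange) != k)
        msg <- c(msg, "per-class parameter lengths must match classes")
    if (anyDuplicated(object@classes))
        msg <- c(msg, "class labels must be unique")
    if (k > 1L && any(diff(object@lumenMean) <= 0))
        msg <- c(msg, "expected lumen counts must increase across classes")
    if (any(object@lumenMean < 0) || object@noiseSd < 0 ||
        any(object@textureAmplitude < 0))
        msg <- c(msg, "rates and noise levels must be non-negative")
    if (object@glandSize < 8L || object@glandsPerImage < 1L ||
        object@imagesPerClass < 1L)
        msg <- c(msg, "counts and sizes must be positive")
    rmax <- max(object@lumenRadiusRange)
    if (2 * (rmax + object@ringWidth + 2) >= object@glandSize)
        msg <- c(msg, "lumen radius too large for gland size")
    if (object@lumenValue >= object@bodyValue)
        msg <- c(msg, "lumen rim must be darker than the gland body")
    if (length(msg)) msg else TRUE
})
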