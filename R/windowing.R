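#' Sliding-window positions over a gland image
#'
#' Square windows of side `windowSize` swept with the given stride, in
#' row-major order. Coordinates are 0-based and windows are half-open
#' `[r, r + w) x [c, c + w)`; per axis there are
#' `floor((extent - windowSize) / stride) + 1` positions. Windows are never
#' padded: trailing pixels not covered by a full window are dropped, so no
#' window exceeds the image bounds. With a gland mask, windows whose
#' in-mask pixel fraction falls below `minCoverage` are discarded.
#'
#' @param image numeric matrix (or anything with a `dim`), the gland image.
#' @param windowSize window side in pixels (>= 2; the study sizes are 40,
#'   50, 60).
#' @param stride step in pixels, `1 <= stride <= windowSize`; the default
#'   half-window stride gives the usual 50% overlap.
#' @param mask optional matrix of the same size; pixels > 0 are in-gland.
#' @param minCoverage minimal in-mask fraction for a window to survive.
#' @return data.frame with 0-based columns `row`, `col`.
#' @examples
#' nrow(slideWindows(matrix(0, 100, 100), 50, 25))  # 9
#' @export
slideWindows <- function(image, windowSize, stride = max(1L, windowSize %/% 2L),
                         mask = NULL, minCoverage = 0.5) {
    d <- dim(image)
    if (is.null(d) || length(d) != 2L) stop("'image' must be a matrix")
    windowSize <- as.integer(windowSize); stride <- as.integer(stride)
    if (windowSize < 2L) stop("windowSize must be at least 2")
    if (stride < 1L || stride > windowSize)
        stop("stride must satisfy 1 <= stride <= windowSize")
    if (windowSize > d[1L] || windowSize > d[2L])
        stop(sprintf("window (%d) larger than image (%d x %d)",
                     windowSize, d[1L], d[2L]))
    rs <- seq.int(0L, d[1L] - windowSize, by = stride)
    cs <- seq.int(0L, d[2L] - windowSize, by = stride)
    g <- expand.grid(col = cs, row = rs)  # col fastest -> row-major
    pos <- data.frame(row = g$row, col = g$col)
    if (!is.null(mask)) {
        if (!identical(dim(mask), d)) stop("mask dimensions must match image")
        keep <- vapply(seq_len(nrow(pos)), function(i) {
            sub <- mask[pos$row[i] + seq_len(windowSize),
                        pos$col[i] + seq_len(windowSize)]
            mean(sub > 0) >= minCoverage
        }, logical(1))
        pos <- pos[keep, , drop = FALSE]
        if (!nrow(pos)) stop("no window reaches the mask coverage threshold")
        rownames(pos) <- NULL
    }
    pos
}

#' Extract window feature vectors for one gland
#'
#' Runs [windowFeatures()] on every surviving window position of
#' [slideWindows()]. Windows are independent, so the result does not
#' depend on traversal order beyond row ordering.
#'
#' @inheritParams slideWindows
#' @param glandId,imageId,classLabel metadata attached to every window row.
#' @return data.frame: `image_id`, `gland_id`, `class_label`,
#'   `window_row`, `window_col`, then the 8 features.
#' @export
extractGlandFeatures <- function(image, glandId, imageId = glandId,
                                 classLabel = NA_character_,
                                 windowSize = 50L,
                                 stride = max(1L, windowSize %/% 2L),
                                 mask = NULL, minCoverage = 0.5) {
    pos <- slideWindows(image, windowSize, stride, mask, minCoverage)
    feats <- t(vapply(seq_len(nrow(pos)), function(i) {
        w <- image[pos$row[i] + seq_len(windowSize),
                   pos$col[i] + seq_len(windowSize)]
        windowFeatures(w)
    }, numeric(length(.FEATURE_NAMES))))
    cbind(data.frame(image_id = as.character(imageId),
                     gland_id = as.character(glandId),
                     class_label = as.character(classLabel),
                     window_row = pos$row, window_col = pos$col,
                     stringsAsFactors = FALSE),
          as.data.frame(feats))
}

#' Extract features for a whole labelled dataset
#'
#' Consumes a manifest (data.frame or CSV path) with columns `path`,
#' `image_id`, `gland_id`, `class_label`, one row per cropped gland image,
#' reads each image with [readGrayImage()] and assembles all window
#' feature vectors into a [TopoFeatureSet-class].
#'
#' @param manifest data.frame or CSV path.
#' @param dir directory that relative `path` entries are resolved against
#'   (defaults to the manifest's own directory when a path is given).
#' @inheritParams slideWindows
#' @return a [TopoFeatureSet-class].
#' @export
extractDatasetFeatures <- function(manifest, dir = NULL, windowSize = 50L,
                                   stride = max(1L, windowSize %/% 2L),
                                   minCoverage = 0.5) {
    if (is.character(manifest)) {
        if (is.null(dir)) dir <- dirname(manifest)
        manifest <- read.csv(manifest, stringsAsFactors = FALSE)
    }
    need <- c("path", "image_id", "gland_id", "class_label")
    if (!all(need %in% names(manifest)))
        stop("manifest needs columns: ", paste(need, collapse = ", "))
    tabs <- lapply(seq_len(nrow(manifest)), function(i) {
        p <- manifest$path[i]
        if (!is.null(dir) && !file.exists(p)) p <- file.path(dir, p)
        extractGlandFeatures(readGrayImage(p),
                             glandId = manifest$gland_id[i],
                             imageId = manifest$image_id[i],
                             classLabel = manifest$class_label[i],
                             windowSize = windowSize, stride = stride)
    })
    TopoFeatureSet(do.call(rbind, tabs))
}

#' Construct a TopoFeatureSet from a window feature table
#'
#' @param table data.frame as produced by [extractGlandFeatures()] (window
#'   metadata columns plus the 8 features).
#' @return a [TopoFeatureSet-class].
#' @export
TopoFeatureSet <- function(table) {
    meta <- c("image_id", "gland_id", "class_label",
              "window_row", "window_col")
    if (!all(c(meta, .FEATURE_NAMES) %in% names(table)))
        stop("feature table is missing required columns")
    m <- t(as.matrix(table[.FEATURE_NAMES]))
    colnames(m) <- sprintf("w%05d", seq_len(ncol(m)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = m),
        colData = S4Vectors::DataFrame(table[meta],
                                       row.names = colnames(m)))
    new("TopoFeatureSet", se)
}

#' @rdname TopoFeatureSet-accessors
#' @export
setMethod("featureMatrix", "TopoFeatureSet", function(x)
    t(SummarizedExperiment::assay(x, "features")))

#' @rdname TopoFeatureSet-accessors
#' @export
setMethod("classLabels", "TopoFeatureSet", function(x)
    as.character(SummarizedExperiment::colData(x)$class_label))

#' @rdname TopoFeatureSet-accessors
#' @export
setMethod("glandIds", "TopoFeatureSet", function(x)
    paste(SummarizedExperiment::colData(x)$image_id,
          SummarizedExperiment::colData(x)$gland_id, sep = "/"))

#' @rdname TopoFeatureSet-accessors
#' @export
setMethod("imageIds", "TopoFeatureSet", function(x)
    as.character(SummarizedExperiment::colData(x)$image_id))

setMethod("show", "TopoFeatureSet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf(
        "TopoFeatureSet: %d windows, %d glands, %d images, %d classes\n",
        ncol(object), length(unique(paste(cd$image_id, cd$gland_id))),
        length(unique(cd$image_id)),
        length(unique(cd$class_label[!is.na(cd$class_label)]))))
    cat("  features:", paste(rownames(object), collapse = ", "), "\n")
})

#' Write / read a window feature table CSV
#'
#' Plain-text interchange of a [TopoFeatureSet-class]: one row per window
#' with `image_id`, `gland_id`, `class_label`, `window_row`, `window_col`
#' and the 8 features.
#'
#' @param fs a [TopoFeatureSet-class].
#' @param path CSV file path.
#' @export
writeFeatureTable <- function(fs, path) {
    stopifnot(is(fs, "TopoFeatureSet"))
    df <- cbind(as.data.frame(SummarizedExperiment::colData(fs)),
                as.data.frame(featureMatrix(fs)))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    TopoFeatureSet(read.csv(path, stringsAsFactors = FALSE))
}
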