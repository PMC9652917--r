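.CLASSIFIERS <- c("DTC", "RF", "SVM", "NBC", "LDA")

.asFeatureDf <- function(x) {
    df <- as.data.frame(x)
    names(df) <- make.names(names(df))
    df
}

#' Fit one of the five window classifiers
#'
#' Trains a decision tree (`rpart`), random forest (`randomForest`),
#' one-against-all multi-class SVM (one binary `e1071::svm` machine per
#' class), naive Bayes (`e1071::naiveBayes`) or linear discriminant
#' analysis (`MASS::lda`) on window feature vectors. All learners use
#' library defaults; stochastic learners are made reproducible through
#' `seed`. Features are unscaled by default (trees, NB and LDA are
#' unaffected by monotone rescaling); `standardize = TRUE` centres and
#' scales, which mainly matters for the SVM margins.
#'
#' @param x windows x features numeric matrix, or a
#'   [TopoFeatureSet-class] (labels then default to its `class_label`).
#' @param labels class label per window; at least two classes.
#' @param method one of `"DTC"`, `"RF"`, `"SVM"`, `"NBC"`, `"LDA"`.
#' @param seed integer seed applied before fitting.
#' @param standardize centre/scale features (stored and re-applied at
#'   prediction).
#' @return a [TopoClassifier-class].
#' @export
fitClassifier <- function(x, labels = NULL,
                          method = c("DTC", "RF", "SVM", "NBC", "LDA"),
                          seed = NULL, standardize = FALSE) {
    method <- match.arg(method)
    if (is(x, "TopoFeatureSet")) {
        if (is.null(labels)) labels <- classLabels(x)
        x <- featureMatrix(x)
    }
    x <- as.matrix(x)
    if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
    if (length(labels) != nrow(x)) stop("labels must match rows of x")
    y <- factor(as.character(labels))
    if (nlevels(y) < 2L) stop("training set must contain at least 2 classes")

    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
    if (standardize) {
        ctr <- colMeans(x)
        scl <- apply(x, 2L, stats::sd); scl[scl == 0] <- 1
        x <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
    }
    if (!is.null(seed)) set.seed(seed)

    df <- .asFeatureDf(x)
    fit <- switch(method,
        DTC = rpart::rpart(.y ~ ., data = cbind(df, .y = y),
                           method = "class"),
        RF  = randomForest::randomForest(x, y),
        NBC = e1071::naiveBayes(x, y),
        LDA = MASS::lda(x, grouping = y),
        SVM = lapply(levels(y), function(k) {
            yb <- factor(ifelse(y == k, "pos", "rest"),
                         levels = c("pos", "rest"))
            e1071::svm(x, yb, kernel = "radial", scale = FALSE)
        }))

    new("TopoClassifier", method = method, fit = fit, levels = levels(y),
        featureNames = colnames(x) %||% character(0),
        standardize = standardize, center = ctr, scale = scl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname predictScores
#' @export
setMethod("predictScores", "TopoClassifier", function(object, newdata) {
    if (is(newdata, "TopoFeatureSet")) newdata <- featureMatrix(newdata)
    newdata <- as.matrix(newdata)
    if (object@standardize)
        newdata <- sweep(sweep(newdata, 2L, object@center), 2L,
                         object@scale, "/")
    sc <- switch(object@method,
        DTC = predict(object@fit, newdata = .asFeatureDf(newdata),
                      type = "prob"),
        RF  = predict(object@fit, newdata = newdata, type = "prob"),
        NBC = predict(object@fit, newdata = newdata, type = "raw"),
        LDA = predict(object@fit, newdata = newdata)$posterior,
        SVM = {
            dv <- vapply(object@fit, function(f) {
                d <- attr(predict(f, newdata, decision.values = TRUE),
                          "decision.values")
                v <- as.numeric(d)
                # libsvm orients the margin towards whichever label it saw
                # first in training; normalise so "pos" is positive
                if (!startsWith(colnames(d)[1L], "pos")) v <- -v
                v
            }, numeric(nrow(newdata)))
            if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1L)
            colnames(dv) <- object@levels
            dv
        })
    sc <- as.matrix(sc)
    sc[, object@levels, drop = FALSE]
})

#' Predict window class labels
#'
#' Argmax over [predictScores()]; ties resolve to the first (sort-order
#' smallest) class.
#'
#' @param object a [TopoClassifier-class].
#' @param newdata matrix or [TopoFeatureSet-class].
#' @param ... ignored.
#' @return character vector of predicted labels.
#' @export
setMethod("predict", "TopoClassifier", function(object, newdata, ...) {
    sc <- predictScores(object, newdata)
    object@levels[max.col(sc, ties.method = "first")]
})

setMethod("show", "TopoClassifier", function(object) {
    cat(sprintf("TopoClassifier (%s): %d classes [%s]%s\n",
                object@method, length(object@levels),
                paste(object@levels, collapse = ", "),
                if (object@standardize) ", standardized features" else ""))
})

#' Majority vote over window predictions
#'
#' A gland's predicted class is the most common class among its windows'
#' predictions. Ties resolve deterministically to the smallest label in
#' sort order.
#'
#' @param labels non-empty vector of predicted labels.
#' @return single label (character).
#' @examples
#' majorityVote(c("3", "3", "4"))  # "3"
#' majorityVote(c("4", "3"))       # "3" (tie-break)
#' @export
majorityVote <- function(labels) {
    if (!length(labels)) stop("majority vote of an empty prediction list")
    tab <- table(as.character(labels))  # names sorted ascending
    names(tab)[which.max(tab)]
}
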