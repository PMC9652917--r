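#' One-vs-rest ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' `score >= t`), records the (FPR, TPR) operating points and integrates
#' by the trapezoid rule. Tied scores collapse to a single operating
#' point.
#'
#' @param scores numeric score for the positive class.
#' @param positive logical (or coercible) indicator of the positive class;
#'   must contain both classes.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`,
#'   including the (0,0) endpoint at `threshold = Inf`) and `auc`.
#' @export
rocAuc <- function(scores, positive) {
    positive <- as.logical(positive)
    if (length(scores) != length(positive)) stop("length mismatch")
    nP <- sum(positive); nN <- sum(!positive)
    if (nP == 0L || nN == 0L)
        stop("ROC needs both positive and negative examples")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; p <- positive[ord]
    tp <- cumsum(p); fp <- cumsum(!p)
    last <- !duplicated(s, fromLast = TRUE)  # one point per distinct score
    pts <- data.frame(threshold = c(Inf, s[last]),
                      fpr = c(0, fp[last] / nN),
                      tpr = c(0, tp[last] / nP))
    auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
    list(points = pts, auc = auc)
}

.aucValue <- function(scores, positive) rocAuc(scores, positive)$auc

#' Confusion matrix and derived accuracy
#'
#' @param true,predicted aligned label vectors.
#' @param levels label universe for the matrix axes (default: union, in
#'   sort order).
#' @return `confusionCounts`: counts matrix (true x predicted);
#'   `accuracyFromConfusion`: percent accuracy `100 * trace / total`.
#' @export
confusionCounts <- function(true, predicted, levels = NULL) {
    if (length(true) != length(predicted)) stop("length mismatch")
    if (is.null(levels))
        levels <- sort(unique(c(as.character(true), as.character(predicted))))
    table(true = factor(true, levels = levels),
          predicted = factor(predicted, levels = levels))
}

#' @rdname confusionCounts
#' @param confusion square counts matrix.
#' @export
accuracyFromConfusion <- function(confusion) {
    100 * sum(diag(as.matrix(confusion))) / sum(confusion)
}

#' Stratified gland-level fold assignment
#'
#' Assigns glands to k folds, stratified by class so that every fold holds
#' a roughly equal share (sizes differing by at most one) of each class's
#' glands. Splitting at the gland level keeps all windows of a gland in
#' one fold, so no window of a test gland ever appears in training.
#'
#' @param glandClass named character vector: class label per gland id.
#' @param k number of folds.
#' @return named integer vector of fold ids (1..k) per gland.
#' @export
makeGlandFolds <- function(glandClass, k) {
    k <- as.integer(k)
    counts <- table(glandClass)
    if (any(counts < k))
        stop(sprintf(
            "class '%s' has %d glands, fewer than k = %d folds",
            names(counts)[which.min(counts)], min(counts), k))
    folds <- integer(length(glandClass))
    names(folds) <- names(glandClass)
    offset <- 0L  # rotate leftover assignment so overall sizes stay even
    for (cl in names(counts)) {
        ids <- which(glandClass == cl)
        folds[ids[sample.int(length(ids))]] <-
            (seq_along(ids) - 1L + offset) %% k + 1L
        offset <- (offset + length(ids)) %% k
    }
    folds
}

#' Permute class labels across glands
#'
#' Null-model control: reassigns the gland-to-class map by a random
#' permutation while keeping every window attached to its gland, breaking
#' any feature/label association without touching the feature geometry.
#'
#' @param fs a [TopoFeatureSet-class].
#' @param seed RNG seed.
#' @return a [TopoFeatureSet-class] with permuted `class_label`.
#' @export
permuteGlandLabels <- function(fs, seed = NULL) {
    stopifnot(is(fs, "TopoFeatureSet"))
    if (!is.null(seed)) set.seed(seed)
    g <- glandIds(fs)
    glands <- unique(g)
    cls <- classLabels(fs)[match(glands, g)]
    newcls <- cls[sample.int(length(cls))]
    SummarizedExperiment::colData(fs)$class_label <-
        newcls[match(g, glands)]
    fs
}

#' Repeated stratified k-fold cross-validation of a window classifier
#'
#' For each of `repeats` repetitions, glands are split into `k`
#' class-stratified folds ([makeGlandFolds()]); each fold in turn is held
#' out, the classifier is trained on the remaining glands' windows and
#' evaluated on the held-out windows. Accuracy is reported at three
#' levels: window (raw predictions), gland (majority vote over each test
#' gland's windows, [majorityVote()]) and image (mean over images of the
#' per-image fraction of correctly voted glands; the global image-level
#' accuracy is the mean of per-image accuracies). One-vs-rest AUC is
#' computed per class on the held-out window scores via [rocAuc()] and
#' macro-averaged; reported AUCs are means over folds and repeats, as are
#' accuracies.
#'
#' `splitLevel = "window"` instead stratifies individual windows over
#' folds, letting windows of one gland straddle the train/test boundary.
#' That inflates accuracy through intra-gland correlation and exists only
#' for literal replication of window-level protocols; the gland-level
#' split is the leakage-safe default.
#'
#' @param fs a [TopoFeatureSet-class] with class labels.
#' @param method classifier name, see [fitClassifier()].
#' @param k folds (2-5 typical); every class needs at least k glands.
#' @param repeats number of repeated random partitions (the study protocol
#'   uses 100).
#' @param seed RNG seed governing all partitioning and stochastic fits.
#' @param splitLevel `"gland"` or `"window"`.
#' @param standardize passed to [fitClassifier()].
#' @return an [EvaluationReport-class].
#' @export
kfoldEvaluate <- function(fs, method = c("DTC", "RF", "SVM", "NBC", "LDA"),
                          k = 5L, repeats = 100L, seed = 1L,
                          splitLevel = c("gland", "window"),
                          standardize = FALSE) {
    method <- match.arg(method)
    splitLevel <- match.arg(splitLevel)
    stopifnot(is(fs, "TopoFeatureSet"))
    k <- as.integer(k); repeats <- as.integer(repeats)
    if (k < 2L) stop("k must be at least 2")

    X <- featureMatrix(fs)
    y <- classLabels(fs)
    if (any(is.na(y))) stop("all windows need a class label")
    gl <- glandIds(fs)
    im <- imageIds(fs)
    classes <- sort(unique(y))
    if (length(classes) < 2L) stop("need at least two classes")
    glands <- unique(gl)
    glandClass <- setNames(y[match(glands, gl)], glands)

    set.seed(seed)
    perFold <- list(); perRepeat <- list()
    confW <- confG <- matrix(0, length(classes), length(classes),
                             dimnames = list(true = classes,
                                             predicted = classes))
    aucSum <- setNames(numeric(length(classes)), classes)
    aucN <- setNames(numeric(length(classes)), classes)

    for (rep_i in seq_len(repeats)) {
        if (splitLevel == "gland") {
            gfold <- makeGlandFolds(glandClass, k)
            wfold <- gfold[gl]
        } else {
            wfold <- makeGlandFolds(setNames(y, seq_along(y)), k)
        }
        repPred <- character(length(y))
        for (f in seq_len(k)) {
            test <- which(wfold == f); train <- which(wfold != f)
            model <- fitClassifier(X[train, , drop = FALSE], y[train],
                                   method = method,
                                   standardize = standardize)
            sc <- predictScores(model, X[test, , drop = FALSE])
            pred <- model@levels[max.col(sc, ties.method = "first")]
            repPred[test] <- pred

            confW <- confW + confusionCounts(y[test], pred, classes)
            aucs <- rep(NA_real_, length(classes))
            names(aucs) <- classes
            for (cl in intersect(classes, model@levels)) {
                posv <- y[test] == cl
                if (any(posv) && any(!posv)) {
                    a <- .aucValue(sc[, cl], posv)
                    aucs[cl] <- a
                    aucSum[cl] <- aucSum[cl] + a
                    aucN[cl] <- aucN[cl] + 1
                }
            }
            ## gland-level vote within this fold
            tg <- unique(gl[test])
            gpred <- vapply(tg, function(g)
                majorityVote(pred[gl[test] == g]), character(1))
            gtrue <- glandClass[tg]
            confG <- confG + confusionCounts(gtrue, gpred, classes)
            gcorrect <- gpred == gtrue
            ## per-image accuracy over this fold's test glands
            gim <- im[match(tg, gl)]
            imAcc <- vapply(unique(gim), function(i)
                mean(gcorrect[gim == i]), numeric(1))
            perFold[[length(perFold) + 1L]] <- data.frame(
                rep = rep_i, fold = f, n_test_windows = length(test),
                n_test_glands = length(tg),
                window_acc = 100 * mean(pred == y[test]),
                gland_acc = 100 * mean(gcorrect),
                image_acc = 100 * mean(imAcc),
                macro_auc = mean(aucs, na.rm = TRUE))
        }
        ## per-repeat aggregates: each gland/window tested exactly once
        repG <- vapply(glands, function(g)
            majorityVote(repPred[gl == g]), character(1))
        gcorrect <- repG == glandClass
        glandIm <- im[match(glands, gl)]
        imAcc <- vapply(unique(glandIm), function(i)
            mean(gcorrect[glandIm == i]), numeric(1))
        perRepeat[[rep_i]] <- data.frame(
            rep = rep_i,
            window_acc = 100 * mean(repPred == y),
            gland_acc = 100 * mean(gcorrect),
            image_acc = 100 * mean(imAcc))
    }

    perFold <- do.call(rbind, perFold)
    perRepeat <- do.call(rbind, perRepeat)
    aucClass <- ifelse(aucN > 0, aucSum / aucN, NA_real_)

    new("EvaluationReport",
        method = method, k = k, repeats = repeats, splitLevel = splitLevel,
        accuracy = c(window = mean(perRepeat$window_acc),
                     gland = mean(perRepeat$gland_acc),
                     image = mean(perRepeat$image_acc)),
        aucClass = aucClass, aucMacro = mean(aucClass, na.rm = TRUE),
        perFold = perFold, perRepeat = perRepeat,
        confusionWindow = unclass(as.matrix(confW)),
        confusionGland = unclass(as.matrix(confG)),
        hyperparameters = list(standardize = standardize, seed = seed,
                               learner_defaults = method))
}

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport: %s, %d-fold CV x %d repeats (%s split)\n",
                object@method, object@k, object@repeats, object@splitLevel))
    cat(sprintf("  accuracy (%%): window %.1f | gland %.1f | image %.1f\n",
                object@accuracy["window"], object@accuracy["gland"],
                object@accuracy["image"]))
    cat(sprintf("  macro one-vs-rest AUC: %.4f\n", object@aucMacro))
    cat("  gland-level confusion (true x predicted):\n")
    print(object@confusionGland)
})

#' Serialise an evaluation report to JSON
#'
#' @param report an [EvaluationReport-class].
#' @param path output file.
#' @export
writeEvaluationReport <- function(report, path) {
    stopifnot(is(report, "EvaluationReport"))
    jsonlite::write_json(list(
        method = report@method, k = report@k, repeats = report@repeats,
        split_level = report@splitLevel,
        accuracy = as.list(report@accuracy),
        auc_class = as.list(report@aucClass),
        auc_macro = report@aucMacro,
        confusion_window = report@confusionWindow,
        confusion_gland = report@confusionGland,
        hyperparameters = report@hyperparameters),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
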