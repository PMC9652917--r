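test_that("ROC/AUC by threshold sweep matches hand values and pROC", {
    # perfect ranking
    expect_equal(rocAuc(c(0.9, 0.8, 0.1, 0.2),
                        c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
    # anti-perfect ranking
    expect_equal(rocAuc(c(0.1, 0.2, 0.9, 0.8),
                        c(TRUE, TRUE, FALSE, FALSE))$auc, 0)
    # curve endpoints and monotonicity
    set.seed(50)
    s <- rnorm(60); p <- rep(c(TRUE, FALSE), 30)
    r <- rocAuc(s, p)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(!is.unsorted(r$points$fpr) && !is.unsorted(r$points$tpr))
    # independent cross-check, including tied scores
    skip_if_not_installed("pROC")
    for (i in 1:5) {
        s <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)
        p <- runif(40) < 0.4
        if (!any(p) || all(p)) next
        expect_equal(rocAuc(s, p)$auc,
                     as.numeric(pROC::auc(pROC::roc(p, s, quiet = TRUE,
                                                    direction = "<"))))
    }
    expect_error(rocAuc(1:3, c(TRUE, FALSE)), "mismatch")
    expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("random scores give AUC near one half", {
    set.seed(61)
    aucs <- replicate(20, rocAuc(rnorm(500), rep(c(TRUE, FALSE), 250))$auc)
    expect_lt(abs(mean(aucs) - 0.5), 0.02)
    expect_true(all(abs(aucs - 0.5) < 0.1))
})

test_that("confusion matrix bookkeeping is conserved", {
    true <- c("a", "a", "b", "b", "c")
    pred <- c("a", "b", "b", "b", "a")
    cm <- confusionCounts(true, pred)
    expect_equal(sum(cm), 5)
    expect_equal(unname(rowSums(cm)), c(2, 2, 1))
    expect_equal(accuracyFromConfusion(cm), 100 * 3 / 5)
    # all-correct predictions give a diagonal matrix
    cm <- confusionCounts(true, true)
    expect_equal(sum(cm) - sum(diag(cm)), 0)
    expect_equal(accuracyFromConfusion(cm), 100)
    expect_error(confusionCounts(1:3, 1:2), "mismatch")
})

test_that("gland folds are stratified, balanced and leakage-free", {
    set.seed(70)
    glandClass <- setNames(rep(c("x", "y"), each = 5),
                           paste0("g", 1:10))
    folds <- makeGlandFolds(glandClass, 2L)
    expect_setequal(unname(table(folds)), c(5L, 5L))  # 5/5 split
    for (cl in c("x", "y"))
        expect_true(max(table(folds[glandClass == cl])) -
                    min(table(folds[glandClass == cl])) <= 1)
    expect_error(makeGlandFolds(glandClass, 6L), "fewer than k")

    # no window of a test gland appears in training, by construction:
    # the window fold equals its gland's fold
    fs <- toyFeatureSet(classes = c("x", "y"), nGlands = 5L, nWin = 4L)
    gl <- glandIds(fs)
    gfold <- makeGlandFolds(setNames(classLabels(fs)[match(unique(gl), gl)],
                                     unique(gl)), 2L)
    wfold <- gfold[gl]
    for (f in 1:2) {
        testGlands <- unique(gl[wfold == f])
        trainGlands <- unique(gl[wfold != f])
        expect_length(intersect(testGlands, trainGlands), 0L)
    }
})

test_that("cross-validation report is consistent and reproducible", {
    set.seed(80)
    fs <- toyFeatureSet(classes = c("p", "q"), nGlands = 6L, nWin = 3L)
    r1 <- kfoldEvaluate(fs, "DTC", k = 3L, repeats = 4L, seed = 5L)
    r2 <- kfoldEvaluate(fs, "DTC", k = 3L, repeats = 4L, seed = 5L)
    expect_equal(r1@accuracy, r2@accuracy)
    expect_equal(r1@confusionGland, r2@confusionGland)

    # confusion-derived accuracy equals the reported mean accuracy
    expect_equal(accuracyFromConfusion(r1@confusionGland),
                 r1@accuracy[["gland"]])
    expect_equal(accuracyFromConfusion(r1@confusionWindow),
                 r1@accuracy[["window"]])
    # every gland evaluated once per repeat
    expect_equal(sum(r1@confusionGland), 12 * 4)
    # reported image-level accuracy is the mean of per-image accuracies
    expect_equal(r1@accuracy[["image"]], mean(r1@perRepeat$image_acc))
    expect_identical(nrow(r1@perFold), 3L * 4L)
})

test_that("widely separated classes evaluate perfectly", {
    set.seed(90)
    fs <- toyFeatureSet(classes = c("lo", "hi"), nGlands = 5L, nWin = 4L,
                        sep = 50, noise = 0.01)
    r <- kfoldEvaluate(fs, "DTC", k = 5L, repeats = 2L, seed = 2L)
    expect_equal(r@accuracy[["gland"]], 100)
    expect_equal(r@accuracy[["window"]], 100)
    expect_equal(r@aucMacro, 1)
})

test_that("evaluation guards its preconditions", {
    set.seed(95)
    fs <- toyFeatureSet(classes = c("p", "q"), nGlands = 3L, nWin = 2L)
    expect_error(kfoldEvaluate(fs, "DTC", k = 4L, repeats = 1L),
                 "fewer than k")
    one <- toyFeatureSet(classes = "p", nGlands = 4L, nWin = 2L)
    expect_error(kfoldEvaluate(one, "DTC", k = 2L, repeats = 1L),
                 "two classes")
})

test_that("gland-label permutation preserves structure, breaks signal", {
    set.seed(101)
    fs <- toyFeatureSet(classes = c("p", "q", "r"), nGlands = 4L,
                        nWin = 3L)
    perm <- permuteGlandLabels(fs, seed = 3L)
    # same label multiset, all windows of a gland share one label
    expect_equal(table(classLabels(perm)), table(classLabels(fs)))
    g <- glandIds(perm)
    expect_true(all(tapply(classLabels(perm), g,
                           function(x) length(unique(x))) == 1L))
})

test_that("evaluation report serialises to JSON", {
    d <- withr::local_tempdir()
    set.seed(105)
    fs <- toyFeatureSet(classes = c("p", "q"), nGlands = 4L, nWin = 2L)
    r <- kfoldEvaluate(fs, "NBC", k = 2L, repeats = 2L, seed = 1L)
    p <- file.path(d, "report.json")
    writeEvaluationReport(r, p)
    back <- jsonlite::read_json(p, simplifyVector = TRUE)
    expect_equal(back$accuracy$gland, r@accuracy[["gland"]])
    expect_equal(back$method, "NBC")
})
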