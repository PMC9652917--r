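test_that("generator configuration is validated", {
    expect_s4_class(syntheticConfig(), "SyntheticGlandConfig")
    expect_error(syntheticConfig(lumenMean = c(5, 3, 1)), "increase")
    expect_error(syntheticConfig(lumenRadiusRange = c(90, 120)),
                 "too large")
    expect_error(syntheticConfig(lumenValue = 200), "darker")
    expect_error(syntheticConfig(classes = c("a", "a", "b")),
                 "unique|match")
})

test_that("the same seed reproduces a gland exactly", {
    cfg <- syntheticConfig()
    g1 <- simulateGland("44", cfg, seed = 123L)
    g2 <- simulateGland("44", cfg, seed = 123L)
    expect_identical(g1$image, g2$image)
    expect_identical(g1$n_lumens, g2$n_lumens)
    expect_error(simulateGland("99", cfg), "unknown class")
    # integer 8-bit intensities
    expect_true(all(g1$image == round(g1$image)))
    expect_true(all(g1$image >= 0 & g1$image <= 255))
})

test_that("a noiseless lumen yields one dominant dim-1 bar in its window", {
    cfg <- syntheticConfig(lumenMean = c(1, 6, 12), textureAmplitude = c(0, 0, 0),
                           noiseSd = 0)
    set.seed(17)
    g <- simulateGland("33", cfg)
    while (g$n_lumens != 1L) g <- simulateGland("33", cfg)
    r0 <- round(g$lumens$row[1]); c0 <- round(g$lumens$col[1])
    w <- g$image[(r0 - 24):(r0 + 25), (c0 - 24):(c0 + 25)]
    d1 <- bars(computePersistence(cubicalComplex(w)), dim = 1L,
               dropZero = TRUE)
    expect_identical(nrow(d1), 1L)
    expect_equal(d1$birth, cfg@lumenValue)
    expect_equal(d1$death, cfg@bodyValue)
    expect_gt(windowFeatures(w)[["mean_life_dim1"]], 100)
})

test_that("a lumen-free constant gland has zero dim-1 entropy everywhere", {
    cfg <- syntheticConfig(lumenMean = c(0.0001, 6, 12),
                           textureAmplitude = c(0, 0, 0), noiseSd = 0)
    set.seed(19)
    g <- simulateGland("33", cfg)
    while (g$n_lumens != 0L) g <- simulateGland("33", cfg)
    tab <- extractGlandFeatures(g$image, "g", windowSize = 50L,
                                stride = 50L)
    expect_true(all(tab$entropy_dim1 == 0))
    expect_true(all(tab$mean_life_dim1 == 0))
})

test_that("dataset generation writes a consistent manifest and files", {
    d <- withr::local_tempdir()
    cfg <- syntheticConfig(glandsPerImage = 4L, imagesPerClass = 2L,
                           glandSize = 80L, lumenRadiusRange = c(5, 8))
    man <- simulateDataset(cfg, file.path(d, "ds"))
    # 3 classes x 2 images x 4 glands
    expect_identical(nrow(man), 24L)
    expect_true(all(file.exists(file.path(d, "ds", man$path))))
    expect_equal(as.vector(table(man$class_label)), rep(8L, 3))
    # all glands of one image share a class
    expect_true(all(tapply(man$class_label, man$image_id,
                           function(x) length(unique(x))) == 1L))
    truth <- jsonlite::read_json(file.path(d, "ds", "ground_truth.json"))
    expect_length(truth, 24L)
    # byte-identical regeneration from the same config
    man2 <- simulateDataset(cfg, file.path(d, "ds2"))
    f1 <- file.path(d, "ds", man$path[1])
    f2 <- file.path(d, "ds2", man2$path[1])
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
})

test_that("window dim-1 lifetime grows with the lumens it contains", {
    cfg <- syntheticConfig()
    set.seed(29)
    n1 <- 0; n0 <- 0; acc1 <- c(); acc0 <- c()
    for (i in 1:6) {
        g <- simulateGland("55", cfg)
        tab <- extractGlandFeatures(g$image, "g", windowSize = 50L,
                                    stride = 50L)
        for (j in seq_len(nrow(tab))) {
            rs <- tab$window_row[j]; cs <- tab$window_col[j]
            inside <- g$lumens$row - g$lumens$radius > rs &
                g$lumens$row + g$lumens$radius < rs + 50 &
                g$lumens$col - g$lumens$radius > cs &
                g$lumens$col + g$lumens$radius < cs + 50
            if (any(inside)) acc1 <- c(acc1, tab$mean_life_dim1[j])
            else acc0 <- c(acc0, tab$mean_life_dim1[j])
        }
    }
    expect_gt(length(acc1), 5)
    # windows fully containing a lumen carry the long-lived loop signal
    expect_gt(mean(acc1), mean(acc0))
    expect_true(all(acc1 > 0))
})

test_that("class-average dim-1 statistics are monotone in lumen count", {
    cfg <- syntheticConfig()  # expected lumen counts 2 / 6 / 12
    fs <- defaultDatasetFeatures()
    fm <- featureMatrix(fs); y <- classLabels(fs)
    mld1 <- tapply(fm[, "mean_life_dim1"], y, mean)[cfg@classes]
    ed1 <- tapply(fm[, "entropy_dim1"], y, mean)[cfg@classes]
    # more lumens: more long-lived loops, so mean lifetime rises while
    # persistent entropy falls (dominant bars concentrate the lifetime
    # distribution away from the equal-length maximum)
    expect_true(all(diff(mld1) > 0))
    expect_true(all(diff(ed1) < 0))
})
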