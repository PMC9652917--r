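# Shared in-code fixtures

# 3x3 ring: dark border (1) around a bright centre (5); its sublevel
# filtration has a single dimension-1 bar [1, 5).
ringImage <- function() {
    m <- matrix(1, 3, 3)
    m[2, 2] <- 5
    m
}

randomIntImage <- function(maxSide = 8L, maxVal = 6L) {
    r <- sample(seq_len(maxSide), 1L)
    cc <- sample(seq_len(maxSide), 1L)
    matrix(sample(0:maxVal, r * cc, replace = TRUE), r, cc)
}

# Small labelled feature set with a perfectly separating feature, built
# directly (no image pipeline): nGlands per class, nWin windows each.
toyFeatureSet <- function(classes = c("A", "B"), nGlands = 5L, nWin = 4L,
                          sep = 10, noise = 0.1) {
    rows <- list()
    for (ci in seq_along(classes)) {
        for (g in seq_len(nGlands)) {
            for (w in seq_len(nWin)) {
                f <- setNames(rnorm(8, sd = noise), featureNames())
                f["pixel_mean"] <- f["pixel_mean"] + ci * sep
                rows[[length(rows) + 1L]] <- cbind(
                    data.frame(image_id = sprintf("im%s%02d", classes[ci], g),
                               gland_id = sprintf("g%02d", g),
                               class_label = classes[ci],
                               window_row = (w - 1L) * 10L, window_col = 0L),
                    as.data.frame(as.list(f)))
            }
        }
    }
    TopoFeatureSet(do.call(rbind, rows))
}

# Default synthetic dataset features, generated once per test run (the
# extraction is the expensive step shared by several tests).
.fixtureCache <- new.env(parent = emptyenv())
defaultDatasetFeatures <- function() {
    if (is.null(.fixtureCache$fs)) {
        d <- file.path(tempdir(), "phg-default-dataset")
        simulateDataset(syntheticConfig(), d)
        .fixtureCache$fs <- extractDatasetFeatures(
            file.path(d, "manifest.csv"), windowSize = 50L, stride = 50L)
    }
    .fixtureCache$fs
}

# Barcode literal for entropy tests
barcodeOf <- function(lifetimes, dim = 1L, m = max(lifetimes) + 1) {
    n <- length(lifetimes)
    new("PersistenceBarcode", dim = rep(as.integer(dim), n),
        birth = rep(0, n), death = as.numeric(lifetimes),
        essential = rep(FALSE, n), m = m)
}
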