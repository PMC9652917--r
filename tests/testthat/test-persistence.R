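test_that("worked barcodes match hand-derived sublevel persistence", {
    # constant 4x4: a single sublevel step, one essential component [7, 8)
    bc <- computePersistence(cubicalComplex(matrix(7, 4, 4)))
    pos <- bars(bc, dropZero = TRUE)
    expect_identical(nrow(pos), 1L)
    expect_equal(pos$dim, 0L)
    expect_equal(pos$birth, 7)
    expect_equal(pos$death, 8)
    expect_true(pos$essential)
    expect_identical(nrow(bars(bc, dim = 1L, dropZero = TRUE)), 0L)

    # 1x3 [0,9,0]: two components at 0, one dies when the bright pixel
    # bridges them at 9; the survivor is essential with death m = 10
    bc <- computePersistence(cubicalComplex(matrix(c(0, 9, 0), nrow = 1)))
    expect_equal(bc@m, 10)
    d0 <- bars(bc, dim = 0L, dropZero = TRUE)
    expect_equal(d0[order(d0$death), ]$birth, c(0, 0))
    expect_equal(sort(d0$death), c(9, 10))
    expect_identical(sum(d0$essential), 1L)

    # dark ring around a bright centre: one loop [1, 5)
    bc <- computePersistence(cubicalComplex(ringImage()))
    d1 <- bars(bc, dim = 1L, dropZero = TRUE)
    expect_identical(nrow(d1), 1L)
    expect_equal(d1$birth, 1)
    expect_equal(d1$death, 5)
    expect_false(d1$essential)
})

test_that("betti curve oracle reproduces hand counts", {
    cx <- cubicalComplex(matrix(5, 3, 3))
    expect_equal(bettiCurve(cx, 0L)$betti, 1)
    expect_equal(bettiCurve(cx, 1L)$betti, 0)

    cx <- cubicalComplex(matrix(c(0, 9, 0), nrow = 1))
    b0 <- bettiCurve(cx, 0L)
    expect_equal(b0$betti[b0$level == 0], 2)
    expect_equal(b0$betti[b0$level == 9], 1)

    cx <- cubicalComplex(ringImage())
    b1 <- bettiCurve(cx, 1L)
    expect_equal(b1$betti[b1$level == 1], 1)
    expect_equal(b1$betti[b1$level == 5], 0)
})

test_that("reduction agrees with the union-find/Euler oracle everywhere", {
    set.seed(4242)
    for (i in 1:80) {
        cx <- cubicalComplex(randomIntImage(8L, 6L))
        bc <- computePersistence(cx)
        for (d in 0:1) {
            oracle <- bettiCurve(cx, d)
            implied <- barcodeBettiCurve(bc, d, oracle$level)
            expect_equal(implied$betti, oracle$betti,
                         info = sprintf("image %d dim %d", i, d))
        }
    }
})

test_that("structural barcode invariants hold on random connected grids", {
    set.seed(99)
    for (i in 1:25) {
        cx <- cubicalComplex(randomIntImage(8L, 9L))
        bc <- computePersistence(cx)
        b <- bars(bc)
        expect_true(all(b$lifetime >= 0))
        expect_identical(sum(b$essential & b$dim == 0L), 1L)
        expect_identical(sum(b$essential & b$dim == 1L), 0L)
        expect_equal(bc@m, max(cx@levels) + 1)
        expect_equal(b$death[b$essential], bc@m)
        # the filtration's first vertex creates the essential component
        expect_equal(min(b$birth[b$dim == 0L]), min(cx@levels))
    }
})

test_that("persistence is deterministic and records zero-lifetime pairs", {
    set.seed(5)
    img <- randomIntImage(6L, 4L)
    b1 <- bars(computePersistence(cubicalComplex(img)))
    b2 <- bars(computePersistence(cubicalComplex(img)))
    expect_identical(b1, b2)
    # constant 3x3: 8 vertex-edge pairs, 4 edge-square pairs, 1 essential;
    # every non-essential pair has zero lifetime
    bc <- computePersistence(cubicalComplex(matrix(2, 3, 3)))
    expect_identical(nrow(bars(bc)), 13L)
    expect_true(all(bars(bc)$lifetime[!bars(bc)$essential] == 0))
})

test_that("uniform intensity shifts translate every bar endpoint exactly", {
    set.seed(31)
    img <- randomIntImage(7L, 9L)
    eps <- 0.25
    b0 <- bars(computePersistence(cubicalComplex(img)))
    b1 <- bars(computePersistence(cubicalComplex(img + eps)))
    expect_equal(b1$birth, b0$birth + eps)
    expect_equal(b1$death, b0$death + eps)
})

test_that("small independent perturbations move long bars by at most eps", {
    set.seed(77)
    img <- matrix(sample(seq(0, 90, by = 10), 49, replace = TRUE), 7, 7)
    eps <- 0.2
    pert <- img + matrix(runif(49, -eps, eps), 7, 7)
    for (d in 0:1) {
        orig <- bars(computePersistence(cubicalComplex(img)), dim = d)
        new <- bars(computePersistence(cubicalComplex(pert)), dim = d)
        long <- orig[orig$lifetime > 2 * eps, , drop = FALSE]
        used <- rep(FALSE, nrow(new))
        for (k in seq_len(nrow(long))) {
            hit <- which(!used &
                         abs(new$birth - long$birth[k]) <= eps + 1e-12 &
                         abs(new$death - long$death[k]) <= eps + 1e-12)
            expect_gt(length(hit), 0)
            used[hit[1L]] <- TRUE
        }
    }
})

test_that("barcode CSV export round-trips", {
    d <- withr::local_tempdir()
    bc <- computePersistence(cubicalComplex(ringImage()))
    p <- file.path(d, "bars.csv")
    writeBarcode(bc, p)
    back <- readBarcode(p)
    expect_equal(bars(back), bars(bc))
    expect_equal(back@m, bc@m)
    writeLines("a,b\n1,2", p)
    expect_error(readBarcode(p), "columns")
})
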