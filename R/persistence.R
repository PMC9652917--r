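#' Persistent homology of a filtered cubical complex
#'
#' Computes dimension-0/1 persistence pairs by standard column reduction of
#' the Z2 boundary matrix in filtration order (compiled core). Each
#' destroyer cell is paired with the creator of the class it fills; the
#' bar's birth and death are the two cells' filtration values. Classes
#' still alive at the top of the filtration are flagged essential and
#' assigned the finite death \eqn{m = \max F + 1}. Zero-lifetime pairs are
#' retained (see [bars()] for dropping them).
#'
#' For any connected image grid the result has exactly one essential
#' dimension-0 bar and no essential dimension-1 bars (the full complex has
#' all squares, so every loop eventually fills).
#'
#' @param complex a [CubicalComplex-class].
#' @return a [PersistenceBarcode-class].
#' @examples
#' bc <- computePersistence(cubicalComplex(matrix(c(0, 9, 0), nrow = 1)))
#' bars(bc, dropZero = TRUE)  # essential [0, 10) and finite [0, 9)
#' @export
computePersistence <- function(complex) {
    stopifnot(is(complex, "CubicalComplex"))
    res <- reduce_filtration(complex@boundary)
    m <- max(complex@levels) + 1

    dimb <- complex@dim[res$creator]
    birth <- complex@value[res$creator]
    death <- complex@value[res$destroyer]

    edim <- complex@dim[res$essential]
    keep <- edim <= 1L
    ebirth <- complex@value[res$essential][keep]
    edim <- edim[keep]

    dim <- c(dimb, edim)
    birth <- c(birth, ebirth)
    death <- c(death, rep(m, length(ebirth)))
    essential <- c(rep(FALSE, length(dimb)), rep(TRUE, length(ebirth)))

    ord <- order(dim, birth, death, essential)
    new("PersistenceBarcode",
        dim = as.integer(dim[ord]), birth = birth[ord], death = death[ord],
        essential = essential[ord], m = m)
}

#' @rdname bars
#' @export
setMethod("bars", "PersistenceBarcode", function(x, dim = NULL,
                                                 dropZero = FALSE) {
    df <- data.frame(dim = x@dim, birth = x@birth, death = x@death,
                     essential = x@essential,
                     lifetime = x@death - x@birth)
    if (!is.null(dim)) df <- df[df$dim == dim, , drop = FALSE]
    if (dropZero) df <- df[df$lifetime > 0, , drop = FALSE]
    rownames(df) <- NULL
    df
})

setMethod("show", "PersistenceBarcode", function(object) {
    cat(sprintf("PersistenceBarcode: %d bars (dim 0: %d, dim 1: %d), m = %g\n",
                length(object@dim), sum(object@dim == 0L),
                sum(object@dim == 1L), object@m))
    pos <- object@death > object@birth
    cat(sprintf("  positive-lifetime: %d; essential: %d\n",
                sum(pos), sum(object@essential)))
})

#' Betti number curve by union-find and Euler characteristic
#'
#' Independent oracle for [computePersistence()]: sweeps the distinct
#' filtration levels once, incrementally adding cells. At each level,
#' \eqn{\beta_0} is the number of connected components of the sublevel
#' subcomplex (union-find over vertices and edges) and
#' \eqn{\beta_1 = \beta_0 - \chi} with \eqn{\chi = V - E + F}, valid
#' because a planar 2-complex has no 2-cycles. Shares nothing with the
#' boundary-matrix reduction.
#'
#' @param complex a [CubicalComplex-class].
#' @param dim homology dimension, 0 or 1.
#' @return data.frame with columns `level` and `betti`.
#' @export
bettiCurve <- function(complex, dim) {
    stopifnot(is(complex, "CubicalComplex"), dim %in% c(0L, 1L))
    n <- length(complex@dim)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    lv <- complex@levels
    b0 <- b1 <- numeric(length(lv))
    V <- E <- FF <- 0L
    comps <- 0L
    j <- 1L
    for (li in seq_along(lv)) {
        while (j <= n && complex@value[j] <= lv[li]) {
            d <- complex@dim[j]
            if (d == 0L) {
                V <- V + 1L; comps <- comps + 1L
            } else if (d == 1L) {
                E <- E + 1L
                ends <- complex@boundary[[j]]
                ra <- find(ends[1L]); rb <- find(ends[2L])
                if (ra != rb) { parent[ra] <- rb; comps <- comps - 1L }
            } else {
                FF <- FF + 1L
            }
            j <- j + 1L
        }
        b0[li] <- comps
        b1[li] <- comps - (V - E + FF)
    }
    data.frame(level = lv, betti = if (dim == 0L) b0 else b1)
}

#' Betti curve implied by a barcode
#'
#' Counts, at each queried level `a`, the bars of dimension `dim` with
#' `birth <= a < death`. With the essential death substituted at
#' `m = max(F) + 1` this equals the Betti number of the sublevel
#' subcomplex at every true filtration level.
#'
#' @param barcode a [PersistenceBarcode-class].
#' @param dim homology dimension, 0 or 1.
#' @param levels numeric vector of levels to evaluate.
#' @return data.frame with columns `level` and `betti`.
#' @export
barcodeBettiCurve <- function(barcode, dim, levels) {
    stopifnot(is(barcode, "PersistenceBarcode"))
    sel <- barcode@dim == dim
    b <- barcode@birth[sel]; d <- barcode@death[sel]
    data.frame(level = levels,
               betti = vapply(levels,
                              function(a) sum(b <= a & a < d), numeric(1)))
}

#' Export / import a barcode as CSV
#'
#' Plain-text interchange with columns `dim`, `birth`, `death`,
#' `essential`. On import, `m` is recovered from the essential deaths
#' (they all equal `max(F) + 1`); a barcode without essential bars gets
#' `m = max(death)`.
#'
#' @param barcode a [PersistenceBarcode-class].
#' @param path CSV file path.
#' @return `writeBarcode` returns `path` invisibly; `readBarcode` a
#'   [PersistenceBarcode-class].
#' @export
writeBarcode <- function(barcode, path) {
    stopifnot(is(barcode, "PersistenceBarcode"))
    write.csv(bars(barcode)[c("dim", "birth", "death", "essential")],
              path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeBarcode
#' @export
readBarcode <- function(path) {
    df <- read.csv(path)
    need <- c("dim", "birth", "death", "essential")
    if (!all(need %in% names(df)))
        stop("barcode CSV must have columns dim, birth, death, essential")
    m <- if (any(df$essential)) df$death[df$essential][1L]
         else if (nrow(df)) max(df$death) else 0
    new("PersistenceBarcode", dim = as.integer(df$dim), birth = df$birth,
        death = df$death, essential = as.logical(df$essential), m = m)
}
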