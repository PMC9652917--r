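#' Build the filtered cubical complex of a grayscale image
#'
#' Implements the V-construction: each pixel is a vertex carrying its
#' intensity, edges connect 4-neighbours (horizontally and vertically) and
#' carry the maximum of their endpoint values, and each unit square carries
#' the maximum of its four edges. Cells are sorted into filtration order
#' (value, then dimension, then anchor row/column/orientation), which is a
#' valid filtration because a facet's value never exceeds its coface's.
#'
#' Single-row or single-column images degenerate to a 1-complex (no
#' squares) and are supported.
#'
#' @param image numeric matrix of intensities (rows x cols). Intensities
#'   are used as-is; integer-valued images yield integer filtration levels.
#' @return a [CubicalComplex-class].
#' @examples
#' cx <- cubicalComplex(matrix(c(0, 9, 0), nrow = 1))
#' length(cx@dim)  # 3 vertices + 2 edges
#' @export
cubicalComplex <- function(image) {
    if (!is.matrix(image) || !is.numeric(image))
        stop("'image' must be a numeric matrix")
    r <- nrow(image); cc <- ncol(image)
    if (r < 1L || cc < 1L || length(image) == 0L)
        stop("empty image")
    if (any(!is.finite(image)))
        stop("image contains non-finite values")

    ## vertex id v(i,j) = (i-1)*cc + j, row-major
    vid <- function(i, j) (i - 1L) * cc + j
    nV <- r * cc
    vi <- rep(seq_len(r), each = cc)
    vj <- rep(seq_len(cc), times = r)
    vval <- as.vector(t(image))

    ## horizontal edges between (i,j) and (i,j+1)
    hi <- hj <- ha <- hb <- integer(0); hval <- numeric(0)
    if (cc > 1L) {
        hi <- rep(seq_len(r), each = cc - 1L)
        hj <- rep(seq_len(cc - 1L), times = r)
        ha <- vid(hi, hj); hb <- vid(hi, hj + 1L)
        hval <- pmax(vval[ha], vval[hb])
    }
    nH <- length(ha)

    ## vertical edges between (i,j) and (i+1,j)
    ui <- uj <- ua <- ub <- integer(0); uval <- numeric(0)
    if (r > 1L) {
        ui <- rep(seq_len(r - 1L), each = cc)
        uj <- rep(seq_len(cc), times = r - 1L)
        ua <- vid(ui, uj); ub <- vid(ui + 1L, uj)
        uval <- pmax(vval[ua], vval[ub])
    }
    nU <- length(ua)

    ## squares anchored at (i,j): edges h(i,j), h(i+1,j), v(i,j), v(i,j+1)
    hid <- function(i, j) nV + (i - 1L) * (cc - 1L) + j
    uid <- function(i, j) nV + nH + (i - 1L) * cc + j
    si <- sj <- se1 <- se2 <- se3 <- se4 <- integer(0); sval <- numeric(0)
    if (r > 1L && cc > 1L) {
        si <- rep(seq_len(r - 1L), each = cc - 1L)
        sj <- rep(seq_len(cc - 1L), times = r - 1L)
        se1 <- hid(si, sj); se2 <- hid(si + 1L, sj)
        se3 <- uid(si, sj); se4 <- uid(si, sj + 1L)
        allev <- c(hval, uval)
        sval <- pmax(allev[se1 - nV], allev[se2 - nV],
                     allev[se3 - nV], allev[se4 - nV])
    }
    nS <- length(si)

    dim <- c(rep(0L, nV), rep(1L, nH + nU), rep(2L, nS))
    value <- c(vval, hval, uval, sval)
    row0 <- c(vi, hi, ui, si) - 1L
    col0 <- c(vj, hj, uj, sj) - 1L
    orient <- c(rep(0L, nV), rep(1L, nH), rep(2L, nU), rep(0L, nS))

    ord <- order(value, dim, row0, col0, orient)
    pos <- integer(length(ord)); pos[ord] <- seq_along(ord)

    ## facet lists in filtration order, each sorted ascending (vectorised:
    ## pmin/pmax for edges, a 5-comparator sorting network for squares)
    bnd <- vector("list", length(ord))
    sdim <- dim[ord]
    bnd[sdim == 0L] <- list(integer(0))
    if (nH + nU > 0L) {
        ea <- pos[c(ha, ua)]; eb <- pos[c(hb, ub)]
        eSorted <- cbind(pmin(ea, eb), pmax(ea, eb))
        eIdx <- which(sdim == 1L)
        rows <- ord[eIdx] - nV
        bnd[eIdx] <- split(as.integer(t(eSorted[rows, , drop = FALSE])),
                           rep(seq_along(eIdx), each = 2L))
    }
    if (nS > 0L) {
        a <- pos[se1]; b <- pos[se2]; c2 <- pos[se3]; d2 <- pos[se4]
        s1 <- pmin(a, b); s2 <- pmax(a, b)
        s3 <- pmin(c2, d2); s4 <- pmax(c2, d2)
        t1 <- pmin(s1, s3); t2 <- pmax(s1, s3)
        t3 <- pmin(s2, s4); t4 <- pmax(s2, s4)
        sSorted <- cbind(t1, pmin(t2, t3), pmax(t2, t3), t4)
        sIdx <- which(sdim == 2L)
        rows <- ord[sIdx] - nV - nH - nU
        bnd[sIdx] <- split(as.integer(t(sSorted[rows, , drop = FALSE])),
                           rep(seq_along(sIdx), each = 4L))
    }

    new("CubicalComplex",
        nrow = r, ncol = cc,
        dim = dim[ord], value = value[ord],
        anchor = cbind(row = row0[ord], col = col0[ord]),
        orientation = orient[ord],
        boundary = bnd,
        levels = sort(unique(value)))
}

#' Cells of a sublevel subcomplex
#'
#' Indices (into filtration order) of all cells whose filtration value does
#' not exceed `level`. By the max rule the result is always facet-closed,
#' and it is monotone in `level`. Because cells are stored in filtration
#' order the result is simply a prefix of `seq_along` (up to ties resolved
#' within a level, which are all included together).
#'
#' @param complex a [CubicalComplex-class].
#' @param level filtration threshold; `-Inf` gives the empty set,
#'   `max(complex@levels)` the whole complex.
#' @return integer vector of cell indices.
#' @export
sublevelCells <- function(complex, level) {
    stopifnot(is(complex, "CubicalComplex"))
    which(complex@value <= level)
}

#' Read a grayscale image file
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF into an integer-valued
#' intensity matrix (0..2^depth - 1). Colour or alpha-carrying inputs are
#' rejected: the sublevel filtration is defined on a single channel.
#'
#' @param path file path; format inferred from the extension.
#' @return numeric matrix with attribute `bit_depth`.
#' @export
readGrayImage <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        img <- png::readPNG(path, info = TRUE)
        depth <- attr(img, "info")$bit.depth
        if (is.null(depth)) depth <- 8L
    } else if (ext %in% c("tif", "tiff")) {
        img <- tiff::readTIFF(path, info = TRUE)
        depth <- attr(img, "bits.per.sample")
        if (is.null(depth)) depth <- 8L
    } else stop("unsupported image format: '", ext, "' (use PNG or TIFF)")
    if (length(dim(img)) == 3L)
        stop("colour or multi-channel image; grayscale input required")
    out <- round(img * (2^depth - 1))
    attr(out, "bit_depth") <- as.integer(depth)
    out
}

setMethod("show", "CubicalComplex", function(object) {
    cat(sprintf(
        "CubicalComplex: %d x %d image, %d cells (%d vertices, %d edges, %d squares)\n",
        object@nrow, object@ncol, length(object@dim),
        sum(object@dim == 0L), sum(object@dim == 1L), sum(object@dim == 2L)))
    cat(sprintf("  filtration levels: %d distinct in [%g, %g]\n",
                length(object@levels), min(object@levels),
                max(object@levels)))
})
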