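## Population standard deviation; 0 for empty or single-element input, so
## that single-bar barcodes and empty dimension-1 barcodes stay total.
.popSd <- function(x) {
    if (length(x) < 2L) return(0)
    sqrt(mean((x - mean(x))^2))
}

## Positive lifetimes of one dimension; essential bars (death = m)
## included, zero-lifetime noise excluded.
.lifetimes <- function(barcode, dim) {
    l <- barcode@death[barcode@dim == dim] - barcode@birth[barcode@dim == dim]
    l[l > 0]
}

#' Persistent entropy of a barcode dimension
#'
#' Shannon entropy of the normalised bar lifetimes: with lifetimes
#' \eqn{l_i = b_i - a_i}, \eqn{L = \sum_i l_i} and \eqn{p_i = l_i / L},
#' \deqn{H = - \sum_i p_i \log p_i.}
#' Essential bars contribute through the finite substitution death
#' \eqn{m = \max F + 1}; zero-lifetime bars are dropped (their limiting
#' contribution \eqn{0 \log 0} is zero regardless). An empty or single-bar
#' barcode has entropy 0 by convention; n equal-length bars attain the
#' maximum \eqn{\log n}.
#'
#' @param barcode a [PersistenceBarcode-class].
#' @param dim homology dimension, 0 or 1.
#' @param base logarithm base; natural log (nats) by default. Any base
#'   rescales all entropies uniformly.
#' @return non-negative scalar, at most `log(k, base)` for k bars.
#' @examples
#' bc <- new("PersistenceBarcode", dim = c(1L, 1L), birth = c(0, 0),
#'           death = c(2, 4), essential = c(FALSE, FALSE), m = 5)
#' persistentEntropy(bc, 1)  # -(1/3)log(1/3) - (2/3)log(2/3)
#' @export
persistentEntropy <- function(barcode, dim, base = exp(1)) {
    stopifnot(is(barcode, "PersistenceBarcode"), dim %in% c(0L, 1L))
    l <- .lifetimes(barcode, dim)
    if (length(l) <= 1L) return(0)
    p <- l / sum(l)
    -sum(p * log(p)) / log(base)
}

#' Topological feature vector of an image window
#'
#' Composes [cubicalComplex()], [computePersistence()] and summary
#' statistics into the 8-dimensional window descriptor, in fixed order:
#' mean and population standard deviation of dimension-0 and dimension-1
#' bar lifetimes, persistent entropy in dimensions 0 and 1, and the mean
#' and (population) standard deviation of the pixel values. Lifetime
#' statistics include the essential dimension-0 bar (death substituted at
#' `max(F) + 1`) and exclude zero-lifetime bars; the statistics of an
#' empty lifetime multiset are 0.
#'
#' Adding a constant to all pixels shifts `pixel_mean` only: the sublevel
#' filtration is translation-covariant, so all six topological components
#' are intensity-shift invariant.
#'
#' @param window numeric matrix, at least 2 x 2.
#' @param base entropy logarithm base, passed to [persistentEntropy()].
#' @return named numeric vector of length 8.
#' @examples
#' windowFeatures(matrix(5, 4, 4))  # (1, 0, 0, 0, 0, 0, 5, 0)
#' @export
windowFeatures <- function(window, base = exp(1)) {
    if (!is.matrix(window) || nrow(window) < 2L || ncol(window) < 2L)
        stop("window must be a matrix of at least 2 x 2 pixels")
    bc <- computePersistence(cubicalComplex(window))
    l0 <- .lifetimes(bc, 0L)
    l1 <- .lifetimes(bc, 1L)
    out <- c(if (length(l0)) mean(l0) else 0, .popSd(l0),
             if (length(l1)) mean(l1) else 0, .popSd(l1),
             persistentEntropy(bc, 0L, base), persistentEntropy(bc, 1L, base),
             mean(window), .popSd(as.vector(window)))
    names(out) <- .FEATURE_NAMES
    if (any(!is.finite(out))) stop("non-finite feature value")
    out
}

#' Canonical window feature names
#'
#' @return character vector of length 8, the row order of every
#'   [TopoFeatureSet-class] and feature CSV.
#' @export
featureNames <- function() .FEATURE_NAMES
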