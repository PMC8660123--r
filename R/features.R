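#' @include PolarMapSet-class.R
NULL

.FEATURE_NAMES <- c(paste0("h", 1:5), paste0("v", 1:5))

# near-equal integer partition of n into `bands` contiguous bands; remainder
# pixels go to the trailing bands (175 -> five bands of exactly 35)
.bandSizes <- function(n, bands = 5L) {
    base <- n %/% bands
    rem <- n %% bands
    if (base == 0L)
        stop("image side must be at least ", bands, " pixels")
    sizes <- rep(base, bands)
    if (rem > 0L)
        sizes[(bands - rem + 1L):bands] <- base + 1L
    sizes
}

.bandId <- function(n, bands = 5L)
    rep(seq_len(bands), times = .bandSizes(n, bands))

#' Band-slicing feature extraction
#'
#' Slices an image into five contiguous horizontal bands (top to bottom,
#' `h1..h5`) and five vertical bands (left to right, `v1..v5`) and sums the
#' pixel intensities within each band, giving the 10 attributes used for
#' classification. Every pixel lies in exactly one horizontal and one
#' vertical band, so `h1+...+h5 = v1+...+v5 =` total image intensity, exactly.
#'
#' For the default 175-pixel maps each band is exactly 35 pixels wide; other
#' sizes use a near-equal integer partition with remainder pixels assigned to
#' the trailing bands.
#'
#' @param x a square numeric matrix (one image, row 1 = top of the image) or
#'   a [PolarMapSet-class].
#' @param ... unused.
#' @return for a matrix: a named numeric vector `h1..h5, v1..v5`; for a
#'   `PolarMapSet`: the 11-column feature matrix of [buildFeatureMatrix()].
#' @examples
#' extractFeatures(matrix(1, 175, 175))  # each band sums to 35*175 = 6125
#' @export
setGeneric("extractFeatures", function(x, ...)
    standardGeneric("extractFeatures"))

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "matrix", function(x, ...) {
    if (nrow(x) != ncol(x))
        stop("image must be square, got ", nrow(x), " x ", ncol(x))
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
        stop("image must contain finite numeric intensities")
    band <- .bandId(nrow(x))
    h <- as.numeric(rowsum(rowSums(x), band))
    v <- as.numeric(rowsum(colSums(x), band))
    stats::setNames(c(h, v), .FEATURE_NAMES)
})

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "PolarMapSet", function(x, ...)
    buildFeatureMatrix(x))

#' Build the feature matrix of a map set
#'
#' Applies [extractFeatures()] to every map of a [PolarMapSet-class] and
#' binds the class label, giving the canonical 11-column matrix: columns
#' `h1..h5, v1..v5, label`, one row per image in input order.
#'
#' @param x a non-empty [PolarMapSet-class].
#' @return numeric matrix with 11 columns; rownames are the map identifiers.
#' @export
buildFeatureMatrix <- function(x) {
    if (!methods::is(x, "PolarMapSet"))
        stop("x must be a PolarMapSet")
    if (length(x) == 0L)
        stop("cannot build a feature matrix from an empty PolarMapSet")
    feats <- t(vapply(x@images, function(img) extractFeatures(img),
                      numeric(10L)))
    out <- cbind(feats, label = as.numeric(mapLabels(x)))
    rownames(out) <- x@mapData$mapId
    out
}

# shared schema check for 10-feature inputs (with or without label column)
.checkFeatureColumns <- function(features, requireLabel = FALSE) {
    if (!is.matrix(features) && !is.data.frame(features))
        stop("features must be a matrix or data.frame")
    features <- as.matrix(features)
    cn <- colnames(features)
    if (is.null(cn)) {
        if (ncol(features) == 10L) {
            colnames(features) <- .FEATURE_NAMES
        } else if (ncol(features) == 11L) {
            colnames(features) <- c(.FEATURE_NAMES, "label")
        } else {
            stop("feature input must have 10 columns (h1..h5, v1..v5) ",
                 "or 11 (plus label); got ", ncol(features))
        }
        cn <- colnames(features)
    }
    if (!all(.FEATURE_NAMES %in% cn))
        stop("feature columns must include h1..h5 and v1..v5")
    if (requireLabel && !"label" %in% cn)
        stop("a 'label' column is required")
    features
}
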