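#' Configuration for rotation augmentation
#'
#' @description
#' Minority-class (normal) maps are expanded by rotated copies, a number of
#' copies per source image (default 3). The default angles 90/180/270 degrees
#' are exact index permutations on a square grid: lossless, interpolation-free
#' and — for a centred uptake disc — free of border artefacts. Arbitrary
#' angles (e.g. small rotations of +-10 degrees) are supported through
#' bilinear or nearest-neighbour resampling and require the `EBImage`
#' package.
#'
#' @param copiesPerImage number of rotated copies per source image.
#' @param angles rotation angles in degrees (counterclockwise); length must
#'   equal `copiesPerImage`.
#' @param interpolation `"bilinear"` or `"nearest"`; only used for angles
#'   that are not multiples of 90 degrees.
#' @param fillValue intensity for pixels rotated in from outside the frame.
#' @return a validated list of class `AugmentationConfig`.
#' @export
augmentationConfig <- function(copiesPerImage = 3L,
                               angles = c(90, 180, 270),
                               interpolation = c("bilinear", "nearest"),
                               fillValue = 0) {
    interpolation <- match.arg(interpolation)
    copiesPerImage <- as.integer(copiesPerImage)
    if (copiesPerImage < 1L)
        stop("copiesPerImage must be at least 1")
    if (length(angles) != copiesPerImage)
        stop("length(angles) must equal copiesPerImage")
    if (any(!is.finite(angles)))
        stop("angles must be finite")
    if (fillValue < 0 || fillValue > 255)
        stop("fillValue must lie in [0, 255]")
    structure(list(copiesPerImage = copiesPerImage, angles = angles,
                   interpolation = interpolation, fillValue = fillValue),
              class = "AugmentationConfig")
}

# exact quarter-turn permutations, counterclockwise
.rotate90 <- function(x) t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
.rotate180 <- function(x) x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))),
                            drop = FALSE]
.rotate270 <- function(x) t(x)[, rev(seq_len(nrow(x))), drop = FALSE]

.rotateFree <- function(x, angle, interpolation, fillValue) {
    if (!requireNamespace("EBImage", quietly = TRUE))
        stop("rotation by angles that are not multiples of 90 degrees ",
             "requires the EBImage package")
    filt <- if (interpolation == "nearest") "none" else "bilinear"
    # EBImage rotates clockwise in its x/y frame; with images stored as
    # row = image row this comes out counterclockwise on screen, matching
    # the package convention (verified against the quarter-turn permutations)
    out <- EBImage::rotate(x, angle, filter = filt,
                           output.dim = dim(x), bg.col = fillValue)
    out <- pmin(pmax(as.matrix(out), 0), 255)
    out
}

#' Rotate a polar map about the grid centre
#'
#' Angles that are multiples of 90 degrees are implemented as exact index
#' permutations (no interpolation, total intensity preserved exactly);
#' other angles are resampled. Positive angles rotate counterclockwise,
#' with row 1 as the top of the image.
#'
#' @param x square numeric matrix.
#' @param angle rotation angle in degrees.
#' @param interpolation `"bilinear"` (default) or `"nearest"`, used only for
#'   non-quarter-turn angles.
#' @param fillValue intensity assigned to out-of-support pixels.
#' @return the rotated matrix, same dimensions as `x`.
#' @examples
#' x <- matrix(1:16, 4, 4)
#' stopifnot(identical(rotateMap(x, 0), x))
#' stopifnot(sum(rotateMap(x, 90)) == sum(x))
#' @export
rotateMap <- function(x, angle, interpolation = "bilinear", fillValue = 0) {
    if (!is.matrix(x) || nrow(x) != ncol(x))
        stop("x must be a square matrix")
    if (!is.finite(angle))
        stop("angle must be finite")
    a <- angle %% 360
    if (a %% 90 == 0) {
        switch(as.character(a),
               "0" = x,
               "90" = .rotate90(x),
               "180" = .rotate180(x),
               "270" = .rotate270(x))
    } else {
        .rotateFree(x, a, interpolation, fillValue)
    }
}

#' Augment the normal class with rotated copies
#'
#' Produces `copiesPerImage` rotated copies of every *normal* (label = 1)
#' map in the input; abnormal maps are never augmented. The returned set
#' contains only the newly generated maps, each with
#' `provenance = "augmented"`, the label/phase/sex of its source, and a
#' `sourceMapId` pointing back to the source map so that leakage audits can
#' trace every copy. Intended to be applied to the *training* partition of
#' each cross-validation fold only — never to test data.
#'
#' @param x a [PolarMapSet-class] (may mix labels and provenances; every
#'   normal input is augmented).
#' @param config an [augmentationConfig()].
#' @return a [PolarMapSet-class] of `copiesPerImage * n_normal` augmented
#'   maps (empty if the input has no normal maps).
#' @examples
#' pms <- simulatePolarMaps(2, 3, polarMapConfig(imageSize = 35), seed = 1)
#' aug <- augmentNormals(pms, augmentationConfig())
#' length(aug)  # 2 normals x 3 copies = 6
#' @export
augmentNormals <- function(x, config = augmentationConfig()) {
    if (!methods::is(x, "PolarMapSet"))
        stop("x must be a PolarMapSet")
    if (!inherits(config, "AugmentationConfig"))
        stop("config must be created by augmentationConfig()")
    idx <- which(mapLabels(x) == 1L)
    if (length(idx) == 0L)
        return(x[integer(0)])
    md <- x@mapData
    images <- vector("list", length(idx) * config$copiesPerImage)
    rows <- vector("list", length(images))
    k <- 0L
    for (i in idx) {
        for (j in seq_len(config$copiesPerImage)) {
            k <- k + 1L
            images[[k]] <- rotateMap(x@images[[i]], config$angles[j],
                                     interpolation = config$interpolation,
                                     fillValue = config$fillValue)
            rows[[k]] <- data.frame(
                mapId = sprintf("%s_aug%d", md$mapId[i], j),
                label = md$label[i], phase = md$phase[i], sex = md$sex[i],
                provenance = "augmented", patientId = md$patientId[i],
                sourceMapId = md$mapId[i])
        }
    }
    methods::new("PolarMapSet", images = images,
                 mapData = do.call(rbind, rows))
}
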