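#' PolarMapSet: a collection of polar-map images with sample metadata
#'
#' @description
#' `PolarMapSet` is the central container of the package. It holds a list of
#' square single-channel polar-map images (numeric matrices with intensities
#' on the 8-bit \[0, 255\] scale) together with one row of per-map metadata:
#' the class label (1 = normal, 0 = abnormal), the acquisition phase
#' (stress / rest / prone), patient sex, provenance (acquired vs. augmented),
#' a patient identifier, a unique map identifier, and — for augmented maps —
#' the identifier of the source map the rotation was derived from.
#'
#' The `sourceMapId` column is what makes leakage audits possible: every
#' rotated copy can be traced back to the acquired image it came from, so a
#' cross-validation run can assert that no training-fold augmentation was
#' derived from a test-partition image.
#'
#' @slot images list of square numeric matrices, all with identical
#'   dimensions, values finite and in \[0, 255\].
#' @slot mapData `data.frame` with columns `mapId`, `label`, `phase`, `sex`,
#'   `provenance`, `patientId`, `sourceMapId`; one row per image.
#'
#' @seealso [simulatePolarMaps()], [augmentNormals()], [buildFeatureMatrix()]
#' @export
setClass("PolarMapSet",
         representation(images = "list", mapData = "data.frame"))

.MAPDATA_COLS <- c("mapId", "label", "phase", "sex", "provenance",
                   "patientId", "sourceMapId")
.PHASES <- c("stress", "rest", "prone")

setValidity("PolarMapSet", function(object) {
    imgs <- object@images
    md <- object@mapData
    if (length(imgs) != nrow(md))
        return("number of images must equal number of mapData rows")
    if (!identical(colnames(md), .MAPDATA_COLS))
        return(paste("mapData columns must be exactly:",
                     paste(.MAPDATA_COLS, collapse = ", ")))
    if (length(imgs) == 0L)
        return(TRUE)
    dims <- vapply(imgs, function(x) {
        if (!is.matrix(x) || !is.numeric(x)) return(c(-1L, -1L))
        dim(x)
    }, integer(2))
    if (any(dims < 0L))
        return("every image must be a numeric matrix")
    if (any(dims[1L, ] != dims[2L, ]))
        return("every image must be square")
    if (length(unique(dims[1L, ])) != 1L)
        return("all images must share the same dimensions")
    ok <- vapply(imgs, function(x) all(is.finite(x)) &&
                     min(x) >= 0 && max(x) <= 255, logical(1))
    if (!all(ok))
        return("pixel values must be finite and within [0, 255]")
    if (!all(md$label %in% c(0L, 1L)))
        return("labels must be 0 (abnormal) or 1 (normal)")
    if (!all(md$phase %in% .PHASES))
        return("phase must be one of stress, rest, prone")
    if (!all(md$sex %in% c("M", "F")))
        return("sex must be 'M' or 'F'")
    if (!all(md$provenance %in% c("acquired", "augmented")))
        return("provenance must be 'acquired' or 'augmented'")
    if (anyDuplicated(md$mapId))
        return("mapId values must be unique")
    if (any(md$provenance == "augmented" & is.na(md$sourceMapId)))
        return("augmented maps must carry a sourceMapId")
    TRUE
})

#' Construct a PolarMapSet
#'
#' @param images list of square numeric matrices (intensities in \[0, 255\]).
#' @param mapData `data.frame` with columns `mapId`, `label`, `phase`, `sex`,
#'   `provenance`, `patientId`, `sourceMapId` (missing optional columns are
#'   filled with defaults: `provenance = "acquired"`, `sourceMapId = NA`).
#' @return a validated [PolarMapSet-class] object.
#' @examples
#' img <- matrix(100, 25, 25)
#' pms <- PolarMapSet(list(img),
#'                    data.frame(mapId = "m1", label = 1L, phase = "stress",
#'                               sex = "F", patientId = "P1"))
#' pms
#' @export
PolarMapSet <- function(images, mapData) {
    if (!is.list(images))
        images <- list(images)
    if (!"provenance" %in% names(mapData))
        mapData$provenance <- rep("acquired", nrow(mapData))
    if (!"sourceMapId" %in% names(mapData))
        mapData$sourceMapId <- rep(NA_character_, nrow(mapData))
    mapData$label <- as.integer(mapData$label)
    md <- mapData[, .MAPDATA_COLS, drop = FALSE]
    rownames(md) <- NULL
    methods::new("PolarMapSet", images = images, mapData = md)
}

#' @describeIn PolarMapSet number of maps in the set
#' @param x a `PolarMapSet`
#' @export
setMethod("length", "PolarMapSet", function(x) length(x@images))

#' @describeIn PolarMapSet subset by index or logical mask
#' @param i index vector
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "PolarMapSet", function(x, i, j, ..., drop = FALSE) {
    methods::new("PolarMapSet",
                 images = x@images[i],
                 mapData = {
                     md <- x@mapData[i, , drop = FALSE]
                     rownames(md) <- NULL
                     md
                 })
})

#' Combine PolarMapSet objects
#'
#' @param x a `PolarMapSet`
#' @param ... further `PolarMapSet` objects with identical image dimensions
#' @return the concatenated `PolarMapSet`
#' @export
setMethod("c", "PolarMapSet", function(x, ...) {
    rest <- list(...)
    imgs <- c(x@images, do.call(c, c(list(list()),
                                     lapply(rest, function(p) p@images))))
    md <- do.call(rbind, c(list(x@mapData),
                           lapply(rest, function(p) p@mapData)))
    rownames(md) <- NULL
    methods::new("PolarMapSet", images = imgs, mapData = md)
})

setMethod("show", "PolarMapSet", function(object) {
    n <- length(object)
    cat("PolarMapSet with", n, "maps\n")
    if (n > 0L) {
        d <- dim(object@images[[1L]])
        md <- object@mapData
        cat(sprintf("  image size: %d x %d\n", d[1L], d[2L]))
        cat(sprintf("  labels: %d normal, %d abnormal\n",
                    sum(md$label == 1L), sum(md$label == 0L)))
        cat(sprintf("  provenance: %d acquired, %d augmented\n",
                    sum(md$provenance == "acquired"),
                    sum(md$provenance == "augmented")))
    }
    invisible(object)
})

#' @rdname PolarMapSet-accessors
#' @export
setGeneric("mapImages", function(x) standardGeneric("mapImages"))

#' @rdname PolarMapSet-accessors
#' @export
setGeneric("mapData", function(x) standardGeneric("mapData"))

#' @rdname PolarMapSet-accessors
#' @export
setGeneric("mapLabels", function(x) standardGeneric("mapLabels"))

#' Accessors for PolarMapSet
#'
#' `mapImages()` returns the list of image matrices, `mapData()` the
#' per-map metadata `data.frame`, and `mapLabels()` the integer label vector
#' (1 = normal, 0 = abnormal).
#'
#' @param x a [PolarMapSet-class]
#' @return see description
#' @name PolarMapSet-accessors
#' @export
setMethod("mapImages", "PolarMapSet", function(x) x@images)

#' @rdname PolarMapSet-accessors
#' @export
setMethod("mapData", "PolarMapSet", function(x) x@mapData)

#' @rdname PolarMapSet-accessors
#' @export
setMethod("mapLabels", "PolarMapSet", function(x) x@mapData$label)
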