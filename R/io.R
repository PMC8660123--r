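#' Read a polar map from a grayscale TIFF
#'
#' Reads an 8-bit TIFF into an integer intensity matrix on the \[0, 255\]
#' scale. Multi-channel files are collapsed to a single channel by the
#' per-pixel channel mean, with a warning (the maps this package targets are
#' single-channel).
#'
#' @param path path to the TIFF file.
#' @param expectedSize expected side length in pixels (default 175), or
#'   `NULL` to skip the check.
#' @param strict if `TRUE` an unexpected size is an error; if `FALSE`, a
#'   warning.
#' @return integer matrix with values in \[0, 255\].
#' @export
readPolarMapTiff <- function(path, expectedSize = 175L, strict = TRUE) {
    if (!file.exists(path))
        stop("no such file: ", path)
    img <- tryCatch(tiff::readTIFF(path),
                    error = function(e)
                        stop("cannot decode TIFF '", path, "': ",
                             conditionMessage(e)))
    if (length(dim(img)) == 3L) {
        warning("multi-channel TIFF '", basename(path),
                "' collapsed to single channel by channel mean")
        img <- apply(img, c(1L, 2L), mean)
    }
    if (nrow(img) != ncol(img))
        stop("polar map must be square, got ",
             nrow(img), " x ", ncol(img))
    if (!is.null(expectedSize) && nrow(img) != expectedSize) {
        msg <- sprintf("expected a %d x %d image, got %d x %d",
                       expectedSize, expectedSize, nrow(img), ncol(img))
        if (strict) stop(msg) else warning(msg)
    }
    out <- round(img * 255)
    storage.mode(out) <- "integer"
    out
}

#' Write a polar map as an 8-bit grayscale TIFF
#'
#' @param image square numeric matrix with intensities in \[0, 255\]
#'   (rounded to integers on write).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePolarMapTiff <- function(image, path) {
    if (!is.matrix(image) || any(!is.finite(image)) ||
        min(image) < 0 || max(image) > 255)
        stop("image must be a finite matrix with values in [0, 255]")
    tiff::writeTIFF(round(image) / 255, path, bits.per.sample = 8L)
    invisible(path)
}

.MANIFEST_COLS <- c("filename", "label", "phase", "sex", "patient_id",
                    "provenance", "source_map_id", "map_id")

#' Write a PolarMapSet to disk
#'
#' Writes one 8-bit grayscale TIFF per map plus a `manifest.csv` carrying
#' the labels and metadata (`filename`, `label`, `phase`, `sex`,
#' `patient_id`, `provenance`, `source_map_id`, `map_id`). The manifest —
#' not filename parsing — is the authoritative label source on re-read.
#'
#' @param x a [PolarMapSet-class].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writePolarMapSet <- function(x, dir) {
    if (!methods::is(x, "PolarMapSet"))
        stop("x must be a PolarMapSet")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    md <- mapData(x)
    fn <- paste0(md$mapId, ".tiff")
    for (i in seq_len(length(x)))
        writePolarMapTiff(x@images[[i]], file.path(dir, fn[i]))
    manifest <- data.frame(filename = fn, label = md$label,
                           phase = md$phase, sex = md$sex,
                           patient_id = md$patientId,
                           provenance = md$provenance,
                           source_map_id = md$sourceMapId,
                           map_id = md$mapId)
    mpath <- file.path(dir, "manifest.csv")
    utils::write.csv(manifest, mpath, row.names = FALSE)
    invisible(mpath)
}

#' Read a PolarMapSet from a directory with a manifest
#'
#' @param dir directory holding the TIFF files.
#' @param manifest path to the manifest CSV (default `dir/manifest.csv`).
#' @param expectedSize,strict forwarded to [readPolarMapTiff()].
#' @return a [PolarMapSet-class].
#' @export
readPolarMapSet <- function(dir, manifest = file.path(dir, "manifest.csv"),
                            expectedSize = NULL, strict = TRUE) {
    if (!file.exists(manifest))
        stop("manifest not found: ", manifest)
    # colClasses = "character": a sex column of all "F" must not be parsed
    # as logical FALSE by read.csv's type inference
    md <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                          colClasses = "character")
    missing <- setdiff(c("filename", "label"), names(md))
    if (length(missing) > 0L)
        stop("manifest lacks required column(s): ",
             paste(missing, collapse = ", "))
    n <- nrow(md)
    fill <- function(col, default) if (col %in% names(md)) md[[col]] else
        rep(default, n)
    images <- lapply(md$filename, function(f)
        readPolarMapTiff(file.path(dir, f), expectedSize = expectedSize,
                         strict = strict))
    PolarMapSet(images, data.frame(
        mapId = as.character(fill("map_id",
                                  tools::file_path_sans_ext(md$filename))),
        label = as.integer(md$label),
        phase = as.character(fill("phase", "stress")),
        sex = as.character(fill("sex", "F")),
        provenance = as.character(fill("provenance", "acquired")),
        patientId = as.character(fill("patient_id",
                                      paste0("unknown", seq_len(n)))),
        sourceMapId = as.character(fill("source_map_id", NA_character_))))
}

#' Write / read the 11-column feature matrix as CSV
#'
#' The on-disk schema is fixed: header exactly
#' `h1,h2,h3,h4,h5,v1,v2,v3,v4,v5,label`, label integer 0/1. Round-trips are
#' lossless.
#'
#' @param features an 11-column feature matrix (from
#'   [buildFeatureMatrix()]).
#' @param path CSV path.
#' @return `writeFeatureCSV`: `path`, invisibly. `readFeatureCSV`: the
#'   feature matrix.
#' @export
writeFeatureCSV <- function(features, path) {
    features <- .checkFeatureColumns(features, requireLabel = TRUE)
    df <- as.data.frame(features[, c(.FEATURE_NAMES, "label"),
                                 drop = FALSE])
    df$label <- as.integer(df$label)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    expected <- c(.FEATURE_NAMES, "label")
    if (!identical(names(df), expected))
        stop("feature CSV schema mismatch: header must be exactly '",
             paste(expected, collapse = ","), "'")
    if (!all(df$label %in% c(0L, 1L)))
        stop("label column must contain only 0 and 1")
    as.matrix(df)
}

#' Write a CVReport to JSON and Table-shaped CSV
#'
#' `writeReportJSON()` serialises the per-fold table, the aggregated
#' summary, the leakage audit and the effective configuration.
#' `writeReportCSV()` writes the conventional presentation: one block per
#' partition, models as rows, `mean +/- sd` cells for accuracy, F1,
#' precision, sensitivity, wall time and AUC.
#'
#' @param report a [CVReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(report, path) {
    out <- list(summary = cvSummary(report),
                foldMetrics = foldMetrics(report),
                leakageAudit = leakageAudit(report),
                config = cvConfig(report))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname writeReportJSON
#' @export
writeReportCSV <- function(report, path) {
    parts <- intersect(c("train", "train_unaugmented", "test"),
                       unique(report@summary$partition))
    blocks <- lapply(parts, function(p) {
        tab <- formatReportTable(report, partition = p)
        cbind(partition = p, model = rownames(tab), tab)
    })
    out <- do.call(rbind, blocks)
    utils::write.csv(out, path, row.names = FALSE)
    invisible(path)
}

.RUNCONFIG_KEYS <- c("seed", "k", "positive_class", "threshold", "sd_type",
                     "models", "augmentation", "synth")
.AUG_KEYS <- c("copies_per_image", "angles", "interpolation", "fill_value",
               "enabled")
.SYNTH_KEYS <- c("image_size", "disc_radius_fraction",
                 "normal_intensity_mean", "normal_intensity_sd",
                 "pixel_noise_sd", "defect_count_range",
                 "defect_angular_extent_range", "defect_severity_range",
                 "background_value", "n_normal", "n_abnormal")

.checkKeys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown) > 0L)
        stop("unknown ", where, " key(s): ",
             paste(unknown, collapse = ", "))
}

#' Read a YAML run configuration
#'
#' Parses and validates a YAML file describing a full run: global seed,
#' fold count, positive class, model list and augmentation/synthesis
#' settings. Unknown keys anywhere in the file are errors, so typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return a list with elements `pipeline` (a [pipelineConfig()]), `synth`
#'   (a [polarMapConfig()] plus `n_normal`/`n_abnormal`, or `NULL`) and
#'   `seed`.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    cfg <- yaml::read_yaml(path)
    if (!is.list(cfg))
        stop("malformed configuration file")
    .checkKeys(cfg, .RUNCONFIG_KEYS, "configuration")
    seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
    models <- if (is.null(cfg$models)) {
        list(modelSpec("random_forest", seed = seed))
    } else {
        lapply(cfg$models, function(m) {
            .checkKeys(m, c("family", "seed", "params"), "model")
            if (is.null(m$family))
                stop("every model entry needs a 'family'")
            modelSpec(m$family,
                      seed = if (is.null(m$seed)) seed else m$seed,
                      params = if (is.null(m$params)) list() else m$params)
        })
    }
    augmentation <- augmentationConfig()
    if (!is.null(cfg$augmentation)) {
        a <- cfg$augmentation
        .checkKeys(a, .AUG_KEYS, "augmentation")
        if (isFALSE(a$enabled)) {
            augmentation <- NULL
        } else {
            angles <- if (is.null(a$angles)) c(90, 180, 270) else
                as.numeric(a$angles)
            augmentation <- augmentationConfig(
                copiesPerImage = if (is.null(a$copies_per_image))
                    length(angles) else a$copies_per_image,
                angles = angles,
                interpolation = if (is.null(a$interpolation)) "bilinear"
                    else a$interpolation,
                fillValue = if (is.null(a$fill_value)) 0 else a$fill_value)
        }
    }
    pipeline <- pipelineConfig(
        k = if (is.null(cfg$k)) 10L else cfg$k,
        seed = seed,
        models = models,
        augmentation = augmentation,
        positiveClass = if (is.null(cfg$positive_class)) 0L else
            as.integer(cfg$positive_class),
        threshold = if (is.null(cfg$threshold)) 0.5 else cfg$threshold,
        sdType = if (is.null(cfg$sd_type)) "sample" else cfg$sd_type)
    synth <- NULL
    if (!is.null(cfg$synth)) {
        s <- cfg$synth
        .checkKeys(s, .SYNTH_KEYS, "synth")
        pick <- function(key, default) if (is.null(s[[key]])) default else
            s[[key]]
        synth <- list(
            config = polarMapConfig(
                imageSize = pick("image_size", 175L),
                discRadiusFraction = pick("disc_radius_fraction", 0.48),
                normalIntensityMean = pick("normal_intensity_mean", 150),
                normalIntensitySd = pick("normal_intensity_sd", 10),
                pixelNoiseSd = pick("pixel_noise_sd", 8),
                defectCountRange = pick("defect_count_range", c(1L, 3L)),
                defectAngularExtentRange =
                    pick("defect_angular_extent_range", c(30, 120)),
                defectSeverityRange = pick("defect_severity_range",
                                           c(0.3, 0.8)),
                backgroundValue = pick("background_value", 0)),
            n_normal = pick("n_normal", 108L),
            n_abnormal = pick("n_abnormal", 899L))
    }
    list(pipeline = pipeline, synth = synth, seed = seed)
}
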