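#' Configuration for the synthetic polar-map generator
#'
#' @description
#' The generator emulates the image regime of clinical perfusion polar maps
#' (bull's-eye plots): a centred circular uptake disc on a dark background.
#' Normal maps have near-homogeneous tracer uptake over the disc; abnormal
#' maps additionally carry one or more angular-sector perfusion defects whose
#' intensity is multiplied by `1 - severity`.
#'
#' Defaults describe a regime in which defects are clearly visible but the
#' classification task is not trivial: the disc fills most of the frame
#' (radius 0.48 of the image width, so rotation never clips it), uptake sits
#' around 150 of 255 with modest per-patient variation, pixel noise is a few
#' grey levels, and each abnormal map has 1–3 sector defects of 30–120
#' degrees losing 30–80% of intensity.
#'
#' @param imageSize side length of the square image in pixels (default 175).
#' @param discRadiusFraction disc radius as a fraction of the image width;
#'   must lie in (0, 0.5] so the disc fits the frame and survives rotation
#'   without clipping.
#' @param normalIntensityMean mean in-disc intensity (0–255 scale).
#' @param normalIntensitySd standard deviation of the per-map baseline
#'   intensity (between-patient variation).
#' @param pixelNoiseSd standard deviation of per-pixel noise.
#' @param defectCountRange integer interval (length-2) for the number of
#'   sector defects on an abnormal map; lower bound at least 1.
#' @param defectAngularExtentRange angular extent interval in degrees,
#'   within (0, 360).
#' @param defectSeverityRange fractional intensity reduction interval,
#'   within (0, 1].
#' @param backgroundValue intensity of out-of-disc pixels.
#' @return a validated list of class `PolarMapConfig`.
#' @examples
#' cfg <- polarMapConfig(imageSize = 35)
#' set.seed(1)
#' img <- simulatePolarMap(cfg, label = 0L)
#' attr(img, "defects")
#' @export
polarMapConfig <- function(imageSize = 175L,
                           discRadiusFraction = 0.48,
                           normalIntensityMean = 150,
                           normalIntensitySd = 10,
                           pixelNoiseSd = 8,
                           defectCountRange = c(1L, 3L),
                           defectAngularExtentRange = c(30, 120),
                           defectSeverityRange = c(0.3, 0.8),
                           backgroundValue = 0) {
    cfg <- list(imageSize = as.integer(imageSize),
                discRadiusFraction = discRadiusFraction,
                normalIntensityMean = normalIntensityMean,
                normalIntensitySd = normalIntensitySd,
                pixelNoiseSd = pixelNoiseSd,
                defectCountRange = as.integer(defectCountRange),
                defectAngularExtentRange = defectAngularExtentRange,
                defectSeverityRange = defectSeverityRange,
                backgroundValue = backgroundValue)
    if (cfg$imageSize < 5L)
        stop("imageSize must be at least 5 pixels")
    if (!(cfg$discRadiusFraction > 0 && cfg$discRadiusFraction <= 0.5))
        stop("discRadiusFraction must lie in (0, 0.5]")
    if (cfg$normalIntensityMean < 0 || cfg$normalIntensityMean > 255)
        stop("normalIntensityMean must lie in [0, 255]")
    if (cfg$normalIntensitySd < 0 || cfg$pixelNoiseSd < 0)
        stop("intensity standard deviations must be non-negative")
    if (length(cfg$defectCountRange) != 2L ||
        cfg$defectCountRange[1L] < 1L ||
        cfg$defectCountRange[1L] > cfg$defectCountRange[2L])
        stop("defectCountRange must be an increasing integer interval >= 1")
    if (length(cfg$defectAngularExtentRange) != 2L ||
        cfg$defectAngularExtentRange[1L] <= 0 ||
        cfg$defectAngularExtentRange[2L] >= 360 ||
        cfg$defectAngularExtentRange[1L] > cfg$defectAngularExtentRange[2L])
        stop("defectAngularExtentRange must lie within (0, 360) degrees")
    if (length(cfg$defectSeverityRange) != 2L ||
        cfg$defectSeverityRange[1L] <= 0 ||
        cfg$defectSeverityRange[2L] > 1 ||
        cfg$defectSeverityRange[1L] > cfg$defectSeverityRange[2L])
        stop("defectSeverityRange must lie within (0, 1]")
    if (cfg$backgroundValue < 0 || cfg$backgroundValue > 255)
        stop("backgroundValue must lie in [0, 255]")
    class(cfg) <- "PolarMapConfig"
    cfg
}

# disc mask and per-pixel polar angle (degrees, [0, 360), mathematical
# convention: 0 = rightwards, counterclockwise positive, row 1 = top)
.discGeometry <- function(n, radiusFraction) {
    ctr <- (n + 1) / 2
    r <- radiusFraction * n
    rowOff <- matrix(ctr - seq_len(n), n, n)        # y axis points up
    colOff <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
    mask <- rowOff^2 + colOff^2 <= r^2
    theta <- (atan2(rowOff, colOff) * 180 / pi) %% 360
    list(mask = mask, theta = theta)
}

.sectorMask <- function(theta, centerAngle, extent) {
    d <- abs(((theta - centerAngle + 180) %% 360) - 180)
    d <= extent / 2
}

#' Simulate a single polar map
#'
#' Draws one synthetic polar map from the current R random-number stream
#' (seed control is the caller's job, e.g. via `set.seed()`; use
#' [simulatePolarMaps()] for seeded dataset generation).
#'
#' @param config a [polarMapConfig()] object.
#' @param label 1 for a normal map, 0 for an abnormal map.
#' @param geometry optional precomputed `.discGeometry()` result (internal
#'   fast path for bulk generation).
#' @return an integer matrix of size `imageSize` x `imageSize`, with an
#'   attribute `defects`: a `data.frame` (`centerAngle`, `extent`,
#'   `severity`), empty for normal maps, giving the ground-truth defect
#'   parameters actually drawn.
#' @export
simulatePolarMap <- function(config, label, geometry = NULL) {
    if (!inherits(config, "PolarMapConfig"))
        stop("config must be created by polarMapConfig()")
    if (!label %in% c(0L, 1L))
        stop("label must be 1 (normal) or 0 (abnormal)")
    n <- config$imageSize
    if (is.null(geometry))
        geometry <- .discGeometry(n, config$discRadiusFraction)
    mask <- geometry$mask
    img <- matrix(config$backgroundValue, n, n)
    base <- config$normalIntensityMean +
        stats::rnorm(1L, 0, config$normalIntensitySd)
    vals <- base + stats::rnorm(sum(mask), 0, config$pixelNoiseSd)
    defects <- data.frame(centerAngle = numeric(0), extent = numeric(0),
                          severity = numeric(0))
    if (label == 0L) {
        dcr <- config$defectCountRange
        nDef <- if (dcr[1L] == dcr[2L]) dcr[1L] else
            sample(seq.int(dcr[1L], dcr[2L]), 1L)
        defects <- data.frame(
            centerAngle = stats::runif(nDef, 0, 360),
            extent = stats::runif(nDef, config$defectAngularExtentRange[1L],
                                  config$defectAngularExtentRange[2L]),
            severity = stats::runif(nDef, config$defectSeverityRange[1L],
                                    config$defectSeverityRange[2L]))
        thetaIn <- geometry$theta[mask]
        for (i in seq_len(nDef)) {
            inSector <- .sectorMask(thetaIn, defects$centerAngle[i],
                                    defects$extent[i])
            vals[inSector] <- vals[inSector] * (1 - defects$severity[i])
        }
    }
    img[mask] <- pmin(pmax(round(vals), 0), 255)
    storage.mode(img) <- "integer"
    attr(img, "defects") <- defects
    img
}

# patient sex mix per class mirrors the archive structure being emulated:
# normal patients 39 F / 10 M, abnormal 313 F / 91 M; females contribute
# stress + rest maps, males stress + rest + prone.
.CLASS_FEMALE_FRAC <- c(normal = 39 / 49, abnormal = 313 / 404)

.simulateClassMetadata <- function(nMaps, label, patientStart) {
    pFemale <- .CLASS_FEMALE_FRAC[[if (label == 1L) "normal" else "abnormal"]]
    sex <- character(0); phase <- character(0); patient <- character(0)
    pid <- patientStart
    while (length(phase) < nMaps) {
        s <- if (stats::runif(1L) < pFemale) "F" else "M"
        ph <- if (s == "F") c("stress", "rest") else
            c("stress", "rest", "prone")
        id <- sprintf("P%05d", pid)
        pid <- pid + 1L
        sex <- c(sex, rep(s, length(ph)))
        phase <- c(phase, ph)
        patient <- c(patient, rep(id, length(ph)))
    }
    keep <- seq_len(nMaps)
    list(sex = sex[keep], phase = phase[keep], patientId = patient[keep],
         nextPatient = pid)
}

#' Simulate a dataset of polar maps
#'
#' Generates `nNormal` normal and `nAbnormal` abnormal synthetic polar maps
#' with patient-level phase/sex structure: each simulated female patient
#' contributes two maps (stress, rest) and each male patient three
#' (stress, rest, prone), with the per-class sex mix of a typical referral
#' archive. Identical `(config, seed)` give byte-identical output.
#'
#' @param nNormal,nAbnormal non-negative map counts per class.
#' @param config a [polarMapConfig()].
#' @param seed integer seed controlling all randomness of the call.
#' @return a [PolarMapSet-class] with `nNormal + nAbnormal` maps (normals
#'   first), all with `provenance = "acquired"`.
#' @examples
#' pms <- simulatePolarMaps(5, 5, polarMapConfig(imageSize = 35), seed = 1)
#' table(mapLabels(pms))
#' @export
simulatePolarMaps <- function(nNormal, nAbnormal,
                              config = polarMapConfig(), seed = 1L) {
    if (nNormal < 0 || nAbnormal < 0)
        stop("map counts must be non-negative")
    if (!inherits(config, "PolarMapConfig"))
        stop("config must be created by polarMapConfig()")
    set.seed(seed)
    nTot <- nNormal + nAbnormal
    if (nTot == 0L) {
        md <- data.frame(mapId = character(0), label = integer(0),
                         phase = character(0), sex = character(0),
                         provenance = character(0),
                         patientId = character(0),
                         sourceMapId = character(0))
        return(methods::new("PolarMapSet", images = list(), mapData = md))
    }
    metaN <- .simulateClassMetadata(nNormal, 1L, patientStart = 1L)
    metaA <- .simulateClassMetadata(nAbnormal, 0L,
                                    patientStart = metaN$nextPatient)
    md <- data.frame(
        mapId = sprintf("map%05d", seq_len(nTot)),
        label = rep(c(1L, 0L), c(nNormal, nAbnormal)),
        phase = c(metaN$phase, metaA$phase),
        sex = c(metaN$sex, metaA$sex),
        provenance = "acquired",
        patientId = c(metaN$patientId, metaA$patientId),
        sourceMapId = NA_character_)
    geom <- .discGeometry(config$imageSize, config$discRadiusFraction)
    images <- lapply(md$label, function(lab)
        simulatePolarMap(config, lab, geometry = geom))
    methods::new("PolarMapSet", images = images, mapData = md)
}
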