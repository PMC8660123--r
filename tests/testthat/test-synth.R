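test_that("noise-free normal maps are a homogeneous disc on background", {
    cfg <- noiseFreeConfig(imageSize = 35L, normalIntensityMean = 150,
                           backgroundValue = 0)
    set.seed(1)
    img <- simulatePolarMap(cfg, label = 1L)
    mask <- discMaskOracle(35L, cfg$discRadiusFraction)
    expect_true(all(img[mask] == 150))
    expect_true(all(img[!mask] == 0))
    expect_equal(nrow(attr(img, "defects")), 0L)
})

test_that("a full-severity sector removes exactly the sector-mask sum", {
    cfg <- noiseFreeConfig(imageSize = 35L,
                           defectCountRange = c(1L, 1L),
                           defectAngularExtentRange = c(90, 90),
                           defectSeverityRange = c(1, 1))
    set.seed(7)
    normal <- simulatePolarMap(cfg, label = 1L)
    set.seed(7)
    abnormal <- simulatePolarMap(cfg, label = 0L)
    def <- attr(abnormal, "defects")
    expect_equal(nrow(def), 1L)
    n <- nrow(normal)
    mask <- discMaskOracle(n, cfg$discRadiusFraction)
    # independent sector-sum oracle: per-pixel angle test
    sectorSum <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (!mask[i, j]) next
            d <- abs(((pixelAngleOracle(i, j, n) - def$centerAngle + 180)
                      %% 360) - 180)
            if (d <= def$extent / 2)
                sectorSum <- sectorSum + normal[i, j]
        }
    }
    expect_identical(sum(abnormal), sum(normal) - as.integer(sectorSum))
})

test_that("generation is deterministic under a fixed seed", {
    cfg <- tinyConfig()
    a <- simulatePolarMaps(5, 5, cfg, seed = 42)
    b <- simulatePolarMaps(5, 5, cfg, seed = 42)
    expect_identical(mapImages(a), mapImages(b))
    expect_identical(mapData(a), mapData(b))
    c <- simulatePolarMaps(5, 5, cfg, seed = 43)
    expect_false(identical(mapImages(a), mapImages(c)))
})

test_that("dataset counts and degenerate requests behave as specified", {
    cfg <- tinyConfig()
    pms <- simulatePolarMaps(4, 9, cfg, seed = 1)
    expect_equal(length(pms), 13L)
    expect_equal(sum(mapLabels(pms) == 1L), 4L)
    expect_equal(sum(mapLabels(pms) == 0L), 9L)
    expect_true(all(mapData(pms)$provenance == "acquired"))
    empty <- simulatePolarMaps(0, 0, cfg, seed = 1)
    expect_equal(length(empty), 0L)
    expect_error(simulatePolarMaps(-1, 5, cfg), "non-negative")
})

test_that("maximum-severity defects strictly depress abnormal uptake", {
    cfg <- noiseFreeConfig(imageSize = 35L,
                           defectSeverityRange = c(1, 1))
    pms <- simulatePolarMaps(10, 10, cfg, seed = 3)
    mask <- discMaskOracle(35L, cfg$discRadiusFraction)
    inDiscMean <- vapply(mapImages(pms), function(x) mean(x[mask]),
                         numeric(1))
    lab <- mapLabels(pms)
    expect_true(max(inDiscMean[lab == 0L]) < min(inDiscMean[lab == 1L]))
})

test_that("phase and sex follow the per-patient acquisition scheme", {
    pms <- simulatePolarMaps(30, 60, tinyConfig(), seed = 5)
    md <- mapData(pms)
    for (pid in unique(md$patientId)) {
        rows <- md[md$patientId == pid, ]
        expect_length(unique(rows$sex), 1L)
        expect_length(unique(rows$label), 1L)
        if (rows$sex[1L] == "F") {
            expect_lte(nrow(rows), 2L)
            expect_true(all(rows$phase %in% c("stress", "rest")))
        } else {
            expect_lte(nrow(rows), 3L)
        }
        expect_false(anyDuplicated(rows$phase) > 0L)
    }
})

test_that("invalid generator configurations are rejected", {
    expect_error(polarMapConfig(discRadiusFraction = 0.6), "0.5")
    expect_error(polarMapConfig(discRadiusFraction = 0), "0.5")
    expect_error(polarMapConfig(defectSeverityRange = c(0, 0.5)), "0, 1")
    expect_error(polarMapConfig(defectSeverityRange = c(0.5, 1.2)), "0, 1")
    expect_error(polarMapConfig(defectAngularExtentRange = c(10, 400)),
                 "360")
    expect_error(polarMapConfig(defectCountRange = c(0L, 2L)), ">= 1")
    expect_error(polarMapConfig(pixelNoiseSd = -1), "non-negative")
    expect_error(simulatePolarMap(list(), 1L), "polarMapConfig")
    expect_error(simulatePolarMap(tinyConfig(), 2L), "label")
})

test_that("pixel values stay in [0, 255] even under heavy noise", {
    cfg <- tinyConfig(normalIntensityMean = 240, normalIntensitySd = 40,
                      pixelNoiseSd = 60)
    pms <- simulatePolarMaps(5, 5, cfg, seed = 9)
    rng <- range(unlist(mapImages(pms)))
    expect_gte(rng[1L], 0)
    expect_lte(rng[2L], 255)
})
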