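# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive per-pixel / all-pairs computations so they cannot share bugs with
# the vectorised implementation they check.

tinyConfig <- function(...) polarMapConfig(imageSize = 35L, ...)

noiseFreeConfig <- function(imageSize = 35L, ...)
    polarMapConfig(imageSize = imageSize, normalIntensitySd = 0,
                   pixelNoiseSd = 0, ...)

randomImage <- function(n) matrix(sample(0:255, n * n, replace = TRUE), n, n)

# naive band-sum oracle: explicit double loop over pixels
featureOracle <- function(x, bands = 5L) {
    n <- nrow(x)
    base <- n %/% bands
    rem <- n %% bands
    sizes <- rep(base, bands)
    if (rem > 0L) sizes[(bands - rem + 1L):bands] <- base + 1L
    bounds <- cumsum(sizes)
    bandOf <- function(i) which(i <= bounds)[1L]
    h <- numeric(bands); v <- numeric(bands)
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            h[bandOf(i)] <- h[bandOf(i)] + x[i, j]
            v[bandOf(j)] <- v[bandOf(j)] + x[i, j]
        }
    }
    stats::setNames(c(h, v), c(paste0("h", 1:5), paste0("v", 1:5)))
}

# naive pixel-remapping rotation oracle (counterclockwise, row 1 = top):
# a CCW quarter turn sends pixel (i, j) to (n + 1 - j, i)
rotateOracle <- function(x, angle) {
    n <- nrow(x)
    turns <- (angle %/% 90) %% 4
    out <- x
    for (t in seq_len(turns)) {
        nxt <- matrix(0L, n, n)   # promotes to double if x is double
        for (i in seq_len(n))
            for (j in seq_len(n))
                nxt[n + 1 - j, i] <- out[i, j]
        out <- nxt
    }
    out
}

# naive all-pairs AUC oracle with half credit for ties
aucOracle <- function(scores, isPositive) {
    pos <- scores[isPositive]
    neg <- scores[!isPositive]
    total <- 0
    for (p in pos)
        for (q in neg)
            total <- total + (p > q) + 0.5 * (p == q)
    total / (length(pos) * length(neg))
}

# disc membership recomputed independently of .discGeometry
discMaskOracle <- function(n, radiusFraction) {
    ctr <- (n + 1) / 2
    outer(seq_len(n), seq_len(n), function(i, j)
        sqrt((i - ctr)^2 + (j - ctr)^2) <= radiusFraction * n)
}

# polar angle of pixel (i, j), degrees in [0, 360), y axis pointing up
pixelAngleOracle <- function(i, j, n) {
    ctr <- (n + 1) / 2
    (atan2(ctr - i, j - ctr) * 180 / pi) %% 360
}

smallModelSpecs <- function(seed = 1L) list(
    modelSpec("adaptive_boosting", seed = seed,
              params = list(n_estimators = 20L)),
    modelSpec("gradient_boosting", seed = seed,
              params = list(n_estimators = 40L)),
    modelSpec("random_forest", seed = seed, params = list(ntree = 100L)),
    modelSpec("extreme_gradient_boosting", seed = seed,
              params = list(nrounds = 30L)))
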