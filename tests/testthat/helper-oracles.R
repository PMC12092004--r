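# Independent circular-hue oracle: angle of the chromatic opponent vector
# alpha = R - (G + B)/2, beta = (sqrt(3)/2) (G - B), computed through complex
# Arg() -- a different parameterisation and code path from the package's
# atan2-based formula.
hueOracle <- function(R, G, B) {
    z <- complex(real = R - 0.5 * G - 0.5 * B,
                 imaginary = sqrt(3) / 2 * (G - B))
    h <- Arg(z) * 180 / pi
    h <- ifelse(h < 0, h + 360, h)
    h[Mod(z) == 0] <- NA_real_
    h
}

# Small, fast scene for unit tests (256 px, 3 neurons, ~1 s to render);
# ... overrides any SceneConfig argument.
smallSceneConfig <- function(seed = 7L, ...) {
    args <- list(widthPx = 256L, heightPx = 256L, nNeurons = 3L, seed = seed)
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(SceneConfig, args)
}

# Noise- and blur-free configuration: the rendered field is the bare
# forward model, so spot intensities are analytically checkable.
cleanSceneConfig <- function(seed = 7L, ...) {
    args <- list(widthPx = 256L, heightPx = 256L, nNeurons = 3L,
        psfSigmaUm = 0, poissonNoise = FALSE, readNoiseSd = 0,
        backgroundLevel = 0, clumpFraction = 0,
        somaLevels = c(RFP_LC3 = 0, GFP_LC3 = 0, CTSD = 0), seed = seed)
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(SceneConfig, args)
}

# A field built directly from matrices, for constructed fixtures.
makeField <- function(R, G, B, pixelSizeUm = 0.2, bitDepth = 12L) {
    MultiChannelField(list(R, G, B),
        c(RFP_LC3 = 1L, GFP_LC3 = 2L, CTSD = 3L),
        pixelSizeUm = pixelSizeUm, bitDepth = bitDepth)
}
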