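test_that("hue angle reproduces the six canonical color axes", {
    expect_equal(computeHueAngle(1, 0, 0), 0)
    expect_equal(computeHueAngle(0, 1, 0), 120)
    expect_equal(computeHueAngle(0, 0, 1), 240)
    expect_equal(computeHueAngle(1, 1, 0), 60)   # yellow, AP
    expect_equal(computeHueAngle(1, 0, 1), 300)  # magenta, AL
    expect_equal(computeHueAngle(0, 1, 1), 180)  # cyan
    expect_true(is.na(computeHueAngle(0.4, 0.4, 0.4)))  # achromatic
    # the canonical axes also agree with the hexcone hue of rgb2hsv
    ax <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
    expect_equal(computeHueAngle(ax[, 1], ax[, 2], ax[, 3]),
        as.numeric(grDevices::rgb2hsv(t(ax))["h", ]) * 360)
})

test_that("hue agrees with the independent circular-hue oracle on random triples", {
    set.seed(101)
    n <- 10000
    R <- runif(n); G <- runif(n); B <- runif(n)
    got <- computeHueAngle(R, G, B)
    want <- hueOracle(R, G, B)
    expect_true(all(abs(got - want) < 1e-9))
})

test_that("hue rejects negative intensities and handles recycling", {
    expect_error(computeHueAngle(-1, 0, 0), "must be >= 0")
    expect_length(computeHueAngle(c(1, 2, 3), 0, 0), 3L)
})

test_that("hue rotates by 120 degrees under cyclic channel permutation", {
    set.seed(5)
    R <- runif(200); G <- runif(200); B <- runif(200)
    h0 <- computeHueAngle(R, G, B)
    h1 <- computeHueAngle(B, R, G)  # cyclic shift
    chromatic <- !is.na(h0)
    expect_true(all(abs((h1 - h0) %% 360 - 120)[chromatic] < 1e-9 |
                    abs((h1 - h0) %% 360 - 120)[chromatic] > 360 - 1e-9))
})

test_that("hue and saturation are invariant under positive intensity scaling", {
    set.seed(6)
    R <- runif(100); G <- runif(100); B <- runif(100)
    for (k in c(0.25, 3, 117)) {
        expect_equal(computeHueAngle(k * R, k * G, k * B),
            computeHueAngle(R, G, B), tolerance = 1e-12)
        # the ratio cancels the scale as long as the lightness guard
        # (normalised max+min < 2) stays inactive, hence 12-bit scale here
        expect_equal(as.numeric(computeSaturation(k * R, k * G, k * B, 12)),
            as.numeric(computeSaturation(R, G, B, 12)), tolerance = 1e-12)
    }
})

test_that("saturation implements (max-min)/(max+min) x 100 with guards", {
    expect_equal(as.numeric(computeSaturation(4095, 0, 0, 12)), 100)
    expect_equal(as.numeric(computeSaturation(0.5, 0.5, 0.5, 0)), 0)
    expect_equal(as.numeric(computeSaturation(0.75, 0.25, 0.25, 0)), 50)
    expect_equal(as.numeric(computeSaturation(0, 0, 0, 12)), 0)  # max+min = 0
    set.seed(7)
    R <- runif(500); G <- runif(500); B <- runif(500)
    s <- computeSaturation(R, G, B, 0)
    mx <- pmax(R, G, B); mn <- pmin(R, G, B)
    expect_equal(as.numeric(s), (mx - mn) / (mx + mn) * 100, tolerance = 1e-12)
    expect_equal(attr(s, "lightness"), (mx + mn) / 2, tolerance = 1e-12)
    # full-lightness white is flagged and zeroed
    sw <- computeSaturation(4095, 4095, 4095, 12)
    expect_true(attr(sw, "saturated_white"))
    expect_equal(as.numeric(sw), 0)
    expect_error(computeSaturation(-1, 0, 0), "must be >= 0")
})

test_that("subtype rules validate hue ranges at construction", {
    expect_s3_class(subtypeRules(), "subtypeRules")
    expect_error(subtypeRules(apHueDeg = c(30, 280)), "overlap")
    expect_error(subtypeRules(apHueDeg = c(90, 30)), "interval")
    expect_error(subtypeRules(whiteCutoffPct = 0), "whiteCutoffPct")
})

test_that("classification follows the reporter color logic with priority", {
    thr <- ChannelThresholds(c(GFP_LC3 = 100, RFP_LC3 = 100, CTSD = 100))
    ves <- data.frame(
        # AP: yellow hue 60, R and G above threshold, B below
        mean_R = c(1000, 10, 1000, 1000, 50, 1000),
        mean_G = c(1000, 10, 10, 950, 50, 1000),
        mean_B = c(10, 1000, 1000, 900, 50, 10))
    # rows: AP, LY, AL, PA_AL(low saturation), all-below, red-ish AP again
    cls <- classifyVesicles(ves, thr)
    expect_equal(as.character(cls$subtype[1]), "AP")
    expect_equal(as.character(cls$subtype[2]), "LY")
    expect_equal(as.character(cls$subtype[3]), "AL")
    expect_equal(as.character(cls$subtype[4]), "PA_AL")
    expect_equal(as.character(cls$subtype[5]), "UNCLASSIFIED")
    expect_true(all(cls$hue_deg >= 0 & cls$hue_deg < 360, na.rm = TRUE))
    # hue 60 / 240 / 300 for the constructed rows
    expect_equal(cls$hue_deg[1], 60, tolerance = 1e-9)
    expect_equal(cls$hue_deg[2], 240, tolerance = 1e-9)
    expect_equal(cls$hue_deg[3], 300, tolerance = 1e-9)
})

test_that("classification is scale invariant while presence flags persist", {
    thr <- ChannelThresholds(c(GFP_LC3 = 10, RFP_LC3 = 10, CTSD = 10))
    ves <- data.frame(mean_R = c(500, 20, 400), mean_G = c(450, 15, 30),
        mean_B = c(30, 480, 420))
    a <- classifyVesicles(ves, thr)
    b <- classifyVesicles(transform(ves, mean_R = 2 * mean_R,
        mean_G = 2 * mean_G, mean_B = 2 * mean_B), thr)
    expect_equal(as.character(a$subtype), as.character(b$subtype))
})

test_that("red-only vesicles are unclassified by default, AL when opted in", {
    thr <- ChannelThresholds(c(GFP_LC3 = 100, RFP_LC3 = 100, CTSD = 100))
    ves <- data.frame(mean_R = 1000, mean_G = 30, mean_B = 30)  # hue ~ 0
    expect_equal(as.character(classifyVesicles(ves, thr)$subtype), "UNCLASSIFIED")
    expect_equal(as.character(classifyVesicles(ves, thr,
        rules = subtypeRules(redAsAL = TRUE))$subtype), "AL")
})

test_that("neuron profiles conserve vesicle counts and emit empty neurons", {
    ves <- data.frame(
        neuron_id = c(1L, 1L, 1L, 1L, 1L, 2L, 0L),
        subtype = factor(c("AP", "AP", "AP", "LY", "LY", "AL", "AP"),
            levels = c(vesicleSubtypes(), "UNCLASSIFIED")),
        area_um2 = c(1, 2, 3, 4, 5, 6, 7))
    prof <- profileNeurons(ves, neuronIds = 1:3)
    expect_equal(prof$neuron_id, 1:3)
    expect_equal(prof$AP, c(3L, 0L, 0L))
    expect_equal(prof$LY, c(2L, 0L, 0L))
    expect_equal(prof$AL, c(0L, 1L, 0L))
    expect_equal(prof$total, c(5L, 1L, 0L))  # background vesicle excluded
    expect_true(all(rowSums(prof[, c(vesicleSubtypes(), "UNCLASSIFIED")]) ==
        prof$total))
    expect_equal(prof$mean_area_AP[1], 2)
    expect_true(is.na(prof$mean_area_AP[3]))
})
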