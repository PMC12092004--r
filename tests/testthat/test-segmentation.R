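test_that("thresholds average per-perikaryon channel means", {
    lab <- matrix(0L, 20, 20)
    lab[2:5, 2:5] <- 1L; lab[10:13, 10:13] <- 2L
    mask <- ROILabelMask(lab)
    mk <- function(v1, v2) { m <- matrix(0, 20, 20); m[lab == 1L] <- v1
        m[lab == 2L] <- v2; m }
    field <- makeField(mk(40, 60), mk(10, 30), mk(100, 100))
    thr <- computeChannelThresholds(field, mask, nSample = 2L)
    expect_equal(thr@values[["RFP_LC3"]], 50)
    expect_equal(thr@values[["GFP_LC3"]], 20)
    expect_equal(thr@values[["CTSD"]], 100)
    expect_setequal(thr@roiIds, c(1L, 2L))
    # fewer perikarya than requested: use all, with a warning
    expect_warning(computeChannelThresholds(field, mask, nSample = 20L),
        "using all")
    # empty mask errors
    expect_error(computeChannelThresholds(field,
        ROILabelMask(matrix(0L, 20, 20))), "no regions")
})

test_that("perikaryon sampling is seeded and reproducible", {
    lab <- matrix(0L, 40, 40)
    for (k in 1:8) lab[(4 * k - 3):(4 * k - 1), 2:4] <- k
    mask <- ROILabelMask(lab)
    ch <- matrix(as.numeric(lab) * 10, 40, 40)
    field <- makeField(ch, ch, ch)
    t1 <- computeChannelThresholds(field, mask, nSample = 4L, seed = 3L)
    t2 <- computeChannelThresholds(field, mask, nSample = 4L, seed = 3L)
    expect_identical(t1@roiIds, t2@roiIds)
    # threshold equals the hand-computed mean of the sampled ROI means
    expect_equal(t1@values[["RFP_LC3"]], mean(t1@roiIds * 10))
})

test_that("puncta masks use a strict inequality and union the channels", {
    R <- matrix(c(49, 50, 51, 0), 2, 2)
    field <- makeField(R, matrix(0, 2, 2), matrix(0, 2, 2))
    thr <- ChannelThresholds(c(GFP_LC3 = 50, RFP_LC3 = 50, CTSD = 50))
    masks <- buildPunctaMask(field, thr)
    expect_equal(sum(masks$RFP_LC3), 1L)       # only the 51 pixel
    expect_false(masks$RFP_LC3[2, 1])          # tie (50) excluded
    expect_equal(masks$combined, masks$RFP_LC3 | masks$GFP_LC3 | masks$CTSD)
})

test_that("raising a threshold never grows the mask", {
    set.seed(11)
    R <- matrix(runif(400, 0, 100), 20, 20)
    field <- makeField(R, R, R)
    areas <- vapply(c(10, 30, 50, 70), function(t) {
        thr <- ChannelThresholds(c(GFP_LC3 = t, RFP_LC3 = t, CTSD = t))
        sum(buildPunctaMask(field, thr)$combined)
    }, numeric(1))
    expect_true(all(diff(areas) <= 0))
})

test_that("watershed splits seeded doublets and conserves pixels", {
    g <- function(n, cx, cy, s, amp) amp * exp(-outer((1:n - cx)^2,
        (1:n - cy)^2, "+") / (2 * s^2))
    # single isolated disk-like spot -> 1 label
    L1 <- g(40, 20, 20, 2, 1000)
    m1 <- L1 > 100
    w1 <- watershedSplit(m1, L1)
    expect_equal(max(w1), 1L)
    # doublet, centers 6 px apart (3 sigma) -> exactly 2 labels
    set.seed(21)
    for (rep in 1:10) {
        cx <- runif(1, 15, 25); cy <- runif(1, 12, 20)
        ang <- runif(1, 0, 2 * pi)
        L <- g(40, cx, cy, 2, 1000) +
            g(40, cx + 6 * cos(ang), cy + 6 * sin(ang), 2, 1000)
        m <- L > 100
        w <- watershedSplit(m, L)
        expect_equal(max(w), 2L)
        expect_equal(sum(w > 0), sum(m))  # pixel conservation
        expect_true(all(w[m] > 0))
    }
    # empty mask -> 0 labels
    expect_equal(max(watershedSplit(matrix(FALSE, 10, 10),
        matrix(0, 10, 10))), 0L)
})

test_that("size exclusion removes out-of-range puncta and renumbers", {
    lab <- matrix(0L, 10, 10)
    lab[2, 2] <- 1L                    # 1 px speck
    lab[5:6, 5:6] <- 2L                # 4 px
    lab[8:9, 1:8] <- 3L                # 16 px
    out <- applySizeExclusion(lab, minAreaPx = 3L, maxAreaPx = 10L)
    expect_equal(sort(unique(out[out > 0L])), 1L)
    expect_equal(sum(out == 1L), 4L)
    expect_equal(attr(out, "removed_small"), 1L)
    expect_equal(attr(out, "removed_large"), 1L)
    # all puncta within bounds: unchanged
    keep <- applySizeExclusion(lab, minAreaPx = 1L)
    expect_equal(sum(keep > 0L), sum(lab > 0L))
    expect_error(applySizeExclusion(lab, minAreaPx = 5L, maxAreaPx = 3L),
        "must not exceed")
})

test_that("vesicle extraction reports areas and channel means", {
    lab <- matrix(0L, 8, 8)
    lab[2:3, 2:3] <- 1L
    R <- matrix(0, 8, 8); R[2:3, 2:3] <- 100
    field <- makeField(R, matrix(0, 8, 8), matrix(0, 8, 8), pixelSizeUm = 0.5)
    ves <- extractVesicles(lab, field)
    expect_equal(nrow(ves), 1L)
    expect_equal(ves$area_px, 4L)
    expect_equal(ves$area_um2, 4 * 0.25)
    expect_equal(ves$mean_R, 100)
    expect_equal(ves$mean_G, 0)
    expect_equal(ves$mean_B, 0)
    expect_equal(ves$centroid_row, 2.5)
    # no labels -> empty table
    expect_equal(nrow(extractVesicles(matrix(0L, 8, 8), field)), 0L)
})

test_that("neuron assignment follows the pixel-majority rule", {
    lab <- matrix(0L, 10, 10)
    lab[1, 1:10] <- 1L     # vesicle 1: 10 px straddling two neurons
    lab[5, 1:4] <- 2L      # vesicle 2: fully inside neuron 3
    lab[9, 1:4] <- 3L      # vesicle 3: fully on background
    neurons <- matrix(0L, 10, 10)
    neurons[1, 1:6] <- 1L  # 60 % of vesicle 1
    neurons[1, 7:10] <- 2L # 40 %
    neurons[5, ] <- 3L
    ves <- extractVesicles(lab, makeField(matrix(1, 10, 10),
        matrix(1, 10, 10), matrix(1, 10, 10)))
    ves <- assignToNeurons(ves, lab, ROILabelMask(neurons))
    expect_equal(ves$neuron_id[ves$vesicle_id == 1L], 1L)
    expect_equal(ves$neuron_id[ves$vesicle_id == 2L], 3L)
    expect_equal(ves$neuron_id[ves$vesicle_id == 3L], 0L)
})

test_that("watershed labels partition the combined mask on a real scene", {
    scene <- generateScene(smallSceneConfig(seed = 19L))
    thr <- computeChannelThresholds(scene$field, scene$mask, nSample = 3L)
    masks <- buildPunctaMask(scene$field, thr)
    land <- getChannel(scene$field, "RFP_LC3") +
        getChannel(scene$field, "GFP_LC3") + getChannel(scene$field, "CTSD")
    lab <- watershedSplit(masks$combined, land)
    expect_equal(sum(lab > 0L), sum(masks$combined))
})
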