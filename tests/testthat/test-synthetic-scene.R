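test_that("scene generation is deterministic under a fixed seed", {
    a <- generateScene(smallSceneConfig(seed = 3L))
    b <- generateScene(smallSceneConfig(seed = 3L))
    expect_identical(a$field@pixels, b$field@pixels)
    expect_identical(labelMatrix(a$mask), labelMatrix(b$mask))
    expect_identical(a$groundTruth@vesicles, b$groundTruth@vesicles)
    c <- generateScene(smallSceneConfig(seed = 4L))
    expect_false(identical(a$field@pixels, c$field@pixels))
})

test_that("scene generation restores the caller's RNG state", {
    set.seed(123); before <- .Random.seed
    invisible(generateScene(smallSceneConfig(seed = 3L)))
    expect_identical(.Random.seed, before)
})

test_that("configured counts are honored exactly in fixed mode", {
    cfg <- SceneConfig(widthPx = 1024L, heightPx = 1024L, nNeurons = 10L,
        vesiclesPerNeuron = c(AP = 5, AL = 5, PA_AL = 2, LY = 8), seed = 2L)
    gt <- generateScene(cfg)$groundTruth
    expect_equal(nrow(gt@vesicles), 200L)  # 10 x (5+5+2+8)
    comp <- gt@composition
    expect_true(all(comp$AP == 5L & comp$AL == 5L & comp$PA_AL == 2L &
        comp$LY == 8L))
})

test_that("zero neurons produce an empty scene", {
    s <- generateScene(smallSceneConfig(nNeurons = 0L))
    expect_equal(nNeurons(s$mask), 0L)
    expect_equal(nrow(s$groundTruth@vesicles), 0L)
})

test_that("every ground-truth vesicle lies inside its neuron's soma", {
    s <- generateScene(smallSceneConfig(seed = 9L))
    lab <- labelMatrix(s$mask)
    gt <- s$groundTruth@vesicles
    at <- lab[cbind(round(gt$row), round(gt$col))]
    expect_equal(at, gt$neuron_id)
})

test_that("composition table matches a group-by count of the vesicle table", {
    s <- generateScene(smallSceneConfig(seed = 12L))
    gt <- s$groundTruth
    recount <- table(factor(gt@vesicles$neuron_id,
            levels = gt@composition$neuron_id),
        factor(gt@vesicles$subtype, levels = vesicleSubtypes()))
    for (st in vesicleSubtypes())
        expect_equal(gt@composition[[st]], as.integer(recount[, st]))
    expect_true(validObject(gt))
})

test_that("clump bookkeeping yields the configured number of doublets", {
    cfg <- smallSceneConfig(seed = 15L, clumpFraction = 0.2)
    gt <- generateScene(cfg)$groundTruth@vesicles
    # 20 vesicles/neuron x 0.2 / 2 = 2 doublets per neuron, 3 neurons
    clumps <- unique(gt$clump_id[gt$clump_id > 0])
    expect_equal(length(clumps), 6L)
    expect_true(all(table(gt$clump_id[gt$clump_id > 0]) == 2L))
    # doublet members touch: center distance < sum of radii
    for (cl in clumps) {
        pair <- gt[gt$clump_id == cl, ]
        d <- sqrt(diff(pair$row)^2 + diff(pair$col)^2)
        expect_lt(d, sum(pair$radius_px))
    }
})

test_that("noise-free rendering matches the Gaussian forward model exactly", {
    cfg <- cleanSceneConfig(seed = 8L)
    s <- generateScene(cfg)
    fs <- fullScale(s$field)
    sig <- subtypeSignatures()
    gt <- s$groundTruth@vesicles
    # with no blur, background or noise, every pixel holds exactly the
    # rounded sum of all Gaussian spot contributions (the forward model)
    forward <- function(r0, c0, role) {
        w <- ceiling(4 * gt$radius_px / 2 + 1)  # spot rendering window
        inWin <- r0 >= floor(gt$row - w) & r0 <= ceiling(gt$row + w) &
                 c0 >= floor(gt$col - w) & c0 <= ceiling(gt$col + w)
        sum((sig[gt$subtype, role] * fs *
            exp(-((r0 - gt$row)^2 + (c0 - gt$col)^2) /
                (2 * (gt$radius_px / 2)^2)))[inWin])
    }
    for (i in seq_len(nrow(gt))) {
        r0 <- round(gt$row[i]); c0 <- round(gt$col[i])
        for (role in c("RFP_LC3", "GFP_LC3", "CTSD")) {
            got <- getChannel(s$field, role)[r0, c0]
            expect_equal(got, round(forward(r0, c0, role)), tolerance = 1e-8)
        }
    }
})

test_that("IR overlay honors the association fraction in ground truth", {
    cfg <- smallSceneConfig(seed = 31L)
    s <- generateScene(cfg)
    ov <- generateIROverlay(s$field, s$groundTruth, cfg, nObjects = 50L,
        assocFraction = 0.4, seed = 32L)
    ir <- ov$groundTruth@irObjects
    expect_equal(nrow(ir), 50L)
    expect_equal(sum(ir$associated), 20L)  # 0.4 x 50
    expect_true("IR" %in% boundRoles(ov$field))
    # exhaustive geometry check: associated objects sit on an RFP+ vesicle
    gt <- s$groundTruth@vesicles
    rfp <- gt[gt$subtype %in% c("AP", "AL", "PA_AL"), ]
    for (i in which(ir$associated)) {
        d <- sqrt((rfp$row - ir$row[i])^2 + (rfp$col - ir$col[i])^2)
        expect_true(any(d < rfp$radius_px + ir$radius_px[i]))
    }
    # unassociated objects are clear of every RFP+ vesicle
    for (i in which(!ir$associated)) {
        d <- sqrt((rfp$row - ir$row[i])^2 + (rfp$col - ir$col[i])^2)
        expect_true(all(d > rfp$radius_px + ir$radius_px[i]))
    }
    # edge cases
    ov0 <- generateIROverlay(s$field, s$groundTruth, cfg, nObjects = 10L,
        assocFraction = 0, seed = 33L)
    expect_equal(sum(ov0$groundTruth@irObjects$associated), 0L)
    ov1 <- generateIROverlay(s$field, s$groundTruth, cfg, nObjects = 10L,
        assocFraction = 1, seed = 34L)
    expect_equal(sum(ov1$groundTruth@irObjects$associated), 10L)
    # a field that already has an IR channel is rejected
    expect_error(generateIROverlay(ov$field, ov$groundTruth, cfg),
        "already has an IR channel")
})

test_that("ground truth round-trips through plain-text files", {
    cfg <- smallSceneConfig(seed = 41L)
    s <- generateScene(cfg)
    ov <- generateIROverlay(s$field, s$groundTruth, cfg, nObjects = 20L,
        assocFraction = 0.5, seed = 42L)
    dir <- withr::local_tempdir()
    writeGroundTruth(ov$groundTruth, dir)
    back <- readGroundTruth(dir)
    expect_equal(back@vesicles, ov$groundTruth@vesicles)
    expect_equal(back@composition, ov$groundTruth@composition)
    expect_equal(back@irObjects, ov$groundTruth@irObjects)
    expect_identical(labelMatrix(back@somaMask),
        labelMatrix(ov$groundTruth@somaMask))
    expect_equal(back@somaMask@kind, "PERIKARYON")
})
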