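#' SceneConfig: parameters of the synthetic confocal scene simulator
#'
#' Describes one simulated field: geometry (default 1024 x 1024 px covering
#' 212.34 x 212.34 um, the standard 40x confocal raster), neuron layout,
#' per-neuron vesicle composition, optical blur and the noise model. The
#' simulator renders each vesicle as an isotropic 2-D Gaussian spot
#' (amplitude = subtype signature x full scale, sigma = radius / 2) on top
#' of diffuse somatic reporter signal, applies a global Gaussian PSF, then
#' Poisson photon noise plus Gaussian read noise.
#'
#' Subtype signatures follow the tandem-reporter logic: AP carries eGFP +
#' mRFP (yellow), AL mRFP + CTSD (purple), pa-AL all three with equal peaks
#' (white, near-zero saturation), LY CTSD only (blue).
#'
#' @slot widthPx,heightPx field size in pixels.
#' @slot pixelSizeUm micrometres per pixel edge.
#' @slot bitDepth acquisition bit depth.
#' @slot nNeurons number of somata.
#' @slot somaRadiusUm soma radius in micrometres.
#' @slot vesiclesPerNeuron named numeric (AP, AL, PA_AL, LY): per-neuron
#'   subtype counts ("fixed" mode) or Poisson means ("poisson" mode).
#' @slot countMode "fixed" or "poisson".
#' @slot vesicleRadiusUmRange uniform range of vesicle radii (um).
#' @slot psfSigmaUm Gaussian PSF sigma (um).
#' @slot backgroundLevel background intensity as a fraction of full scale.
#' @slot somaLevels named fractions of full scale for diffuse somatic signal
#'   per channel role.
#' @slot signatures 4 x 3 matrix of peak amplitudes (fractions of full
#'   scale), rows AP/AL/PA_AL/LY, columns RFP_LC3/GFP_LC3/CTSD.
#' @slot poissonNoise apply Poisson photon noise?
#' @slot readNoiseSd Gaussian read-noise sigma as a fraction of full scale.
#' @slot clumpFraction fraction of vesicles placed as touching doublets.
#' @slot seed integer RNG seed (base R Mersenne-Twister).
#' @export
setClass("SceneConfig",
    slots = c(
        widthPx = "integer", heightPx = "integer",
        pixelSizeUm = "numeric", bitDepth = "integer",
        nNeurons = "integer", somaRadiusUm = "numeric",
        vesiclesPerNeuron = "numeric", countMode = "character",
        vesicleRadiusUmRange = "numeric", psfSigmaUm = "numeric",
        backgroundLevel = "numeric", somaLevels = "numeric",
        signatures = "matrix", poissonNoise = "logical",
        readNoiseSd = "numeric", clumpFraction = "numeric",
        seed = "integer"
    )
)

setValidity("SceneConfig", function(object) {
    msg <- character()
    if (object@widthPx < 8L || object@heightPx < 8L)
        msg <- c(msg, "field must be at least 8 x 8 px")
    if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
    if (object@nNeurons < 0L) msg <- c(msg, "nNeurons must be >= 0")
    if (object@somaRadiusUm <= 0) msg <- c(msg, "somaRadiusUm must be > 0")
    if (!setequal(names(object@vesiclesPerNeuron), .SUBTYPES))
        msg <- c(msg, "vesiclesPerNeuron must be named AP, AL, PA_AL, LY")
    if (any(object@vesiclesPerNeuron < 0))
        msg <- c(msg, "vesicle counts must be >= 0")
    if (!object@countMode %in% c("fixed", "poisson"))
        msg <- c(msg, "countMode must be 'fixed' or 'poisson'")
    r <- object@vesicleRadiusUmRange
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
        msg <- c(msg, "vesicleRadiusUmRange must be a positive increasing pair")
    if (object@clumpFraction < 0 || object@clumpFraction > 1)
        msg <- c(msg, "clumpFraction must be in [0, 1]")
    sig <- object@signatures
    if (!identical(rownames(sig), .SUBTYPES) ||
        !identical(colnames(sig), c("RFP_LC3", "GFP_LC3", "CTSD")))
        msg <- c(msg, "signatures must have rows AP/AL/PA_AL/LY and columns RFP_LC3/GFP_LC3/CTSD")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SceneConfig", function(object) {
    cat(sprintf(
        "SceneConfig: %d x %d px (%.5f um/px), %d neurons, %s counts (%s), seed %d\n",
        object@widthPx, object@heightPx, object@pixelSizeUm, object@nNeurons,
        object@countMode,
        paste(sprintf("%s=%g", names(object@vesiclesPerNeuron),
            object@vesiclesPerNeuron), collapse = " "),
        object@seed))
})

#' Default subtype intensity signatures
#'
#' Peak channel amplitudes (fractions of full scale) encoding the reporter
#' logic. The pa-AL row uses equal R, G, B peaks so its rendered saturation
#' is near zero ("white").
#'
#' @param peak the "high" channel amplitude (fraction of full scale).
#' @return 4 x 3 numeric matrix, rows AP/AL/PA_AL/LY, columns
#'   RFP_LC3/GFP_LC3/CTSD.
#' @export
subtypeSignatures <- function(peak = 0.8) {
    sig <- rbind(
        AP    = c(peak, peak, 0),
        AL    = c(peak, 0,    peak),
        PA_AL = c(peak, peak, peak),
        LY    = c(0,    0,    peak)
    )
    colnames(sig) <- c("RFP_LC3", "GFP_LC3", "CTSD")
    sig
}

#' Construct a SceneConfig
#'
#' @param widthPx,heightPx field size in pixels (default 1024).
#' @param pixelSizeUm um per pixel; default 212.34/1024, the 40x raster.
#' @param bitDepth acquisition bit depth (default 12).
#' @param nNeurons somata per field (default 10).
#' @param somaRadiusUm soma radius (default 8 um, a medium spiny neuron
#'   perikaryon).
#' @param vesiclesPerNeuron named counts or Poisson means per subtype;
#'   default AP 5, AL 5, PA_AL 2, LY 8 (20 vesicles/neuron).
#' @param countMode "fixed" (exact counts) or "poisson" (sampled).
#' @param vesicleRadiusUmRange vesicle radius range (default 0.3-1.0 um).
#' @param psfSigmaUm PSF sigma (default 0.15 um, ~diffraction-limited).
#' @param backgroundLevel background fraction of full scale (default 0.02).
#' @param somaLevels diffuse somatic signal fractions; default mRFP/eGFP
#'   0.06 (cytosolic reporter), CTSD 0.02.
#' @param signatures subtype signature matrix, see [subtypeSignatures()].
#' @param poissonNoise apply Poisson noise (default TRUE).
#' @param readNoiseSd read-noise sigma fraction (default 0.005).
#' @param clumpFraction fraction of vesicles placed as touching doublets
#'   (default 0.1).
#' @param seed RNG seed.
#' @return A validated [SceneConfig-class].
#' @export
SceneConfig <- function(widthPx = 1024L, heightPx = 1024L,
                        pixelSizeUm = 212.34 / 1024, bitDepth = 12L,
                        nNeurons = 10L, somaRadiusUm = 8,
                        vesiclesPerNeuron = c(AP = 5, AL = 5, PA_AL = 2, LY = 8),
                        countMode = "fixed",
                        vesicleRadiusUmRange = c(0.3, 1.0),
                        psfSigmaUm = 0.15, backgroundLevel = 0.02,
                        somaLevels = c(RFP_LC3 = 0.06, GFP_LC3 = 0.06,
                            CTSD = 0.02),
                        signatures = subtypeSignatures(),
                        poissonNoise = TRUE, readNoiseSd = 0.005,
                        clumpFraction = 0.1, seed = 1L) {
    new("SceneConfig", widthPx = as.integer(widthPx),
        heightPx = as.integer(heightPx), pixelSizeUm = pixelSizeUm,
        bitDepth = as.integer(bitDepth), nNeurons = as.integer(nNeurons),
        somaRadiusUm = somaRadiusUm,
        vesiclesPerNeuron = vesiclesPerNeuron[.SUBTYPES],
        countMode = countMode, vesicleRadiusUmRange = vesicleRadiusUmRange,
        psfSigmaUm = psfSigmaUm, backgroundLevel = backgroundLevel,
        somaLevels = somaLevels, signatures = signatures,
        poissonNoise = poissonNoise, readNoiseSd = readNoiseSd,
        clumpFraction = clumpFraction, seed = as.integer(seed))
}

## Add an unnormalised Gaussian spot into a channel matrix (in place value).
.addSpot <- function(ch, row, col, sigma, amp) {
    if (amp <= 0) return(ch)
    w <- ceiling(4 * sigma + 1)
    r0 <- max(1L, floor(row - w)); r1 <- min(nrow(ch), ceiling(row + w))
    c0 <- max(1L, floor(col - w)); c1 <- min(ncol(ch), ceiling(col + w))
    rr <- r0:r1; cc <- c0:c1
    g <- exp(-outer((rr - row)^2, (cc - col)^2, "+") / (2 * sigma^2))
    ch[rr, cc] <- ch[rr, cc] + amp * g
    ch
}

## Draw a filled disk of value `val` into an integer matrix.
.drawDisk <- function(m, row, col, radius, val) {
    r0 <- max(1L, floor(row - radius)); r1 <- min(nrow(m), ceiling(row + radius))
    c0 <- max(1L, floor(col - radius)); c1 <- min(ncol(m), ceiling(col + radius))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - row)^2, (cc - col)^2, "+")
    sub <- m[rr, cc]
    sub[d2 <= radius^2] <- val
    m[rr, cc] <- sub
    m
}

#' Generate a synthetic confocal scene with ground truth
#'
#' Places non-overlapping circular somata, samples each neuron's vesicle
#' complement (subtype, radius, position; a configured fraction placed as
#' touching same-subtype doublets), renders the three reporter channels by
#' the Gaussian-spot forward model, and applies PSF blur and noise. Every
#' ground-truth vesicle lies inside its neuron's soma; before blur and noise
#' the peak channel intensities at spot centers match the subtype signature
#' exactly.
#'
#' Deterministic for a fixed `seed` (base R Mersenne-Twister; the caller's
#' RNG state is restored on exit).
#'
#' @param config a [SceneConfig-class].
#' @return list with elements `field` ([MultiChannelField-class]), `mask`
#'   (the soma [ROILabelMask-class]) and `groundTruth`
#'   ([SceneGroundTruth-class]).
#' @export
generateScene <- function(config) {
    stopifnot(is(config, "SceneConfig"))
    validObject(config)
    .withSeed(config@seed, .generateSceneImpl(config))
}

.generateSceneImpl <- function(config) {
    nr <- config@heightPx; nc <- config@widthPx
    fs <- 2^config@bitDepth - 1
    somaR <- config@somaRadiusUm / config@pixelSizeUm
    margin <- somaR + 6

    ## soma centers: rejection sampling with a bounded retry budget
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < config@nNeurons) {
        if (tries > 200L * max(1L, config@nNeurons))
            stop(sprintf(
                "could not place %d non-overlapping somata of radius %.1f um in a %d x %d px field",
                config@nNeurons, config@somaRadiusUm, nr, nc))
        tries <- tries + 1L
        cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
        if (nrow(centers) == 0 ||
            all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > 2 * somaR + 4))
            centers <- rbind(centers, cand)
    }

    somaLab <- matrix(0L, nr, nc)
    for (k in seq_len(config@nNeurons))
        somaLab <- .drawDisk(somaLab, centers[k, 1], centers[k, 2], somaR, k)

    ## per-neuron vesicle complements
    lam <- config@vesiclesPerNeuron
    recs <- list()
    vid <- 0L; clumpId <- 0L
    for (k in seq_len(config@nNeurons)) {
        counts <- if (config@countMode == "fixed") round(lam)
            else vapply(lam, function(l) rpois(1L, l), numeric(1))
        subtypes <- rep(names(counts), counts)
        if (length(subtypes) == 0L) next
        subtypes <- sample(subtypes)
        nPairs <- floor(config@clumpFraction * length(subtypes) / 2)
        placed <- matrix(numeric(0), 0, 3)  # row, col, radius_px
        place1 <- function(rad, near = NULL) {
            for (i in 1:3000) {
                if (is.null(near)) {
                    u <- sqrt(runif(1)) * max(somaR - rad - 2, 1)
                    a <- runif(1, 0, 2 * pi)
                    p <- centers[k, ] + u * c(cos(a), sin(a))
                } else {
                    a <- runif(1, 0, 2 * pi)
                    d <- 0.9 * (near[3] + rad)
                    p <- near[1:2] + d * c(cos(a), sin(a))
                    if (sqrt(sum((p - centers[k, ])^2)) > somaR - rad - 1) next
                }
                ok <- TRUE
                if (nrow(placed)) {
                    dd <- sqrt(rowSums(sweep(placed[, 1:2, drop = FALSE], 2, p)^2))
                    minsep <- placed[, 3] + rad + 1
                    ## a doublet's second member may (must) touch its partner,
                    ## which is the most recently placed vesicle
                    exempt <- if (is.null(near)) rep(FALSE, length(dd))
                        else seq_along(dd) == length(dd)
                    ok <- all(dd >= minsep | exempt)
                }
                if (ok) return(p)
            }
            NULL
        }
        i <- 1L
        ## a crowded soma may not accommodate a large vesicle: re-draw the
        ## radius a few times before declaring the density infeasible
        drawPlace <- function(near = NULL) {
            for (attempt in 1:8) {
                radUm <- runif(1, config@vesicleRadiusUmRange[1],
                    config@vesicleRadiusUmRange[2])
                rad <- radUm / config@pixelSizeUm
                p <- place1(rad, near = near)
                if (!is.null(p)) return(list(p = p, rad = rad, radUm = radUm))
            }
            NULL
        }
        while (i <= length(subtypes)) {
            dp <- drawPlace()
            if (is.null(dp))
                stop("vesicle placement failed: soma too crowded for the configured density")
            p <- dp$p; rad <- dp$rad; radUm <- dp$radUm
            vid <- vid + 1L
            pairUp <- (i %% 2L == 1L) && (i + 1L <= 2L * nPairs)
            thisClump <- 0L
            if (pairUp) { clumpId <- clumpId + 1L; thisClump <- clumpId }
            placed <- rbind(placed, c(p, rad))
            recs[[length(recs) + 1L]] <- data.frame(vesicle_id = vid,
                neuron_id = k, row = p[1], col = p[2], radius_px = rad,
                radius_um = radUm, subtype = subtypes[i], clump_id = thisClump)
            if (pairUp) {
                dp2 <- drawPlace(near = c(p, rad))
                if (is.null(dp2))
                    stop("doublet placement failed: soma too crowded")
                p2 <- dp2$p; rad2 <- dp2$rad; rad2Um <- dp2$radUm
                vid <- vid + 1L
                placed <- rbind(placed, c(p2, rad2))
                recs[[length(recs) + 1L]] <- data.frame(vesicle_id = vid,
                    neuron_id = k, row = p2[1], col = p2[2], radius_px = rad2,
                    radius_um = rad2Um, subtype = subtypes[i + 1L],
                    clump_id = thisClump)
                i <- i + 2L
            } else i <- i + 1L
        }
    }
    vesicles <- if (length(recs)) do.call(rbind, recs) else
        data.frame(vesicle_id = integer(), neuron_id = integer(),
            row = numeric(), col = numeric(), radius_px = numeric(),
            radius_um = numeric(), subtype = character(),
            clump_id = integer())

    ## render channels: background + diffuse soma + Gaussian spots
    roles <- c("RFP_LC3", "GFP_LC3", "CTSD")
    inSoma <- somaLab > 0L
    channels <- lapply(roles, function(role) {
        ch <- matrix(config@backgroundLevel * fs, nr, nc)
        lev <- config@somaLevels[[role]]
        if (!is.null(lev) && !is.na(lev) && lev > 0) ch[inSoma] <- ch[inSoma] + lev * fs
        ch
    })
    names(channels) <- roles
    if (nrow(vesicles)) {
        for (i in seq_len(nrow(vesicles))) {
            sig <- config@signatures[vesicles$subtype[i], ]
            for (role in roles)
                channels[[role]] <- .addSpot(channels[[role]],
                    vesicles$row[i], vesicles$col[i],
                    sigma = vesicles$radius_px[i] / 2, amp = sig[[role]] * fs)
        }
    }
    psfPx <- config@psfSigmaUm / config@pixelSizeUm
    channels <- lapply(channels, function(ch) {
        if (psfPx > 0) ch <- as.matrix(EBImage::gblur(EBImage::Image(ch),
            sigma = psfPx))
        if (config@poissonNoise)
            ch <- matrix(rpois(length(ch), pmax(ch, 0)), nr, nc)
        if (config@readNoiseSd > 0)
            ch <- ch + rnorm(length(ch), 0, config@readNoiseSd * fs)
        matrix(pmin(pmax(round(ch), 0), fs), nr, nc)
    })

    field <- MultiChannelField(unname(channels),
        c(RFP_LC3 = 1L, GFP_LC3 = 2L, CTSD = 3L),
        pixelSizeUm = config@pixelSizeUm, bitDepth = config@bitDepth)
    mask <- ROILabelMask(somaLab, kind = "PERIKARYON")
    comp <- .composition(vesicles, seq_len(config@nNeurons))
    gt <- new("SceneGroundTruth", vesicles = vesicles, composition = comp,
        somaMask = mask, irObjects = .emptyIRTable())
    list(field = field, mask = mask, groundTruth = gt)
}

.composition <- function(vesicles, neuronIds) {
    tab <- table(factor(vesicles$neuron_id, levels = neuronIds),
        factor(vesicles$subtype, levels = .SUBTYPES))
    out <- data.frame(neuron_id = as.integer(neuronIds))
    for (s in .SUBTYPES) out[[s]] <- as.integer(tab[, s])
    out$total <- as.integer(rowSums(tab))
    out
}

.emptyIRTable <- function() {
    data.frame(ir_id = integer(), row = numeric(), col = numeric(),
        radius_px = numeric(), radius_um = numeric(), associated = logical(),
        neuron_id = integer())
}

#' Overlay a synthetic immunoreactivity channel
#'
#' Adds a fourth (IR) channel to a generated scene: `nObjects` Gaussian
#' blobs of which a fraction `assocFraction` is placed overlapping an
#' mRFP-positive vesicle (subtype AP, AL or pa-AL; the AV-associated form)
#' and the rest well away from all somata and reporter puncta (the
#' unassociated form). Per-object true association is recorded in the
#' ground truth. Rendering uses the scene's PSF and noise model.
#'
#' @param field the scene's [MultiChannelField-class] (must not already have
#'   an IR channel).
#' @param groundTruth the scene's [SceneGroundTruth-class].
#' @param config the [SceneConfig-class] the scene was generated with.
#' @param nObjects number of IR objects.
#' @param assocFraction fraction in \[0, 1\] of objects to place overlapping
#'   an RFP punctum.
#' @param radiusRangeUm uniform radius range of IR objects (um).
#' @param irPeak peak amplitude as a fraction of full scale.
#' @param seed RNG seed for the overlay.
#' @return list with updated `field` and `groundTruth`.
#' @export
generateIROverlay <- function(field, groundTruth, config, nObjects = 200L,
                              assocFraction = 0.4, radiusRangeUm = c(0.3, 0.8),
                              irPeak = 0.7, seed = 1L) {
    stopifnot(is(field, "MultiChannelField"), is(groundTruth, "SceneGroundTruth"))
    if ("IR" %in% boundRoles(field))
        stop("field already has an IR channel")
    if (assocFraction < 0 || assocFraction > 1)
        stop("assocFraction must be in [0, 1]")
    .withSeed(seed, .irOverlayImpl(field, groundTruth, config, nObjects,
        assocFraction, radiusRangeUm, irPeak))
}

.irOverlayImpl <- function(field, groundTruth, config, nObjects, assocFraction,
                           radiusRangeUm, irPeak) {
    d <- fieldDim(field); nr <- d[1]; nc <- d[2]
    fs <- fullScale(field)
    psfPx <- config@psfSigmaUm / config@pixelSizeUm
    ves <- groundTruth@vesicles
    rfpVes <- ves[ves$subtype %in% c("AP", "AL", "PA_AL"), , drop = FALSE]
    nAssoc <- round(assocFraction * nObjects)
    if (nAssoc > nrow(rfpVes))
        stop(sprintf(
            "cannot place %d associated IR objects: scene has only %d RFP-positive vesicles",
            nAssoc, nrow(rfpVes)))
    ## one host vesicle per associated object keeps objects separable; a
    ## shuffled pool lets a crowded host be swapped for an unused one
    hostPool <- if (nrow(rfpVes)) sample(nrow(rfpVes)) else integer()
    hostPtr <- 0L
    somaLab <- labelMatrix(groundTruth@somaMask)
    somaR <- config@somaRadiusUm / config@pixelSizeUm
    ## soma centers recovered from the label mask
    somaCtr <- .labelStats(somaLab, list())[, c("centroid_row", "centroid_col")]

    placed <- matrix(numeric(0), 0, 3)
    recs <- vector("list", nObjects)
    for (i in seq_len(nObjects)) {
        radUm <- runif(1, radiusRangeUm[1], radiusRangeUm[2])
        rad <- radUm / config@pixelSizeUm
        assoc <- i <= nAssoc
        ok <- FALSE
        if (assoc) {
            if (hostPtr >= length(hostPool))
                stop("IR object placement failed: no usable RFP-positive host vesicles left")
            hostPtr <- hostPtr + 1L
            j <- hostPool[hostPtr]
        }
        for (try in 1:2000) {
            if (assoc) {
                if (try %% 100L == 0L) {  # crowded host: swap for an unused one
                    if (hostPtr >= length(hostPool))
                        stop("IR object placement failed: no usable RFP-positive host vesicles left")
                    hostPtr <- hostPtr + 1L
                    j <- hostPool[hostPtr]
                }
                jit <- 0.4 * min(rad, rfpVes$radius_px[j])
                a <- runif(1, 0, 2 * pi); u <- runif(1, 0, jit)
                p <- c(rfpVes$row[j], rfpVes$col[j]) + u * c(cos(a), sin(a))
                host <- rfpVes$neuron_id[j]
            } else {
                p <- c(runif(1, rad + 4, nr - rad - 4),
                       runif(1, rad + 4, nc - rad - 4))
                ## keep clear of all somata (and hence of all reporter puncta)
                if (nrow(somaCtr) && any(sqrt((somaCtr[, 1] - p[1])^2 +
                        (somaCtr[, 2] - p[2])^2) < somaR + rad + 4 * psfPx + 6))
                    next
                host <- 0L
            }
            if (p[1] < rad + 2 || p[1] > nr - rad - 2 ||
                p[2] < rad + 2 || p[2] > nc - rad - 2) next
            if (nrow(placed)) {
                dd <- sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2)
                ## separation on the above-threshold footprints (~1.4 x the
                ## nominal radius after blur), so objects segment discretely
                if (any(dd < 1.4 * (placed[, 3] + rad) + 4)) next
            }
            ok <- TRUE
            break
        }
        if (!ok) stop("IR object placement failed: density too high for the field")
        placed <- rbind(placed, c(p, rad))
        recs[[i]] <- data.frame(ir_id = i, row = p[1], col = p[2],
            radius_px = rad, radius_um = radUm, associated = assoc,
            neuron_id = as.integer(host))
    }
    irObjects <- do.call(rbind, recs)

    ch <- matrix(config@backgroundLevel * fs, nr, nc)
    for (i in seq_len(nObjects))
        ch <- .addSpot(ch, irObjects$row[i], irObjects$col[i],
            sigma = irObjects$radius_px[i] / 2, amp = irPeak * fs)
    if (psfPx > 0)
        ch <- as.matrix(EBImage::gblur(EBImage::Image(ch), sigma = psfPx))
    if (config@poissonNoise) ch <- matrix(rpois(length(ch), pmax(ch, 0)), nr, nc)
    if (config@readNoiseSd > 0)
        ch <- ch + rnorm(length(ch), 0, config@readNoiseSd * fs)
    ch <- matrix(pmin(pmax(round(ch), 0), fs), nr, nc)

    px <- c(field@pixels, list(ch))
    cm <- c(field@channelMap, IR = length(px))
    newField <- MultiChannelField(px, cm, pixelSizeUm = field@pixelSizeUm,
        bitDepth = field@bitDepth)
    newGt <- groundTruth
    newGt@irObjects <- irObjects
    list(field = newField, groundTruth = newGt)
}

#' Match detected vesicles to simulator ground truth
#'
#' For each ground-truth vesicle, finds the detected punctum whose label
#' region contains the true center (falling back to the nearest detected
#' centroid within one true radius + 2 px), and tabulates true versus
#' detected subtype.
#'
#' @param vesicles detected (and, if available, classified) vesicle
#'   data.frame.
#' @param labels the segmentation label matrix the vesicles came from.
#' @param groundTruth a [SceneGroundTruth-class].
#' @return data.frame with one row per ground-truth vesicle: `vesicle_id`,
#'   `neuron_id`, `true_subtype`, `detected_id` (NA if undetected) and
#'   `detected_subtype` (NA if undetected or unclassified input).
#' @export
matchToGroundTruth <- function(vesicles, labels, groundTruth) {
    stopifnot(is(groundTruth, "SceneGroundTruth"))
    gt <- groundTruth@vesicles
    det <- rep(NA_integer_, nrow(gt))
    for (i in seq_len(nrow(gt))) {
        r <- round(gt$row[i]); cc <- round(gt$col[i])
        lab <- 0L
        if (r >= 1 && r <= nrow(labels) && cc >= 1 && cc <= ncol(labels))
            lab <- labels[r, cc]
        if (lab == 0L && nrow(vesicles)) {
            dd <- sqrt((vesicles$centroid_row - gt$row[i])^2 +
                       (vesicles$centroid_col - gt$col[i])^2)
            j <- which.min(dd)
            if (dd[j] <= gt$radius_px[i] + 2) lab <- vesicles$vesicle_id[j]
        }
        if (lab > 0L) det[i] <- lab
    }
    out <- data.frame(vesicle_id = gt$vesicle_id, neuron_id = gt$neuron_id,
        true_subtype = gt$subtype, detected_id = det)
    if (!is.null(vesicles$subtype)) {
        out$detected_subtype <- as.character(
            vesicles$subtype[match(det, vesicles$vesicle_id)])
    } else out$detected_subtype <- NA_character_
    out
}

#' Classification accuracy against ground truth
#'
#' @param matched output of [matchToGroundTruth()].
#' @return Fraction of ground-truth vesicles whose detected subtype equals
#'   the true subtype (undetected or unclassified count as incorrect).
#' @export
classificationAccuracy <- function(matched) {
    if (nrow(matched) == 0L) return(NA_real_)
    mean(!is.na(matched$detected_subtype) &
         matched$detected_subtype == matched$true_subtype)
}

#' Write / read simulator ground truth
#'
#' Serialises a [SceneGroundTruth-class] into plain-text tables
#' (`vesicles.csv`, `composition.csv`, `ir_objects.csv`) plus the soma label
#' mask as 16-bit TIFF (`soma_mask.tif`); `readGroundTruth` restores the
#' object losslessly.
#'
#' @param groundTruth a [SceneGroundTruth-class].
#' @param dir output directory (created if needed).
#' @return `writeGroundTruth` returns `dir` invisibly; `readGroundTruth`
#'   returns the restored [SceneGroundTruth-class].
#' @export
writeGroundTruth <- function(groundTruth, dir) {
    stopifnot(is(groundTruth, "SceneGroundTruth"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    .writeTableWithMeta(groundTruth@vesicles, file.path(dir, "vesicles.csv"))
    .writeTableWithMeta(groundTruth@composition, file.path(dir, "composition.csv"))
    .writeTableWithMeta(groundTruth@irObjects, file.path(dir, "ir_objects.csv"),
        meta = list(kind = groundTruth@somaMask@kind))
    writeROIMask(groundTruth@somaMask, file.path(dir, "soma_mask.tif"))
    invisible(dir)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(dir) {
    ves <- .readTableWithMeta(file.path(dir, "vesicles.csv"))
    comp <- .readTableWithMeta(file.path(dir, "composition.csv"))
    ir <- .readTableWithMeta(file.path(dir, "ir_objects.csv"))
    if (nrow(ir)) ir$associated <- as.logical(ir$associated)
    else ir <- .emptyIRTable()
    first <- readLines(file.path(dir, "ir_objects.csv"), n = 1L)
    kind <- if (startsWith(first, "# kind:"))
        jsonlite::fromJSON(sub("^# kind: ", "", first)) else "PERIKARYON"
    mask <- loadROIMask(file.path(dir, "soma_mask.tif"), kind = kind)
    new("SceneGroundTruth", vesicles = ves, composition = comp,
        somaMask = mask, irObjects = ir)
}
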