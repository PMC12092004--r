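#' Perikaryon-derived channel thresholds
#'
#' For each classification channel the threshold is the average of the mean
#' pixel intensity of sampled neuronal perikarya: each sampled perikaryon ROI
#' contributes its mean intensity in that channel, and the threshold is the
#' mean of those per-ROI means. By default 20 perikarya are sampled (without
#' replacement, seeded for reproducibility); if the mask holds fewer, all are
#' used with a warning.
#'
#' @param field a [MultiChannelField-class] with GFP_LC3, RFP_LC3 and CTSD
#'   bound.
#' @param perikarya an [ROILabelMask-class] of perikaryon regions.
#' @param nSample number of perikarya to sample (default 20).
#' @param seed integer seed for the ROI sample; `NULL` uses the current RNG
#'   state.
#' @return A [ChannelThresholds-class] with the sampled ROI ids recorded.
#' @export
computeChannelThresholds <- function(field, perikarya, nSample = 20L,
                                     seed = NULL) {
    checkClassifyRoles(field)
    stopifnot(is(perikarya, "ROILabelMask"))
    if (!identical(dim(labelMatrix(perikarya)), fieldDim(field)))
        stop("perikaryon mask shape does not match the field")
    ids <- neuronIds(perikarya)
    if (length(ids) == 0L) stop("perikaryon mask contains no regions")
    if (length(ids) < nSample) {
        warning(sprintf(
            "mask has only %d perikarya (< %d requested); using all of them",
            length(ids), nSample))
        sampled <- ids
    } else {
        sampled <- .withSeed(seed, sort(sample(ids, nSample)))
    }
    lab <- labelMatrix(perikarya)
    sel <- lab %in% sampled
    f <- factor(lab[sel], levels = sampled)
    vals <- vapply(.CLASSIFY_ROLES, function(role) {
        ch <- getChannel(field, role)
        mean(as.numeric(tapply(ch[sel], f, mean)))
    }, numeric(1))
    ChannelThresholds(vals, roiIds = sampled)
}

#' Build per-channel and combined puncta masks
#'
#' A pixel belongs to a channel's mask when its intensity is strictly greater
#' than that channel's threshold (ties are excluded, making the rule
#' deterministic); the combined vesicle mask is the union of the three
#' channel masks.
#'
#' @param field a [MultiChannelField-class].
#' @param thresholds a [ChannelThresholds-class].
#' @return A list with logical matrices `GFP_LC3`, `RFP_LC3`, `CTSD` and
#'   `combined`.
#' @export
buildPunctaMask <- function(field, thresholds) {
    checkClassifyRoles(field)
    stopifnot(is(thresholds, "ChannelThresholds"))
    masks <- lapply(.CLASSIFY_ROLES, function(role)
        getChannel(field, role) > thresholds@values[[role]])
    names(masks) <- .CLASSIFY_ROLES
    masks$combined <- masks$GFP_LC3 | masks$RFP_LC3 | masks$CTSD
    masks
}

#' Watershed splitting of clumped puncta
#'
#' Separates touching vesicles into individual puncta by running a watershed
#' on the (smoothed) intensity landscape restricted to the binary mask: local
#' intensity maxima seed the labels and basins are grown until they meet.
#' Every mask pixel receives exactly one label, so pixel area is conserved;
#' touching doublets whose centers are at least about two spot-sigmas apart
#' are split into two labels.
#'
#' @param mask logical matrix of candidate vesicle pixels (e.g. the
#'   `combined` mask from [buildPunctaMask()]).
#' @param landscape numeric matrix of the intensity landscape used to find
#'   peaks, typically the sum of the three classification channels.
#' @param tolerance minimum peak-to-saddle intensity drop (native units)
#'   for two maxima to count as separate objects; smaller bumps are merged.
#' @param ext neighbourhood radius (px) for the local-maximum search.
#' @param smoothSigma Gaussian pre-smoothing sigma in px (0 disables).
#' @return Integer label matrix; 0 = background, labels 1..k.
#' @export
watershedSplit <- function(mask, landscape, tolerance = 80, ext = 2L,
                           smoothSigma = 1) {
    if (!identical(dim(mask), dim(landscape)))
        stop("mask and landscape shapes differ")
    mask <- mask != 0
    if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
    land <- landscape
    if (smoothSigma > 0)
        land <- as.matrix(EBImage::gblur(EBImage::Image(landscape),
            sigma = smoothSigma))
    ## +1 keeps every mask pixel strictly positive so the watershed labels it
    w <- EBImage::watershed(EBImage::Image((land - min(land) + 1) * mask),
        tolerance = tolerance, ext = ext)
    matrix(as.integer(w), nrow(mask), ncol(mask))
}

#' Remove out-of-size puncta (background elimination)
#'
#' Drops labels whose pixel area is below `minAreaPx` or above `maxAreaPx`,
#' the size-exclusion step that eliminates background specks. Remaining
#' labels are renumbered 1..k; removal counts are recorded in attributes.
#'
#' @param labels integer label matrix from [watershedSplit()].
#' @param minAreaPx minimum area in pixels (default 3, about 0.13 um^2 at
#'   the default confocal scale).
#' @param maxAreaPx maximum area in pixels (default `Inf`, no upper bound).
#' @return Filtered and renumbered label matrix with attributes
#'   `removed_small` and `removed_large` (label counts removed).
#' @export
applySizeExclusion <- function(labels, minAreaPx = 3L, maxAreaPx = Inf) {
    if (minAreaPx > maxAreaPx)
        stop("minAreaPx must not exceed maxAreaPx")
    pos <- labels[labels > 0L]
    if (length(pos) == 0L)
        return(structure(labels, removed_small = 0L, removed_large = 0L))
    area <- tabulate(pos)
    ids <- which(area > 0L)
    small <- ids[area[ids] < minAreaPx]
    large <- ids[area[ids] > maxAreaPx]
    out <- labels
    out[out %in% c(small, large)] <- 0L
    structure(.relabel(out), removed_small = length(small),
        removed_large = length(large))
}

#' Extract vesicle objects with per-channel mean intensities
#'
#' Builds one vesicle record per punctum label: pixel area (and area in
#' um^2), centroid, and the mean native intensity of each classification
#' channel over the label's pixels (`mean_R` = mRFP-LC3, `mean_G` =
#' eGFP-LC3, `mean_B` = CTSD).
#'
#' @param labels integer label matrix of segmented puncta.
#' @param field the [MultiChannelField-class] the labels came from.
#' @return data.frame with columns `vesicle_id`, `area_px`, `area_um2`,
#'   `centroid_row`, `centroid_col`, `mean_R`, `mean_G`, `mean_B`.
#' @export
extractVesicles <- function(labels, field) {
    checkClassifyRoles(field)
    if (!identical(dim(labels), fieldDim(field)))
        stop("label matrix shape does not match the field")
    st <- .labelStats(labels, list(
        mean_R = getChannel(field, "RFP_LC3"),
        mean_G = getChannel(field, "GFP_LC3"),
        mean_B = getChannel(field, "CTSD")))
    data.frame(
        vesicle_id = st$label,
        area_px = st$area_px,
        area_um2 = st$area_px * pixelSize(field)^2,
        centroid_row = st$centroid_row,
        centroid_col = st$centroid_col,
        mean_R = st$mean_R,
        mean_G = st$mean_G,
        mean_B = st$mean_B
    )
}

#' Assign vesicles to neurons by pixel majority
#'
#' Each vesicle is assigned to the neuron label owning the most of its
#' pixels. Vesicles whose plurality of pixels lies on background get
#' `neuron_id` 0 and are excluded from per-neuron counts; a tie between a
#' neuron and background goes to the neuron, ties between neurons to the
#' lower id.
#'
#' @param vesicles vesicle data.frame from [extractVesicles()].
#' @param labels the label matrix the vesicles were extracted from.
#' @param neuronMask an [ROILabelMask-class] of neuron territories.
#' @return `vesicles` with a `neuron_id` column added.
#' @export
assignToNeurons <- function(vesicles, labels, neuronMask) {
    stopifnot(is(neuronMask, "ROILabelMask"))
    if (!identical(dim(labels), dim(labelMatrix(neuronMask))))
        stop("label matrix and neuron mask shapes differ")
    mr <- .majorityRegion(labels, labelMatrix(neuronMask))
    vesicles$neuron_id <- mr$region[match(vesicles$vesicle_id, mr$label)]
    vesicles$neuron_id[is.na(vesicles$neuron_id)] <- 0L
    vesicles
}

#' Segment a field end-to-end
#'
#' Convenience wrapper running the full segmentation sequence: perikaryon
#' thresholds, per-channel masks and their union, watershed splitting of
#' clumps, size exclusion, vesicle extraction and neuron assignment.
#'
#' @param field a [MultiChannelField-class].
#' @param neuronMask [ROILabelMask-class] used both for thresholds and for
#'   neuron assignment.
#' @param nSample perikarya sampled for thresholds.
#' @param thresholdSeed seed for the perikaryon sample.
#' @param minAreaPx,maxAreaPx size-exclusion bounds.
#' @param tolerance,ext,smoothSigma watershed parameters, see
#'   [watershedSplit()].
#' @return list with `thresholds`, `masks`, `labels` and `vesicles`.
#' @export
segmentField <- function(field, neuronMask, nSample = 20L,
                         thresholdSeed = NULL, minAreaPx = 3L,
                         maxAreaPx = Inf, tolerance = 80, ext = 2L,
                         smoothSigma = 1) {
    thr <- computeChannelThresholds(field, neuronMask, nSample = nSample,
        seed = thresholdSeed)
    masks <- buildPunctaMask(field, thr)
    landscape <- getChannel(field, "RFP_LC3") + getChannel(field, "GFP_LC3") +
        getChannel(field, "CTSD")
    lab <- watershedSplit(masks$combined, landscape, tolerance = tolerance,
        ext = ext, smoothSigma = smoothSigma)
    lab <- applySizeExclusion(lab, minAreaPx = minAreaPx, maxAreaPx = maxAreaPx)
    ves <- extractVesicles(lab, field)
    ves <- assignToNeurons(ves, lab, neuronMask)
    list(thresholds = thr, masks = masks, labels = lab, vesicles = ves)
}
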