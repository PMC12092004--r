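#' Segment the immunoreactivity channel
#'
#' Binary threshold (strictly greater than), 8-connected components, then
#' size exclusion — the same conventions as the vesicle segmentation, but
#' without watershed splitting: each stained structure is one object.
#'
#' @param field a [MultiChannelField-class] with an IR channel bound.
#' @param irThreshold scalar intensity threshold (native units).
#' @param minAreaPx minimum object area in pixels.
#' @return Integer label matrix of IR objects (attributes from
#'   [applySizeExclusion()] preserved).
#' @export
segmentIR <- function(field, irThreshold, minAreaPx = 3L) {
    if (!"IR" %in% boundRoles(field))
        stop("field has no IR channel bound")
    ch <- getChannel(field, "IR")
    lab <- .label8(ch > irThreshold)
    applySizeExclusion(lab, minAreaPx = minAreaPx)
}

#' Partition immunoreactivity area by AV association
#'
#' Splits each cell's IR-covered area into the AV-associated and
#' AV-unassociated forms. Association is object-level against the mRFP-LC3
#' puncta mask (the channel that identifies autophagic vacuoles): an IR
#' object is AV-associated when at least one of its pixels overlaps the RFP
#' puncta mask, and its whole area then counts to the associated form.
#' Objects are assigned to neurons by the majority-pixel rule; objects with
#' background majority are reported under `neuron_id` 0. By construction
#' `total = associated + unassociated` exactly, per neuron, to the last
#' pixel.
#'
#' With `pixelLevel = TRUE` the overlap area itself (IR intersect RFP) counts
#' as associated and the remainder of each object as unassociated — a
#' sensitivity-analysis mode; the partition identity still holds.
#'
#' @param irLabels IR object label matrix from [segmentIR()].
#' @param rfpMask logical matrix of mRFP-LC3 puncta (e.g. the `RFP_LC3`
#'   mask from [buildPunctaMask()]).
#' @param neuronMask an [ROILabelMask-class].
#' @param pixelSizeUm micrometres per pixel edge, for areas in um^2.
#' @param pixelLevel use pixel-level instead of object-level association.
#' @return list with `partition` (one row per neuron incl. background 0:
#'   `neuron_id`, `total_area_um2`, `av_associated_area_um2`,
#'   `av_unassociated_area_um2`, `area_fraction_of_cell`, `n_ir_objects`,
#'   `n_associated_objects`) and `objects` (per-object table with
#'   `associated` flags).
#' @export
partitionAVAssociation <- function(irLabels, rfpMask, neuronMask,
                                   pixelSizeUm, pixelLevel = FALSE) {
    stopifnot(is(neuronMask, "ROILabelMask"))
    if (!identical(dim(irLabels), dim(rfpMask)) ||
        !identical(dim(irLabels), dim(labelMatrix(neuronMask))))
        stop("shape mismatch between IR labels, RFP mask and neuron mask")
    idx <- which(irLabels > 0L)
    pxArea <- pixelSizeUm^2
    if (length(idx)) {
        f <- factor(irLabels[idx])
        ids <- as.integer(levels(f))
        area <- as.integer(tabulate(f))
        ovl <- as.integer(rowsum(as.numeric(rfpMask[idx] != 0), f))
        mr <- .majorityRegion(irLabels, labelMatrix(neuronMask))
        objects <- data.frame(ir_id = ids, area_px = area,
            overlap_px = ovl, associated = ovl > 0L,
            neuron_id = mr$region[match(ids, mr$label)])
    } else {
        objects <- data.frame(ir_id = integer(), area_px = integer(),
            overlap_px = integer(), associated = logical(),
            neuron_id = integer())
    }
    nids <- sort(unique(c(0L, neuronIds(neuronMask), objects$neuron_id)))
    fN <- factor(objects$neuron_id, levels = nids)
    assocSrc <- if (pixelLevel) objects$overlap_px
        else objects$area_px * objects$associated
    tot <- as.numeric(tapply(objects$area_px, fN, sum, default = 0))
    assoc <- as.numeric(tapply(assocSrc, fN, sum, default = 0))
    nObj <- as.integer(table(fN))
    nAssoc <- as.integer(tapply(objects$associated, fN, sum, default = 0))
    cellPx <- tabulate(factor(labelMatrix(neuronMask)[labelMatrix(neuronMask) > 0L],
        levels = nids))
    partition <- data.frame(
        neuron_id = nids,
        total_area_um2 = tot * pxArea,
        av_associated_area_um2 = assoc * pxArea,
        av_unassociated_area_um2 = (tot - assoc) * pxArea,
        area_fraction_of_cell = ifelse(cellPx > 0, tot / cellPx, NA_real_),
        n_ir_objects = nObj,
        n_associated_objects = nAssoc
    )
    list(partition = partition, objects = objects)
}

#' Integrated density with low-staining region exclusion
#'
#' Sums pixel intensities of a channel over the whole field after excluding
#' minimally stained regions (e.g. striatal fiber bundles) by a threshold:
#' pixels with intensity less than or equal to `exclusionThreshold` are
#' excluded (mode `"below"`; mode `"above"` inverts the rule). Integrated
#' density is additive over disjoint included regions and zero when nothing
#' is included.
#'
#' @param field a [MultiChannelField-class].
#' @param role channel role to quantify (e.g. "IR").
#' @param exclusionThreshold scalar intensity cutoff (native units).
#' @param mode `"below"` excludes pixels <= threshold (default; the
#'   minimal-staining exclusion), `"above"` excludes pixels > threshold.
#' @return data.frame with `integrated_density`, `included_area_um2`,
#'   `excluded_area_um2`, `included_px`, `excluded_px`.
#' @export
integratedDensity <- function(field, role, exclusionThreshold = 0,
                              mode = c("below", "above")) {
    mode <- match.arg(mode)
    ch <- getChannel(field, role)
    excl <- if (mode == "below") ch <= exclusionThreshold
        else ch > exclusionThreshold
    pxArea <- pixelSize(field)^2
    data.frame(
        integrated_density = sum(as.numeric(ch[!excl])),
        included_area_um2 = sum(!excl) * pxArea,
        excluded_area_um2 = sum(excl) * pxArea,
        included_px = sum(!excl),
        excluded_px = sum(excl)
    )
}

#' Count rate per 100 units
#'
#' Converts a raw tally over counting units into a rate per 100 units, the
#' form used for electron-microscopy lipofuscin tallies (granules per 100
#' neurons). Both the unrounded rate and the nearest-integer rate are
#' reported.
#'
#' @param count total event tally (e.g. lipofuscin granules counted).
#' @param nUnits number of counting units (e.g. neurons examined); must be
#'   positive.
#' @return data.frame with `count`, `n_units`, `rate_per_100` and
#'   `rate_per_100_rounded`.
#' @examples
#' countRatePer100(113, 420)  # 26.90..., rounds to 27
#' countRatePer100(228, 586)  # 38.91..., rounds to 39
#' @export
countRatePer100 <- function(count, nUnits) {
    if (any(nUnits <= 0)) stop("nUnits must be positive")
    if (any(count < 0)) stop("count must be >= 0")
    rate <- count / nUnits * 100
    data.frame(count = count, n_units = nUnits, rate_per_100 = rate,
        rate_per_100_rounded = round(rate))
}
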