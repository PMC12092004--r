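#' @import methods
NULL

## Channel roles recognised throughout the package. GFP_LC3, RFP_LC3 and CTSD
## must all be bound before vesicle classification can run; IR and NUCLEAR are
## optional extras.
.CHANNEL_ROLES <- c("GFP_LC3", "RFP_LC3", "CTSD", "IR", "NUCLEAR")
.CLASSIFY_ROLES <- c("GFP_LC3", "RFP_LC3", "CTSD")
.SUBTYPES <- c("AP", "AL", "PA_AL", "LY")
.MASK_KINDS <- c("PERIKARYON", "WHOLE_CELL", "FIELD")

#' Channel roles used by the classifier
#'
#' @return Character vector of recognised channel role names.
#' @export
channelRoles <- function() .CHANNEL_ROLES

#' Vesicle subtype labels
#'
#' AP = autophagosome (yellow), AL = autolysosome (purple), PA_AL = poorly
#' acidified autolysosome (white), LY = lysosome (blue).
#'
#' @return Character vector of the four subtype labels.
#' @export
vesicleSubtypes <- function() .SUBTYPES

#' MultiChannelField: one imaged confocal field
#'
#' Holds one 2-D intensity matrix per channel (native integer units,
#' 0 .. 2^bitDepth - 1), a mapping from semantic channel roles to channel
#' indices, and the physical pixel size.
#'
#' @slot pixels list of numeric matrices, one per channel, identical dims.
#' @slot channelMap named integer vector mapping roles (see
#'   [channelRoles()]) to indices into `pixels`.
#' @slot pixelSizeUm micrometres per pixel edge (scalar, > 0).
#' @slot bitDepth integer bit depth of the acquisition (full scale is
#'   `2^bitDepth - 1`).
#'
#' @export
setClass("MultiChannelField",
    slots = c(
        pixels = "list",
        channelMap = "integer",
        pixelSizeUm = "numeric",
        bitDepth = "integer"
    )
)

setValidity("MultiChannelField", function(object) {
    msg <- character()
    px <- object@pixels
    if (length(px) == 0L) msg <- c(msg, "field must contain at least one channel")
    if (!all(vapply(px, is.matrix, logical(1))))
        msg <- c(msg, "all channels must be matrices")
    dims <- vapply(px, dim, integer(2))
    if (length(px) > 1L && any(dims != dims[, 1]))
        msg <- c(msg, "all channels must share identical width/height")
    if (any(vapply(px, function(m) any(m < 0), logical(1))))
        msg <- c(msg, "intensities must be >= 0")
    cm <- object@channelMap
    if (is.null(names(cm)) || !all(names(cm) %in% .CHANNEL_ROLES))
        msg <- c(msg, sprintf("channelMap names must be among: %s",
            paste(.CHANNEL_ROLES, collapse = ", ")))
    if (anyDuplicated(names(cm)))
        msg <- c(msg, "channelMap roles must be unique")
    if (any(cm < 1L | cm > length(px)))
        msg <- c(msg, "channel index out of range")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
        msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (length(object@bitDepth) != 1L || object@bitDepth < 1L)
        msg <- c(msg, "bitDepth must be a positive integer")
    if (length(msg)) msg else TRUE
})

#' Construct a MultiChannelField
#'
#' @param pixels list of numeric channel matrices (native intensity units).
#' @param channelMap named integer vector, role -> index into `pixels`.
#' @param pixelSizeUm micrometres per pixel edge.
#' @param bitDepth acquisition bit depth (default 12, typical for confocal).
#' @return A [MultiChannelField-class] object.
#' @examples
#' ch <- matrix(0, 64, 64)
#' f <- MultiChannelField(list(ch, ch, ch),
#'     c(GFP_LC3 = 1L, RFP_LC3 = 2L, CTSD = 3L),
#'     pixelSizeUm = 212.34 / 1024)
#' @export
MultiChannelField <- function(pixels, channelMap, pixelSizeUm, bitDepth = 12L) {
    cm <- as.integer(channelMap)
    names(cm) <- names(channelMap)
    new("MultiChannelField", pixels = pixels, channelMap = cm,
        pixelSizeUm = as.numeric(pixelSizeUm), bitDepth = as.integer(bitDepth))
}

#' ROILabelMask: neuron / perikaryon label map
#'
#' Integer label image the same shape as its field: 0 = background, k > 0 =
#' neuron k. Labels need not be contiguous but must be unique per neuron.
#'
#' @slot labels integer-valued matrix of region labels.
#' @slot kind one of "PERIKARYON", "WHOLE_CELL", "FIELD".
#' @export
setClass("ROILabelMask",
    slots = c(labels = "matrix", kind = "character"))

setValidity("ROILabelMask", function(object) {
    msg <- character()
    lab <- object@labels
    if (any(lab < 0)) msg <- c(msg, "labels must be non-negative")
    if (any(lab != floor(lab))) msg <- c(msg, "labels must be integers")
    if (!(length(object@kind) == 1L && object@kind %in% .MASK_KINDS))
        msg <- c(msg, sprintf("kind must be one of: %s",
            paste(.MASK_KINDS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct an ROILabelMask
#'
#' @param labels integer-valued matrix (0 = background, k > 0 = neuron k).
#' @param kind what the regions delineate: "PERIKARYON" (cell bodies, the
#'   region the paper samples for thresholds), "WHOLE_CELL", or "FIELD".
#' @return An [ROILabelMask-class] object.
#' @export
ROILabelMask <- function(labels, kind = "PERIKARYON") {
    new("ROILabelMask", labels = labels, kind = kind)
}

#' ChannelThresholds: perikaryon-derived segmentation thresholds
#'
#' One scalar threshold per classification channel, computed as the mean of
#' per-perikaryon mean intensities; the sampled ROI ids are recorded.
#'
#' @slot values named numeric vector with elements GFP_LC3, RFP_LC3, CTSD
#'   (native intensity units).
#' @slot roiIds integer ids of the perikarya used.
#' @export
setClass("ChannelThresholds",
    slots = c(values = "numeric", roiIds = "integer"))

setValidity("ChannelThresholds", function(object) {
    msg <- character()
    v <- object@values
    if (!setequal(names(v), .CLASSIFY_ROLES))
        msg <- c(msg, "thresholds must cover exactly GFP_LC3, RFP_LC3, CTSD")
    if (any(v < 0)) msg <- c(msg, "thresholds must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct ChannelThresholds
#'
#' @param values named numeric vector (GFP_LC3, RFP_LC3, CTSD).
#' @param roiIds integer vector of perikaryon ROI ids used.
#' @return A [ChannelThresholds-class] object.
#' @export
ChannelThresholds <- function(values, roiIds = integer()) {
    new("ChannelThresholds", values = values[.CLASSIFY_ROLES],
        roiIds = as.integer(roiIds))
}

#' SceneGroundTruth: simulator truth for one synthetic scene
#'
#' @slot vesicles data.frame with one row per ground-truth vesicle
#'   (vesicle_id, neuron_id, x, y, radius_px, radius_um, subtype, clump_id).
#' @slot composition per-neuron subtype composition table.
#' @slot somaMask the true soma [ROILabelMask-class].
#' @slot irObjects data.frame of immunoreactivity objects (possibly 0-row):
#'   ir_id, x, y, radius_px, associated (true AV-association flag), neuron_id.
#' @export
setClass("SceneGroundTruth",
    slots = c(
        vesicles = "data.frame",
        composition = "data.frame",
        somaMask = "ROILabelMask",
        irObjects = "data.frame"
    )
)

setValidity("SceneGroundTruth", function(object) {
    msg <- character()
    v <- object@vesicles
    comp <- object@composition
    if (nrow(v)) {
        tab <- table(factor(v$neuron_id, levels = comp$neuron_id),
            factor(v$subtype, levels = .SUBTYPES))
        for (s in .SUBTYPES) {
            if (!all(comp[[s]] == as.integer(tab[, s]))) {
                msg <- c(msg, "per-neuron composition does not match per-vesicle records")
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "MultiChannelField", function(object) {
    d <- dim(object@pixels[[1]])
    cat(sprintf("MultiChannelField: %d x %d px, %d channel(s), %.5f um/px, %d-bit\n",
        d[1], d[2], length(object@pixels), object@pixelSizeUm, object@bitDepth))
    cat("  roles:", paste(sprintf("%s=%d", names(object@channelMap),
        object@channelMap), collapse = ", "), "\n")
})

setMethod("show", "ROILabelMask", function(object) {
    d <- dim(object@labels)
    cat(sprintf("ROILabelMask (%s): %d x %d px, %d region(s)\n",
        object@kind, d[1], d[2], nNeurons(object)))
})

setMethod("show", "ChannelThresholds", function(object) {
    cat("ChannelThresholds:",
        paste(sprintf("%s=%.3f", names(object@values), object@values),
            collapse = ", "),
        sprintf("(from %d perikarya)\n", length(object@roiIds)))
})

setMethod("show", "SceneGroundTruth", function(object) {
    cat(sprintf("SceneGroundTruth: %d vesicle(s) in %d neuron(s), %d IR object(s)\n",
        nrow(object@vesicles), nrow(object@composition), nrow(object@irObjects)))
})

## ---- accessors --------------------------------------------------------------

#' @rdname MultiChannelField-accessors
#' @title Accessors for MultiChannelField and ROILabelMask
#' @param field a [MultiChannelField-class].
#' @param role channel role name, e.g. "RFP_LC3".
#' @return `getChannel` returns the channel intensity matrix for a role;
#'   `fieldDim` the c(rows, cols) pixel dimensions; `pixelSize` the pixel
#'   edge in micrometres; `fullScale` the maximum representable intensity;
#'   `boundRoles` the roles bound in the field's channel map.
#' @export
getChannel <- function(field, role) {
    stopifnot(is(field, "MultiChannelField"))
    if (!role %in% names(field@channelMap))
        stop(sprintf("channel role '%s' is not bound in this field", role))
    field@pixels[[field@channelMap[[role]]]]
}

#' @rdname MultiChannelField-accessors
#' @export
fieldDim <- function(field) dim(field@pixels[[1]])

#' @rdname MultiChannelField-accessors
#' @export
pixelSize <- function(field) field@pixelSizeUm

#' @rdname MultiChannelField-accessors
#' @export
fullScale <- function(field) 2^field@bitDepth - 1

#' @rdname MultiChannelField-accessors
#' @export
boundRoles <- function(field) names(field@channelMap)

#' @rdname MultiChannelField-accessors
#' @param mask an [ROILabelMask-class].
#' @export
labelMatrix <- function(mask) mask@labels

#' @rdname MultiChannelField-accessors
#' @export
neuronIds <- function(mask) {
    ids <- sort(unique(as.integer(mask@labels)))
    ids[ids > 0L]
}

#' @rdname MultiChannelField-accessors
#' @export
nNeurons <- function(mask) length(neuronIds(mask))

#' Check that a field is ready for vesicle classification
#'
#' Classification requires all three of GFP_LC3, RFP_LC3 and CTSD to be
#' bound to channels.
#'
#' @param field a [MultiChannelField-class].
#' @return Invisibly `TRUE`; errors if a required role is missing.
#' @export
checkClassifyRoles <- function(field) {
    missing <- setdiff(.CLASSIFY_ROLES, boundRoles(field))
    if (length(missing))
        stop("missing channel role(s) required for classification: ",
            paste(missing, collapse = ", "))
    invisible(TRUE)
}
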