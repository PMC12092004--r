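#' Load a multichannel field from TIFF
#'
#' Reads a multichannel confocal image (TIFF / OME-TIFF, single z-plane) and
#' binds channels to semantic roles. Both confocal export dialects are
#' accepted: planar (one page per channel) and interleaved (one page with a
#' channel axis); `channelMap` indexes into pages or the channel axis
#' respectively. Intensities are read as native integers, losslessly.
#'
#' @param path TIFF file path.
#' @param channelMap named integer vector mapping roles (see
#'   [channelRoles()]) to channel indices.
#' @param pixelSizeUm micrometres per pixel edge.
#' @param bitDepth acquisition bit depth (default 12).
#' @return A [MultiChannelField-class].
#' @examples
#' \dontrun{
#' f <- loadField("scene.tif",
#'     c(RFP_LC3 = 1L, GFP_LC3 = 2L, CTSD = 3L),
#'     pixelSizeUm = 212.34 / 1024)
#' }
#' @export
loadField <- function(path, channelMap, pixelSizeUm, bitDepth = 12L) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) {
        ## interleaved dialect: h x w x channels
        arr <- pages[[1]]
        pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    } else {
        pages <- lapply(pages, function(p) {
            if (length(dim(p)) == 3L && dim(p)[3] == 1L) p <- p[, , 1]
            p
        })
    }
    if (any(channelMap < 1L | channelMap > length(pages)))
        stop(sprintf("channel index out of range: file has %d channel(s)",
            length(pages)))
    dims <- vapply(pages, dim, integer(2))
    if (any(dims != dims[, 1]))
        stop("shape mismatch between channels")
    pages <- lapply(pages, function(p) {
        storage.mode(p) <- "double"
        p
    })
    MultiChannelField(pages, channelMap, pixelSizeUm = pixelSizeUm,
        bitDepth = bitDepth)
}

#' Write a multichannel field as multi-page 16-bit TIFF
#'
#' Intensities (native integer units, at most 65535) round-trip exactly
#' through [loadField()].
#'
#' @param field a [MultiChannelField-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeField <- function(field, path) {
    stopifnot(is(field, "MultiChannelField"))
    if (any(vapply(field@pixels, max, numeric(1)) > 65535))
        stop("intensities exceed the 16-bit range")
    tiff::writeTIFF(lapply(field@pixels, function(m) m / 65535), path,
        bits.per.sample = 16L)
    invisible(path)
}

#' Load an ROI label mask
#'
#' Reads a single-channel integer label image (16-bit TIFF or PNG);
#' 0 = background, k > 0 = neuron k.
#'
#' @param path image path.
#' @param expectedShape optional `c(rows, cols)` to validate against.
#' @param kind what the labels delineate (see [ROILabelMask()]).
#' @return An [ROILabelMask-class]; the count of distinct non-zero labels is
#'   reported via [nNeurons()].
#' @export
loadROIMask <- function(path, expectedShape = NULL, kind = "PERIKARYON") {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) {
        if (dim(img)[3] != 1L) stop("ROI mask must be single-channel")
        img <- img[, , 1]
    }
    if (!is.null(expectedShape) && !identical(dim(img), as.integer(expectedShape)))
        stop(sprintf("mask shape %s does not match expected %s",
            paste(dim(img), collapse = "x"),
            paste(expectedShape, collapse = "x")))
    if (any(img < 0) || any(img != floor(img)))
        stop("ROI mask must contain non-negative integer labels")
    storage.mode(img) <- "integer"
    ROILabelMask(img, kind = kind)
}

#' Write an ROI label mask as 16-bit TIFF
#'
#' @param mask an [ROILabelMask-class] (labels at most 65535).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeROIMask <- function(mask, path) {
    stopifnot(is(mask, "ROILabelMask"))
    lab <- labelMatrix(mask)
    if (max(lab) > 65535) stop("labels exceed the 16-bit range")
    tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
    invisible(path)
}

#' Write / read a vesicle table
#'
#' CSV with UTF-8 encoding, "." decimal separator, one row per vesicle, and
#' '#'-prefixed metadata header lines (e.g. the effective subtype rules).
#' Numeric columns are written at full double precision so the table
#' round-trips losslessly.
#'
#' @param vesicles vesicle data.frame (typically classified: hue,
#'   saturation and subtype columns present).
#' @param path output CSV path.
#' @param meta optional named list echoed into the metadata header.
#' @return `writeVesicleTable` returns `path` invisibly;
#'   `readVesicleTable` the restored data.frame.
#' @export
writeVesicleTable <- function(vesicles, path, meta = NULL) {
    out <- vesicles
    if (!is.null(out$subtype)) out$subtype <- as.character(out$subtype)
    .writeTableWithMeta(out, path, meta = meta)
    invisible(path)
}

#' @rdname writeVesicleTable
#' @export
readVesicleTable <- function(path) {
    df <- .readTableWithMeta(path)
    if (!is.null(df$subtype))
        df$subtype <- factor(df$subtype, levels = c(.SUBTYPES, "UNCLASSIFIED"))
    df
}
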