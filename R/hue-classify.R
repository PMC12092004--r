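#' Hue angle of a vesicle's mean RGB intensities
#'
#' Converts per-vesicle mean channel intensities (R = mRFP-LC3, G = eGFP-LC3,
#' B = CTSD immunolabel) into a hue angle in degrees. The hue is the angle of
#' the 2-D chromatic vector with components \eqn{(2R - G - B)} and
#' \eqn{\sqrt{3}(G - B)}, measured counter-clockwise from the first-component
#' axis and mapped into \[0, 360) by adding 360 to negative angles. The
#' spreadsheet-style formula this reproduces uses the `ATAN2(x, y)` argument
#' order; the common `atan2(y, x)` convention therefore takes the arguments
#' swapped, which the red/green/blue axis identities (0, 120, 240 degrees)
#' pin down unambiguously.
#'
#' The result is invariant under positive rescaling of (R, G, B), which is
#' why native intensity units can be used directly.
#'
#' @param R,G,B numeric vectors of mean channel intensities (>= 0); recycled
#'   to a common length.
#' @return Numeric vector of hue angles in degrees in \[0, 360); `NA` where
#'   the input is achromatic (R = G = B), for which hue is undefined.
#' @examples
#' computeHueAngle(1, 0, 0)  # 0   (red axis)
#' computeHueAngle(1, 1, 0)  # 60  (yellow, the AP signature)
#' computeHueAngle(0, 0, 1)  # 240 (blue, the LY signature)
#' @export
computeHueAngle <- function(R, G, B) {
    n <- max(length(R), length(G), length(B))
    R <- rep_len(as.numeric(R), n)
    G <- rep_len(as.numeric(G), n)
    B <- rep_len(as.numeric(B), n)
    if (any(is.na(R) | is.na(G) | is.na(B)))
        stop("R, G, B must not contain missing values")
    if (any(R < 0 | G < 0 | B < 0))
        stop("R, G, B intensities must be >= 0")
    x <- 2 * R - G - B
    y <- sqrt(3) * (G - B)
    hue <- 180 / pi * atan2(y, x)
    hue <- ifelse(hue < 0, hue + 360, hue)
    hue[x == 0 & y == 0] <- NA_real_
    hue
}

#' Saturation percentage of a vesicle's mean RGB intensities
#'
#' Saturation is \eqn{(\max - \min) / (\max + \min) \times 100} computed on
#' intensities normalised to \[0, 1\] by the full scale \eqn{2^{bitDepth}-1}.
#' Achromatic input (max + min = 0, or R = G = B) gives 0. The formula is
#' valid provided lightness \eqn{(\max + \min)/2 < 1}; vesicles at full
#' lightness (saturated white pixels) are flagged and assigned saturation 0.
#'
#' @param R,G,B numeric vectors of mean channel intensities in native units
#'   (>= 0); recycled to a common length.
#' @param bitDepth acquisition bit depth used to normalise intensities.
#' @return Numeric vector of saturation percentages in \[0, 100\], with
#'   attributes `lightness` (numeric, (max+min)/2 of normalised values) and
#'   `saturated_white` (logical, lightness >= 1).
#' @examples
#' computeSaturation(4095, 0, 0, bitDepth = 12)       # 100
#' computeSaturation(0.5, 0.5, 0.5, bitDepth = 0)     # 0 (achromatic)
#' @export
computeSaturation <- function(R, G, B, bitDepth = 12L) {
    n <- max(length(R), length(G), length(B))
    R <- rep_len(as.numeric(R), n)
    G <- rep_len(as.numeric(G), n)
    B <- rep_len(as.numeric(B), n)
    if (any(is.na(R) | is.na(G) | is.na(B)))
        stop("R, G, B must not contain missing values")
    if (any(R < 0 | G < 0 | B < 0))
        stop("R, G, B intensities must be >= 0")
    scale <- 2^as.numeric(bitDepth) - 1
    if (scale <= 0) scale <- 1  # bitDepth 0: treat input as already normalised
    rn <- R / scale; gn <- G / scale; bn <- B / scale
    mx <- pmax(rn, gn, bn)
    mn <- pmin(rn, gn, bn)
    sat <- ifelse(mx + mn > 0, (mx - mn) / (mx + mn) * 100, 0)
    lightness <- (mx + mn) / 2
    white <- lightness >= 1
    sat[white] <- 0
    structure(sat, lightness = lightness, saturated_white = white)
}

#' Default subtype classification rules
#'
#' Builds the rule set mapping hue/saturation/channel-presence to the four
#' vesicle subtypes. Rules are evaluated in a fixed priority order:
#' \enumerate{
#'   \item PA_AL ("white"): all three channels above threshold and
#'     saturation below `whiteCutoffPct`;
#'   \item AP ("yellow"): hue in `apHueDeg` and R, G above threshold;
#'   \item AL ("purple"): hue in `alHueDeg` and R, B above threshold;
#'   \item LY ("blue"): hue in `lyHueDeg` and only B above threshold;
#'   \item otherwise UNCLASSIFIED.
#' }
#' Hue intervals are half-open \[min, max). The numeric boundaries are not
#' fixed by the reporter logic itself, only the colors are; the defaults
#' centre on the canonical color axes (yellow 60, blue 240, magenta 300).
#'
#' @param apHueDeg,lyHueDeg,alHueDeg numeric length-2 half-open hue intervals
#'   in degrees for AP, LY and AL.
#' @param whiteCutoffPct saturation percentage below which an all-channel-
#'   positive vesicle counts as white (PA_AL).
#' @param redAsAL if `TRUE`, vesicles that are R-above / B-below threshold
#'   with hue in the red sector (outside `apHueDeg`) are counted as
#'   CTSD-negative AL rather than UNCLASSIFIED.
#' @return A list of class `subtypeRules`; overlapping AP/AL/LY hue ranges
#'   raise an error at construction time.
#' @export
subtypeRules <- function(apHueDeg = c(30, 90), lyHueDeg = c(210, 270),
                         alHueDeg = c(270, 330), whiteCutoffPct = 25,
                         redAsAL = FALSE) {
    ranges <- list(AP = apHueDeg, LY = lyHueDeg, AL = alHueDeg)
    for (nm in names(ranges)) {
        r <- ranges[[nm]]
        if (length(r) != 2L || r[1] < 0 || r[2] > 360 || r[1] >= r[2])
            stop(sprintf("hue range for %s must be an interval within [0, 360)", nm))
    }
    nms <- names(ranges)
    for (i in seq_along(ranges)) for (j in seq_along(ranges)) {
        if (i >= j) next
        a <- ranges[[i]]; b <- ranges[[j]]
        if (a[1] < b[2] && b[1] < a[2])
            stop(sprintf("hue ranges for %s and %s overlap", nms[i], nms[j]))
    }
    if (whiteCutoffPct <= 0 || whiteCutoffPct > 100)
        stop("whiteCutoffPct must be in (0, 100]")
    structure(list(apHueDeg = apHueDeg, lyHueDeg = lyHueDeg,
        alHueDeg = alHueDeg, whiteCutoffPct = whiteCutoffPct,
        redAsAL = isTRUE(redAsAL)), class = "subtypeRules")
}

.inHue <- function(hue, range) !is.na(hue) & hue >= range[1] & hue < range[2]

#' Classify vesicles into AV/LY subtypes
#'
#' Computes hue angle, saturation and lightness from each vesicle's mean
#' channel intensities and assigns a subtype by the priority rules in
#' [subtypeRules()]. Channel presence is judged against the perikaryon-
#' derived thresholds (strictly greater than). Classification is invariant
#' under positive rescaling of intensities that leaves the presence flags
#' unchanged.
#'
#' @param vesicles data.frame with columns `mean_R`, `mean_G`, `mean_B`
#'   (mean mRFP-LC3, eGFP-LC3 and CTSD intensities), e.g. from
#'   [extractVesicles()].
#' @param thresholds a [ChannelThresholds-class] object.
#' @param rules a rule set from [subtypeRules()].
#' @param bitDepth bit depth for the saturation lightness guard.
#' @return The input data.frame with columns `hue_deg`, `saturation_pct`,
#'   `lightness` and `subtype` (factor with levels AP, AL, PA_AL, LY,
#'   UNCLASSIFIED) added.
#' @export
classifyVesicles <- function(vesicles, thresholds, rules = subtypeRules(),
                             bitDepth = 12L) {
    stopifnot(is(thresholds, "ChannelThresholds"))
    if (!inherits(rules, "subtypeRules"))
        stop("rules must be created by subtypeRules()")
    R <- vesicles$mean_R; G <- vesicles$mean_G; B <- vesicles$mean_B
    if (is.null(R) || is.null(G) || is.null(B))
        stop("vesicles must carry mean_R, mean_G, mean_B columns")
    thr <- thresholds@values
    hue <- computeHueAngle(R, G, B)
    sat <- computeSaturation(R, G, B, bitDepth = bitDepth)
    aboveR <- R > thr[["RFP_LC3"]]
    aboveG <- G > thr[["GFP_LC3"]]
    aboveB <- B > thr[["CTSD"]]

    subtype <- rep("UNCLASSIFIED", length(R))
    isLY <- aboveB & !aboveR & !aboveG & .inHue(hue, rules$lyHueDeg)
    subtype[isLY] <- "LY"
    isAL <- aboveR & aboveB & .inHue(hue, rules$alHueDeg)
    subtype[isAL] <- "AL"
    if (rules$redAsAL) {
        redOnly <- aboveR & !aboveB & !.inHue(hue, rules$apHueDeg) &
            !is.na(hue) & (hue < rules$apHueDeg[1] | hue >= 330)
        subtype[redOnly & subtype == "UNCLASSIFIED"] <- "AL"
    }
    isAP <- aboveR & aboveG & .inHue(hue, rules$apHueDeg)
    subtype[isAP] <- "AP"
    isWhite <- aboveR & aboveG & aboveB & as.numeric(sat) < rules$whiteCutoffPct
    subtype[isWhite] <- "PA_AL"

    vesicles$hue_deg <- hue
    vesicles$saturation_pct <- as.numeric(sat)
    vesicles$lightness <- attr(sat, "lightness")
    vesicles$subtype <- factor(subtype, levels = c(.SUBTYPES, "UNCLASSIFIED"))
    vesicles
}

#' Per-neuron vesicle subtype profiles
#'
#' Aggregates classified, neuron-assigned vesicles into one profile per
#' neuron: counts of AP, AL, PA_AL, LY and UNCLASSIFIED vesicles, the total,
#' and the mean vesicle area per subtype. Data are reported per neuron
#' ("Vesicle #/Neuron"); vesicles with `neuron_id` 0 (background majority)
#' are excluded. Neurons with no vesicles still get an all-zero profile, so
#' pass the full id universe via `neuronIds`.
#'
#' @param vesicles classified vesicle data.frame with `neuron_id` and
#'   `subtype` columns (and optionally `area_um2`).
#' @param neuronIds integer vector of all neuron ids to profile; defaults to
#'   the ids present among the vesicles.
#' @return data.frame with one row per neuron: `neuron_id`, subtype counts,
#'   `UNCLASSIFIED`, `total`, and `mean_area_<subtype>` columns (NA where a
#'   neuron has no vesicle of that subtype). Counts sum to `total`.
#' @export
profileNeurons <- function(vesicles, neuronIds = NULL) {
    if (is.null(vesicles$subtype) || is.null(vesicles$neuron_id))
        stop("vesicles must be classified and assigned to neurons first")
    if (is.null(neuronIds))
        neuronIds <- sort(unique(vesicles$neuron_id[vesicles$neuron_id > 0]))
    neuronIds <- sort(unique(as.integer(neuronIds)))
    v <- vesicles[vesicles$neuron_id > 0 & vesicles$neuron_id %in% neuronIds, ,
        drop = FALSE]
    lv <- c(.SUBTYPES, "UNCLASSIFIED")
    tab <- table(factor(v$neuron_id, levels = neuronIds),
        factor(v$subtype, levels = lv))
    out <- data.frame(neuron_id = neuronIds)
    for (s in lv) out[[s]] <- as.integer(tab[, s])
    out$total <- as.integer(rowSums(tab))
    hasArea <- !is.null(v$area_um2)
    for (s in .SUBTYPES) {
        col <- rep(NA_real_, length(neuronIds))
        if (hasArea && nrow(v)) {
            sel <- v[v$subtype == s, , drop = FALSE]
            if (nrow(sel)) {
                m <- tapply(sel$area_um2, factor(sel$neuron_id, levels = neuronIds),
                    mean)
                col <- as.numeric(m)
            }
        }
        out[[paste0("mean_area_", s)]] <- col
    }
    out
}
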