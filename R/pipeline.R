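#' Process one field through segmentation and classification
#'
#' Runs the per-field sequence: perikaryon thresholds, puncta masks,
#' watershed, size exclusion, vesicle extraction, neuron assignment, hue
#' classification and per-neuron profiling.
#'
#' @param field a [MultiChannelField-class].
#' @param neuronMask an [ROILabelMask-class].
#' @param rules subtype rules from [subtypeRules()].
#' @param nSample,thresholdSeed,minAreaPx,maxAreaPx,tolerance,ext,smoothSigma
#'   segmentation parameters, see [segmentField()].
#' @return list with `segmentation` (see [segmentField()]), `vesicles`
#'   (classified, neuron-assigned) and `profiles` (one row per neuron in
#'   the mask).
#' @export
processField <- function(field, neuronMask, rules = subtypeRules(),
                         nSample = 20L, thresholdSeed = NULL, minAreaPx = 3L,
                         maxAreaPx = Inf, tolerance = 80, ext = 2L,
                         smoothSigma = 1) {
    seg <- segmentField(field, neuronMask, nSample = nSample,
        thresholdSeed = thresholdSeed, minAreaPx = minAreaPx,
        maxAreaPx = maxAreaPx, tolerance = tolerance, ext = ext,
        smoothSigma = smoothSigma)
    ves <- classifyVesicles(seg$vesicles, seg$thresholds, rules = rules,
        bitDepth = field@bitDepth)
    prof <- profileNeurons(ves, neuronIds = neuronIds(neuronMask))
    list(segmentation = seg, vesicles = ves, profiles = prof)
}

#' Simulate a multi-group imaging experiment
#'
#' Generates synthetic fields for each experimental group (each group may
#' shift the per-neuron subtype means, emulating a disease or treatment
#' effect), runs every field through the full analysis pipeline, and pools
#' the per-neuron profiles. The unit of analysis is the neuron.
#'
#' @param groups named list; each element is a list with `nFields` and
#'   either a full [SceneConfig-class] under `scene` or a named numeric
#'   `means` (per-neuron subtype means, AP/AL/PA_AL/LY) applied to a base
#'   config.
#' @param baseConfig the [SceneConfig-class] used as template (its
#'   `countMode` is forced to "poisson" so neurons vary).
#' @param seed master seed; per-field seeds are derived deterministically.
#' @param rules subtype rules.
#' @param ... further arguments passed to [processField()].
#' @return data.frame of per-neuron profiles with `group` and `field`
#'   columns prepended.
#' @export
simulateExperiment <- function(groups, baseConfig = SceneConfig(),
                               seed = 1L, rules = subtypeRules(), ...) {
    out <- list()
    gi <- 0L
    for (gname in names(groups)) {
        gi <- gi + 1L
        g <- groups[[gname]]
        for (fi in seq_len(g$nFields)) {
            cfg <- if (!is.null(g$scene)) g$scene else baseConfig
            if (!is.null(g$means))
                cfg@vesiclesPerNeuron <- g$means[.SUBTYPES]
            cfg@countMode <- "poisson"
            cfg@seed <- as.integer((seed * 131L + gi * 17L + fi) %% .Machine$integer.max)
            scene <- generateScene(cfg)
            res <- processField(scene$field, scene$mask, rules = rules,
                thresholdSeed = cfg@seed, ...)
            prof <- res$profiles
            prof <- cbind(group = gname, field = fi, prof)
            out[[length(out) + 1L]] <- prof
        }
    }
    do.call(rbind, out)
}

.defaultMetrics <- c("AP", "AL", "PA_AL", "LY")

#' Group statistics on per-neuron subtype counts
#'
#' For two groups: unpaired two-tailed t-tests per vesicle subtype. For
#' three or more: one-way ANOVA per subtype followed by Sidak-adjusted
#' selected comparisons.
#'
#' @param profiles pooled per-neuron profiles with a `group` column (from
#'   [simulateExperiment()] or assembled manually).
#' @param metrics profile columns to test (default the four subtypes).
#' @param comparisons list of group pairs for the Sidak family (>= 3
#'   groups); `NULL` = all pairs.
#' @param welch use Welch's t for the two-group case.
#' @return data.frame of test results, one row per metric (two groups) or
#'   per metric x comparison (ANOVA path), with a `metric` column.
#' @export
groupStatistics <- function(profiles, metrics = .defaultMetrics,
                            comparisons = NULL, welch = FALSE) {
    groups <- unique(as.character(profiles$group))
    if (length(groups) < 2L) stop("need at least two groups")
    rows <- list()
    for (m in metrics) {
        vals <- profiles[[m]]
        if (is.null(vals)) stop(sprintf("profiles have no column '%s'", m))
        if (length(groups) == 2L) {
            r <- unpairedTTest(vals[profiles$group == groups[1]],
                vals[profiles$group == groups[2]], labels = groups,
                welch = welch)
            rows[[length(rows) + 1L]] <- cbind(metric = m, r)
        } else {
            r <- anovaSidak(vals, profiles$group, comparisons = comparisons)
            if (nrow(r$comparisons))
                rows[[length(rows) + 1L]] <- cbind(metric = m,
                    F = r$anova$F, anova_p = r$anova$p, r$comparisons)
        }
    }
    do.call(rbind, rows)
}

.pipelineRules <- function(cfgRules) {
    if (is.null(cfgRules)) return(subtypeRules())
    do.call(subtypeRules, cfgRules[intersect(names(cfgRules),
        names(formals(subtypeRules)))])
}

#' Run the full analysis pipeline from a JSON configuration
#'
#' Orchestrates the whole analysis either on synthetic scenes (`groups`
#' entries describing simulated experimental groups) or on real image
#' inputs (`fields` entries with image/mask paths and a channel map), and
#' writes the result tables plus a provenance record to `outDir`. Runs are
#' deterministic given the configured seed; re-running with the same
#' configuration produces byte-identical tables.
#'
#' Configuration keys (JSON object or equivalent R list):
#' \describe{
#'   \item{seed}{master seed (default 1).}
#'   \item{groups}{synthetic mode: named object of group specs, each with
#'     `n_fields` and optional `scene` overrides (any [SceneConfig()]
#'     argument) and `means` (per-neuron subtype means).}
#'   \item{fields}{image mode: array of objects with `image`, `mask`,
#'     `channel_map` (role -> 1-based index), `pixel_size_um`, `bit_depth`,
#'     `group`.}
#'   \item{segmentation}{`n_sample`, `min_area_px`, `max_area_px`,
#'     `tolerance`, `ext`, `smooth_sigma`.}
#'   \item{rules}{arguments of [subtypeRules()].}
#'   \item{comparisons}{array of group pairs for Sidak-adjusted selected
#'     comparisons (3+ groups).}
#' }
#'
#' @param config a named list, or path to a JSON file with the keys above.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with `vesicles`, `profiles`, `summary`,
#'   `stats` and `provenance`; the same objects are written as
#'   `vesicles.csv`, `neuron_profiles.csv`, `group_summary.csv`,
#'   `group_stats.csv` and `provenance.json` under `outDir`.
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
        config <- jsonlite::fromJSON(config, simplifyVector = TRUE,
            simplifyDataFrame = FALSE)
    }
    if (!is.list(config)) stop("config must be a list or a JSON file path")
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    segp <- config$segmentation
    segArgs <- list(
        nSample = if (is.null(segp$n_sample)) 20L else as.integer(segp$n_sample),
        minAreaPx = if (is.null(segp$min_area_px)) 3L else as.integer(segp$min_area_px),
        maxAreaPx = if (is.null(segp$max_area_px)) Inf else segp$max_area_px,
        tolerance = if (is.null(segp$tolerance)) 80 else segp$tolerance,
        ext = if (is.null(segp$ext)) 2L else as.integer(segp$ext),
        smoothSigma = if (is.null(segp$smooth_sigma)) 1 else segp$smooth_sigma)
    rules <- .pipelineRules(config$rules)

    allVes <- list(); allProf <- list()
    if (!is.null(config$groups)) {
        gi <- 0L
        for (gname in names(config$groups)) {
            gi <- gi + 1L
            g <- config$groups[[gname]]
            nFields <- if (is.null(g$n_fields)) 1L else as.integer(g$n_fields)
            sceneArgs <- if (is.null(g$scene)) list() else g$scene
            for (fi in seq_len(nFields)) {
                cfg <- do.call(SceneConfig, sceneArgs)
                if (!is.null(g$means)) {
                    mn <- unlist(g$means)
                    cfg@vesiclesPerNeuron <- mn[.SUBTYPES]
                    cfg@countMode <- "poisson"
                }
                cfg@seed <- as.integer((seed * 131L + gi * 17L + fi) %%
                    .Machine$integer.max)
                scene <- generateScene(cfg)
                res <- do.call(processField, c(list(scene$field, scene$mask,
                    rules = rules, thresholdSeed = cfg@seed), segArgs))
                v <- res$vesicles; v$group <- gname; v$field <- fi
                p <- res$profiles; p <- cbind(group = gname, field = fi, p)
                allVes[[length(allVes) + 1L]] <- v
                allProf[[length(allProf) + 1L]] <- p
            }
        }
    } else if (!is.null(config$fields)) {
        for (fi in seq_along(config$fields)) {
            fspec <- config$fields[[fi]]
            cm <- unlist(fspec$channel_map)
            missing <- setdiff(.CLASSIFY_ROLES, names(cm))
            if (length(missing))
                stop("field config is missing channel role(s): ",
                    paste(missing, collapse = ", "))
            bd <- if (is.null(fspec$bit_depth)) 12L else as.integer(fspec$bit_depth)
            field <- loadField(fspec$image, cm, fspec$pixel_size_um, bitDepth = bd)
            mask <- loadROIMask(fspec$mask, expectedShape = fieldDim(field))
            res <- do.call(processField, c(list(field, mask, rules = rules,
                thresholdSeed = seed + fi), segArgs))
            gname <- if (is.null(fspec$group)) "all" else fspec$group
            v <- res$vesicles; v$group <- gname; v$field <- fi
            p <- res$profiles; p <- cbind(group = gname, field = fi, p)
            allVes[[length(allVes) + 1L]] <- v
            allProf[[length(allProf) + 1L]] <- p
        }
    } else stop("config must contain either 'groups' (synthetic mode) or 'fields'")

    vesicles <- do.call(rbind, allVes)
    profiles <- do.call(rbind, allProf)
    groups <- unique(as.character(profiles$group))
    statsTab <- if (length(groups) >= 2L)
        groupStatistics(profiles, comparisons = config$comparisons)
        else data.frame()
    summaryTabs <- lapply(.defaultMetrics, function(m)
        cbind(metric = m, summarizeGroups(profiles[[m]], profiles$group)))
    summaryTab <- do.call(rbind, summaryTabs)

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ruleMeta <- list(subtype_rules = unclass(rules), seed = seed,
        segmentation = segArgs[c("nSample", "minAreaPx", "tolerance", "ext",
            "smoothSigma")])
    writeVesicleTable(vesicles, file.path(outDir, "vesicles.csv"),
        meta = ruleMeta)
    .writeTableWithMeta(profiles, file.path(outDir, "neuron_profiles.csv"),
        meta = ruleMeta)
    .writeTableWithMeta(summaryTab, file.path(outDir, "group_summary.csv"))
    if (nrow(statsTab))
        .writeTableWithMeta(statsTab, file.path(outDir, "group_stats.csv"))
    provenance <- list(
        package = "tfLC3quant",
        version = as.character(utils::packageVersion("tfLC3quant")),
        seed = seed,
        effective_rules = unclass(rules),
        segmentation = segArgs[c("nSample", "minAreaPx", "tolerance", "ext",
            "smoothSigma")],
        config = config
    )
    jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
    invisible(list(vesicles = vesicles, profiles = profiles,
        summary = summaryTab, stats = statsTab, provenance = provenance))
}
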