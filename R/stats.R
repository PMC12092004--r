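#' Unpaired two-tailed t-test
#'
#' Student's pooled-variance two-sample t-test (two-sided), the test used to
#' compare two groups of per-neuron measurements. Welch's unequal-variance
#' form is available by flag. When both groups have zero variance and equal
#' means the statistic is 0 and p = 1 by convention, flagged in the output.
#'
#' @param a,b numeric vectors of measurements, length >= 2 each.
#' @param labels length-2 character vector of group labels.
#' @param welch use Welch's unequal-variance t instead of the pooled form.
#' @return One-row data.frame: `comparison`, `mean_a`, `mean_b`,
#'   `statistic`, `df`, `p_raw`, `p_adjusted` (equal to `p_raw`),
#'   `adjustment` ("NONE"), `stars`, `degenerate` (zero-variance flag).
#' @examples
#' unpairedTTest(c(1, 2, 3), c(4, 5, 6))  # |t| = 3.674, df = 4
#' @export
unpairedTTest <- function(a, b, labels = c("A", "B"), welch = FALSE) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 observations")
    n1 <- length(a); n2 <- length(b)
    m1 <- mean(a); m2 <- mean(b)
    v1 <- stats::var(a); v2 <- stats::var(b)
    degenerate <- FALSE
    if (v1 == 0 && v2 == 0) {
        degenerate <- TRUE
        if (m1 == m2) {
            tt <- 0; df <- n1 + n2 - 2; p <- 1
        } else {
            tt <- sign(m1 - m2) * Inf; df <- n1 + n2 - 2; p <- 0
        }
    } else if (welch) {
        se2 <- v1 / n1 + v2 / n2
        tt <- (m1 - m2) / sqrt(se2)
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
        p <- 2 * stats::pt(-abs(tt), df)
    } else {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- n1 + n2 - 2
        p <- 2 * stats::pt(-abs(tt), df)
    }
    data.frame(comparison = paste(labels, collapse = " vs "),
        mean_a = m1, mean_b = m2, statistic = tt, df = df, p_raw = p,
        p_adjusted = p, adjustment = "NONE", stars = .stars(p),
        degenerate = degenerate)
}

#' Sidak multiple-comparison adjustment
#'
#' @param p raw p-values.
#' @param m number of comparisons in the family (recycled against `p`).
#' @return Adjusted p-values \eqn{1 - (1 - p)^m}, monotone in both `p` and
#'   `m`; with `m = 1` the p-value is unchanged.
#' @examples
#' sidakAdjust(0.01, 3)  # 0.029701
#' @export
sidakAdjust <- function(p, m) {
    if (any(m < 1L)) stop("m must be >= 1")
    pmin(1, 1 - (1 - p)^m)
}

#' One-way ANOVA with Sidak-adjusted selected comparisons
#'
#' Fits a one-way ANOVA across all groups, then tests the requested pairs
#' using the pooled within-group error (mean square error with N - k
#' degrees of freedom) and adjusts their p-values by the Sidak formula over
#' the m requested comparisons — the "selected comparisons" convention, with
#' m recorded in the output.
#'
#' @param values numeric vector of measurements.
#' @param groups group labels, same length as `values`.
#' @param comparisons list of length-2 character vectors naming the pairs
#'   to compare; `NULL` (default) compares all pairs; an empty list returns
#'   the ANOVA only.
#' @return list with `anova` (one-row data.frame: `F`, `df1`, `df2`, `p`)
#'   and `comparisons` (data.frame of pairwise results with columns as in
#'   [unpairedTTest()] plus `m`; `adjustment` is "SIDAK").
#' @export
anovaSidak <- function(values, groups, comparisons = NULL) {
    groups <- as.character(groups)
    if (length(values) != length(groups))
        stop("values and groups must have equal length")
    lev <- unique(groups)
    if (length(lev) < 2L) stop("need at least 2 groups")
    ns <- table(factor(groups, levels = lev))
    if (any(ns < 2L)) stop("each group needs at least 2 observations")
    fit <- stats::aov(values ~ g, data = data.frame(values = values,
        g = factor(groups, levels = lev)))
    tab <- summary(fit)[[1]]
    an <- data.frame(F = tab[1, "F value"], df1 = tab[1, "Df"],
        df2 = tab[2, "Df"], p = tab[1, "Pr(>F)"])
    mse <- tab[2, "Mean Sq"]
    dfe <- tab[2, "Df"]
    if (is.null(comparisons))
        comparisons <- utils::combn(lev, 2, simplify = FALSE)
    m <- length(comparisons)
    if (m == 0L)
        return(list(anova = an, comparisons = data.frame()))
    means <- tapply(values, factor(groups, levels = lev), mean)
    rows <- lapply(comparisons, function(pr) {
        if (!all(pr %in% lev))
            stop(sprintf("unknown group in comparison: %s",
                paste(pr, collapse = " vs ")))
        n1 <- ns[[pr[1]]]; n2 <- ns[[pr[2]]]
        diff <- means[[pr[1]]] - means[[pr[2]]]
        se <- sqrt(mse * (1 / n1 + 1 / n2))
        tt <- if (se > 0) diff / se else if (diff == 0) 0 else sign(diff) * Inf
        p <- 2 * stats::pt(-abs(tt), dfe)
        data.frame(comparison = paste(pr, collapse = " vs "),
            mean_a = means[[pr[1]]], mean_b = means[[pr[2]]],
            statistic = tt, df = dfe, p_raw = p,
            p_adjusted = sidakAdjust(p, m), adjustment = "SIDAK",
            m = m, stars = NA_character_, degenerate = se == 0)
    })
    cmp <- do.call(rbind, rows)
    cmp$stars <- .stars(cmp$p_adjusted)
    list(anova = an, comparisons = cmp)
}

#' Group summaries (mean +/- SEM)
#'
#' @param values numeric vector of measurements.
#' @param groups group labels, same length as `values`.
#' @return data.frame per group: `group`, `n`, `mean`, `sd`, `sem`
#'   (sd / sqrt(n); `NA` for single-observation groups, 0 for constant
#'   groups).
#' @examples
#' summarizeGroups(c(2, 4, 6), rep("A", 3))  # mean 4, SEM 1.1547
#' @export
summarizeGroups <- function(values, groups) {
    groups <- as.character(groups)
    if (length(values) != length(groups))
        stop("values and groups must have equal length")
    lev <- unique(groups)
    f <- factor(groups, levels = lev)
    n <- as.integer(table(f))
    data.frame(
        group = lev,
        n = n,
        mean = as.numeric(tapply(values, f, mean)),
        sd = as.numeric(tapply(values, f, stats::sd)),
        sem = as.numeric(tapply(values, f, stats::sd)) / sqrt(n)
    )
}
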