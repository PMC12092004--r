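## Internal helpers shared across modules.

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

## 8-connected component labeling. EBImage::bwlabel is 4-connected, so merge
## labels that touch diagonally with a union-find pass over label adjacency.
.label8 <- function(mask) {
    lab <- EBImage::bwlabel(mask != 0)
    lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
    n <- max(lab)
    if (n < 2L) return(lab)
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                          cbind(a2[keep2], b2[keep2])))
    if (nrow(pairs) == 0L) return(lab)
    parent <- seq_len(n)
    findRoot <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    for (k in seq_len(nrow(pairs))) {
        ra <- findRoot(pairs[k, 1]); rb <- findRoot(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), findRoot, integer(1))
    relab <- match(root, sort(unique(root)))
    out <- lab
    out[out > 0L] <- relab[out[out > 0L]]
    out
}

## Renumber positive labels to 1..k preserving order; 0 stays background.
.relabel <- function(lab) {
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) == 0L) return(lab)
    out <- lab
    out[out > 0L] <- match(out[out > 0L], ids)
    out
}

## Per-label pixel statistics computed without looping over labels.
## Returns a data.frame ordered by label id.
.labelStats <- function(lab, channels) {
    idx <- which(lab > 0L)
    if (length(idx) == 0L) {
        out <- data.frame(label = integer(), area_px = integer(),
            centroid_row = numeric(), centroid_col = numeric())
        for (nm in names(channels)) out[[nm]] <- numeric()
        return(out)
    }
    ids <- lab[idx]
    f <- factor(ids)
    area <- as.integer(tabulate(f))
    rows <- ((idx - 1L) %% nrow(lab)) + 1L
    cols <- ((idx - 1L) %/% nrow(lab)) + 1L
    out <- data.frame(
        label = as.integer(levels(f)),
        area_px = area,
        centroid_row = as.numeric(rowsum(as.numeric(rows), f)) / area,
        centroid_col = as.numeric(rowsum(as.numeric(cols), f)) / area
    )
    for (nm in names(channels))
        out[[nm]] <- as.numeric(rowsum(as.numeric(channels[[nm]][idx]), f)) / area
    out
}

## Majority (plurality) region assignment: for each positive label in `lab`,
## the region label of `regions` owning the most of its pixels. Ties between
## two neurons go to the lower neuron id; a tie between background and a
## neuron goes to the neuron.
.majorityRegion <- function(lab, regions) {
    idx <- which(lab > 0L)
    if (length(idx) == 0L)
        return(data.frame(label = integer(), region = integer()))
    tab <- table(label = lab[idx], region = regions[idx])
    regIds <- as.integer(colnames(tab))
    pick <- apply(tab, 1L, function(cnt) {
        best <- which(cnt == max(cnt))
        cand <- regIds[best]
        if (length(cand) > 1L && any(cand > 0L)) cand <- cand[cand > 0L]
        min(cand)
    })
    data.frame(label = as.integer(rownames(tab)), region = as.integer(pick))
}

## Significance stars following the figure-legend convention.
.stars <- function(p) {
    vapply(p, function(x) {
        if (is.na(x)) return(NA_character_)
        if (x < 1e-4) "****"
        else if (x < 1e-3) "***"
        else if (x < 0.01) "**"
        else if (x < 0.05) "*"
        else "ns"
    }, character(1))
}

## Write a data.frame as CSV with '#'-prefixed metadata header lines,
## formatting numerics at full double precision so tables round-trip.
.writeTableWithMeta <- function(df, path, meta = NULL) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(meta)) {
        for (nm in names(meta))
            writeLines(sprintf("# %s: %s", nm,
                jsonlite::toJSON(meta[[nm]], auto_unbox = TRUE, digits = NA)), con)
    }
    fmt <- df
    for (nm in names(fmt)) {
        if (is.double(fmt[[nm]]))
            fmt[[nm]] <- vapply(fmt[[nm]], function(x)
                if (is.na(x)) "" else format(x, digits = 17), character(1))
    }
    utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE)
}

.readTableWithMeta <- function(path, colClasses = NA) {
    utils::read.csv(path, comment.char = "#", colClasses = colClasses,
        stringsAsFactors = FALSE)
}
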