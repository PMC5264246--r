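#' Abundance-weighted mean niche per feature
#'
#' Estimates each feature's position on an environmental gradient (e.g. pH)
#' as the abundance-weighted mean of the sample gradient values:
#' `niche_x = sum_i g_i * x_i / sum_i x_i`, with the sums over samples `i`.
#' By default abundances are first closed to per-sample proportions (so
#' deeply sequenced samples do not dominate); set `proportions = FALSE` to
#' weight by raw counts.
#'
#' @param table a non-negative [CompositionTable-class].
#' @param gradient numeric gradient values, either named by sample id or in
#'   the table's sample order; must be finite for every sample.
#' @param proportions close each sample to proportions before weighting
#'   (default `TRUE`).
#' @param zeroTotal what to do with features never observed: `"error"`
#'   (default) or `"drop"`.
#' @return Named numeric vector of mean niche values, one per feature,
#'   bounded by the observed gradient range.
#' @examples
#' tab <- CompositionTable(matrix(c(1, 3, 2, 2), 2, byrow = TRUE,
#'   dimnames = list(c("s1", "s2"), c("A", "B"))))
#' meanNicheEstimator(tab, c(s1 = 4, s2 = 8))
#' @export
meanNicheEstimator <- function(table, gradient, proportions = TRUE,
                               zeroTotal = c("error", "drop")) {
    zeroTotal <- match.arg(zeroTotal)
    if (!is(table, "CompositionTable")) table <- CompositionTable(table)
    g <- .alignGradient(gradient, sampleIds(table))
    m <- table@values
    if (proportions) m <- .closureMatrix(m)
    tot <- colSums(m)
    zero <- tot <= 0
    if (any(zero)) {
        if (zeroTotal == "error")
            btDataError("feature(s) with zero total abundance: %s (use zeroTotal = 'drop' or filterFeatures())",
                        .fmtIds(colnames(m)[zero]))
        m <- m[, !zero, drop = FALSE]
        tot <- tot[!zero]
    }
    drop(crossprod(m, g)) / tot
}

.alignGradient <- function(gradient, ids) {
    if (!is.null(names(gradient))) {
        miss <- setdiff(ids, names(gradient))
        if (length(miss))
            btDataError("gradient value missing for sample(s): %s",
                        .fmtIds(miss))
        gradient <- gradient[ids]
    } else if (length(gradient) != length(ids)) {
        btDataError("gradient length %d does not match %d samples",
                    length(gradient), length(ids))
    }
    if (any(!is.finite(gradient)))
        btDataError("non-finite gradient value for sample(s): %s",
                    .fmtIds(ids[!is.finite(gradient)]))
    as.numeric(gradient)
}

#' Sort a table along the gradient
#'
#' Reorders samples (rows) by ascending gradient value and features
#' (columns) by ascending mean niche, leaving the values untouched.  On
#' niche-structured data the nonzero mass of the sorted matrix concentrates
#' in a diagonal band.
#'
#' @inheritParams meanNicheEstimator
#' @return The reordered [CompositionTable-class].
#' @export
nicheSort <- function(table, gradient, proportions = TRUE) {
    if (!is(table, "CompositionTable")) table <- CompositionTable(table)
    g <- .alignGradient(gradient, sampleIds(table))
    niche <- meanNicheEstimator(table, g, proportions = proportions)
    ro <- order(g)
    co <- order(niche)
    CompositionTable(table@values[ro, co, drop = FALSE])
}

#' Filter features by total read count
#'
#' Keeps features whose total count across the whole study is strictly
#' greater than `minTotalReads`; the sample set is unchanged.  The case
#' studies use thresholds of 100 (soils) and 500 (CF sputum) reads.
#'
#' @param table a count [CompositionTable-class].
#' @param minTotalReads non-negative threshold; a feature is retained iff
#'   `sum(counts) > minTotalReads`.
#' @return The filtered [CompositionTable-class].
#' @export
filterFeatures <- function(table, minTotalReads) {
    if (!is(table, "CompositionTable")) table <- CompositionTable(table)
    if (!is.numeric(minTotalReads) || length(minTotalReads) != 1 ||
        is.na(minTotalReads) || minTotalReads < 0)
        btConfigError("minTotalReads must be a single non-negative number")
    keep <- colSums(table@values) > minTotalReads
    CompositionTable(table@values[, keep, drop = FALSE])
}
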