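#' Accessors for the core containers
#'
#' `sampleIds()` and `featureIds()` return the row/column identifiers of a
#' [CompositionTable-class]; `nodeNames()` returns the internal-node names of
#' a [BalanceTable-class] or [OrthonormalBasis-class]; `tableValues()` and
#' `basisMatrix()` return the underlying numeric matrices.
#'
#' @param x a container object.
#' @return Character vectors of identifiers, or a numeric matrix.
#' @name accessors
NULL

#' @rdname accessors
setMethod("sampleIds", "CompositionTable", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIds", "BalanceTable", function(x) rownames(x@values))
#' @rdname accessors
setMethod("featureIds", "CompositionTable", function(x) colnames(x@values))
#' @rdname accessors
setMethod("featureIds", "OrthonormalBasis", function(x) colnames(x@matrix))
#' @rdname accessors
setMethod("nodeNames", "BalanceTable", function(x) colnames(x@values))
#' @rdname accessors
setMethod("nodeNames", "OrthonormalBasis", function(x) rownames(x@matrix))
#' @rdname accessors
setMethod("tableValues", "CompositionTable", function(x) x@values)
#' @rdname accessors
setMethod("tableValues", "BalanceTable", function(x) x@values)
#' @rdname accessors
setMethod("basisMatrix", "OrthonormalBasis", function(x) x@matrix)

setMethod("dim", "CompositionTable", function(x) dim(x@values))
setMethod("dim", "BalanceTable", function(x) dim(x@values))

setMethod("[", "CompositionTable", function(x, i, j, ..., drop = FALSE) {
    CompositionTable(x@values[i, j, drop = FALSE])
})

setMethod("show", "CompositionTable", function(object) {
    d <- dim(object@values)
    cat(sprintf("CompositionTable: %d samples x %d features\n", d[1], d[2]))
    rs <- rowSums(object@values)
    kind <- if (max(abs(rs - 1)) < 1e-6) "proportions (closed)" else "counts/raw"
    cat(sprintf("  values: %s; total = %g\n", kind, sum(object@values)))
    cat("  samples: ", .abbrev(rownames(object@values)), "\n", sep = "")
    cat("  features: ", .abbrev(colnames(object@values)), "\n", sep = "")
})

setMethod("show", "BalanceTable", function(object) {
    d <- dim(object@values)
    cat(sprintf("BalanceTable: %d samples x %d balances\n", d[1], d[2]))
    cat("  nodes: ", .abbrev(colnames(object@values)), "\n", sep = "")
})

setMethod("show", "OrthonormalBasis", function(object) {
    d <- dim(object@matrix)
    cat(sprintf("OrthonormalBasis: %d internal nodes x %d features\n",
                d[1], d[2]))
    cat("  nodes: ", .abbrev(rownames(object@matrix)), "\n", sep = "")
})

setMethod("show", "RegressionResult", function(object) {
    cat(sprintf("RegressionResult (%s): %s\n", object@model, object@formula))
    if (!is.na(object@grouping))
        cat(sprintf("  random intercept per '%s'\n", object@grouping))
    if (!is.na(object@r2))
        cat(sprintf("  global R2 (balance space): %.4f\n", object@r2))
    cf <- object@coefficients
    nsig <- sum(cf$significant & cf$term != "(Intercept)", na.rm = TRUE)
    cat(sprintf("  %d nodes x %d terms; %d significant non-intercept rows at alpha = %g (Bonferroni)\n",
                length(unique(cf$node)), length(unique(cf$term)), nsig,
                object@alpha))
})

#' Accessors for RegressionResult
#'
#' `coefTable()` returns the per-(node, term) coefficient data.frame,
#' `globalR2()` the balance-space coefficient of determination (NA for mixed
#' models), and `fittedBalances()` / `residualBalances()` the fitted and
#' residual [BalanceTable-class] objects.
#'
#' @param x a [RegressionResult-class].
#' @name regression-accessors
NULL

#' @rdname regression-accessors
setMethod("coefTable", "RegressionResult", function(x) x@coefficients)
#' @rdname regression-accessors
setMethod("globalR2", "RegressionResult", function(x) x@r2)
#' @rdname regression-accessors
setMethod("fittedBalances", "RegressionResult", function(x) x@fitted)
#' @rdname regression-accessors
setMethod("residualBalances", "RegressionResult", function(x) x@residuals)

.abbrev <- function(x, n = 5) {
    if (length(x) <= n) return(paste(x, collapse = ", "))
    paste0(paste(x[seq_len(n)], collapse = ", "), ", ... (",
           length(x), " total)")
}
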