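#' Closure: normalise abundances to proportions
#'
#' Divides every row by its total so each sample becomes a composition
#' summing to one.  Relative magnitudes within a row are preserved.
#'
#' @param x a [CompositionTable-class], numeric matrix (samples x features)
#'   or a single numeric vector (treated as one sample).
#' @return Object of the same kind as `x` with rows summing to 1.
#' @examples
#' closure(c(1, 1, 2))
#' @name closure
NULL

.closureMatrix <- function(m) {
    tot <- rowSums(m)
    zero <- tot <= 0
    if (any(zero))
        btDataError("closure undefined for all-zero sample(s): %s",
                    .fmtIds(rownames(m)[zero]))
    m / tot
}

#' @rdname closure
setMethod("closure", "CompositionTable", function(x) {
    CompositionTable(.closureMatrix(x@values))
})

#' @rdname closure
setMethod("closure", "matrix", function(x) .closureMatrix(.asCompMatrix(x)))

#' @rdname closure
setMethod("closure", "numeric", function(x) {
    if (any(x < 0)) btDataError("closure requires non-negative entries")
    drop(.closureMatrix(.asCompMatrix(x)))
})

#' Add a pseudocount to every abundance
#'
#' Adds a strictly positive constant to every entry so that log ratios are
#' defined in the presence of zero counts.  The conventional default, used
#' throughout the package pipelines, is 1.
#'
#' @param x a [CompositionTable-class], matrix, or numeric vector of counts.
#' @param pseudocount positive real added to every entry (default 1).
#' @return Same kind as `x`, with `pseudocount` added everywhere.
#' @examples
#' addPseudocount(c(0, 5, 10))
#' @name addPseudocount
NULL

.checkPseudocount <- function(pseudocount) {
    if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
        !is.finite(pseudocount) || pseudocount <= 0)
        btConfigError("pseudocount must be a single positive number, got %s",
                      deparse(pseudocount))
}

#' @rdname addPseudocount
setMethod("addPseudocount", "CompositionTable", function(x, pseudocount = 1) {
    .checkPseudocount(pseudocount)
    CompositionTable(x@values + pseudocount)
})

#' @rdname addPseudocount
setMethod("addPseudocount", "matrix", function(x, pseudocount = 1) {
    .checkPseudocount(pseudocount)
    x + pseudocount
})

#' @rdname addPseudocount
setMethod("addPseudocount", "numeric", function(x, pseudocount = 1) {
    .checkPseudocount(pseudocount)
    x + pseudocount
})

## centred log-ratio of a strictly positive matrix (rows = samples)
.clrMatrix <- function(m) {
    lx <- log(m)
    lx - rowMeans(lx)
}

.checkStrictlyPositive <- function(m, context) {
    if (any(m <= 0))
        btDataError(paste0(
            "%s requires strictly positive values; ",
            "add a pseudocount to zero-containing counts first ",
            "(see addPseudocount())"), context)
}

#' Perturbation and powering on the simplex
#'
#' The two Aitchison-geometry vector-space operations on compositions:
#' `perturbation(x, y)` is the closed element-wise product (simplex
#' addition) and `powering(x, t)` the closed element-wise power (simplex
#' scalar multiplication).  In balance coordinates they become ordinary
#' addition and scalar multiplication: `ilr(perturbation(x, y)) = ilr(x) +
#' ilr(y)` and `ilr(powering(x, t)) = t * ilr(x)`.
#'
#' @param x,y strictly positive compositions ([CompositionTable-class],
#'   matrix, or numeric vector).  For two tables, samples are matched by
#'   position and must agree in dimension.
#' @param t real scalar power.
#' @return Closed composition(s) of the same kind as `x`.
#' @examples
#' perturbation(c(0.5, 0.5), c(0.8, 0.2))
#' powering(c(0.8, 0.2), 0)
#' @name perturbation
NULL

.perturbMatrix <- function(mx, my) {
    if (nrow(my) == 1 && nrow(mx) > 1)
        my <- my[rep(1, nrow(mx)), , drop = FALSE]
    if (!all(dim(mx) == dim(my)))
        btDataError("perturbation requires matching dimensions (%d x %d vs %d x %d)",
                    nrow(mx), ncol(mx), nrow(my), ncol(my))
    .checkStrictlyPositive(mx, "perturbation")
    .checkStrictlyPositive(my, "perturbation")
    .closureMatrix(mx * my)
}

#' @rdname perturbation
setMethod("perturbation", signature("CompositionTable", "ANY"), function(x, y) {
    CompositionTable(.perturbMatrix(x@values, .asCompMatrix(y)))
})

#' @rdname perturbation
setMethod("perturbation", signature("matrix", "ANY"), function(x, y) {
    .perturbMatrix(.asCompMatrix(x), .asCompMatrix(y))
})

#' @rdname perturbation
setMethod("perturbation", signature("numeric", "numeric"), function(x, y) {
    drop(.perturbMatrix(.asCompMatrix(x), .asCompMatrix(y)))
})

.powerMatrix <- function(m, t) {
    if (!is.numeric(t) || length(t) != 1 || !is.finite(t))
        btConfigError("power must be a single finite number")
    .checkStrictlyPositive(m, "powering")
    .closureMatrix(m^t)
}

#' @rdname perturbation
setMethod("powering", "CompositionTable", function(x, t) {
    CompositionTable(.powerMatrix(x@values, t))
})

#' @rdname perturbation
setMethod("powering", "matrix", function(x, t) .powerMatrix(.asCompMatrix(x), t))

#' @rdname perturbation
setMethod("powering", "numeric", function(x, t) {
    drop(.powerMatrix(.asCompMatrix(x), t))
})

#' Prepare a table for the ILR transform
#'
#' Pipeline helper implementing the conventional zero handling: count tables
#' get a pseudocount added to every entry and are then closed to
#' proportions; tables that already look like proportions (every row sums to
#' 1 within `1e-6`) skip the pseudocount, and raise an error if they contain
#' zeros, since a meaningful pseudocount cannot be chosen for proportions.
#'
#' @param table a [CompositionTable-class].
#' @param pseudocount positive constant added to counts (default 1).
#' @return A closed, strictly positive [CompositionTable-class].
#' @export
prepareComposition <- function(table, pseudocount = 1) {
    if (!is(table, "CompositionTable")) table <- CompositionTable(table)
    rs <- rowSums(table@values)
    isProportions <- all(abs(rs - 1) < 1e-6)
    if (isProportions) {
        if (any(table@values == 0))
            btDataError(paste0(
                "proportion-valued table contains zeros; supply the original ",
                "counts so a pseudocount can be applied before closure"))
        return(closure(table))
    }
    closure(addPseudocount(table, pseudocount))
}
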