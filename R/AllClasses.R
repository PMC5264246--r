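#' @import methods
NULL

.checkMatrix <- function(m, what) {
    if (!is.matrix(m) || !is.numeric(m))
        return(sprintf("%s must be a numeric matrix", what))
    if (anyNA(m))
        return(sprintf("%s contains missing values", what))
    if ((nrow(m) > 0 && is.null(rownames(m))) ||
        (ncol(m) > 0 && is.null(colnames(m))))
        return(sprintf("%s must have row and column names", what))
    if (anyDuplicated(rownames(m)))
        return(sprintf("duplicated row names in %s", what))
    if (anyDuplicated(colnames(m)))
        return(sprintf("duplicated column names in %s", what))
    TRUE
}

#' CompositionTable: samples-by-features abundance matrix
#'
#' Container for a non-negative abundance matrix (counts or proportions)
#' with samples as rows and features (e.g. OTUs) as columns.  Row names are
#' sample identifiers and column names are feature identifiers; both must be
#' unique and all entries must be finite and non-negative.
#'
#' @slot values numeric matrix, samples x features, non-negative.
#'
#' @seealso [closure()], [addPseudocount()], [ilrTransform()]
#' @export
setClass("CompositionTable", representation(values = "matrix"))

setValidity("CompositionTable", function(object) {
    m <- object@values
    ok <- .checkMatrix(m, "values")
    if (!isTRUE(ok)) return(ok)
    if (any(m < 0)) return("negative abundances are not allowed")
    if (any(!is.finite(m))) return("non-finite abundances are not allowed")
    TRUE
})

#' OrthonormalBasis: clr-space ILR contrast matrix
#'
#' A (D-1) x D matrix of clr-space basis vectors, one row per internal node
#' of a bifurcating tree over D features.  Each row sums to zero, has unit
#' Euclidean norm, and rows are pairwise orthogonal.
#'
#' @slot matrix numeric matrix with internal-node names as row names and
#'   feature identifiers as column names.
#'
#' @seealso [buildIlrBasis()]
#' @export
setClass("OrthonormalBasis", representation(matrix = "matrix"))

setValidity("OrthonormalBasis", function(object) {
    m <- object@matrix
    ok <- .checkMatrix(m, "basis matrix")
    if (!isTRUE(ok)) return(ok)
    if (nrow(m) != ncol(m) - 1L)
        return("basis must have D-1 rows for D feature columns")
    tol <- 1e-8
    if (max(abs(rowSums(m))) > tol)
        return("basis rows must sum to zero (clr subspace)")
    gram <- tcrossprod(m)
    if (max(abs(gram - diag(nrow(m)))) > tol)
        return("basis rows must be orthonormal")
    TRUE
})

#' BalanceTable: samples-by-balances coordinates
#'
#' Real-valued ILR coordinates (balances), samples as rows and internal-node
#' names as columns, aligned to the node order of the generating
#' [OrthonormalBasis].
#'
#' @slot values numeric matrix, samples x (D-1), finite.
#'
#' @seealso [ilrTransform()], [inverseIlr()]
#' @export
setClass("BalanceTable", representation(values = "matrix"))

setValidity("BalanceTable", function(object) {
    m <- object@values
    ok <- .checkMatrix(m, "values")
    if (!isTRUE(ok)) return(ok)
    if (any(!is.finite(m))) return("balances must be finite")
    TRUE
})

#' RegressionResult: per-balance model fits
#'
#' Result of regressing every balance on a shared design: a per-(node, term)
#' coefficient table with raw and Bonferroni-adjusted p-values, fitted and
#' residual balances, a global coefficient of determination (OLS only;
#' `NA` for mixed models) and a model descriptor.
#'
#' @slot model character, `"ols"` or `"lme"`.
#' @slot formula character, the fixed-effects formula used.
#' @slot grouping character, random-intercept grouping column (`NA` for OLS).
#' @slot coefficients data.frame with columns node, term, estimate, stderr,
#'   pvalue, padj, significant.
#' @slot r2 numeric, global R-squared in balance space (OLS) or `NA`.
#' @slot alpha numeric, significance level used for the flags.
#' @slot fitted BalanceTable of fitted values.
#' @slot residuals BalanceTable of residuals.
#' @slot converged named logical, per-node convergence flag.
#'
#' @seealso [fitOls()], [fitLme()], [predictProportions()]
#' @export
setClass("RegressionResult", representation(
    model = "character",
    formula = "character",
    grouping = "character",
    coefficients = "data.frame",
    r2 = "numeric",
    alpha = "numeric",
    fitted = "BalanceTable",
    residuals = "BalanceTable",
    converged = "logical"
))

setValidity("RegressionResult", function(object) {
    cf <- object@coefficients
    need <- c("node", "term", "estimate", "stderr", "pvalue", "padj",
              "significant")
    if (!all(need %in% names(cf)))
        return(paste("coefficient table must have columns:",
                     paste(need, collapse = ", ")))
    bad <- !is.na(cf$padj) & !is.na(cf$pvalue) & cf$padj < cf$pvalue - 1e-12
    if (any(bad)) return("adjusted p-values must be >= raw p-values")
    if (any(cf$padj > 1 + 1e-12, na.rm = TRUE))
        return("adjusted p-values must be clipped at 1")
    TRUE
})

#' Construct a CompositionTable
#'
#' @param values numeric matrix (samples x features), or a data.frame that
#'   can be coerced to one.
#' @param sample_ids optional character vector of row identifiers; defaults
#'   to existing row names.
#' @param feature_ids optional character vector of column identifiers;
#'   defaults to existing column names.
#' @return A [CompositionTable-class] object.
#' @examples
#' counts <- matrix(c(1, 1, 2, 0, 3, 5), nrow = 2, byrow = TRUE,
#'                  dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' CompositionTable(counts)
#' @export
CompositionTable <- function(values, sample_ids = NULL, feature_ids = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (!is.null(sample_ids)) rownames(values) <- sample_ids
    if (!is.null(feature_ids)) colnames(values) <- feature_ids
    if (nrow(values) > 0 && is.null(rownames(values)))
        rownames(values) <- paste0("S", seq_len(nrow(values)))
    if (ncol(values) > 0 && is.null(colnames(values)))
        colnames(values) <- paste0("F", seq_len(ncol(values)))
    new("CompositionTable", values = values)
}

#' Construct a BalanceTable
#'
#' @param values numeric matrix (samples x internal nodes).
#' @return A [BalanceTable-class] object.
#' @export
BalanceTable <- function(values) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("BalanceTable", values = values)
}

#' Construct an OrthonormalBasis
#'
#' Wraps a pre-computed clr-space contrast matrix; most users should build
#' the basis from a tree with [buildIlrBasis()] instead.
#'
#' @param matrix numeric (D-1) x D matrix with node row names and feature
#'   column names.
#' @return An [OrthonormalBasis-class] object.
#' @export
OrthonormalBasis <- function(matrix) {
    matrix <- as.matrix(matrix)
    storage.mode(matrix) <- "double"
    new("OrthonormalBasis", matrix = matrix)
}
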