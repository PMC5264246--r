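#' Build the ILR orthonormal basis from a bifurcating tree
#'
#' Each internal node `l` with `r` tips in its first (numerator) subtree and
#' `s` tips in its second (denominator) subtree contributes one clr-space
#' basis vector with value `sqrt(s / (r * (r + s)))` on numerator tips,
#' `-sqrt(r / (s * (r + s)))` on denominator tips and 0 elsewhere.  The rows
#' (one per internal node, level order from the root) are orthonormal and
#' span the clr hyperplane, so the induced balance coordinates form an
#' isometry of the Aitchison simplex.
#'
#' @param tree a strictly binary `ape::phylo` tree whose tips are feature
#'   identifiers; unlabelled internal nodes are named `y0...` in level order.
#' @param features optional character vector giving the column order of the
#'   basis; must be a permutation of the tip labels (default: tree tip
#'   order).
#' @param flip logical; if `TRUE` the numerator/denominator orientation of
#'   every node is reversed (all rows negated).
#' @return An [OrthonormalBasis-class] with node names as row names and
#'   feature identifiers as column names.
#' @examples
#' tr <- readNewickBinary("((A,B)y1,C)y0;")
#' basisMatrix(buildIlrBasis(tr))
#' @export
buildIlrBasis <- function(tree, features = NULL, flip = FALSE) {
    assertBinaryTree(tree)
    tree <- nameInternalNodes(tree)
    tipLabels <- tree$tip.label
    if (is.null(features)) {
        features <- tipLabels
    } else {
        extraT <- setdiff(tipLabels, features)
        extraF <- setdiff(features, tipLabels)
        if (length(extraT) || length(extraF))
            btDataError(
                "tree tips and features disagree; only in tree: {%s}; only in features: {%s}",
                .fmtIds(extraT), .fmtIds(extraF))
    }
    nt <- length(tipLabels)
    nodes <- .internalNodesLevelOrder(tree)
    children <- .treeChildren(tree)
    tips <- .subtreeTips(tree)
    col <- match(tipLabels, features)

    m <- matrix(0, nrow = length(nodes), ncol = nt,
                dimnames = list(tree$node.label[nodes - nt], features))
    for (k in seq_along(nodes)) {
        kids <- children[[nodes[k] - nt]]
        num <- tips[[kids[1]]]
        den <- tips[[kids[2]]]
        r <- length(num); s <- length(den)
        m[k, col[num]] <- sqrt(s / (r * (r + s)))
        m[k, col[den]] <- -sqrt(r / (s * (r + s)))
    }
    if (flip) m <- -m
    OrthonormalBasis(m)
}

.alignFeatures <- function(m, basis, context) {
    bf <- colnames(basis@matrix)
    tf <- colnames(m)
    extraT <- setdiff(tf, bf)
    extraB <- setdiff(bf, tf)
    if (length(extraT) || length(extraB))
        btDataError(
            "%s: features do not match the basis; only in table: {%s}; only in basis: {%s}",
            context, .fmtIds(extraT), .fmtIds(extraB))
    m[, bf, drop = FALSE]
}

#' Isometric log-ratio transform of a composition table
#'
#' Maps each D-part composition to D-1 balances: for internal node `i` with
#' numerator subtree `iL` (r tips) and denominator subtree `iR` (s tips),
#' `b_i = sqrt(r*s/(r+s)) * ln(g(iL) / g(iR))` where `g()` is the geometric
#' mean of the proportions in the subtree.  Computed as the matrix product
#' of the clr-transformed samples with the basis rows, which is identical to
#' the per-node formula.
#'
#' @param table a strictly positive, closed [CompositionTable-class]
#'   (use [prepareComposition()] for raw counts); features are aligned to
#'   the basis columns by name.
#' @param basis an [OrthonormalBasis-class] from [buildIlrBasis()].
#' @return A [BalanceTable-class] (samples x internal nodes).
#' @examples
#' tr <- readNewickBinary("(A,B)y0;")
#' tab <- prepareComposition(CompositionTable(
#'   matrix(c(200, 100), 1, dimnames = list("s1", c("A", "B")))))
#' tableValues(ilrTransform(tab, buildIlrBasis(tr)))
#' @export
ilrTransform <- function(table, basis) {
    if (!is(table, "CompositionTable")) table <- CompositionTable(table)
    if (!is(basis, "OrthonormalBasis"))
        btConfigError("basis must be an OrthonormalBasis")
    m <- .alignFeatures(table@values, basis, "ilrTransform")
    .checkStrictlyPositive(m, "ilrTransform")
    BalanceTable(.clrMatrix(m) %*% t(basis@matrix))
}

#' Inverse ILR transform: balances back to proportions
#'
#' Maps balance coordinates back to the simplex:
#' `x = C(exp(b %*% basis))` where `C` is closure.  Round-trips with
#' [ilrTransform()]: `inverseIlr(ilrTransform(x, basis), basis)` equals
#' `closure(x)`.
#'
#' @param balances a [BalanceTable-class] (or matrix) whose columns match
#'   the basis node names.
#' @param basis the [OrthonormalBasis-class] used for the forward transform.
#' @return A closed [CompositionTable-class].
#' @export
inverseIlr <- function(balances, basis) {
    if (!is(basis, "OrthonormalBasis"))
        btConfigError("basis must be an OrthonormalBasis")
    v <- if (is(balances, "BalanceTable")) balances@values else {
        b <- as.matrix(balances)
        if (is.null(rownames(b))) rownames(b) <- paste0("S", seq_len(nrow(b)))
        if (is.null(colnames(b)) && ncol(b) == nrow(basis@matrix))
            colnames(b) <- rownames(basis@matrix)
        b
    }
    bn <- rownames(basis@matrix)
    if (ncol(v) != length(bn))
        btDataError("dimension mismatch: %d balance columns vs %d basis nodes",
                    ncol(v), length(bn))
    if (!is.null(colnames(v))) {
        if (!setequal(colnames(v), bn))
            btDataError("balance columns do not match basis nodes; only in balances: {%s}; only in basis: {%s}",
                        .fmtIds(setdiff(colnames(v), bn)),
                        .fmtIds(setdiff(bn, colnames(v))))
        v <- v[, bn, drop = FALSE]
    }
    CompositionTable(.closureMatrix(exp(v %*% basis@matrix)))
}
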