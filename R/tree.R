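## Trees are represented as ape "phylo" objects.  All functions assume a
## rooted, strictly binary tree whose tips are feature identifiers and whose
## internal nodes carry unique labels (y0 = root, level order).  Child order
## is meaningful: the first child of each internal node is the numerator
## subtree of its balance.

## list of integer child vectors indexed by internal node number - Ntip,
## preserving stored (newick) child order
.treeChildren <- function(tree) {
    nt <- length(tree$tip.label)
    nn <- tree$Nnode
    split(tree$edge[, 2], factor(tree$edge[, 1], levels = (nt + 1):(nt + nn)))
}

.rootNode <- function(tree) {
    nt <- length(tree$tip.label)
    setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}

## internal node numbers in breadth-first (level) order from the root,
## visiting children in stored order
.internalNodesLevelOrder <- function(tree) {
    nt <- length(tree$tip.label)
    children <- .treeChildren(tree)
    queue <- .rootNode(tree)
    out <- integer(0)
    while (length(queue)) {
        node <- queue[1]
        queue <- queue[-1]
        out <- c(out, node)
        kids <- children[[node - nt]]
        queue <- c(queue, kids[kids > nt])
    }
    out
}

#' Check that a tree is strictly binary
#'
#' @param tree an `ape::phylo` tree.
#' @return Invisibly `TRUE`; otherwise an error naming the offending node.
#' @export
assertBinaryTree <- function(tree) {
    if (!inherits(tree, "phylo"))
        btConfigError("expected an ape 'phylo' tree")
    nt <- length(tree$tip.label)
    deg <- tabulate(tree$edge[, 1], nbins = nt + tree$Nnode)
    bad <- which(deg[(nt + 1):(nt + tree$Nnode)] != 2) + nt
    if (length(bad)) {
        lab <- if (!is.null(tree$node.label))
            tree$node.label[bad - nt] else paste0("#", bad)
        btDataError("tree is not strictly binary at internal node(s): %s",
                    .fmtIds(lab))
    }
    if (anyDuplicated(tree$tip.label))
        btDataError("duplicated tip labels: %s",
                    .fmtIds(unique(tree$tip.label[duplicated(tree$tip.label)])))
    invisible(TRUE)
}

#' Name internal nodes in level order
#'
#' Assigns the labels `y0, y1, ...` to internal nodes in breadth-first order
#' from the root (`y0` = root), the convention used for balance names
#' throughout the package.  Existing labels are overwritten only when
#' `overwrite = TRUE` or when any label is missing or empty.
#'
#' @param tree an `ape::phylo` tree.
#' @param overwrite force renaming even when labels exist.
#' @return The tree with `node.label` set.
#' @export
nameInternalNodes <- function(tree, overwrite = FALSE) {
    nt <- length(tree$tip.label)
    have <- !is.null(tree$node.label) &&
        length(tree$node.label) == tree$Nnode &&
        !anyNA(tree$node.label) && all(nzchar(tree$node.label)) &&
        !anyDuplicated(tree$node.label)
    if (have && !overwrite) return(tree)
    ord <- .internalNodesLevelOrder(tree)
    lab <- character(tree$Nnode)
    lab[ord - nt] <- paste0("y", seq_along(ord) - 1L)
    tree$node.label <- lab
    tree
}

#' Read and write strictly binary newick trees
#'
#' `readNewickBinary()` parses a newick string or file into an `ape::phylo`
#' tree, checks that every internal node has exactly two children and tips
#' are unique, and names unlabelled internal nodes `y0...` in level order.
#' `writeNewickBinary()` serialises the tree back to newick, preserving
#' topology, labels and child order.
#'
#' @param text newick string (used when `file` is `NULL`).
#' @param file path to a newick file.
#' @return A `phylo` tree, or (for write) a newick string, invisibly when
#'   written to a file.
#' @examples
#' tr <- readNewickBinary("((A,B)y1,C)y0;")
#' writeNewickBinary(tr)
#' @export
readNewickBinary <- function(text = NULL, file = NULL) {
    tree <- tryCatch(
        if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text),
        error = function(e) btDataError("failed to parse newick: %s",
                                        conditionMessage(e)))
    if (is.null(tree) || !inherits(tree, "phylo"))
        btDataError("failed to parse newick input")
    assertBinaryTree(tree)
    nameInternalNodes(tree)
}

#' @rdname readNewickBinary
#' @param tree a `phylo` tree to serialise.
#' @export
writeNewickBinary <- function(tree, file = NULL) {
    txt <- ape::write.tree(tree, file = "")
    if (is.null(file)) return(txt)
    writeLines(txt, file)
    invisible(txt)
}

#' Numerator / denominator tip sets of an internal node
#'
#' Returns the tip labels of the two subtrees contrasted by the balance at
#' `node`: the first (numerator) child's tips and the second (denominator)
#' child's tips, in stored child order.
#'
#' @param tree a binary `phylo` tree with named internal nodes.
#' @param node internal-node label (e.g. `"y0"`) or internal node number.
#' @return `list(numerator = <tips>, denominator = <tips>)`.
#' @export
subtreeTipSets <- function(tree, node) {
    assertBinaryTree(tree)
    tree <- nameInternalNodes(tree)
    nt <- length(tree$tip.label)
    if (is.character(node)) {
        idx <- match(node, tree$node.label)
        if (is.na(idx)) {
            if (node %in% tree$tip.label)
                btDataError("'%s' is a tip, not an internal node", node)
            btDataError("unknown internal node '%s'", node)
        }
        node <- idx + nt
    }
    if (node <= nt)
        btDataError("node %d is a tip, not an internal node", node)
    children <- .treeChildren(tree)
    tips <- .subtreeTips(tree)
    kids <- children[[node - nt]]
    tipLab <- function(k) tree$tip.label[tips[[k]]]
    list(numerator = tipLab(kids[1]), denominator = tipLab(kids[2]))
}

## integer tip numbers under every node (tips included), via postorder pass
.subtreeTips <- function(tree) {
    nt <- length(tree$tip.label)
    nn <- tree$Nnode
    po <- ape::reorder.phylo(tree, "postorder")$edge
    tips <- vector("list", nt + nn)
    for (i in seq_len(nt)) tips[[i]] <- i
    for (r in seq_len(nrow(po))) {
        p <- po[r, 1]; ch <- po[r, 2]
        tips[[p]] <- c(tips[[p]], tips[[ch]])
    }
    tips
}

#' UPGMA tree from a one-dimensional niche vector
#'
#' Builds a strictly binary dendrogram over features by average-linkage
#' (UPGMA) agglomerative clustering of the pairwise distances
#' `d(x, y) = |niche_x - niche_y|`.  Internal nodes are named `y0...` in
#' level order from the root.  Within each merge the cluster with the larger
#' mean niche value is placed first (numerator) so that every balance reads
#' "high-niche over low-niche"; set `highFirst = FALSE` to reverse.  Equal
#' merge distances are broken deterministically in favour of the pair whose
#' smallest member comes first in sorted feature-identifier order.
#'
#' @param niche named numeric vector of per-feature niche values (e.g. mean
#'   pH), as returned by [meanNicheEstimator()].
#' @param highFirst logical; numerator = higher mean niche (default `TRUE`).
#' @return A `phylo` tree with UPGMA heights as branch lengths.
#' @examples
#' upgmaNiche(c(A = 4, B = 5, C = 9))
#' @export
upgmaNiche <- function(niche, highFirst = TRUE) {
    ids <- names(niche)
    if (is.null(ids) || anyDuplicated(ids))
        btConfigError("niche vector must have unique feature names")
    if (length(niche) < 2)
        btDataError("need at least 2 features to build a tree, got %d",
                    length(niche))
    if (any(!is.finite(niche)))
        btDataError("non-finite niche value for feature(s): %s",
                    .fmtIds(ids[!is.finite(niche)]))

    n <- length(niche)
    ## active cluster state
    members <- as.list(ids)           # feature ids per cluster
    key <- ids                        # sorted-order smallest member
    meanNiche <- as.numeric(niche)
    sizes <- rep(1L, n)
    heights <- rep(0, n)
    nodes <- as.list(seq_len(n))      # build record: tip index or list(l, r, h)
    D <- abs(outer(as.numeric(niche), as.numeric(niche), "-"))
    diag(D) <- Inf
    active <- rep(TRUE, n)

    recs <- list()                    # merge records for newick construction
    for (step in seq_len(n - 1L)) {
        idx <- which(active)
        sub <- D[idx, idx, drop = FALSE]
        dmin <- min(sub)
        hits <- which(sub == dmin, arr.ind = TRUE)
        hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
        ## deterministic tie-break on sorted smallest-member ids
        pk <- vapply(seq_len(nrow(hits)), function(r) {
            k <- sort(c(key[idx[hits[r, 1]]], key[idx[hits[r, 2]]]))
            paste(k, collapse = "\r")
        }, character(1))
        pick <- hits[order(pk)[1], ]
        i <- idx[pick[1]]; j <- idx[pick[2]]

        h <- dmin / 2
        ## child order: numerator (first child) = larger mean niche
        swap <- if (meanNiche[i] == meanNiche[j])
            key[i] > key[j] else meanNiche[i] < meanNiche[j]
        if (!highFirst) swap <- !swap
        first <- if (swap) j else i
        second <- if (swap) i else j

        newNode <- list(left = nodes[[first]], right = nodes[[second]],
                        height = h)
        ## UPGMA (average linkage) distance update
        ni <- sizes[i]; nj <- sizes[j]
        newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
        D[i, ] <- newd; D[, i] <- newd; D[i, i] <- Inf
        active[j] <- FALSE
        D[j, ] <- Inf; D[, j] <- Inf

        meanNiche[i] <- (ni * meanNiche[i] + nj * meanNiche[j]) / (ni + nj)
        sizes[i] <- ni + nj
        key[i] <- min(key[i], key[j])
        members[[i]] <- c(members[[i]], members[[j]])
        heights[i] <- h
        nodes[[i]] <- newNode
    }
    root <- nodes[[which(active)]]
    nwk <- paste0(.nodeNewick(root, ids, rootHeight = root$height), ";")
    tree <- ape::read.tree(text = nwk)
    nameInternalNodes(tree, overwrite = TRUE)
}

## recursive newick with branch lengths = parent height - child height
.nodeNewick <- function(node, ids, rootHeight = NULL) {
    fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
    render <- function(nd, parentHeight) {
        if (!is.list(nd))
            return(paste0(ids[nd], ":", fmt(parentHeight)))
        inner <- paste0("(", render(nd$left, nd$height), ",",
                        render(nd$right, nd$height), ")")
        if (is.null(parentHeight)) inner
        else paste0(inner, ":", fmt(parentHeight - nd$height))
    }
    render(node, NULL)
}

#' Caterpillar (ladder) tree over an ordered tip list
#'
#' Builds the fully unbalanced binary tree `(t1, (t2, (t3, ...)))` where
#' `tips[1]` is the singleton child of the root.  Used by the blooming-
#' species false-discovery experiments to place a feature at the top or
#' bottom of the tree.
#'
#' @param tips character vector of tip labels (length >= 2).
#' @return A `phylo` tree with internal nodes named `y0...` in level order.
#' @export
caterpillarTree <- function(tips) {
    if (length(tips) < 2) btConfigError("need at least 2 tips")
    if (anyDuplicated(tips)) btConfigError("duplicated tip labels")
    n <- length(tips)
    nwk <- paste0(paste0("(", tips[-n], ",", collapse = ""), tips[n],
                  strrep(")", n - 1), ";")
    tree <- ape::read.tree(text = nwk)
    nameInternalNodes(tree, overwrite = TRUE)
}
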