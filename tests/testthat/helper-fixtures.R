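# Fixtures are generated in code; nothing is read from disk.

# random rooted strictly binary tree over D named features
randomBinaryTree <- function(D, prefix = "F") {
    tr <- ape::rtree(D, tip.label = sprintf("%s%03d", prefix, seq_len(D)))
    nameInternalNodes(tr, overwrite = TRUE)
}

# random strictly positive closed compositions, n samples x D features
randomComposition <- function(n, D, features = sprintf("F%03d", seq_len(D))) {
    m <- matrix(stats::rgamma(n * D, shape = 2), n, D,
                dimnames = list(sprintf("S%03d", seq_len(n)), features))
    m / rowSums(m)
}

# Independent oracle for the balance of one internal node: walks the edge
# matrix itself (no package tip-set code) and evaluates
#   b = sqrt(r*s/(r+s)) * ln(gm(numerator) / gm(denominator))
# on each row of a closed composition matrix.
directBalanceOracle <- function(m, tree, nodeLabel) {
    nt <- length(tree$tip.label)
    kidsOf <- function(nd) tree$edge[tree$edge[, 1] == nd, 2]
    tipsUnder <- function(nd) {
        if (nd <= nt) return(tree$tip.label[nd])
        unlist(lapply(kidsOf(nd), tipsUnder))
    }
    nd <- nt + match(nodeLabel, tree$node.label)
    kids <- kidsOf(nd)
    num <- tipsUnder(kids[1]); den <- tipsUnder(kids[2])
    r <- length(num); s <- length(den)
    gm <- function(v) exp(mean(log(v)))
    apply(m, 1, function(row)
        sqrt(r * s / (r + s)) * log(gm(row[num]) / gm(row[den])))
}

# all balances via the direct per-node oracle, columns in node.label order
directBalancesOracle <- function(m, tree) {
    out <- sapply(tree$node.label, function(nd) directBalanceOracle(m, tree, nd))
    matrix(out, nrow = nrow(m),
           dimnames = list(rownames(m), tree$node.label))
}

# diagonal band statistic of a niche-sorted matrix: mean over columns of
# |relative row position of the column's mass centroid - relative column
# position|; small when mass concentrates along the diagonal
bandStatistic <- function(m) {
    n <- nrow(m); D <- ncol(m)
    centroid <- apply(m, 2, function(col)
        if (sum(col) == 0) NA_real_ else sum(seq_len(n) * col) / sum(col))
    mean(abs(centroid / n - seq_len(D) / D), na.rm = TRUE)
}
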