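## Tabular dialect: TSV, header row of feature identifiers, first column of
## sample identifiers (named "sample_id").

#' Read and write composition tables
#'
#' `readCompositionTable()` reads a samples x features table either from TSV
#' (header of feature ids, first column of sample ids) or from a BIOM file
#' (JSON or HDF5 dialect, via the biomformat package; BIOM stores features
#' as rows and is transposed on the way in).
#'
#' @param path input file.
#' @param dialect `"tsv"` (default) or `"biom"`.
#' @return A [CompositionTable-class].
#' @export
readCompositionTable <- function(path, dialect = c("tsv", "biom")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) btConfigError("no such file: %s", path)
    if (dialect == "biom") {
        if (!requireNamespace("biomformat", quietly = TRUE))
            btConfigError("the 'biomformat' package is required for BIOM input")
        b <- biomformat::read_biom(path)
        m <- as.matrix(biomformat::biom_data(b))
        return(CompositionTable(t(m)))
    }
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    CompositionTable(as.matrix(df))
}

#' @rdname readCompositionTable
#' @param table a [CompositionTable-class] to write as TSV.
#' @export
writeCompositionTable <- function(table, path) {
    if (!is(table, "CompositionTable")) table <- CompositionTable(table)
    df <- data.frame(sample_id = sampleIds(table), table@values,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read sample metadata
#'
#' TSV with sample identifiers in the first column; remaining columns are
#' covariates.  Row names are set to the sample identifiers.
#'
#' @param path metadata TSV.
#' @return A data.frame keyed by sample identifier.
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path)) btConfigError("no such file: %s", path)
    df <- utils::read.delim(path, check.names = FALSE)
    if (ncol(df) < 2) btDataError("metadata needs a sample column plus >= 1 covariate")
    if (anyDuplicated(df[[1]]))
        btDataError("duplicated sample identifiers in metadata")
    rownames(df) <- as.character(df[[1]])
    df
}

#' Export a niche vector as two-column TSV
#'
#' @param niche named numeric vector (e.g. from [meanNicheEstimator()]).
#' @param path output file.
#' @param gradientName column name for the niche value (default
#'   `"mean_niche"`).
#' @export
writeNicheVector <- function(niche, path, gradientName = "mean_niche") {
    df <- data.frame(feature_id = names(niche), value = as.numeric(niche))
    names(df)[2] <- gradientName
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export an ILR basis as TSV
#'
#' Writes the (D-1) x D clr-space matrix with internal-node names in the
#' first column and feature identifiers as the header.
#'
#' @param basis an [OrthonormalBasis-class].
#' @param path output file.
#' @export
writeBasisTsv <- function(basis, path) {
    m <- basisMatrix(basis)
    df <- data.frame(node = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a balance table as TSV
#'
#' @param balances a [BalanceTable-class].
#' @param path output file.
#' @export
writeBalanceTable <- function(balances, path) {
    m <- tableValues(balances)
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export regression results as TSV
#'
#' One row per (node, term) with estimate, standard error, raw and
#' Bonferroni-adjusted p-value and the significance flag.
#'
#' @param result a [RegressionResult-class].
#' @param path output file.
#' @export
writeRegressionTsv <- function(result, path) {
    utils::write.table(coefTable(result), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## node -> tip-set membership audit table
writeTipSetsTsv <- function(tree, path) {
    tree <- nameInternalNodes(tree)
    rows <- lapply(tree$node.label, function(nd) {
        ts <- subtreeTipSets(tree, nd)
        data.frame(node = nd,
                   numerator = paste(ts$numerator, collapse = ","),
                   denominator = paste(ts$denominator, collapse = ","))
    })
    utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
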