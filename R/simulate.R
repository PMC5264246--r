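## Synthetic-data generators.  All draws flow from the `seed` argument so
## generated studies are reproducible; `seed = NULL` uses the current RNG
## state.

.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
            btConfigError("seed must be a single integer")
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        set.seed(as.integer(seed))
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    }
    force(expr)
}

.gaussBump <- function(g, optimum, width) {
    exp(-(g - optimum)^2 / (2 * width^2))
}

#' Simulate a community with unimodal responses along a gradient
#'
#' Each feature's expected proportion along the gradient is a Gaussian bump
#' `exp(-(g - optimum)^2 / (2 * width^2))`, closed per sample.  Proportions
#' below `zeroThreshold` are rounded down to zero (so the pseudocount
#' pathway is exercised downstream) and the sample is re-closed, then counts
#' are drawn multinomially at the stated sequencing depth.
#'
#' @param nFeatures number of features (default 4, the classic small
#'   unimodal illustration).
#' @param gradient per-sample gradient values (default 50 samples evenly
#'   spaced over pH 3-9, a soil-like range).
#' @param optima per-feature niche centres (default evenly spread across
#'   the gradient range).
#' @param widths per-feature niche widths (default 1 gradient unit).
#' @param depth multinomial sequencing depth per sample (default 10000).
#' @param zeroThreshold proportions below this are set to zero before
#'   counts are drawn (default 1e-4).
#' @param seed integer seed for reproducibility.
#' @return `list(counts = CompositionTable, metadata = data.frame(sample,
#'   gradient), truth = list(optima, widths, depth, zeroThreshold,
#'   expected))` where `expected` is the (zero-rounded, closed) expected
#'   proportion matrix.
#' @examples
#' sim <- generateGradientCommunity(nFeatures = 4, seed = 1)
#' dim(sim$counts)
#' @export
generateGradientCommunity <- function(nFeatures = 4,
                                      gradient = seq(3, 9, length.out = 50),
                                      optima = NULL,
                                      widths = 1,
                                      depth = 10000,
                                      zeroThreshold = 1e-4,
                                      seed = NULL) {
    if (nFeatures < 1) btConfigError("nFeatures must be >= 1")
    if (length(gradient) < 1 || any(!is.finite(gradient)))
        btConfigError("gradient must be finite and non-empty")
    if (is.null(optima))
        optima <- seq(min(gradient), max(gradient), length.out = nFeatures)
    if (length(optima) != nFeatures)
        btConfigError("need one optimum per feature")
    if (any(optima < min(gradient) - 1e-9) || any(optima > max(gradient) + 1e-9))
        btConfigError("optima must lie within the gradient range")
    widths <- rep_len(widths, nFeatures)
    if (any(widths <= 0)) btConfigError("widths must be > 0")
    if (depth <= 0) btConfigError("depth must be > 0")
    if (zeroThreshold < 0 || zeroThreshold >= 1)
        btConfigError("zeroThreshold must be in [0, 1)")

    features <- sprintf("F%03d", seq_len(nFeatures))
    samples <- sprintf("S%03d", seq_along(gradient))
    expected <- vapply(seq_len(nFeatures), function(j)
        .gaussBump(gradient, optima[j], widths[j]), numeric(length(gradient)))
    expected <- matrix(expected, nrow = length(gradient),
                       dimnames = list(samples, features))
    expected <- .closureMatrix(expected)
    expected[expected < zeroThreshold] <- 0
    expected <- .closureMatrix(expected)

    counts <- .withSeed(seed, t(apply(expected, 1, function(p)
        stats::rmultinom(1, size = depth, prob = p)[, 1])))
    if (nFeatures == 1) counts <- matrix(counts, ncol = 1)
    dimnames(counts) <- dimnames(expected)

    list(counts = CompositionTable(counts),
         metadata = data.frame(sample = samples, gradient = gradient,
                               row.names = samples),
         truth = list(optima = stats::setNames(optima, features),
                      widths = stats::setNames(widths, features),
                      depth = depth, zeroThreshold = zeroThreshold,
                      expected = expected))
}

#' Simulate a uniform community with one blooming species
#'
#' Two groups of samples over a uniform expected community; in the second
#' group a single feature's absolute abundance is multiplied by
#' `bloomFactor`, so under the compositional constraint every other
#' feature's expected proportion drops from `1/D` to `1/(D - 1 +
#' bloomFactor)` even though nothing but the bloomer changed.  Counts are
#' multinomial at fixed depth.
#'
#' The default bloom is large (`bloomFactor = 1000` over 1000 features, i.e.
#' the bloomer grows to about half the sequenced community): with many
#' features a modest bloom perturbs each remaining proportion by far less
#' than multinomial noise at realistic depths, while a dominant bloom is the
#' regime in which naive per-feature tests flag essentially every taxon.
#'
#' @param nFeatures number of features (default 1000).
#' @param nPerGroup samples per group (default 50).
#' @param bloomFeature index or name of the blooming feature (default the
#'   first).
#' @param bloomFactor multiplier (> 1, or exactly 1 for a null calibration
#'   run) on the bloomer's absolute abundance in group 2 (default 1000).
#' @param depth multinomial depth per sample (default 1e5).
#' @param seed integer seed.
#' @return `list(counts = CompositionTable, labels = factor of "g1"/"g2",
#'   bloomFeature = <feature id>, truth = list(...))`; the analytic group-2
#'   expected bloom proportion `bloomFactor / (bloomFactor + D - 1)` is in
#'   `truth$expectedBloomProportion`.
#' @export
generateBloomDataset <- function(nFeatures = 1000, nPerGroup = 50,
                                 bloomFeature = 1, bloomFactor = 1000,
                                 depth = 1e5, seed = NULL) {
    if (nFeatures < 2) btConfigError("nFeatures must be >= 2")
    if (nPerGroup < 2) btConfigError("nPerGroup must be >= 2")
    if (!is.numeric(bloomFactor) || bloomFactor < 1)
        btConfigError("bloomFactor must be >= 1")
    if (depth <= 0) btConfigError("depth must be > 0")
    features <- sprintf("F%04d", seq_len(nFeatures))
    if (is.character(bloomFeature)) bloomFeature <- match(bloomFeature, features)
    if (is.na(bloomFeature) || bloomFeature < 1 || bloomFeature > nFeatures)
        btConfigError("bloomFeature out of range")

    p1 <- rep(1 / nFeatures, nFeatures)
    w2 <- rep(1, nFeatures)
    w2[bloomFeature] <- bloomFactor
    p2 <- w2 / sum(w2)

    n <- 2 * nPerGroup
    samples <- sprintf("S%03d", seq_len(n))
    labels <- factor(rep(c("g1", "g2"), each = nPerGroup))
    counts <- .withSeed(seed, {
        m <- matrix(0L, n, nFeatures, dimnames = list(samples, features))
        m[labels == "g1", ] <- t(stats::rmultinom(nPerGroup, depth, p1))
        m[labels == "g2", ] <- t(stats::rmultinom(nPerGroup, depth, p2))
        m
    })
    list(counts = CompositionTable(counts),
         labels = stats::setNames(labels, samples),
         bloomFeature = features[bloomFeature],
         truth = list(bloomFactor = bloomFactor, depth = depth,
                      expectedBloomProportion = bloomFactor /
                          (bloomFactor + nFeatures - 1),
                      expectedOtherProportion = 1 /
                          (bloomFactor + nFeatures - 1)))
}

#' False-discovery experiment: proportions vs balances under a bloom
#'
#' Contrasts two testing strategies on a two-group dataset in which at most
#' one feature truly changed: (i) a two-sample t test on each feature's
#' proportion, and (ii) a two-sample t test on each balance of `tree`.
#' Because proportions are not subcompositionally coherent, a single bloom
#' shifts every proportion and the per-feature tests reject almost
#' everywhere; balances whose clade excludes the bloomer are genuinely null
#' and should reject at rate `alpha`.
#'
#' @param counts a count [CompositionTable-class].
#' @param labels two-level factor of group labels, named by sample or in
#'   sample order; each group needs >= 2 samples.
#' @param tree binary `phylo` tree over the features (e.g. a
#'   [caterpillarTree()] placing the bloomer at the top or bottom).
#' @param alpha test level (default 0.05).
#' @param bloomFeature identifier of the blooming feature, used to classify
#'   features and balances as null; `NULL` means no feature changed (pure
#'   null calibration).
#' @param pseudocount pseudocount for the balance pathway (default 1).
#' @return list with `proportionRejectedNull` (fraction of non-blooming
#'   features rejected), `proportionRejectedAll`, `balanceRejectedNull`
#'   (fraction of bloom-free balances rejected), `balanceRejectedAll`,
#'   `nNullFeatures`, `nNullBalances`, and `alpha`.
#' @export
fdrExperiment <- function(counts, labels, tree, alpha = 0.05,
                          bloomFeature = NULL, pseudocount = 1) {
    if (!is(counts, "CompositionTable")) counts <- CompositionTable(counts)
    ids <- sampleIds(counts)
    if (!is.null(names(labels))) labels <- labels[ids]
    labels <- factor(labels)
    if (nlevels(labels) != 2)
        btDataError("labels must have exactly 2 groups, got %d",
                    nlevels(labels))
    if (any(table(labels) < 2))
        btDataError("each group needs >= 2 samples")
    g1 <- labels == levels(labels)[1]

    tTestP <- function(col) {
        x <- col[g1]; y <- col[!g1]
        if (stats::var(x) + stats::var(y) <= 0) return(NA_real_)
        stats::t.test(x, y)$p.value
    }

    props <- .closureMatrix(counts@values)
    pProp <- apply(props, 2, tTestP)

    basis <- buildIlrBasis(tree)
    bal <- ilrTransform(prepareComposition(counts, pseudocount), basis)
    pBal <- apply(bal@values, 2, tTestP)

    featNull <- rep(TRUE, ncol(props))
    names(featNull) <- colnames(props)
    nodeNull <- rep(TRUE, length(pBal))
    names(nodeNull) <- names(pBal)
    if (!is.null(bloomFeature)) {
        if (!bloomFeature %in% colnames(props))
            btConfigError("unknown bloomFeature '%s'", bloomFeature)
        featNull[bloomFeature] <- FALSE
        ## a balance is affected iff the bloomer is inside its clade
        for (nd in names(pBal)) {
            ts <- subtreeTipSets(tree, nd)
            nodeNull[nd] <- !(bloomFeature %in% c(ts$numerator,
                                                  ts$denominator))
        }
    }
    rejProp <- !is.na(pProp) & pProp < alpha
    rejBal <- !is.na(pBal) & pBal < alpha
    list(
        proportionRejectedNull = mean(rejProp[featNull]),
        proportionRejectedAll = mean(rejProp),
        balanceRejectedNull = if (any(nodeNull)) mean(rejBal[nodeNull])
                              else NA_real_,
        balanceRejectedAll = mean(rejBal),
        nNullFeatures = sum(featNull),
        nNullBalances = sum(nodeNull),
        alpha = alpha
    )
}

#' Simulate patient-structured repeated measures along a pH gradient
#'
#' Emulates a sputum-microcosm design: each of `nPatients` patients
#' contributes one community grown at every pH level.  A shared pool of
#' features has niche optima spread over the pH range; each patient carries
#' an idiosyncratic random subset of the pool (every feature kept with
#' probability `1 - idiosyncrasy`, with at least two kept), so different
#' patients respond to pH through different features.  Counts are
#' multinomial at fixed depth.
#'
#' @param nPatients number of patients (default 16).
#' @param phLevels vector of pH levels (default 5 to 8.5 in steps of 0.5).
#' @param nFeatures size of the shared feature pool (default 40).
#' @param width shared niche width in pH units (default 1).
#' @param idiosyncrasy probability in `[0, 1)` that a patient lacks any
#'   given feature (default 0.5); 0 means all patients share the full pool.
#' @param depth multinomial depth per sample (default 10000).
#' @param seed integer seed.
#' @return `list(counts = CompositionTable, metadata = data.frame(sample,
#'   patient, ph), truth = list(optima, width, presence, expected))`.
#' @export
generatePatientGradient <- function(nPatients = 16,
                                    phLevels = seq(5, 8.5, by = 0.5),
                                    nFeatures = 40,
                                    width = 1,
                                    idiosyncrasy = 0.5,
                                    depth = 10000,
                                    seed = NULL) {
    if (nPatients < 2) btConfigError("need >= 2 patients")
    if (length(phLevels) < 2) btConfigError("need >= 2 pH levels")
    if (nFeatures < 2) btConfigError("need >= 2 features")
    if (idiosyncrasy < 0 || idiosyncrasy >= 1)
        btConfigError("idiosyncrasy must be in [0, 1)")
    if (width <= 0 || depth <= 0)
        btConfigError("width and depth must be > 0")

    features <- sprintf("F%03d", seq_len(nFeatures))
    patients <- sprintf("P%02d", seq_len(nPatients))
    optima <- seq(min(phLevels), max(phLevels), length.out = nFeatures)

    .withSeed(seed, {
        presence <- matrix(stats::runif(nPatients * nFeatures) >= idiosyncrasy,
                           nPatients, nFeatures,
                           dimnames = list(patients, features))
        for (i in seq_len(nPatients)) {     # keep >= 2 features per patient
            if (sum(presence[i, ]) < 2)
                presence[i, sample.int(nFeatures, 2)] <- TRUE
        }
        grid <- expand.grid(patient = patients, ph = phLevels,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        grid <- grid[order(grid$patient, grid$ph), ]
        samples <- sprintf("%s_pH%.1f", grid$patient, grid$ph)
        rownames(grid) <- samples

        expected <- matrix(0, nrow(grid), nFeatures,
                           dimnames = list(samples, features))
        for (r in seq_len(nrow(grid))) {
            keep <- presence[grid$patient[r], ]
            lam <- .gaussBump(grid$ph[r], optima, width) * keep
            expected[r, ] <- lam / sum(lam)
        }
        counts <- t(apply(expected, 1, function(p)
            stats::rmultinom(1, depth, p)[, 1]))
        dimnames(counts) <- dimnames(expected)

        list(counts = CompositionTable(counts),
             metadata = data.frame(sample = samples, patient = grid$patient,
                                   ph = grid$ph, row.names = samples),
             truth = list(optima = stats::setNames(optima, features),
                          width = width, presence = presence,
                          depth = depth, expected = expected))
    })
}
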