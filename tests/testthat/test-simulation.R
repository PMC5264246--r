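test_that("gradient community generator honours its spec and seeds", {
    sim <- generateGradientCommunity(nFeatures = 4, seed = 9)
    expect_equal(dim(sim$counts), c(50, 4))
    expect_equal(unname(rowSums(tableValues(sim$counts))), rep(10000, 50))
    expect_equal(unname(rowSums(sim$truth$expected)), rep(1, 50))

    # bit-reproducible under the same seed
    sim2 <- generateGradientCommunity(nFeatures = 4, seed = 9)
    expect_identical(tableValues(sim$counts), tableValues(sim2$counts))

    # one feature: every sample is 100% that feature
    one <- generateGradientCommunity(nFeatures = 1, gradient = 4:6,
                                     depth = 100, seed = 2)
    expect_true(all(tableValues(one$counts) == 100))

    # zero rounding produces structural zeros at gradient extremes
    wide <- generateGradientCommunity(nFeatures = 6, widths = 0.5,
                                      zeroThreshold = 1e-4, seed = 3)
    expect_gt(sum(wide$truth$expected == 0), 0)

    expect_error(generateGradientCommunity(nFeatures = 2, optima = c(1, 99)),
                 class = "bt_config_error")
    expect_error(generateGradientCommunity(widths = 0),
                 class = "bt_config_error")
})

test_that("two features with optima at the gradient ends give a monotone root balance", {
    sim <- generateGradientCommunity(
        nFeatures = 2, gradient = seq(3, 9, length.out = 60),
        optima = c(3, 9), widths = 2, depth = 20000, seed = 44)
    basis <- buildIlrBasis(readNewickBinary("(F001,F002)y0;"))
    bal <- tableValues(ilrTransform(prepareComposition(sim$counts), basis))[, 1]
    g <- sim$metadata$gradient
    # positive where the first species dominates, negative at the other end,
    # with the sign change (turning point) near the gradient midpoint
    expect_gt(bal[1], 0)
    expect_lt(bal[60], 0)
    crossing <- g[max(which(bal > 0))]
    expect_lt(abs(crossing - 6), 1)
    # numerator species prefers the low end, so the balance falls with g
    expect_lt(stats::cor(g, bal), -0.95)
})

test_that("bloom generator matches its analytic expectations", {
    sim <- generateBloomDataset(nFeatures = 50, nPerGroup = 40,
                                bloomFactor = 10, depth = 5e4, seed = 10)
    expect_equal(levels(sim$labels), c("g1", "g2"))
    props <- tableValues(closure(sim$counts))
    g2 <- names(sim$labels)[sim$labels == "g2"]
    g1 <- names(sim$labels)[sim$labels == "g1"]
    empirical <- mean(props[g2, sim$bloomFeature])
    expect_equal(empirical, sim$truth$expectedBloomProportion,
                 tolerance = 0.05)
    # closure forces every non-bloom proportion down in group 2
    other <- setdiff(colnames(props), sim$bloomFeature)
    expect_lt(mean(props[g2, other]), mean(props[g1, other]))

    sim2 <- generateBloomDataset(nFeatures = 50, nPerGroup = 40,
                                 bloomFactor = 10, depth = 5e4, seed = 10)
    expect_identical(tableValues(sim$counts), tableValues(sim2$counts))
    expect_error(generateBloomDataset(bloomFactor = 0.5),
                 class = "bt_config_error")
})

test_that("fdrExperiment distinguishes proportion tests from coherent balance tests", {
    set.seed(1234)
    sim <- generateBloomDataset(nFeatures = 200, nPerGroup = 30,
                                bloomFactor = 200, depth = 2e4, seed = 77)
    feats <- featureIds(sim$counts)
    topTree <- caterpillarTree(c(sim$bloomFeature,
                                 setdiff(feats, sim$bloomFeature)))
    rep1 <- fdrExperiment(sim$counts, sim$labels, topTree,
                          bloomFeature = sim$bloomFeature)
    # proportions: almost everything looks different; balances: calibrated
    expect_gt(rep1$proportionRejectedNull, 0.9)
    expect_lt(rep1$balanceRejectedNull, 0.15)
    expect_equal(rep1$nNullBalances, 198)  # every node except the root

    # bloomer at the bottom of the tree: no balance is bloom-free
    bottomTree <- caterpillarTree(c(setdiff(feats, sim$bloomFeature),
                                    sim$bloomFeature))
    rep2 <- fdrExperiment(sim$counts, sim$labels, bottomTree,
                          bloomFeature = sim$bloomFeature)
    expect_equal(rep2$nNullBalances, 0)
    expect_true(is.na(rep2$balanceRejectedNull))

    expect_error(fdrExperiment(sim$counts, sim$labels[1:10], topTree),
                 class = "bt_data_error")
})

test_that("patient-gradient generator produces the case-study design", {
    sim <- generatePatientGradient(seed = 5)
    expect_equal(nrow(sim$counts), 16 * 8)       # 16 patients x 8 pH levels
    expect_equal(sort(unique(sim$metadata$ph)), seq(5, 8.5, by = 0.5))
    expect_equal(length(unique(sim$metadata$patient)), 16)
    expect_true(all(rowSums(sim$truth$presence) >= 2))

    shared <- generatePatientGradient(nPatients = 3, idiosyncrasy = 0,
                                      nFeatures = 10, seed = 6)
    expect_true(all(shared$truth$presence))      # everyone shares the pool
    expect_error(generatePatientGradient(nPatients = 1),
                 class = "bt_config_error")
    expect_error(generatePatientGradient(idiosyncrasy = 1),
                 class = "bt_config_error")
})

test_that("idiosyncratic patients defeat per-feature tests but not the root balance LME", {
    sim <- generatePatientGradient(nPatients = 12, nFeatures = 30,
                                   idiosyncrasy = 0.6, depth = 5000,
                                   seed = 314)
    g <- stats::setNames(sim$metadata$ph, rownames(sim$metadata))
    niche <- meanNicheEstimator(sim$counts, g, zeroTotal = "drop")
    kept <- CompositionTable(tableValues(sim$counts)[, names(niche)])
    tree <- upgmaNiche(niche)
    bal <- ilrTransform(prepareComposition(kept), buildIlrBasis(tree))
    fit <- fitLme(bal, sim$metadata, ~ ph, grouping = "patient")
    cf <- coefTable(fit)
    root <- cf[cf$node == "y0" & cf$term == "ph", ]
    expect_gt(root$estimate, 0)      # high-pH over low-pH rises with pH
    expect_true(root$significant)
})
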