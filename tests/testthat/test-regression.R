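mkBalances <- function(m, nodes = sprintf("y%d", seq_len(ncol(m)) - 1),
                       samples = sprintf("s%02d", seq_len(nrow(m)))) {
    BalanceTable(matrix(m, nrow(m), dimnames = list(samples, nodes)))
}

test_that("fitOls recovers a noiseless linear signal exactly", {
    ph <- seq(4, 9, length.out = 12)
    Y <- cbind(2 + 1.5 * ph, -1 + 0.3 * ph, 0.7 * ph)
    bal <- mkBalances(Y)
    cov <- data.frame(ph = ph, row.names = sampleIds(bal))
    fit <- fitOls(bal, cov, ~ ph)
    cf <- coefTable(fit)
    slopes <- cf$estimate[cf$term == "ph"]
    expect_lt(max(abs(slopes - c(1.5, 0.3, 0.7))), 1e-9)
    expect_equal(globalR2(fit), 1, tolerance = 1e-9)
    expect_lt(max(abs(tableValues(fittedBalances(fit)) +
                      tableValues(residualBalances(fit)) - Y)), 1e-9)
})

test_that("fitOls gives zero slope and zero R2 for a covariate-orthogonal balance", {
    Y <- cbind(c(1, 1, -1, -1, 1, 1, -1, -1))
    bal <- mkBalances(Y)
    cov <- data.frame(ph = c(1, -1, 1, -1, 1, -1, 1, -1),
                      row.names = sampleIds(bal))
    fit <- fitOls(bal, cov, ~ ph)
    cf <- coefTable(fit)
    expect_equal(cf$estimate[cf$term == "ph"], 0)
    expect_equal(globalR2(fit), 0)
})

test_that("fitOls on the single balance of a 2-feature table equals direct regression", {
    set.seed(31)
    n <- 40
    ph <- stats::runif(n, 4, 9)
    counts <- matrix(stats::rpois(2 * n, 200), n, 2,
                     dimnames = list(sprintf("s%02d", 1:n), c("A", "B")))
    tab <- prepareComposition(CompositionTable(counts))
    basis <- buildIlrBasis(readNewickBinary("(A,B)y0;"))
    bal <- ilrTransform(tab, basis)
    fit <- fitOls(bal, data.frame(ph = ph, row.names = sampleIds(bal)), ~ ph)

    y <- sqrt(1 / 2) * log(tableValues(tab)[, "A"] / tableValues(tab)[, "B"])
    ref <- summary(stats::lm(y ~ ph))$coefficients
    cf <- coefTable(fit)
    expect_equal(cf$estimate[cf$term == "ph"], ref["ph", "Estimate"],
                 tolerance = 1e-9)
    expect_equal(cf$stderr[cf$term == "ph"], ref["ph", "Std. Error"],
                 tolerance = 1e-9)
    expect_equal(cf$pvalue[cf$term == "ph"], ref["ph", "Pr(>|t|)"],
                 tolerance = 1e-9)
})

test_that("fitOls recovers a known slope within 3 analytic standard errors", {
    set.seed(77)
    n <- 100
    ph <- stats::runif(n, 4, 9)
    beta <- 0.8
    Y <- cbind(beta * ph + stats::rnorm(n, sd = 0.5),
               -0.2 * ph + stats::rnorm(n, sd = 0.5))
    fit <- fitOls(mkBalances(Y), data.frame(ph = ph), ~ ph)
    cf <- coefTable(fit)
    est <- cf$estimate[cf$term == "ph" & cf$node == "y0"]
    se <- cf$stderr[cf$term == "ph" & cf$node == "y0"]
    expect_lt(abs(est - beta), 3 * se)
    # the analytic OLS standard error formula
    seRef <- 0.5 / sqrt(sum((ph - mean(ph))^2))
    expect_equal(se, seRef, tolerance = 0.35)
})

test_that("fitOls validates design and sample alignment", {
    Y <- mkBalances(cbind(rnorm(8)))
    cov <- data.frame(a = 1:8, b = 2 * (1:8), row.names = sampleIds(Y))
    err <- expect_error(fitOls(Y, cov, ~ a + b), class = "bt_data_error")
    expect_match(conditionMessage(err), "b")
    expect_error(fitOls(Y, data.frame(a = 1:3), ~ a), class = "bt_data_error")
    expect_error(
        fitOls(Y, data.frame(a = 1:8,
                             row.names = paste0("x", 1:8)), ~ a),
        class = "bt_data_error")
})

test_that("bonferroniCorrect multiplies, clips, flags, and validates", {
    out <- bonferroniCorrect(c(0.01, 0.5, 0.2, 0.03))
    expect_equal(out$adjusted, c(0.04, 1, 0.8, 0.12))
    expect_equal(out$significant, c(TRUE, FALSE, FALSE, FALSE))
    expect_equal(bonferroniCorrect(0.04)$adjusted, 0.04)  # m = 1 is identity
    expect_error(bonferroniCorrect(c(0.5, 1.2)), class = "bt_data_error")
    withNA <- bonferroniCorrect(c(0.01, NA))
    expect_equal(withNA$adjusted, c(0.02, NA))
    expect_equal(withNA$significant, c(TRUE, FALSE))
})

test_that("fitLme recovers a fixed effect on patient-structured balances", {
    set.seed(404)
    nPat <- 16
    ph <- seq(5, 8.5, by = 0.5)
    beta <- 0.6
    pat <- rep(sprintf("P%02d", 1:nPat), each = length(ph))
    phv <- rep(ph, nPat)
    gamma <- stats::rnorm(nPat, sd = 1.5)
    y0 <- gamma[as.integer(factor(pat))] + beta * phv +
        stats::rnorm(length(phv), sd = 0.4)
    y1 <- stats::rnorm(length(phv), sd = 0.4)      # null balance
    bal <- mkBalances(cbind(y0, y1), nodes = c("y0", "y1"))
    cov <- data.frame(ph = phv, patient = pat, row.names = sampleIds(bal))

    fit <- fitLme(bal, cov, ~ ph, grouping = "patient")
    cf <- coefTable(fit)
    est <- cf$estimate[cf$term == "ph" & cf$node == "y0"]
    se <- cf$stderr[cf$term == "ph" & cf$node == "y0"]
    expect_lt(abs(est - beta), 3 * se)
    expect_true(cf$significant[cf$term == "ph" & cf$node == "y0"])
    expect_equal(fit@grouping, "patient")
    expect_true(is.na(globalR2(fit)))

    # adjusted p-values dominate raw ones and are clipped at 1
    expect_true(all(cf$padj >= cf$pvalue - 1e-12, na.rm = TRUE))
    expect_true(all(cf$padj <= 1, na.rm = TRUE))
})

test_that("fitLme matches OLS when the random-effect variance is zero", {
    set.seed(55)
    # identical data replicated across groups: between-group variance is
    # exactly zero, so the mixed model collapses to OLS at the boundary
    ph0 <- stats::runif(20, 5, 8.5)
    y0 <- 1 + 0.5 * ph0 + stats::rnorm(20, sd = 0.3)
    ph <- rep(ph0, 3)
    grp <- rep(c("a", "b", "c"), each = 20)
    Y <- cbind(rep(y0, 3))
    bal <- mkBalances(Y)
    cov <- data.frame(ph = ph, g = grp, row.names = sampleIds(bal))
    lme <- suppressMessages(fitLme(bal, cov, ~ ph, grouping = "g"))
    ols <- fitOls(bal, cov, ~ ph)
    estL <- coefTable(lme)$estimate[coefTable(lme)$term == "ph"]
    estO <- coefTable(ols)$estimate[coefTable(ols)$term == "ph"]
    expect_lt(abs(estL - estO), 1e-6)
})

test_that("fitLme refuses single-group data and reports the OLS alternative", {
    bal <- mkBalances(cbind(rnorm(6)))
    cov <- data.frame(ph = 1:6, g = "only", row.names = sampleIds(bal))
    err <- expect_error(fitLme(bal, cov, ~ ph, grouping = "g"),
                        class = "bt_data_error")
    expect_match(conditionMessage(err), "fitOls")
})

test_that("predictProportions inverts a saturated noiseless model and the constant model", {
    set.seed(61)
    D <- 5
    tr <- randomBinaryTree(D)
    basis <- buildIlrBasis(tr)
    x <- randomComposition(8, D)
    bal <- ilrTransform(CompositionTable(x), basis)

    # saturated: one indicator per sample reproduces the observations
    cov <- data.frame(s = factor(sampleIds(bal)),
                      row.names = sampleIds(bal))
    fit <- fitOls(bal, cov, ~ 0 + s)
    pred <- predictProportions(fit, cov, basis)
    expect_lt(max(abs(tableValues(pred)[, colnames(x)] - x)), 1e-9)

    # intercept-only: every prediction is the ilr-mean composition
    fit0 <- fitOls(bal, data.frame(z = rep(1, 8),
                                   row.names = sampleIds(bal)), ~ 1)
    pred0 <- predictProportions(fit0,
                                data.frame(z = 1, row.names = "new"), basis)
    meanBal <- matrix(colMeans(tableValues(bal)), 1,
                      dimnames = list("new", nodeNames(bal)))
    ref <- inverseIlr(BalanceTable(meanBal), basis)
    expect_lt(max(abs(tableValues(pred0) - tableValues(ref))), 1e-9)

    expect_error(predictProportions(fit, data.frame(other = 1), basis),
                 class = "bt_data_error")
})

test_that("global R2 is invariant to the tree used for the balances", {
    set.seed(88)
    D <- 10
    x <- randomComposition(30, D)
    ph <- stats::runif(30, 4, 9)
    cov <- data.frame(ph = ph, row.names = rownames(x))
    r2 <- sapply(1:8, function(i) {
        tr <- randomBinaryTree(D)
        bal <- ilrTransform(CompositionTable(x), buildIlrBasis(tr))
        globalR2(fitOls(bal, cov, ~ ph))
    })
    expect_lt(max(r2) - min(r2), 1e-9)
})
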