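.asFormula <- function(formula) {
    f <- if (is.character(formula)) stats::as.formula(formula) else formula
    if (!inherits(f, "formula"))
        btConfigError("formula must be a formula or a character string")
    if (length(f) == 3) f <- f[-2]   # drop any LHS; balances are the response
    f
}

.alignCovariates <- function(balances, covariates) {
    if (!is(balances, "BalanceTable"))
        btConfigError("balances must be a BalanceTable")
    covariates <- as.data.frame(covariates)
    ids <- sampleIds(balances)
    if (!is.null(rownames(covariates)) &&
        !all(rownames(covariates) == as.character(seq_len(nrow(covariates))))) {
        miss <- setdiff(ids, rownames(covariates))
        if (length(miss))
            btDataError("covariates missing for sample(s): %s", .fmtIds(miss))
        covariates <- covariates[ids, , drop = FALSE]
    } else if (nrow(covariates) != length(ids)) {
        btDataError("covariate rows (%d) do not match samples (%d)",
                    nrow(covariates), length(ids))
    }
    covariates
}

.designMatrix <- function(formula, covariates) {
    mf <- tryCatch(stats::model.frame(formula, covariates),
                   error = function(e)
                       btDataError("cannot build design: %s",
                                   conditionMessage(e)))
    X <- stats::model.matrix(formula, mf)
    q <- qr(X)
    if (q$rank < ncol(X)) {
        dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
        btDataError("design matrix is rank deficient; collinear term(s): %s",
                    .fmtIds(dropped))
    }
    X
}

#' Ordinary least squares on every balance
#'
#' Fits the same linear model independently to each balance column against a
#' shared design matrix, and aggregates a global coefficient of
#' determination in balance space: `R2 = 1 - SSE/SST` with `SSE` the sum of
#' squared residuals over all balances and samples and `SST` the total sum
#' of squared deviations of the balances from their column means.  Because
#' the ILR is an isometry, this `R2` does not depend on which bifurcating
#' tree generated the balances.  Per-node p-values for each term are
#' Bonferroni-adjusted across the D-1 internal nodes.
#'
#' @param balances a [BalanceTable-class].
#' @param covariates data.frame of per-sample covariates, rows matched to
#'   samples by row name (or by position when unnamed).
#' @param formula model formula, e.g. `~ ph` (any left-hand side is
#'   ignored; each balance is the response).
#' @param alpha significance level for the Bonferroni flags (default 0.05).
#' @return A [RegressionResult-class].
#' @examples
#' b <- BalanceTable(matrix(rnorm(20), 10,
#'        dimnames = list(paste0("s", 1:10), c("y0", "y1"))))
#' fitOls(b, data.frame(ph = 1:10, row.names = paste0("s", 1:10)), ~ ph)
#' @export
fitOls <- function(balances, covariates, formula, alpha = 0.05) {
    covariates <- .alignCovariates(balances, covariates)
    f <- .asFormula(formula)
    X <- .designMatrix(f, covariates)
    Y <- balances@values
    n <- nrow(Y); p <- ncol(X)
    if (n < p)
        btDataError("need at least as many samples (%d) as design columns (%d)",
                    n, p)

    fit <- stats::lm.fit(X, Y)
    B <- fit$coefficients                       # p x K
    res <- Y - X %*% B
    df <- n - p
    ## saturated designs (df = 0) fit exactly; no error variance, no tests
    sigma2 <- if (df > 0) colSums(res^2) / df else rep(NA_real_, ncol(Y))
    XtXinv <- chol2inv(chol(crossprod(X)))
    seB <- sqrt(outer(diag(XtXinv), sigma2))    # p x K
    tval <- B / seB
    pval <- if (df > 0) 2 * stats::pt(-abs(tval), df = df) else tval * NA_real_

    sse <- sum(res^2)
    sst <- sum(scale(Y, scale = FALSE)^2)
    r2 <- if (sst > 0) 1 - sse / sst else NA_real_

    coefs <- .coefFrame(B, seB, pval, nodes = colnames(Y),
                        terms = colnames(X), alpha = alpha)
    new("RegressionResult",
        model = "ols",
        formula = deparse(f),
        grouping = NA_character_,
        coefficients = coefs,
        r2 = r2,
        alpha = alpha,
        fitted = BalanceTable(Y - res),
        residuals = BalanceTable(res),
        converged = stats::setNames(rep(TRUE, ncol(Y)), colnames(Y)))
}

.coefFrame <- function(B, seB, pval, nodes, terms, alpha) {
    out <- data.frame(
        node = rep(nodes, each = length(terms)),
        term = rep(terms, times = length(nodes)),
        estimate = as.vector(B),
        stderr = as.vector(seB),
        pvalue = as.vector(pval),
        stringsAsFactors = FALSE
    )
    ## multiple-testing family = the internal nodes tested, per term
    out$padj <- NA_real_
    out$significant <- NA
    for (tm in terms) {
        sel <- out$term == tm
        adj <- bonferroniCorrect(out$pvalue[sel], alpha = alpha)
        out$padj[sel] <- adj$adjusted
        out$significant[sel] <- adj$significant
    }
    out
}

#' Bonferroni correction
#'
#' Family-wise error control: `adjusted = min(1, p * m)` with `m` the number
#' of tests, flagged significant when the adjusted value falls below
#' `alpha`.  `NA` p-values (e.g. non-convergent mixed fits) stay `NA` but
#' still count toward `m`.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]` (NA allowed).
#' @param alpha significance level (default 0.05).
#' @return `list(adjusted = <numeric>, significant = <logical>)`.
#' @examples
#' bonferroniCorrect(c(0.01, 0.5, 0.03))
#' @export
bonferroniCorrect <- function(pvalues, alpha = 0.05) {
    if (!is.numeric(pvalues))
        btConfigError("pvalues must be numeric")
    ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
    if (!all(ok))
        btDataError("p-values outside [0, 1]: %s",
                    .fmtIds(format(pvalues[!ok])))
    adjusted <- pmin(1, pvalues * length(pvalues))
    list(adjusted = adjusted, significant = !is.na(adjusted) & adjusted < alpha)
}

#' Linear mixed-effects model on every balance
#'
#' Fits, per balance, a linear mixed model with the fixed effects of
#' `formula` and a random intercept per level of `grouping` (REML via
#' lme4).  This tests for gradient effects while absorbing baseline
#' differences between groups (e.g. patients with idiosyncratic
#' microbiomes).  Fixed-effect p-values are Wald normal-approximation
#' p-values; per-node fits that fail or do not converge are flagged and get
#' missing p-values rather than aborting the run.
#'
#' @inheritParams fitOls
#' @param grouping name of the covariate column defining the random
#'   intercept groups (>= 2 levels required).
#' @return A [RegressionResult-class] with `r2 = NA` (not defined for mixed
#'   models here) and a per-node `converged` flag.
#' @export
fitLme <- function(balances, covariates, formula, grouping, alpha = 0.05) {
    covariates <- .alignCovariates(balances, covariates)
    if (!is.character(grouping) || length(grouping) != 1 ||
        !grouping %in% names(covariates))
        btConfigError("grouping must name a covariate column")
    grp <- factor(covariates[[grouping]])
    if (nlevels(grp) < 2)
        btDataError("grouping '%s' has a single level; use fitOls() instead",
                    grouping)
    if (any(table(grp) < 2))
        btDataError("every group needs >= 2 observations; too small: %s",
                    .fmtIds(names(which(table(grp) < 2))))
    f <- .asFormula(formula)
    fixedTerms <- colnames(.designMatrix(f, covariates))
    full <- stats::as.formula(paste(
        ".balance", "~", paste(deparse(f[[2]]), collapse = " "),
        "+ (1 |", grouping, ")"))

    Y <- balances@values
    nodes <- colnames(Y)
    K <- length(nodes); P <- length(fixedTerms)
    est <- se <- pv <- matrix(NA_real_, nrow = P, ncol = K,
                              dimnames = list(fixedTerms, nodes))
    fitted <- resid <- matrix(NA_real_, nrow(Y), K, dimnames = dimnames(Y))
    converged <- stats::setNames(rep(FALSE, K), nodes)

    dat <- covariates
    for (k in seq_len(K)) {
        dat$.balance <- Y[, k]
        warned <- FALSE
        m <- withCallingHandlers(
            tryCatch(lme4::lmer(full, data = dat, REML = TRUE),
                     error = function(e) NULL),
            warning = function(w) {
                warned <<- TRUE
                invokeRestart("muffleWarning")
            })
        if (is.null(m)) next
        cc <- as.matrix(stats::coef(summary(m)))
        rows <- match(fixedTerms, rownames(cc))
        est[, k] <- cc[rows, "Estimate"]
        se[, k] <- cc[rows, "Std. Error"]
        fitted[, k] <- stats::fitted(m)
        resid[, k] <- Y[, k] - fitted[, k]
        bad <- length(m@optinfo$conv$lme4$messages) > 0 || warned
        converged[k] <- !bad
        ## non-convergent fits keep estimates but report no p-value
        if (!bad) pv[, k] <- 2 * stats::pnorm(-abs(cc[rows, "t value"]))
    }

    coefs <- .coefFrame(est, se, pv, nodes = nodes, terms = fixedTerms,
                        alpha = alpha)
    new("RegressionResult",
        model = "lme",
        formula = deparse(f),
        grouping = grouping,
        coefficients = coefs,
        r2 = NA_real_,
        alpha = alpha,
        fitted = BalanceTable(.naToZero(fitted)),
        residuals = BalanceTable(.naToZero(resid)),
        converged = converged)
}

.naToZero <- function(m) { m[!is.finite(m)] <- 0; m }

#' Predict community proportions from covariates
#'
#' Evaluates the fitted per-balance linear predictor (fixed effects only for
#' mixed models) at new covariate values and maps the predicted balances
#' back to the simplex with [inverseIlr()], yielding predicted proportions
#' that sum to one per sample.
#'
#' @param result a [RegressionResult-class] from [fitOls()] or [fitLme()].
#' @param newCovariates data.frame of covariates covering every model term.
#' @param basis the [OrthonormalBasis-class] that generated the balances.
#' @return A closed [CompositionTable-class] of predicted proportions.
#' @export
predictProportions <- function(result, newCovariates, basis) {
    if (!is(result, "RegressionResult"))
        btConfigError("result must be a RegressionResult")
    if (!is(basis, "OrthonormalBasis"))
        btConfigError("basis must be an OrthonormalBasis")
    f <- stats::as.formula(result@formula)
    newCovariates <- as.data.frame(newCovariates)
    vars <- all.vars(f)
    miss <- setdiff(vars, names(newCovariates))
    if (length(miss))
        btDataError("missing covariate(s): %s", .fmtIds(miss))
    X <- stats::model.matrix(f, stats::model.frame(f, newCovariates))

    cf <- result@coefficients
    terms <- unique(cf$term)
    nodes <- unique(cf$node)
    B <- matrix(NA_real_, length(terms), length(nodes),
                dimnames = list(terms, nodes))
    B[cbind(match(cf$term, terms), match(cf$node, nodes))] <- cf$estimate
    if (!setequal(colnames(X), terms))
        btDataError("design terms changed between fit and prediction: {%s} vs {%s}",
                    .fmtIds(colnames(X)), .fmtIds(terms))
    pred <- X[, terms, drop = FALSE] %*% B
    rownames(pred) <- rownames(newCovariates) %||%
        paste0("P", seq_len(nrow(pred)))
    inverseIlr(BalanceTable(pred), basis)
}
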