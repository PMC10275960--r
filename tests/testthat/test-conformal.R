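test_that("margin nonconformity reduces to 1 - P(y) for two classes", {
    expect_equal(marginNonconformity(c(RRMS = 0.2, PMS = 0.8), "PMS"), 0.2)
    expect_equal(marginNonconformity(c(RRMS = 0.2, PMS = 0.8), "RRMS"), 0.8)
    expect_equal(marginNonconformity(c(RRMS = 0.5, PMS = 0.5), "PMS"), 0.5)
    expect_equal(marginNonconformity(c(RRMS = 0.5, PMS = 0.5), "RRMS"), 0.5)
    set.seed(6)
    p1 <- runif(1e4)
    P <- cbind(RRMS = p1, PMS = 1 - p1)
    y <- sample(c("RRMS", "PMS"), 1e4, replace = TRUE)
    a <- marginNonconformity(P, y)
    expect_lt(max(abs(a - (1 - P[cbind(seq_len(1e4), match(y, colnames(P)))]))),
              1e-12)
    expect_error(marginNonconformity(c(RRMS = 0.3, PMS = 0.8), "PMS"),
                 "sum to 1")
})

test_that("Mondrian p-value counting matches the rank definition", {
    ## class scores including the test sample {0.1, 0.4, 0.4(test)}
    expect_equal(mondrianPvalue(c(0.1, 0.4, 0.4), 0.4), 2 / 3)
    ## strictly largest among m+1 members -> 1/(m+1); smallest -> 1
    expect_equal(mondrianPvalue(c(0.1, 0.2, 0.3, 0.9), 0.9), 1 / 4)
    expect_equal(mondrianPvalue(c(0.5, 0.2, 0.3, 0.1), 0.1), 1)
    ## invariant to strictly increasing transforms of the scores
    set.seed(9)
    for (r in 1:50) {
        a <- runif(12)
        a[12] <- a[sample(11, 1)]   # force an occasional tie
        f <- function(z) exp(3 * z) + z   # strictly increasing
        expect_identical(mondrianPvalue(a, a[12]),
                         mondrianPvalue(f(a), f(a[12])))
        u <- runif(1)
        expect_equal(mondrianPvalue(a, a[12], smoothing = TRUE, u = u),
                     mondrianPvalue(f(a), f(a[12]), smoothing = TRUE, u = u))
    }
})

test_that("transductive p-values are deterministic, bounded and class-aware", {
    set.seed(14)
    tr <- gaussTwoClass(40, shift = 1.5); te <- gaussTwoClass(12, shift = 1.5)
    spec <- classifierSpec("radial", cost = 1, gamma = 0.2, seed = 5)
    pv1 <- tcpPvalues(tr$X, tr$y, te$X, spec, seed = 2)
    pv2 <- tcpPvalues(tr$X, tr$y, te$X, spec, seed = 2)
    expect_identical(pvalueMatrix(pv1), pvalueMatrix(pv2))
    p <- pvalueMatrix(pv1)
    expect_true(all(p > 0 & p <= 1))
    ## strongly separated data: the true class gets the larger p-value for
    ## the bulk of the samples
    expect_gte(mean(ifelse(te$y == "PMS", p[, "PMS"] > p[, "RRMS"],
                           p[, "RRMS"] > p[, "PMS"])), 0.75)
    expect_error(tcpPvalues(tr$X, rep("PMS", 40), te$X, spec), "zero")
})

test_that("prediction sets follow the p > epsilon rule", {
    pv <- new("ConformalPValues",
              pvalues = S4Vectors::DataFrame(
                  p_RRMS = c(0.50, 0.20, 0.01),
                  p_PMS = c(0.03, 0.20, 0.02),
                  row.names = paste0("s", 1:3)),
              smoothed = FALSE, classes = c("RRMS", "PMS"))
    ps <- predictionSets(pv, 0.06)
    expect_identical(ps$kind, c("single", "double", "empty"))
    expect_identical(ps$labels[1], "RRMS")
    ps2 <- predictionSets(pv, 0.05)
    expect_identical(ps2$kind[2], "double")
})

test_that("efficiency and calibration curves are coherent", {
    pv <- new("ConformalPValues",
              pvalues = S4Vectors::DataFrame(
                  p_RRMS = c(0.5, 0.4, 0.02),
                  p_PMS = c(0.03, 0.2, 0.01)),
              smoothed = FALSE, classes = c("RRMS", "PMS"))
    eff <- efficiencyCurve(pv, epsilon_grid = 0.05)
    expect_equal(unlist(eff$curve[, c("empty", "single", "double")]),
                 c(empty = 1, single = 1, double = 1) / 3)
    ## epsilon below every p-value: all sets are double
    eff2 <- efficiencyCurve(pv, epsilon_grid = 0.005)
    expect_equal(eff2$curve$double, 1)
    ## smallest epsilon attaining the single-label maximum wins
    ## single fractions 0.2 / 0.8 / 0.8 over the grid: the smallest epsilon
    ## attaining the maximum wins
    pvals <- new("ConformalPValues",
                 pvalues = S4Vectors::DataFrame(
                     p_RRMS = c(0.9, 0.9, 0.9, 0.9, 0.9),
                     p_PMS = c(0.005, 0.03, 0.04, 0.05, 0.90)),
                 smoothed = FALSE, classes = c("RRMS", "PMS"))
    eff3 <- efficiencyCurve(pvals, epsilon_grid = c(0.01, 0.06, 0.10))
    expect_equal(eff3$curve$single, c(0.2, 0.8, 0.8))
    expect_equal(eff3$peak_single_epsilon, 0.06)
    ## calibration curve is the ECDF of true-label p-values
    truth <- c("RRMS", "PMS", "PMS")
    cc <- calibrationCurve(pv, truth, epsilon_grid = c(0, 0.05, 0.5))
    expect_equal(cc$error_overall, c(0, 1 / 3, 1))
    expect_equal(cc$error_overall,
                 ecdf(c(0.5, 0.2, 0.01))(c(0, 0.05, 0.5)))
})

test_that("prediction sets are nested and fractions always sum to one", {
    set.seed(4)
    tr <- gaussTwoClass(40); te <- gaussTwoClass(15)
    pv <- tcpPvalues(tr$X, tr$y, te$X,
                     classifierSpec("radial", 1, 0.2, seed = 1))
    grid <- sort(runif(12, 0.01, 0.5))
    prev <- NULL
    for (eps in grid) {
        ps <- predictionSets(pv, eps)
        m <- as.matrix(ps[, c("RRMS", "PMS")])
        if (!is.null(prev)) expect_true(all(m <= prev))  # shrinking sets
        prev <- m
    }
    eff <- efficiencyCurve(pv, grid)
    expect_equal(eff$curve$empty + eff$curve$single + eff$curve$double,
                 rep(1, length(grid)))
    expect_true(all(diff(eff$curve$empty) >= 0))
    expect_true(all(diff(eff$curve$double) <= 0))
})

test_that("grid search selects a separating spec and breaks ties by cost", {
    set.seed(99)
    ## well separated blobs: chosen spec reaches LOOCV accuracy 1
    n <- 40
    y <- rep(c("RRMS", "PMS"), each = n / 2)
    X <- matrix(rnorm(n * 2, 0, 0.3), n) +
        outer(as.integer(y == "PMS"), c(4, 4))
    cfg <- pipelineConfig(n_cost = 4, n_gamma = 3,
                          cost_log2_min = -2, cost_log2_max = 4,
                          gamma_log2_min = -6, gamma_log2_max = 0)
    spec <- gridSearchHyperparams(X, y, cfg, seed = 1)
    expect_s4_class(spec, "ClassifierSpec")
    fit <- e1071::svm(X, factor(y), kernel = spec@kernel, cost = spec@cost,
                      gamma = spec@gamma, scale = FALSE, cross = n)
    expect_equal(fit$tot.accuracy, 100)
    ## ties break toward the smaller cost, then smaller gamma: on perfectly
    ## separable blobs the smallest cost attaining accuracy 1 is returned
    expect_equal(spec@cost, min(2^seq(-2, 4, length.out = 4))
                 , tolerance = 1e-9)
})

test_that("leave-patient-out monitoring isolates the evaluated patient", {
    set.seed(41)
    n <- 30
    y <- rep(c("RRMS", "PMS"), each = n / 2)
    X <- matrix(rnorm(n * 3), n) + outer(as.integer(y == "PMS"), rep(1, 3))
    subj <- paste0("P", seq_len(n))
    spec <- classifierSpec("radial", 1, 1 / 3, seed = 2)
    ## plant an extreme outlier as the held-out patient's baseline: if it
    ## leaked into training it would dominate its own calibration class
    X[5, ] <- 50
    pv <- looPatientMonitor(X, y, subj, X[5, , drop = FALSE], "P5", spec)
    p <- pvalueMatrix(pv)
    expect_true(all(p > 0 & p <= 1))
    ## against a training set that never saw it, the outlier is highly
    ## nonconforming for its own class
    expect_lte(p[1, "RRMS"], 0.2)
    expect_error(looPatientMonitor(X, y, subj, X[5, , drop = FALSE], "nope",
                                   spec), "absent")
})

test_that("per-class conformal validity holds on exchangeable data", {
    ## compact Monte-Carlo validity check; the acceptance suite runs the
    ## full-scale version
    set.seed(30)
    errs <- replicate(6, {
        tr <- gaussTwoClass(60); te <- gaussTwoClass(60)
        pv <- tcpPvalues(tr$X, tr$y, te$X,
                         classifierSpec("radial", 1, 0.2, seed = 3),
                         smoothing = TRUE, seed = sample.int(1e6, 1))
        p <- pvalueMatrix(pv)
        pt <- p[cbind(seq_along(te$y), match(te$y, c("RRMS", "PMS")))]
        vapply(c(0.1, 0.2), function(e) mean(pt <= e), numeric(1))
    })
    m <- rowMeans(errs)
    n_tot <- 6 * 60
    expect_lte(m[1], 0.1 + 2 * sqrt(0.1 * 0.9 / n_tot) + 0.02)
    expect_lte(m[2], 0.2 + 2 * sqrt(0.2 * 0.8 / n_tot) + 0.02)
})
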