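test_that("PCA follows the SVD with the positive-loading sign convention", {
    ## two points on axis 1: PC1 along axis 1, scores +-1
    X <- rbind(c(-1, 0), c(1, 0))
    m <- pcaFit(X, n_components = 1)
    expect_equal(abs(m$loadings[, 1]), c(1, 0))
    expect_gt(m$loadings[1, 1], 0)    # sign fixed
    expect_equal(sort(m$scores[, 1]), c(-1, 1))
    set.seed(17)
    X2 <- matrix(rnorm(100), 20, 5)
    m2 <- pcaFit(X2, 3)
    expect_equal(crossprod(m2$loadings), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_lte(sum(m2$explained), 1)
    ## projecting the training rows reproduces the training scores
    expect_equal(pcaProject(m2, X2), m2$scores, tolerance = 1e-9)
    expect_error(pcaFit(X2, 6), "rank")
})

test_that("projection is affine-consistent and dimension-checked", {
    set.seed(18)
    X <- matrix(rnorm(60), 12, 5)
    m <- pcaFit(X, 2)
    expect_equal(unname(pcaProject(m, matrix(m$center, 1))[1, ]), c(0, 0),
                 tolerance = 1e-12)
    a <- rnorm(5); b <- rnorm(5)
    lhs <- pcaProject(m, matrix(a + b, 1))
    rhs <- pcaProject(m, matrix(a, 1)) + pcaProject(m, matrix(b, 1)) -
        pcaProject(m, matrix(rep(0, 5), 1))
    expect_equal(lhs, rhs, tolerance = 1e-12)
    expect_error(pcaProject(m, matrix(0, 1, 3)), "mismatch")
})

test_that("ANOSIM attains its boundary values and permutation p is honest", {
    ## complete separation: all between-distances exceed all within
    X <- rbind(matrix(rnorm(10, 0, 0.01), 5, 2),
               matrix(rnorm(10, 100, 0.01), 5, 2))
    g <- rep(c("a", "b"), each = 5)
    res <- anosimTest(X, g, n_perm = 99, seed = 1)
    expect_equal(res$R, 1)
    expect_lte(res$p, 0.05)
    expect_true(res$R >= -1 && res$R <= 1)
    expect_error(anosimTest(X, rep("a", 10)), "2 groups")
    ## full-enumeration oracle at n = 3 + 3: exact p over all 20 label
    ## assignments vs the permutation estimate
    set.seed(77)
    X6 <- matrix(rnorm(12), 6, 2)
    g6 <- rep(c("a", "b"), each = 3)
    d6 <- dist(X6)
    rk <- rank(as.vector(d6))
    Rstat <- function(grp) {
        between <- outer(grp, grp, "!=")[lower.tri(matrix(0, 6, 6))]
        (mean(rk[between]) - mean(rk[!between])) / (length(rk) / 2)
    }
    combs <- combn(6, 3)
    Rs <- apply(combs, 2, function(ix) {
        grp <- rep("b", 6); grp[ix] <- "a"; Rstat(grp)
    })
    R_obs <- Rstat(g6)
    p_exact <- mean(Rs >= R_obs - 1e-12)
    res6 <- anosimTest(X6, g6, n_perm = 999, seed = 3)
    expect_equal(res6$R, R_obs, tolerance = 1e-12)
    se <- sqrt(p_exact * (1 - p_exact) / 999)
    expect_lt(abs(res6$p - p_exact), 3 * se + 2 / 999)
})

test_that("ANOSIM permutation p is uniform under label randomization", {
    set.seed(55)
    ps <- replicate(80, {
        X <- matrix(rnorm(24), 12, 2)
        anosimTest(X, sample(rep(c("a", "b"), each = 6)), n_perm = 199,
                   seed = sample.int(1e6, 1))$p
    })
    ## permutation p-values are discrete at 1/200 granularity; the KS p is
    ## approximate there, which is fine for this coarse check
    expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("paired Wilcoxon matches exact enumeration and its conventions", {
    x <- c(2, 4, 6, 8, 10, 12); y <- 1:6    # all differences positive
    expect_equal(pairedWilcoxon(x, y), 2 / 2^6)   # 0.03125
    expect_equal(pairedWilcoxon(x, y), pairedWilcoxon(y, x))  # sign symmetry
    expect_warning(p <- pairedWilcoxon(x, x), "zero")
    expect_equal(p, 1)
})

test_that("Mann-Whitney check matches enumeration and is rank-invariant", {
    a <- c(10, 11, 12, 13); b <- c(1, 2, 3, 4)
    lv <- c(a, b); tr <- rep(c(TRUE, FALSE), each = 4)
    expect_equal(treatmentCheck(lv, tr), 2 / choose(8, 4))   # 2/70
    expect_equal(treatmentCheck(exp(lv), tr), treatmentCheck(lv, tr))
    set.seed(2)
    same <- rnorm(8)
    expect_gt(treatmentCheck(same, tr), 0.5)
    expect_error(treatmentCheck(lv, rep(TRUE, 8)), "nonempty")
})

test_that("sex-adjusted fold change recovers the group contrast", {
    ## balanced design with no sex effect: estimate = difference of means
    g <- rep(c("RRMS", "PMS"), each = 10)
    sx <- rep(c("F", "M"), 10)
    set.seed(21)
    lv <- 10 + 0.7 * (g == "PMS") + rnorm(20, 0, 0.001)
    r <- adjustedLog2fc(lv, g, sx)
    expect_equal(r$estimate, mean(lv[g == "PMS"]) - mean(lv[g == "RRMS"]),
                 tolerance = 1e-9)
    ## sex-confounded effect: the adjusted estimate stays near truth
    cover <- replicate(60, {
        g2 <- rep(c("RRMS", "PMS"), each = 20)
        sx2 <- ifelse(runif(40) < ifelse(g2 == "PMS", 0.7, 0.3), "M", "F")
        lv2 <- 10 + 0.5 * (g2 == "PMS") + 0.8 * (sx2 == "M") + rnorm(40, 0, 0.3)
        fit <- lm(lv2 ~ factor(g2, c("RRMS", "PMS")) + factor(sx2))
        ci <- confint(fit, level = 0.99)[2, ]
        est <- adjustedLog2fc(lv2, g2, sx2)$estimate
        c(est >= ci[1] - 1e-9 && est <= ci[2] + 1e-9,
          0.5 >= ci[1] && 0.5 <= ci[2])
    })
    expect_true(all(cover[1, ]))          # same estimator as the lm oracle
    expect_gte(mean(cover[2, ]), 0.95)    # and the CI covers the truth
    skip_if_not_installed("emmeans")
    ## the estimate equals the marginal-means contrast
    g2 <- rep(c("RRMS", "PMS"), each = 10); sx2 <- rep(c("F", "M"), 10)
    lv2 <- rnorm(20)
    fit <- lm(lv2 ~ g + s, data = data.frame(lv2 = lv2,
                                             g = factor(g2, c("RRMS", "PMS")),
                                             s = factor(sx2)))
    em <- emmeans::emmeans(fit, "g")
    ctr <- as.data.frame(emmeans::contrast(em, list(d = c(-1, 1))))
    expect_equal(adjustedLog2fc(lv2, g2, sx2)$estimate, ctr$estimate,
                 tolerance = 1e-9)
})

test_that("multilevel association recovers sign and strength conventions", {
    set.seed(33)
    n_pat <- 16; visits <- c(0, 6, 12)
    pat <- rep(paste0("P", 1:n_pat), each = length(visits))
    tm <- rep(visits, n_pat)
    sx <- rep(sample(c("F", "M"), n_pat, replace = TRUE), each = length(visits))
    u <- rep(rnorm(n_pat, 0, 0.5), each = length(visits))
    clin <- rnorm(length(pat), 5, 1)
    lv <- 2 + 0.8 * clin + 0.01 * tm + u + rnorm(length(pat), 0, 0.3)
    r <- clinicalAssociation(lv, clin, tm, sx, pat)
    expect_true(r$converged)
    expect_equal(r$estimate, 0.8, tolerance = 0.25)
    expect_equal(abs(r$strength), -log10(r$p), tolerance = 1e-12)
    expect_gt(r$strength, 0)
    ## sign convention: a negative coefficient flips the strength
    r2 <- clinicalAssociation(-lv, clin, tm, sx, pat)
    expect_lt(r2$strength, 0)
    ## null coefficient: strength is small for most replications
    nulls <- replicate(30, {
        lv0 <- 2 + u + rnorm(length(pat), 0, 0.3)
        clinicalAssociation(lv0, clin, tm, sx, pat)$strength
    })
    expect_gte(mean(abs(nulls) < 2, na.rm = TRUE), 0.80)
})

test_that("Spearman clustering groups monotone-equivalent rows first", {
    base <- c(1, 3, 2, 5, 4, 6)
    strength <- rbind(a = base,
                      b = base^3,               # strictly increasing transform
                      c = rev(base),
                      d = rev(base) * 2 - 1)
    res <- spearmanHclust(strength)
    hm <- res$hclust$merge
    ## the first merge joins the two distance-zero pairs (a,b) or (c,d)
    first <- sort(abs(hm[1, ]))
    expect_true(identical(rownames(strength)[first], c("a", "b")) ||
                identical(rownames(strength)[first], c("c", "d")))
    ## block structure: the two pairs end up adjacent in the leaf order
    ord <- res$order
    expect_true(abs(match("a", ord) - match("b", ord)) == 1)
    expect_true(abs(match("c", ord) - match("d", ord)) == 1)
    ## a constant row is placed last and flagged
    res2 <- spearmanHclust(rbind(strength, e = rep(1, 6)))
    expect_identical(res2$flagged, "e")
    expect_identical(res2$order[5], "e")
})

test_that("projected treated samples drift toward the RRMS group over PC1", {
    shifts <- vapply(1:5, function(s) {
        sim <- generateLongitudinal(generateCohorts(synthConfig(seed = 400 + s)))
        h <- harmonizeSim(sim)
        sel <- selectSignature(h, pipelineConfig(seed = s))
        fids <- signatureFeatures(sel$signature)
        if (length(fids) < 2) return(NA_real_)
        tr <- patientMatrix(h, cohort = 1)
        pca <- pcaFit(tr$X[, fids, drop = FALSE], 2)
        fu <- followupMatrix(h, sim$longitudinal)
        metaL <- injectionMeta(sim$longitudinal)
        m12 <- which(metaL$timepoint_months == 12)
        sc12 <- pcaProject(pca, fu[m12, fids, drop = FALSE])
        rrms_mean <- mean(pca$scores[tr$y == "RRMS", 1])
        pms_mean <- mean(pca$scores[tr$y == "PMS", 1])
        base_cols <- tr$y == "PMS" &
            tr$subjects %in% metaL$subject_id
        base_mean <- mean(pca$scores[base_cols, 1])
        ## signed progress from the PMS toward the RRMS centroid
        (base_mean - mean(sc12[, 1])) / (base_mean - rrms_mean)
    }, numeric(1))
    expect_gte(mean(shifts > 0.2, na.rm = TRUE), 0.8)
})
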