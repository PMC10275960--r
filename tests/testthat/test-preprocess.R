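# fixture: nf features x (2 qc + 1 blank + n dilution + n study) injections;
# `vals` covers the dilution (+ study) columns, QC/blank filled as benign
preprocFixture <- function(vals, n_qc = 2, n_blank = 1, vols = numeric(),
                           n_study = 0) {
    st <- c(rep("qc", n_qc), rep("blank", n_blank),
            rep("dilution", length(vols)), rep("study", n_study))
    dv <- c(rep(NA, n_qc + n_blank), vols, rep(NA, n_study))
    if (ncol(vals) == length(vols) + n_study) {
        pad <- matrix(rep(c(1000, 1), c(n_qc, n_blank) * nrow(vals)),
                      nrow(vals))
        vals <- cbind(pad, vals)
    }
    tinyExperiment(vals, sample_type = st, dilution_volume = dv)
}

test_that("blank-ratio rule removes contaminants with a >= boundary", {
    ## rows: contaminant (blank == qc), boundary (exactly 10x), clean,
    ## absent-in-blanks
    vals <- rbind(
        cont = c(100, 100, 100),
        boundary = c(100, 100, 10),
        clean = c(1000, 1000, 10),
        absent = c(500, 500, NA))
    x <- preprocFixture(vals, n_qc = 2, n_blank = 1)
    out <- removeBlankContaminants(x, ratio_min = 10)
    expect_setequal(rownames(out), c("boundary", "clean", "absent"))
    log <- preprocessLog(out)
    expect_identical(log$feature_id[log$stage == "blank_filter"], "cont")
    ## QC injections are required for the ratio
    x2 <- preprocFixture(vals, n_qc = 0, n_blank = 1)
    expect_error(removeBlankContaminants(x2), "QC")
})

test_that("dilution filter keeps positively correlated features only", {
    vols <- c(0.5, 1, 2, 4, 8, 16)
    vals <- rbind(prop = vols * 100,       # r = 1
                  constant = rep(5, 6),
                  anti = rev(vols) * 100)  # strongly negative r
    x <- preprocFixture(vals, vols = vols)
    out <- filterByDilution(x, p_max = 0.05)
    expect_identical(rownames(out), "prop")
    expect_error(filterByDilution(preprocFixture(vals[, 1:2, drop = FALSE],
                                                 vols = vols[1:2])),
                 "3 dilution")
})

test_that("dilution keep decision matches the t-distribution critical value", {
    ## N = 6: two-sided 5% critical r = sqrt(t^2/(t^2+4)), t = qt(.975, 4)
    tcrit <- qt(0.975, df = 4)
    rcrit <- sqrt(tcrit^2 / (tcrit^2 + 4))
    expect_equal(rcrit, 0.811, tolerance = 1e-3)
    vols <- c(0.5, 1, 2, 4, 8, 16)
    set.seed(42)
    for (r_target in c(0.70, 0.78, 0.83, 0.90, -0.9)) {
        y <- vectorWithCorrelation(vols, r_target) + 10
        x <- preprocFixture(matrix(y, 1, dimnames = list("f", NULL)),
                            vols = vols)
        kept <- nrow(filterByDilution(x)) == 1
        expect_identical(kept, r_target > 0 && abs(r_target) > rcrit,
                         info = paste("r =", r_target))
    }
})

test_that("log2 transform is exact and reversible, errors name the cell", {
    vals <- matrix(c(8, 1, 2, 1024), 2,
                   dimnames = list(c("A", "B"), c("I1", "I2")))
    x <- tinyExperiment(vals)
    lx <- log2Transform(x)
    expect_identical(intensityScale(lx), "log2")
    expect_equal(SummarizedExperiment::assay(lx),
                 matrix(c(3, 0, 1, 10), 2,
                        dimnames = dimnames(vals)))
    back <- 2^SummarizedExperiment::assay(lx)
    expect_equal(back, vals, tolerance = 1e-12)
    vals["A", "I2"] <- 0
    expect_error(log2Transform(tinyExperiment(vals)), "A.*I2")
})

loessFixture <- function(qc_vals, study_vals, qc_orders, study_orders) {
    n <- length(qc_orders) + length(study_orders)
    vals <- matrix(NA_real_, 1, n, dimnames = list("f", NULL))
    st <- character(n)
    st[qc_orders] <- "qc"; st[study_orders] <- "study"
    vals[1, qc_orders] <- qc_vals
    vals[1, study_orders] <- study_vals
    tinyExperiment(vals, sample_type = st, scale = "log2")
}

test_that("LOESS normalization flattens linear drift to the QC mean", {
    qc_orders <- seq(1, 41, by = 5)
    study_orders <- setdiff(1:41, qc_orders)
    drift <- function(o) 10 + 0.05 * o
    x <- loessFixture(drift(qc_orders), drift(study_orders),
                      qc_orders, study_orders)
    out <- loessRunorderNormalize(x, span = 0.5)
    a <- SummarizedExperiment::assay(out)[1, ]
    expect_equal(unname(a[qc_orders]),
                 rep(mean(drift(qc_orders)), length(qc_orders)),
                 tolerance = 1e-6)
    ## study samples are corrected onto the same flat level
    expect_equal(unname(a[study_orders]),
                 rep(mean(drift(qc_orders)), length(study_orders)),
                 tolerance = 1e-6)
})

test_that("LOESS normalization is the identity on drift-free data", {
    qc_orders <- seq(1, 41, by = 5)
    study_orders <- setdiff(1:41, qc_orders)
    set.seed(1)
    study_vals <- rnorm(length(study_orders), 12, 1)
    x <- loessFixture(rep(12, length(qc_orders)), study_vals,
                      qc_orders, study_orders)
    out <- loessRunorderNormalize(x, span = 0.5)
    expect_equal(SummarizedExperiment::assay(out),
                 SummarizedExperiment::assay(x), tolerance = 1e-9)
})

test_that("LOESS removes most of an injected sinusoidal drift and is idempotent", {
    set.seed(7)
    n <- 120
    qc_orders <- seq(1, n, by = 6)
    study_orders <- setdiff(1:n, qc_orders)
    drift <- function(o) sin(2 * pi * o / n) * 1.0
    qc_vals <- 14 + drift(qc_orders) + rnorm(length(qc_orders), 0, 0.1)
    study_vals <- 14 + drift(study_orders) + rnorm(length(study_orders), 0, 0.1)
    x <- loessFixture(qc_vals, study_vals, qc_orders, study_orders)
    out <- loessRunorderNormalize(x, span = 0.2)
    sd_before <- sd(qc_vals)
    sd_after <- sd(SummarizedExperiment::assay(out)[1, qc_orders])
    expect_lt(sd_after, 0.2 * sd_before)
    ## on noisy data a second pass can only chase residual noise
    out2 <- loessRunorderNormalize(out, span = 0.2)
    expect_lt(max(abs(SummarizedExperiment::assay(out2)[1, qc_orders] -
                      SummarizedExperiment::assay(out)[1, qc_orders])), 0.1)
})

test_that("LOESS normalization is idempotent on noise-free drift", {
    qc_orders <- seq(1, 61, by = 4)
    study_orders <- setdiff(1:61, qc_orders)
    drift <- function(o) 12 + 0.03 * o
    x <- loessFixture(drift(qc_orders), drift(study_orders),
                      qc_orders, study_orders)
    out1 <- loessRunorderNormalize(x, span = 0.4)
    out2 <- loessRunorderNormalize(out1, span = 0.4)
    expect_lt(max(abs(SummarizedExperiment::assay(out2) -
                      SummarizedExperiment::assay(out1))), 1e-6)
})

test_that("features with sparse QC coverage pass through flagged", {
    qc_orders <- seq(1, 41, by = 5)
    study_orders <- setdiff(1:41, qc_orders)
    qc_vals <- 10 + 0.05 * qc_orders
    qc_vals[seq_len(length(qc_vals) - 4)] <- NA   # only 4 QC values left
    x <- loessFixture(qc_vals, rep(11, length(study_orders)),
                      qc_orders, study_orders)
    out <- loessRunorderNormalize(x, span = 0.5)
    expect_equal(SummarizedExperiment::assay(out),
                 SummarizedExperiment::assay(x))
    expect_identical(preprocessLog(out)$stage, "loess_normalize")
    expect_identical(preprocessLog(out)$feature_id, "f")
})

test_that("QC CV filter works on de-logged values with a strict cutoff", {
    qcv <- rbind(keep = log2(c(90, 100, 110)),      # CV = 0.10
                 drop = log2(c(50, 100, 150)),      # CV = 0.50
                 boundary = log2(c(80, 100, 120)))  # CV = 0.20 exactly
    x <- tinyExperiment(qcv, sample_type = rep("qc", 3), scale = "log2")
    out <- qcCvFilter(x, cv_max = 0.20)
    expect_identical(rownames(out), "keep")
    log <- preprocessLog(out)
    expect_setequal(log$feature_id, c("drop", "boundary"))
})

test_that("TIC report sums raw intensities and flags gross outliers", {
    x <- tinyExperiment(matrix(c(3, 5, 2, 2), 2, 2, byrow = TRUE,
                               dimnames = list(c("f", "g"), c("I1", "I2"))))
    expect_equal(ticReport(x)$tic, c(5, 7))   # per-injection column sums
    vals <- matrix(rep(10, 40), 2)
    x <- tinyExperiment(vals)
    expect_false(any(ticReport(x)$flagged))
    vals[, 20] <- 1000
    x <- tinyExperiment(vals)
    tr <- ticReport(x)
    expect_identical(which(tr$flagged), 20L)
})

test_that("pipeline order shrinks the feature set monotonically", {
    sim <- generateCohorts(smallSynthConfig(3))
    x <- sim$cohort1
    s1 <- removeBlankContaminants(x)
    s2 <- filterByDilution(s1)
    s3 <- loessRunorderNormalize(log2Transform(s2))
    s4 <- qcCvFilter(s3)
    expect_true(all(rownames(s1) %in% rownames(x)))
    expect_true(all(rownames(s2) %in% rownames(s1)))
    expect_true(all(rownames(s4) %in% rownames(s3)))
    ## contaminants are gone, and few clean features are lost to the blank rule
    cont <- sim$truth$contaminants$feature_id[sim$truth$contaminants$cohort == 1]
    expect_false(any(cont %in% rownames(s1)))
    clean <- setdiff(rownames(x), cont)
    expect_gte(mean(clean %in% rownames(s1)), 0.95)
})
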