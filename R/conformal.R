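#' Transductive Mondrian conformal classification
#'
#' A transductive conformal predictor over a probabilistic binary classifier
#' (support-vector classifier with internal cross-validated sigmoid
#' probability calibration). For every test sample x and every hypothesized
#' phenotype, the classifier is retrained on the training set augmented with
#' (x, hypothesized label); the margin nonconformity score of each example is
#' computed under its own label, and the Mondrian (class-conditional)
#' p-value ranks x's score only among examples of the hypothesized class.
#' High p means high similarity to that phenotype. Applying a significance
#' level epsilon to the pair of p-values yields prediction sets that are
#' empty, single-label or double-label; class-conditional validity holds
#' under exchangeability.
#'
#' @name conformal
NULL

.CP_CLASSES <- c("RRMS", "PMS")

#' Construct a ClassifierSpec
#'
#' @param kernel "linear", "radial", "sigmoid" or "polynomial"
#' @param cost SVM cost parameter (> 0)
#' @param gamma kernel width parameter (> 0; unused by the linear kernel)
#' @param degree polynomial degree
#' @param seed RNG seed for the internal probability-calibration CV
#' @export
classifierSpec <- function(kernel = "radial", cost = 1, gamma = 0.1,
                           degree = 3, seed = 1) {
    new("ClassifierSpec", kernel = kernel, cost = cost, gamma = gamma,
        degree = degree, seed = seed)
}

setMethod("show", "ClassifierSpec", function(object) {
    cat(sprintf("ClassifierSpec: %s kernel, cost = %.4g, gamma = %.4g%s\n",
                object@kernel, object@cost, object@gamma,
                if (object@kernel == "polynomial")
                    sprintf(", degree = %d", as.integer(object@degree)) else ""))
    invisible(NULL)
})

#' Margin nonconformity score
#'
#' For a class-probability vector P and hypothesized class y,
#' alpha = 0.5 - (P(y) - max_{y' != y} P(y')) / 2. For two classes this
#' reduces to 1 - P(y); both routes are implemented and agree to machine
#' precision.
#'
#' @param prob numeric matrix of class probabilities (rows = examples,
#'   named columns), or a single named vector
#' @param y hypothesized class, one per row (recycled if length 1)
#' @return numeric nonconformity scores, one per row
#' @export
marginNonconformity <- function(prob, y) {
    if (is.null(dim(prob))) prob <- matrix(prob, 1,
                                           dimnames = list(NULL, names(prob)))
    if (is.null(colnames(prob))) stopf("probability columns must be named")
    tot <- rowSums(prob)
    if (any(abs(tot - 1) > 1e-6))
        stopf("probabilities must sum to 1 (max deviation %.3g)",
              max(abs(tot - 1)))
    y <- rep_len(as.character(y), nrow(prob))
    vapply(seq_len(nrow(prob)), function(i) {
        p_y <- prob[i, y[i]]
        p_other <- max(prob[i, setdiff(colnames(prob), y[i])])
        0.5 - (p_y - p_other) / 2
    }, numeric(1))
}

## one probabilistic SVM fit + class-probability prediction, RNG-isolated so
## the internal calibration CV is reproducible
.fitPredictProb <- function(X, y, newX, spec) {
    y <- factor(y, levels = .CP_CLASSES)
    fit <- withSeed(spec@seed,
        e1071::svm(X, y, kernel = spec@kernel, cost = spec@cost,
                   gamma = spec@gamma, degree = spec@degree,
                   probability = TRUE, scale = FALSE))
    pr <- stats::predict(fit, newX, probability = TRUE)
    attr(pr, "probabilities")[, .CP_CLASSES, drop = FALSE]
}

#' Mondrian p-value from class-conditional nonconformity scores
#'
#' The rank-based core of the transductive predictor: given the
#' nonconformity scores of every class member of the augmented set
#' (including the hypothetically labeled test example itself) and the test
#' example's score, the unsmoothed p-value is
#' \code{#\{alpha_j >= alpha_x\} / n} with n the class count including the
#' test example, so the numerator is at least 1 and p lies in (0, 1]. With
#' smoothing, scores tied with \code{alpha_x} (again including the test
#' example) contribute through the single uniform weight \code{u}. Being
#' rank-based, the p-value is invariant to any strictly increasing
#' transform of the scores.
#'
#' @param alpha_class nonconformity scores of all class members of the
#'   augmented set (the test example's score among them)
#' @param alpha_x the test example's score
#' @param smoothing logical
#' @param u uniform tie-smoothing weight in [0, 1]
#' @return the p-value in (0, 1]
#' @export
mondrianPvalue <- function(alpha_class, alpha_x, smoothing = FALSE, u = NA) {
    n <- length(alpha_class)
    p <- if (smoothing) {
        (sum(alpha_class > alpha_x) + u * sum(alpha_class == alpha_x)) / n
    } else {
        sum(alpha_class >= alpha_x) / n
    }
    max(p, .Machine$double.eps)   # keep the open-interval invariant
}

#' Transductive Mondrian conformal p-values
#'
#' For each test sample and each hypothesized class, retrains the classifier
#' on the training set augmented with the hypothetically labeled test sample,
#' scores every example's margin nonconformity under its own label, and
#' computes the class-conditional p-value
#' \deqn{p(\hat y) = \#\{j : y_j = \hat y,\ \alpha_j \ge \alpha_x\} / (n_{\hat y} + 1)}
#' where j runs over the augmented set (so the test sample counts itself and
#' the numerator is at least 1). With \code{smoothing = TRUE}, examples tied
#' with the test score contribute through a single U(0,1) draw per
#' (sample, class), making valid p-values exactly uniform under
#' exchangeability.
#'
#' @param train_X,train_y training matrix (samples x features, already on the
#'   training standardization) and labels ("RRMS"/"PMS")
#' @param test_X matrix of samples to evaluate
#' @param spec a \code{\link{classifierSpec}}
#' @param smoothing logical, default FALSE (deterministic p-values)
#' @param seed RNG seed for the smoothing draws
#' @return a \linkS4class{ConformalPValues}
#' @export
tcpPvalues <- function(train_X, train_y, test_X, spec = classifierSpec(),
                       smoothing = FALSE, seed = 1) {
    train_y <- as.character(train_y)
    if (!all(train_y %in% .CP_CLASSES))
        stopf("training labels must be in {RRMS, PMS}")
    n_by_class <- table(factor(train_y, levels = .CP_CLASSES))
    if (any(n_by_class == 0)) stopf("a class has zero training members")
    if (is.null(dim(test_X))) test_X <- matrix(test_X, 1)
    n_test <- nrow(test_X)
    p <- matrix(NA_real_, n_test, 2, dimnames = list(
        rownames(test_X) %||% paste0("s", seq_len(n_test)), .CP_CLASSES))
    n_aug <- nrow(train_X) + 1L
    ## pre-drawn smoothing weights and per-refit row permutations; the
    ## permutation keeps the classifier's internal calibration CV symmetric
    ## in the augmented bag (the hypothetical test example must not occupy a
    ## distinguished position), which the conformal guarantee requires
    draws <- withSeed(seed, list(
        u = matrix(stats::runif(n_test * 2), n_test, 2),
        perms = replicate(n_test * 2, sample.int(n_aug), simplify = FALSE)))
    u <- draws$u
    for (i in seq_len(n_test)) {
        for (ci in seq_along(.CP_CLASSES)) {
            cls <- .CP_CLASSES[ci]
            aug_X <- rbind(train_X, test_X[i, , drop = FALSE])
            aug_y <- c(train_y, cls)
            perm <- draws$perms[[(i - 1L) * 2L + ci]]
            prob <- .fitPredictProb(aug_X[perm, , drop = FALSE], aug_y[perm],
                                    aug_X, spec)
            alpha <- marginNonconformity(prob, aug_y)
            same <- which(aug_y == cls)          # includes the test sample
            p[i, ci] <- mondrianPvalue(alpha[same], alpha[length(aug_y)],
                                       smoothing = smoothing, u = u[i, ci])
        }
    }
    new("ConformalPValues",
        pvalues = DataFrame(p_RRMS = p[, "RRMS"], p_PMS = p[, "PMS"],
                            row.names = rownames(p)),
        smoothed = smoothing, classes = .CP_CLASSES)
}

#' @rdname tcpPvalues
#' @param x a ConformalPValues
#' @return \code{pvalueMatrix}: the numeric matrix of p-values
#'   (samples x classes)
#' @export
pvalueMatrix <- function(x) {
    stopifnot(is(x, "ConformalPValues"))
    m <- cbind(RRMS = x@pvalues$p_RRMS, PMS = x@pvalues$p_PMS)
    rownames(m) <- rownames(x@pvalues)
    m
}

setMethod("show", "ConformalPValues", function(object) {
    cat(sprintf("ConformalPValues: %d samples%s\n", nrow(object@pvalues),
                if (object@smoothed) " (smoothed)" else ""))
    invisible(NULL)
})

#' Prediction sets at a significance level
#'
#' The prediction set at significance epsilon contains every class with
#' p > epsilon; its kind is empty, single or double.
#'
#' @param pvals a ConformalPValues
#' @param epsilon significance level in (0,1)
#' @return data.frame with sample, RRMS/PMS membership, labels, kind
#' @export
predictionSets <- function(pvals, epsilon) {
    stopifnot(epsilon > 0, epsilon < 1)
    p <- pvalueMatrix(pvals)
    inset <- p > epsilon
    kind <- c("empty", "single", "double")[rowSums(inset) + 1L]
    labels <- apply(inset, 1, function(r)
        paste(.CP_CLASSES[r], collapse = "+"))
    data.frame(sample = rownames(p), RRMS = inset[, "RRMS"],
               PMS = inset[, "PMS"], labels = labels, kind = kind,
               row.names = NULL)
}

.epsilonGrid <- function(config = pipelineConfig())
    seq(config$epsilon_min, config$epsilon_max, by = config$epsilon_step)

#' Efficiency curve: prediction-set composition across significance levels
#'
#' Per epsilon, the fractions of empty, single and double prediction sets
#' (always summing to 1); the peak-single epsilon is the smallest epsilon
#' attaining the maximum single-label fraction.
#'
#' @param pvals a ConformalPValues
#' @param epsilon_grid numeric vector of significance levels
#' @return list with \code{curve} (data.frame epsilon/empty/single/double)
#'   and \code{peak_single_epsilon}
#' @export
efficiencyCurve <- function(pvals, epsilon_grid = .epsilonGrid()) {
    p <- pvalueMatrix(pvals)
    if (!nrow(p)) stopf("no samples")
    n <- nrow(p)
    counts <- vapply(epsilon_grid, function(eps) {
        sizes <- rowSums(p > eps)
        c(empty = sum(sizes == 0), single = sum(sizes == 1),
          double = sum(sizes == 2)) / n
    }, numeric(3))
    curve <- data.frame(epsilon = epsilon_grid, empty = counts["empty", ],
                        single = counts["single", ],
                        double = counts["double", ])
    peak <- epsilon_grid[which.max(curve$single)]  # which.max = smallest argmax
    list(curve = curve, peak_single_epsilon = peak)
}

#' Calibration curve: observed error rate across significance levels
#'
#' The error at epsilon is the fraction of samples whose true-label p-value
#' is <= epsilon (the empirical CDF of true-label p-values), reported
#' overall and per true class (the Mondrian view). Validity means the curve
#' stays at or below the diagonal up to finite-sample noise.
#'
#' @param pvals a ConformalPValues
#' @param true_labels character vector of true classes per sample
#' @param epsilon_grid numeric vector of significance levels
#' @return data.frame with epsilon, error_overall, error_RRMS, error_PMS
#' @export
calibrationCurve <- function(pvals, true_labels,
                             epsilon_grid = .epsilonGrid()) {
    p <- pvalueMatrix(pvals)
    true_labels <- as.character(true_labels)
    stopifnot(length(true_labels) == nrow(p))
    p_true <- p[cbind(seq_len(nrow(p)), match(true_labels, .CP_CLASSES))]
    out <- data.frame(epsilon = epsilon_grid)
    out$error_overall <- vapply(epsilon_grid, function(e)
        mean(p_true <= e), numeric(1))
    for (cls in .CP_CLASSES) {
        sel <- true_labels == cls
        out[[paste0("error_", cls)]] <- if (any(sel))
            vapply(epsilon_grid, function(e) mean(p_true[sel] <= e),
                   numeric(1)) else NA_real_
    }
    out
}

.loocvAccuracy <- function(X, y, spec) {
    y <- factor(y, levels = .CP_CLASSES)
    hits <- vapply(seq_len(nrow(X)), function(i) {
        fit <- e1071::svm(X[-i, , drop = FALSE], y[-i], kernel = spec@kernel,
                          cost = spec@cost, gamma = spec@gamma,
                          degree = spec@degree, scale = FALSE)
        as.character(stats::predict(fit, X[i, , drop = FALSE])) ==
            as.character(y[i])
    }, logical(1))
    mean(hits)
}

#' Two-stage hyperparameter grid search with leave-one-out CV
#'
#' Stage 1 screens a small preset parameter set for each of the four kernels
#' (linear: cost in 2^(-3..3); radial/sigmoid: the same costs crossed with
#' gamma in 2^(-7..1) steps of 2^2; polynomial: degrees 2 and 3) by LOOCV
#' accuracy and picks the best kernel. Stage 2 refines that kernel over an
#' \code{n_cost} x \code{n_gamma} log2-spaced (cost, gamma) grid. Ties are
#' broken toward smaller cost, then smaller gamma.
#'
#' @param X standardized training matrix
#' @param y labels ("RRMS"/"PMS")
#' @param config a \code{\link{pipelineConfig}} providing the stage-2 grid
#'   bounds
#' @param seed seed stored in the returned spec (probability calibration)
#' @return the selected \linkS4class{ClassifierSpec}
#' @export
gridSearchHyperparams <- function(X, y, config = pipelineConfig(), seed = 1) {
    y <- as.character(y)
    if (min(table(y)) < 2) stopf("need >= 2 training examples per class")
    costs1 <- 2^seq(-3, 3)
    gammas1 <- 2^seq(-7, 1, by = 2)
    stage1 <- rbind(
        expand.grid(kernel = "linear", cost = costs1, gamma = 1, degree = 3),
        expand.grid(kernel = "radial", cost = costs1, gamma = gammas1, degree = 3),
        expand.grid(kernel = "sigmoid", cost = costs1, gamma = gammas1, degree = 3),
        expand.grid(kernel = "polynomial", cost = 1, gamma = 1 / ncol(X),
                    degree = c(2, 3)))
    evalGrid <- function(grid) {
        acc <- vapply(seq_len(nrow(grid)), function(r) {
            sp <- classifierSpec(as.character(grid$kernel[r]), grid$cost[r],
                                 grid$gamma[r], grid$degree[r], seed)
            .loocvAccuracy(X, y, sp)
        }, numeric(1))
        ## best accuracy; ties toward smaller cost then smaller gamma
        ord <- order(-acc, grid$cost, grid$gamma)
        grid[ord[1], ]
    }
    best1 <- evalGrid(stage1)
    costs2 <- 2^seq(config$cost_log2_min, config$cost_log2_max,
                    length.out = config$n_cost)
    gammas2 <- 2^seq(config$gamma_log2_min, config$gamma_log2_max,
                     length.out = config$n_gamma)
    stage2 <- if (best1$kernel == "linear")
        expand.grid(kernel = "linear", cost = costs2, gamma = 1,
                    degree = best1$degree)
    else
        expand.grid(kernel = as.character(best1$kernel), cost = costs2,
                    gamma = gammas2, degree = best1$degree)
    best2 <- evalGrid(stage2)
    classifierSpec(as.character(best2$kernel), best2$cost, best2$gamma,
                   best2$degree, seed)
}

#' Leave-patient-out conformal monitoring
#'
#' Trains the transductive conformal predictor on all baseline RRMS/PMS
#' samples minus every sample belonging to the evaluated patient, then
#' computes Mondrian p-values for each of the patient's samples (baseline
#' and follow-ups). The held-out patient never contributes to training.
#'
#' @param baseline_X baseline training matrix (samples x features)
#' @param baseline_y baseline labels ("RRMS"/"PMS")
#' @param baseline_subjects subject id per baseline row
#' @param patient_X matrix of the evaluated patient's samples (rows named or
#'   ordered by timepoint)
#' @param patient_id the evaluated patient's subject id; must appear in
#'   \code{baseline_subjects}
#' @param spec a \code{\link{classifierSpec}}
#' @param smoothing,seed passed to \code{\link{tcpPvalues}}
#' @return a \linkS4class{ConformalPValues} for the patient's samples
#' @export
looPatientMonitor <- function(baseline_X, baseline_y, baseline_subjects,
                              patient_X, patient_id, spec = classifierSpec(),
                              smoothing = FALSE, seed = 1) {
    baseline_subjects <- as.character(baseline_subjects)
    if (!patient_id %in% baseline_subjects)
        stopf("patient '%s' absent from the baseline set", patient_id)
    keep <- baseline_subjects != patient_id
    tcpPvalues(baseline_X[keep, , drop = FALSE], baseline_y[keep],
               patient_X, spec, smoothing = smoothing, seed = seed)
}
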