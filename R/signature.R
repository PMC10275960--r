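#' Elastic-net signature selection and validation
#'
#' Discriminatory-feature selection on the training cohort: a binomial
#' elastic-net path (mixing alpha = 0.5) over standardized features, the
#' penalty chosen by balanced k-fold cross-validation (five patients per
#' phenotype per fold by default) with the one-standard-error rule, the
#' signature read off as the features with non-zero coefficients, and
#' validation by scoring the held-out cohort and computing the ROC AUC.
#'
#' @name signature-selection
NULL

#' Balanced cross-validation folds
#'
#' Assigns subjects to \code{k} folds so that each fold receives an equal
#' share of every phenotype: shuffled within class (seeded), the first
#' \code{k * floor(n_class / k)} members are dealt out evenly and the
#' remainder distributed round-robin, so fold class counts differ by at most
#' one. With the study sizes (39 RRMS / 35 PMS, k = 7) every fold holds five
#' PMS patients and five or six RRMS patients.
#'
#' @param labels factor or character vector of per-subject phenotypes
#' @param k number of folds (default 7)
#' @param seed RNG seed for the within-class shuffle
#' @return integer fold assignment in 1..k, same length as \code{labels}
#' @export
makeBalancedFolds <- function(labels, k = 7, seed = 1) {
    labels <- as.character(labels)
    fold <- integer(length(labels))
    withSeed(seed, {
        for (cls in unique(labels)) {
            idx <- which(labels == cls)
            if (length(idx) < k)
                stopf("class '%s' has %d members, fewer than k = %d folds",
                      cls, length(idx), k)
            idx <- sample(idx)
            fold[idx] <- rep_len(seq_len(k), length(idx))
        }
    })
    fold
}

#' Standardize a feature matrix with training parameters
#'
#' @param X numeric matrix, samples x features
#' @param center,scale optional training means/sds; estimated from \code{X}
#'   when omitted
#' @return list with the standardized matrix \code{X} and the parameters
#' @export
standardizeFeatures <- function(X, center = NULL, scale = NULL) {
    if (is.null(center)) center <- colMeans(X)
    if (is.null(scale)) scale <- apply(X, 2, stats::sd)
    if (any(scale <= 0)) stopf("constant feature: standardization sd <= 0")
    Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
    list(X = Xs, center = center, scale = scale)
}

.checkBinaryLabels <- function(y) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("RRMS", "PMS"))
    if (length(bad)) stopf("labels must be RRMS/PMS; got: %s",
                           paste(bad, collapse = ", "))
    if (length(unique(y)) < 2) stopf("degenerate labels: only one class")
    ## fixed encoding: RRMS = 0, PMS = 1
    as.integer(y == "PMS")
}

#' @describeIn signature-selection Fit the binomial elastic-net path at
#'   mixing \code{alpha} over a 100-point lambda grid log-spaced from the
#'   analytic lambda_max (smallest penalty with an all-zero coefficient
#'   vector) down to \code{lambda_min_ratio * lambda_max}. \code{X} must
#'   already be standardized; glmnet's internal standardization is disabled.
#' @param X standardized numeric matrix, samples x features
#' @param y labels ("RRMS"/"PMS" or 0/1 with PMS = 1)
#' @param alpha elastic-net mixing (default 0.5)
#' @param n_lambda grid length (default 100)
#' @param lambda_min_ratio grid floor relative to lambda_max (default 0.01)
#' @export
fitEnetPath <- function(X, y, alpha = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01) {
    yb <- if (is.numeric(y)) {
        if (length(unique(y)) < 2) stopf("degenerate labels: only one class")
        as.integer(y)
    } else .checkBinaryLabels(y)
    fit <- glmnet::glmnet(X, yb, family = "binomial", alpha = alpha,
                          nlambda = n_lambda,
                          lambda.min.ratio = lambda_min_ratio,
                          standardize = FALSE, thresh = 1e-10)
    new("EnetPath", fit = fit, alpha = alpha, lambda = fit$lambda,
        cvm = rep(NA_real_, length(fit$lambda)),
        cvsd = rep(NA_real_, length(fit$lambda)),
        lambda_min = NA_real_, lambda_1se = NA_real_,
        feature_ids = colnames(X) %||% paste0("V", seq_len(ncol(X))))
}

.binomialDeviance <- function(y, p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' @describeIn signature-selection Cross-validate the path over the supplied
#'   balanced folds: per lambda, the mean held-out binomial deviance across
#'   folds and its standard error (sd across folds / sqrt(k));
#'   \code{lambda_min} minimizes the mean deviance and \code{lambda_1se} is
#'   the largest lambda whose mean deviance is within one standard error
#'   (taken at lambda_min) of the minimum.
#' @param folds integer fold assignment from \code{\link{makeBalancedFolds}}
#' @param path an \linkS4class{EnetPath} from \code{fitEnetPath}
#' @export
cvSelectLambda <- function(X, y, folds, path) {
    stopifnot(is(path, "EnetPath"))
    yb <- if (is.numeric(y)) as.integer(y) else .checkBinaryLabels(y)
    k <- max(folds)
    lambda <- path@lambda
    dev_fold <- matrix(NA_real_, k, length(lambda))
    for (f in seq_len(k)) {
        tr <- folds != f
        if (length(unique(yb[!tr])) < 2 || length(unique(yb[tr])) < 2)
            stopf("fold %d holds a single class", f)
        fit_f <- glmnet::glmnet(X[tr, , drop = FALSE], yb[tr],
                                family = "binomial", alpha = path@alpha,
                                lambda = lambda, standardize = FALSE,
                                thresh = 1e-10)
        p <- stats::predict(fit_f, X[!tr, , drop = FALSE], type = "response")
        dev_fold[f, ] <- vapply(seq_along(lambda), function(l)
            .binomialDeviance(yb[!tr], p[, l]), numeric(1))
    }
    cvm <- colMeans(dev_fold)
    cvsd <- apply(dev_fold, 2, stats::sd) / sqrt(k)
    i_min <- which.min(cvm)
    thr <- cvm[i_min] + cvsd[i_min]
    i_1se <- min(which(cvm <= thr))   # lambda grid is decreasing
    initialize(path, cvm = cvm, cvsd = cvsd,
               lambda_min = lambda[i_min], lambda_1se = lambda[i_1se])
}

#' @describeIn signature-selection Extract the ranked signature at the
#'   chosen penalty: features with non-zero coefficients, ordered by
#'   decreasing |coefficient| (ties broken by feature id). Standardization
#'   parameters must be supplied so new cohorts can be scored on the
#'   training scale. An empty selection yields an empty Signature with a
#'   warning.
#' @param at "1se" (default), "min", or a numeric lambda
#' @param center,scale training standardization parameters (named by feature)
#' @export
extractSignature <- function(path, at = "1se", center, scale) {
    stopifnot(is(path, "EnetPath"))
    lam <- if (is.numeric(at)) at
           else if (at == "1se") path@lambda_1se
           else if (at == "min") path@lambda_min
           else stopf("unknown lambda choice '%s'", at)
    if (is.na(lam)) stopf("run cvSelectLambda() before extracting at '%s'", at)
    beta <- stats::coef(path@fit, s = lam, exact = FALSE)
    b0 <- beta[1]
    b <- as.numeric(beta[-1])
    names(b) <- path@feature_ids
    nz <- which(b != 0)
    if (!length(nz)) warnf("empty signature: all coefficients are zero")
    ord <- nz[order(-abs(b[nz]), names(b)[nz])]
    new("Signature", feature_ids = names(b)[ord], coefficients = unname(b[ord]),
        intercept = b0, center = center, scale = scale, lambda = lam)
}

#' @describeIn signature-selection Logistic score of new samples under a
#'   Signature: features are standardized with the stored training
#'   parameters, then score = 1/(1 + exp(-(b0 + x'beta))). Scores are the
#'   probability of the PMS class. Unknown feature ids error.
#' @param sig a \linkS4class{Signature}
#' @param X_new numeric matrix, samples x features, raw (unstandardized)
#'   log2 values with feature columns named
#' @export
predictScores <- function(sig, X_new) {
    stopifnot(is(sig, "Signature"))
    missing_f <- setdiff(sig@feature_ids, colnames(X_new))
    if (length(missing_f))
        stopf("unknown feature id(s) in new data: %s",
              paste(missing_f, collapse = ", "))
    if (!length(sig@feature_ids))
        return(rep(stats::plogis(sig@intercept), nrow(X_new)))
    Xs <- sweep(sweep(X_new[, sig@feature_ids, drop = FALSE], 2,
                      sig@center[sig@feature_ids]), 2,
                sig@scale[sig@feature_ids], "/")
    eta <- sig@intercept + as.numeric(Xs %*% sig@coefficients)
    stats::plogis(eta)
}

#' @describeIn signature-selection Tie-corrected Mann-Whitney AUC:
#'   (number of positive>negative pairs + 0.5 * ties) / (n_pos * n_neg),
#'   with PMS as the positive class. Anti-discriminating scores give
#'   AUC < 0.5 and are reported as-is.
#' @param scores numeric per-sample scores
#' @param labels per-sample labels (PMS = positive)
#' @export
rocAuc <- function(scores, labels) {
    yb <- if (is.numeric(labels)) as.integer(labels)
          else .checkBinaryLabels(labels)
    if (length(unique(yb)) < 2) stopf("both classes required for AUC")
    n_pos <- sum(yb == 1); n_neg <- sum(yb == 0)
    r <- rank(scores)   # midranks handle ties
    (sum(r[yb == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @describeIn signature-selection Per-feature AUC: \code{rocAuc} applied to
#'   each feature column of \code{X} used directly as the score.
#' @export
perFeatureAuc <- function(X, labels) {
    apply(X, 2, rocAuc, labels = labels)
}

#' @describeIn signature-selection Select a signature on the training cohort
#'   of a \linkS4class{HarmonizedExperiment}: standardize cohort-1 RRMS/PMS
#'   samples, fit the path, cross-validate with balanced folds, and extract
#'   at lambda_1se. The model is refit on all cohort-1 patients at the
#'   chosen penalty (the path fit itself provides the coefficients).
#' @param h a HarmonizedExperiment
#' @param config a \code{\link{pipelineConfig}}
#' @return \code{selectSignature}: list with \code{signature}, \code{path},
#'   \code{folds}, \code{X} (training matrix), \code{y}
#' @export
selectSignature <- function(h, config = pipelineConfig()) {
    stopifnot(is(h, "HarmonizedExperiment"))
    cd <- colData(h)
    tr <- which(cd$cohort == 1 & cd$group %in% c("RRMS", "PMS"))
    ## one sample per subject: baseline only for re-sampled patients
    tp <- cd$timepoint_months[tr]
    tr <- tr[is.na(tp) | tp == 0]
    X <- t(assay(h)[, tr, drop = FALSE])
    y <- as.character(cd$group[tr])
    std <- standardizeFeatures(X)
    folds <- makeBalancedFolds(y, k = config$k_folds, seed = config$seed)
    path <- fitEnetPath(std$X, y, alpha = config$alpha_mix,
                        n_lambda = config$n_lambda,
                        lambda_min_ratio = config$lambda_min_ratio)
    path <- cvSelectLambda(std$X, y, folds, path)
    sig <- extractSignature(path, "1se", center = std$center,
                            scale = std$scale)
    list(signature = sig, path = path, folds = folds, X = X, y = y)
}

setMethod("show", "EnetPath", function(object) {
    cat(sprintf("EnetPath: alpha = %g, %d lambdas in [%.4g, %.4g]\n",
                object@alpha, length(object@lambda), min(object@lambda),
                max(object@lambda)))
    if (!is.na(object@lambda_min))
        cat(sprintf("  CV: lambda_min = %.4g, lambda_1se = %.4g\n",
                    object@lambda_min, object@lambda_1se))
    invisible(NULL)
})

setMethod("show", "Signature", function(object) {
    cat(sprintf("Signature: %d features at lambda = %.4g\n",
                length(object@feature_ids), object@lambda))
    n <- min(length(object@feature_ids), 5L)
    if (n) for (i in seq_len(n))
        cat(sprintf("  %s: %+.4f\n", object@feature_ids[i],
                    object@coefficients[i]))
    if (length(object@feature_ids) > n) cat("  ...\n")
    invisible(NULL)
})

#' Signature accessors
#'
#' @param sig a Signature
#' @return \code{signatureFeatures}: ranked feature ids;
#'   \code{signatureCoefficients}: named non-zero coefficients.
#' @export
signatureFeatures <- function(sig) sig@feature_ids

#' @rdname signatureFeatures
#' @export
signatureCoefficients <- function(sig)
    stats::setNames(sig@coefficients, sig@feature_ids)
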