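#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData colData
NULL

.VALID_ION_MODES <- c("positive", "negative")
.VALID_SCALES <- c("raw", "log2")
.VALID_SAMPLE_TYPES <- c("study", "qc", "blank", "dilution")
.VALID_GROUPS <- c("HC", "RRMS", "PMS", "TRANSITIONING")

#' MetabExperiment: a features-by-injections LC-MS feature table
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are quantified metabolic
#' features (with m/z in Da, retention time in seconds and ion mode in
#' \code{rowData}); columns are injections (study samples, pooled QC, blanks
#' and a two-fold dilution series, annotated in \code{colData}). The single
#' assay \code{"intensity"} holds intensities on either the raw or the log2
#' scale, recorded in \code{metadata()$scale}; missing measurements are
#' \code{NA}, never 0.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("MetabExperiment", contains = "SummarizedExperiment")

.validMetabExperiment <- function(object) {
    msg <- character()
    rd <- rowData(object)
    cd <- colData(object)
    need_rd <- c("mz", "rt", "ion_mode")
    if (!all(need_rd %in% colnames(rd)))
        return(paste("rowData must contain columns:",
                     paste(need_rd, collapse = ", ")))
    need_cd <- c("injection_id", "sample_type", "cohort", "injection_order")
    if (!all(need_cd %in% colnames(cd)))
        return(paste("colData must contain columns:",
                     paste(need_cd, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, sprintf("duplicated feature_id: %s",
            paste(unique(rownames(object)[duplicated(rownames(object))]),
                  collapse = ", ")))
    if (any(!is.na(rd$mz) & rd$mz <= 0))
        msg <- c(msg, "all m/z values must be > 0")
    if (any(!is.na(rd$rt) & rd$rt < 0))
        msg <- c(msg, "retention times must be >= 0")
    bad_mode <- setdiff(unique(as.character(rd$ion_mode)), .VALID_ION_MODES)
    if (length(bad_mode))
        msg <- c(msg, sprintf("unknown ion mode: %s",
                              paste(bad_mode, collapse = ", ")))
    sc <- metadata(object)$scale
    if (is.null(sc) || !sc %in% .VALID_SCALES)
        msg <- c(msg, "metadata()$scale must be 'raw' or 'log2'")
    a <- assay(object)
    if (identical(sc, "raw") && any(a[!is.na(a)] < 0))
        msg <- c(msg, "raw-scale intensities must be >= 0")
    st <- as.character(cd$sample_type)
    bad_st <- setdiff(unique(st), .VALID_SAMPLE_TYPES)
    if (length(bad_st))
        msg <- c(msg, sprintf("unknown sample_type: %s",
                              paste(bad_st, collapse = ", ")))
    ## injection order unique within each cohort batch
    for (co in unique(cd$cohort)) {
        ord <- cd$injection_order[cd$cohort == co]
        if (anyDuplicated(ord))
            msg <- c(msg, sprintf(
                "injection_order duplicated within cohort %s", co))
    }
    if ("group" %in% colnames(cd)) {
        grp <- as.character(cd$group)
        if (any(st == "study" & (is.na(grp) | !nzchar(grp))))
            msg <- c(msg, "study injections must carry a phenotype group")
        if (any(st != "study" & !is.na(grp)))
            msg <- c(msg, "group must be absent for non-study injections")
        bad_g <- setdiff(unique(grp[!is.na(grp)]), .VALID_GROUPS)
        if (length(bad_g))
            msg <- c(msg, sprintf("unknown group: %s",
                                  paste(bad_g, collapse = ", ")))
    }
    if ("dilution_volume" %in% colnames(cd)) {
        dv <- cd$dilution_volume
        if (any(st == "dilution" & is.na(dv)))
            msg <- c(msg, "dilution injections must carry dilution_volume")
        if (any(st != "dilution" & !is.na(dv)))
            msg <- c(msg, "dilution_volume must be absent unless dilution")
    }
    if (length(msg)) msg else TRUE
}
setValidity("MetabExperiment", .validMetabExperiment)

#' HarmonizedExperiment: the analysis-ready two-cohort matrix
#'
#' Matched features (canonical ids from cohort 1) by study samples of both
#' cohorts, on the log2 scale, mean-imputed and centered within each cohort.
#' Validity enforces completeness (no \code{NA}) and per-cohort per-feature
#' means of zero (within 1e-9). Filter provenance (age- and presence-removed
#' feature ids, the match table) is kept in \code{metadata()}.
#'
#' @export
setClass("HarmonizedExperiment", contains = "SummarizedExperiment")

.validHarmonized <- function(object) {
    msg <- character()
    a <- assay(object)
    if (anyNA(a)) msg <- c(msg, "harmonized matrix must not contain NA")
    cd <- colData(object)
    if (!"cohort" %in% colnames(cd))
        return("colData must contain 'cohort'")
    for (co in unique(cd$cohort)) {
        m <- rowMeans(a[, cd$cohort == co, drop = FALSE])
        if (any(abs(m) > 1e-9))
            msg <- c(msg, sprintf(
                "features not centered within cohort %s (max |mean| = %.3g)",
                co, max(abs(m))))
    }
    if (length(msg)) msg else TRUE
}
setValidity("HarmonizedExperiment", .validHarmonized)

#' EnetPath: an elastic-net regularization path with optional CV statistics
#'
#' Wraps a fitted binomial elastic-net path (mixing parameter alpha, a
#' decreasing lambda grid, coefficients and intercepts per lambda) together
#' with cross-validated deviance statistics once \code{\link{cvSelectLambda}}
#' has been run: mean held-out binomial deviance per lambda, its standard
#' error across folds, \code{lambda_min} and the one-standard-error choice
#' \code{lambda_1se}.
#'
#' @slot fit the underlying \code{glmnet} fit object
#' @slot alpha numeric mixing parameter
#' @slot lambda numeric decreasing lambda grid
#' @slot cvm numeric mean CV deviance per lambda (NA before CV)
#' @slot cvsd numeric standard error of the CV deviance per lambda
#' @slot lambda_min numeric
#' @slot lambda_1se numeric
#' @slot feature_ids character feature identifiers (column order of X)
#' @export
setClass("EnetPath", representation(
    fit = "ANY", alpha = "numeric", lambda = "numeric",
    cvm = "numeric", cvsd = "numeric",
    lambda_min = "numeric", lambda_1se = "numeric",
    feature_ids = "character"))

setValidity("EnetPath", function(object) {
    msg <- character()
    if (length(object@lambda) && is.unsorted(rev(object@lambda)))
        msg <- c(msg, "lambda grid must be decreasing")
    if (length(object@lambda_1se) && length(object@lambda_min) &&
        !is.na(object@lambda_1se) && !is.na(object@lambda_min) &&
        object@lambda_1se < object@lambda_min - 1e-12)
        msg <- c(msg, "lambda_1se must be >= lambda_min")
    if (length(object@cvm) && any(object@cvm[!is.na(object@cvm)] < 0))
        msg <- c(msg, "CV deviance must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Signature: a ranked discriminatory-feature signature
#'
#' Features with non-zero elastic-net coefficients at the chosen lambda,
#' ranked by decreasing absolute coefficient, together with the intercept and
#' the training standardization parameters (per-feature mean and sd estimated
#' on the training cohort only) needed to score new cohorts.
#'
#' @slot feature_ids character, ranked
#' @slot coefficients numeric, same order (all non-zero)
#' @slot intercept numeric(1)
#' @slot center numeric named per-feature training means
#' @slot scale numeric named per-feature training sds
#' @slot lambda numeric(1) penalty at which the signature was extracted
#' @export
setClass("Signature", representation(
    feature_ids = "character", coefficients = "numeric",
    intercept = "numeric", center = "numeric", scale = "numeric",
    lambda = "numeric"))

setValidity("Signature", function(object) {
    msg <- character()
    if (length(object@feature_ids) != length(object@coefficients))
        msg <- c(msg, "feature_ids and coefficients must align")
    if (any(object@coefficients == 0))
        msg <- c(msg, "signature coefficients must be non-zero")
    if (any(object@scale[object@feature_ids] <= 0))
        msg <- c(msg, "standardization sd must be > 0")
    if (length(msg)) msg else TRUE
})

#' ClassifierSpec: hyperparameters of the underlying SVM classifier
#'
#' Kernel family plus cost and (where relevant) gamma for the support-vector
#' classifier that drives the conformal predictor; probabilities come from the
#' classifier's internal cross-validated sigmoid fit, so a seed is part of the
#' specification.
#'
#' @slot kernel one of linear, radial, sigmoid, polynomial
#' @slot cost numeric(1) > 0
#' @slot gamma numeric(1) > 0 (ignored by the linear kernel)
#' @slot degree integer(1) polynomial degree
#' @slot seed integer(1) RNG seed for the internal probability calibration
#' @export
setClass("ClassifierSpec", representation(
    kernel = "character", cost = "numeric", gamma = "numeric",
    degree = "numeric", seed = "numeric"))

setValidity("ClassifierSpec", function(object) {
    msg <- character()
    if (!object@kernel %in% c("linear", "radial", "sigmoid", "polynomial"))
        msg <- c(msg, "unknown kernel")
    if (object@cost <= 0) msg <- c(msg, "cost must be > 0")
    if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
    if (length(msg)) msg else TRUE
})

#' ConformalPValues: per-sample Mondrian conformal p-values
#'
#' One row per evaluated sample with a conformal p-value for each phenotype
#' class (RRMS and PMS). Each p-value lies in (0, 1]; a high value means high
#' similarity to that phenotype's training examples in the classifier's
#' predictive space.
#'
#' @slot pvalues DataFrame with columns p_RRMS and p_PMS, rownames = sample ids
#' @slot smoothed logical(1) whether tie-smoothing was applied
#' @slot classes character(2) the class labels, fixed to c("RRMS", "PMS")
#' @export
setClass("ConformalPValues", representation(
    pvalues = "DataFrame", smoothed = "logical", classes = "character"))

setValidity("ConformalPValues", function(object) {
    msg <- character()
    if (!identical(object@classes, c("RRMS", "PMS")))
        msg <- c(msg, "classes must be exactly c('RRMS','PMS')")
    p <- as.matrix(as.data.frame(object@pvalues[, c("p_RRMS", "p_PMS")]))
    if (any(p <= 0 | p > 1))
        msg <- c(msg, "conformal p-values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})
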