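#' Per-cohort post-quantification filtering and normalization
#'
#' The preprocessing stages run in a fixed order on each cohort separately:
#' blank-based contaminant removal, dilution-series correlation filter, log2
#' transform, QC-anchored LOESS run-order normalization, QC
#' coefficient-of-variation filter, and a TIC outlier report (flag only).
#' Every stage appends its removals to the table's preprocess log
#' (\code{\link{preprocessLog}}).
#'
#' @name preprocess
NULL

.meanByType <- function(x, type) {
    cols <- which(colData(x)$sample_type == type)
    rowMeans(assay(x)[, cols, drop = FALSE], na.rm = TRUE)
}

#' @describeIn preprocess Remove blank-borne contaminants: a feature is kept
#'   iff its mean QC intensity is at least \code{ratio_min} times its mean
#'   blank intensity; features absent in all blanks are kept. Requires raw
#'   scale and at least one blank and one QC injection.
#' @param x a raw-scale MetabExperiment
#' @param ratio_min minimum QC/blank mean intensity ratio (default 10)
#' @return the filtered MetabExperiment, with the log updated
#' @export
removeBlankContaminants <- function(x, ratio_min = 10) {
    stopifnot(is(x, "MetabExperiment"))
    if (intensityScale(x) != "raw") stopf("expected raw-scale intensities")
    if (!any(colData(x)$sample_type == "blank")) stopf("no blank injections")
    if (!any(colData(x)$sample_type == "qc"))
        stopf("no QC injections: blank ratio undefined")
    blank_mean <- .meanByType(x, "blank")
    qc_mean <- .meanByType(x, "qc")
    absent_in_blanks <- is.nan(blank_mean) | is.na(blank_mean)
    keep <- absent_in_blanks | (qc_mean >= ratio_min * blank_mean)
    keep[is.na(keep)] <- FALSE
    out <- x[keep, ]
    .appendLog(out, "blank_filter", rownames(x)[!keep], "removed",
               sprintf("qc/blank ratio < %g", ratio_min))
}

#' @describeIn preprocess Keep features whose raw intensity has a positive
#'   Pearson correlation with the dilution-series volume at two-sided
#'   p < \code{p_max}; constant features are removed (r undefined). Requires
#'   at least three dilution injections with distinct volumes.
#' @param p_max two-sided p-value cutoff (default 0.05)
#' @export
filterByDilution <- function(x, p_max = 0.05) {
    stopifnot(is(x, "MetabExperiment"))
    if (intensityScale(x) != "raw") stopf("expected raw-scale intensities")
    cols <- which(colData(x)$sample_type == "dilution")
    vol <- colData(x)$dilution_volume[cols]
    if (length(unique(vol)) < 3)
        stopf("need >= 3 dilution injections with distinct volumes")
    vals <- assay(x)[, cols, drop = FALSE]
    keep <- vapply(seq_len(nrow(vals)), function(i) {
        v <- vals[i, ]
        ok <- !is.na(v)
        if (sum(ok) < 3 || stats::sd(v[ok]) == 0) return(FALSE)
        ct <- stats::cor.test(v[ok], vol[ok], method = "pearson")
        ct$estimate > 0 && ct$p.value < p_max
    }, logical(1))
    out <- x[keep, ]
    .appendLog(out, "dilution_filter", rownames(x)[!keep], "removed",
               sprintf("no positive dilution correlation at p < %g", p_max))
}

#' @describeIn preprocess Log2-transform all present intensities (variance
#'   stabilization). Errors on zero or negative entries, naming the cell.
#' @export
log2Transform <- function(x) {
    stopifnot(is(x, "MetabExperiment"))
    if (intensityScale(x) != "raw") stopf("table is already on the log2 scale")
    a <- assay(x)
    bad <- which(!is.na(a) & a <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stopf("non-positive intensity for feature '%s', injection '%s'",
              rownames(a)[bad[1, 1]], colnames(a)[bad[1, 2]])
    assay(x) <- log2(a)
    metadata(x)$scale <- "log2"
    x
}

## LOESS curve of QC log2 intensity vs injection order, evaluated at every
## injection; degree-1 local fit with direct surface so extrapolation beyond
## the QC range is linear.
.loessDriftCurve <- function(qc_order, qc_vals, all_order, span) {
    ## a degree-1 local fit needs several points in each window: raise the
    ## effective span so at least four QC points are covered when QC
    ## coverage is sparse
    span_eff <- max(span, min(1, 4 / length(qc_order)))
    fit <- suppressWarnings(
        stats::loess(qc_vals ~ qc_order, span = span_eff, degree = 1,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct")))
    suppressWarnings(
        stats::predict(fit, newdata = data.frame(qc_order = all_order)))
}

#' @describeIn preprocess Correct run-order intensity drift: per feature, fit
#'   a LOESS curve (span \code{span}, degree 1) of QC log2 intensity against
#'   injection order, evaluate it at every injection's order (linear
#'   extrapolation beyond the QC range), subtract the fitted value and add
#'   back the feature's QC mean. Missing entries are untouched. Features with
#'   fewer than five non-missing QC values pass through unnormalized and are
#'   flagged.
#' @param span LOESS span (default 0.2)
#' @export
loessRunorderNormalize <- function(x, span = 0.2) {
    stopifnot(is(x, "MetabExperiment"))
    if (intensityScale(x) != "log2") stopf("expected log2-scale intensities")
    cd <- colData(x)
    qc_cols <- which(cd$sample_type == "qc")
    if (length(qc_cols) < 5) stopf("need >= 5 QC injections")
    qc_order <- cd$injection_order[qc_cols]
    all_order <- cd$injection_order
    a <- assay(x)
    flagged <- character()
    for (i in seq_len(nrow(a))) {
        qv <- a[i, qc_cols]
        ok <- !is.na(qv)
        if (sum(ok) < 5) {
            flagged <- c(flagged, rownames(a)[i])
            next
        }
        curve <- tryCatch(
            .loessDriftCurve(qc_order[ok], qv[ok], all_order, span),
            error = function(e) NULL)
        if (is.null(curve) || anyNA(curve)) {
            flagged <- c(flagged, rownames(a)[i])
            next
        }
        a[i, ] <- a[i, ] - curve + mean(qv[ok])
    }
    assay(x) <- a
    .appendLog(x, "loess_normalize", flagged, "flagged",
               "insufficient QC coverage; passed through unnormalized")
}

#' @describeIn preprocess QC repeatability filter: per feature, the
#'   coefficient of variation sd/mean of the de-logged (2^log2) QC values;
#'   kept iff CV < \code{cv_max} (strict). Features missing all QC values are
#'   removed and flagged.
#' @param cv_max CV cutoff (default 0.20, strict less-than)
#' @export
qcCvFilter <- function(x, cv_max = 0.20) {
    stopifnot(is(x, "MetabExperiment"))
    if (intensityScale(x) != "log2") stopf("expected log2-scale intensities")
    qc_cols <- which(colData(x)$sample_type == "qc")
    if (length(qc_cols) < 3) stopf("need >= 3 QC injections")
    vals <- 2^assay(x)[, qc_cols, drop = FALSE]
    cv <- vapply(seq_len(nrow(vals)), function(i) {
        v <- vals[i, !is.na(vals[i, ])]
        if (length(v) < 3) return(NA_real_)
        stats::sd(v) / mean(v)
    }, numeric(1))
    keep <- !is.na(cv) & cv < cv_max
    out <- x[keep, ]
    out <- .appendLog(out, "cv_filter",
                      rownames(x)[!keep & !is.na(cv)], "removed",
                      sprintf("QC CV >= %g", cv_max))
    .appendLog(out, "cv_filter", rownames(x)[is.na(cv)], "removed",
               "QC values missing")
}

#' @describeIn preprocess Total-ion-count report: the sum of present
#'   raw-scale intensities per injection; injections with
#'   |TIC - median| > 3 MAD are flagged but never removed.
#' @return \code{ticReport}: a data.frame with injection_id, tic, flagged
#' @export
ticReport <- function(x) {
    stopifnot(is(x, "MetabExperiment"))
    a <- assay(x)
    if (intensityScale(x) == "log2") a <- 2^a
    tic <- colSums(a, na.rm = TRUE)
    med <- stats::median(tic)
    mad <- stats::mad(tic)
    ## a degenerate MAD of 0 (near-identical TICs) flags any deviation
    flagged <- if (mad > 0) abs(tic - med) > 3 * mad else tic != med
    data.frame(injection_id = colnames(x), tic = as.numeric(tic),
               flagged = flagged, row.names = NULL)
}

#' @describeIn preprocess Run the full per-cohort pipeline in the fixed
#'   order: blanks, dilution, log2, LOESS, CV filter. Returns the normalized
#'   log2-scale table; the per-stage report is in \code{preprocessLog()} and
#'   the TIC report in \code{metadata()$tic_report}.
#' @param config a \code{\link{pipelineConfig}}
#' @export
preprocessCohort <- function(x, config = pipelineConfig()) {
    x <- removeBlankContaminants(x, ratio_min = config$blank_ratio_min)
    x <- filterByDilution(x, p_max = config$dilution_p_max)
    x <- log2Transform(x)
    x <- loessRunorderNormalize(x, span = config$loess_span)
    x <- qcCvFilter(x, cv_max = config$cv_max)
    metadata(x)$tic_report <- ticReport(x)
    x
}
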