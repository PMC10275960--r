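#' Construct a MetabExperiment
#'
#' @param values numeric matrix, features x injections. \code{NA} marks a
#'   missing measurement; on the raw scale all present entries must be >= 0.
#' @param features data.frame (or DataFrame) with columns \code{feature_id},
#'   \code{mz} (Da, > 0), \code{rt} (seconds, >= 0), \code{ion_mode}
#'   ("positive"/"negative"), one row per matrix row.
#' @param injections data.frame of injection metadata, one row per matrix
#'   column, with at least \code{injection_id}, \code{cohort},
#'   \code{sample_type} and \code{injection_order}; study rows additionally
#'   carry \code{subject_id}, \code{group}, \code{age}, \code{sex} and
#'   optionally \code{timepoint_months} and \code{treated}; dilution rows
#'   carry \code{dilution_volume} (microlitres).
#' @param scale "raw" or "log2".
#' @return a validated \linkS4class{MetabExperiment}
#' @examples
#' fe <- data.frame(feature_id = c("F1", "F2"), mz = c(123.06, 215.05),
#'                  rt = c(65, 310), ion_mode = "positive")
#' inj <- data.frame(injection_id = c("i1", "i2"), cohort = 1L,
#'                   sample_type = "qc", injection_order = 1:2)
#' me <- MetabExperiment(matrix(1:4, 2, dimnames = list(fe$feature_id,
#'                       inj$injection_id)), fe, inj)
#' @export
MetabExperiment <- function(values, features, injections, scale = "raw") {
    features <- as.data.frame(features)
    injections <- as.data.frame(injections)
    if (anyDuplicated(features$feature_id))
        stopf("duplicated feature_id: %s", paste(
            unique(features$feature_id[duplicated(features$feature_id)]),
            collapse = ", "))
    if (anyDuplicated(injections$injection_id))
        stopf("duplicated injection_id: %s", paste(
            unique(injections$injection_id[duplicated(injections$injection_id)]),
            collapse = ", "))
    values <- as.matrix(values)
    if (nrow(values) != nrow(features) || ncol(values) != nrow(injections))
        stopf("dimension mismatch: values is %d x %d but %d features, %d injections",
              nrow(values), ncol(values), nrow(features), nrow(injections))
    rownames(values) <- features$feature_id
    colnames(values) <- injections$injection_id
    for (col in c("group", "dilution_volume", "subject_id", "age", "sex",
                  "timepoint_months", "treated"))
        if (!col %in% colnames(injections)) injections[[col]] <- NA
    rd <- DataFrame(features[, setdiff(colnames(features), "feature_id"),
                             drop = FALSE], row.names = features$feature_id)
    cd <- DataFrame(injections, row.names = injections$injection_id)
    se <- SummarizedExperiment(assays = list(intensity = values),
                               rowData = rd, colData = cd,
                               metadata = list(scale = scale))
    new("MetabExperiment", se)
}

#' @rdname MetabExperiment-accessors
#' @export
setGeneric("mz", function(x) standardGeneric("mz"))
#' @rdname MetabExperiment-accessors
#' @export
setGeneric("rt", function(x) standardGeneric("rt"))
#' @rdname MetabExperiment-accessors
#' @export
setGeneric("ionMode", function(x) standardGeneric("ionMode"))
#' @rdname MetabExperiment-accessors
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))
#' @rdname MetabExperiment-accessors
#' @export
setGeneric("injectionMeta", function(x) standardGeneric("injectionMeta"))
#' @rdname MetabExperiment-accessors
#' @export
setGeneric("preprocessLog", function(x) standardGeneric("preprocessLog"))

#' Accessors for MetabExperiment
#'
#' \code{mz}, \code{rt} and \code{ionMode} return per-feature annotations;
#' \code{intensityScale} returns "raw" or "log2"; \code{injectionMeta}
#' returns the injection metadata as a data.frame; \code{preprocessLog}
#' returns the accumulated per-stage filter report (one row per removed or
#' flagged feature).
#'
#' @param x a MetabExperiment
#' @name MetabExperiment-accessors
#' @aliases mz rt ionMode intensityScale injectionMeta preprocessLog
NULL

#' @rdname MetabExperiment-accessors
setMethod("mz", "MetabExperiment", function(x)
    stats::setNames(rowData(x)$mz, rownames(x)))
#' @rdname MetabExperiment-accessors
setMethod("rt", "MetabExperiment", function(x)
    stats::setNames(rowData(x)$rt, rownames(x)))
#' @rdname MetabExperiment-accessors
setMethod("ionMode", "MetabExperiment", function(x)
    stats::setNames(as.character(rowData(x)$ion_mode), rownames(x)))
#' @rdname MetabExperiment-accessors
setMethod("intensityScale", "MetabExperiment", function(x) metadata(x)$scale)
#' @rdname MetabExperiment-accessors
setMethod("injectionMeta", "MetabExperiment", function(x)
    as.data.frame(colData(x)))
#' @rdname MetabExperiment-accessors
setMethod("preprocessLog", "MetabExperiment", function(x) {
    log <- metadata(x)$preprocess_log
    if (is.null(log))
        log <- data.frame(stage = character(), feature_id = character(),
                          action = character(), detail = character())
    log
})

.appendLog <- function(x, stage, feature_id, action, detail = "") {
    entry <- if (length(feature_id))
        data.frame(stage = stage, feature_id = feature_id, action = action,
                   detail = detail)
    else
        data.frame(stage = character(), feature_id = character(),
                   action = character(), detail = character())
    metadata(x)$preprocess_log <- rbind(preprocessLog(x), entry)
    x
}

setMethod("show", "MetabExperiment", function(object) {
    cd <- colData(object)
    cat(sprintf("MetabExperiment: %d features x %d injections [%s scale]\n",
                nrow(object), ncol(object), intensityScale(object)))
    cat("  injections:",
        paste(sprintf("%s=%d", names(table(cd$sample_type)),
                      as.integer(table(cd$sample_type))), collapse = ", "),
        "\n")
    cat("  cohorts:", paste(sort(unique(cd$cohort)), collapse = ", "), "\n")
    nlog <- nrow(preprocessLog(object))
    if (nlog) cat(sprintf("  preprocess log: %d entries\n", nlog))
    invisible(NULL)
})

setMethod("show", "HarmonizedExperiment", function(object) {
    cd <- colData(object)
    cat(sprintf("HarmonizedExperiment: %d matched features x %d study samples\n",
                nrow(object), ncol(object)))
    cat("  per cohort:",
        paste(sprintf("cohort %s: %d", names(table(cd$cohort)),
                      as.integer(table(cd$cohort))), collapse = "; "), "\n")
    invisible(NULL)
})

## study-sample column selector used throughout the pipeline
.studyCols <- function(x, cohort = NULL, groups = NULL) {
    cd <- colData(x)
    sel <- cd$sample_type == "study"
    if (!is.null(cohort)) sel <- sel & cd$cohort %in% cohort
    if (!is.null(groups)) sel <- sel & !is.na(cd$group) & cd$group %in% groups
    which(sel)
}
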