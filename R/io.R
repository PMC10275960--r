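#' Read and write feature tables and injection metadata
#'
#' The on-disk feature table is a TSV with columns \code{feature_id},
#' \code{mz}, \code{rt}, \code{ion_mode} followed by one intensity column per
#' injection id; missing measurements are empty cells or \code{NA}, never 0.
#' An optional leading \code{#}-comment line records the intensity scale and
#' provenance. Injection metadata is a TSV with one row per injection.
#'
#' @param path file path
#' @param meta injection metadata: a data.frame from
#'   \code{readInjectionMeta} or a path to the metadata TSV
#' @return \code{readFeatureTable}: a validated
#'   \linkS4class{MetabExperiment}; \code{readInjectionMeta}: a data.frame.
#' @name metab-io
NULL

.FEATURE_COLS <- c("feature_id", "mz", "rt", "ion_mode")

#' @rdname metab-io
#' @export
readFeatureTable <- function(path, meta) {
    if (is.character(meta)) meta <- readInjectionMeta(meta)
    first <- readLines(path, n = 1L)
    scale <- "raw"
    if (startsWith(first, "#")) {
        m <- regmatches(first, regexec("scale=(\\w+)", first))[[1]]
        if (length(m) == 2) scale <- m[2]
    }
    df <- readTsv(path)
    missing_cols <- setdiff(.FEATURE_COLS, colnames(df))
    if (length(missing_cols))
        stopf("feature table lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
    inj_ids <- setdiff(colnames(df), .FEATURE_COLS)
    if (anyDuplicated(df$feature_id))
        stopf("duplicated feature_id: %s", paste(
            unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "))
    vals <- as.matrix(df[, inj_ids, drop = FALSE])
    if (is.character(vals)) {
        suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals)))
        bad <- which(is.na(num) & !is.na(vals) & nzchar(trimws(vals)),
                     arr.ind = TRUE)
        if (nrow(bad))
            stopf("non-numeric intensity for feature '%s', injection '%s'",
                  df$feature_id[bad[1, 1]], inj_ids[bad[1, 2]])
        vals <- num
    }
    storage.mode(vals) <- "double"
    bad_mode <- !df$ion_mode %in% .VALID_ION_MODES
    if (any(bad_mode))
        stopf("unknown ion mode '%s' for feature '%s'",
              df$ion_mode[which(bad_mode)[1]],
              df$feature_id[which(bad_mode)[1]])
    ## the metadata may cover more injections than this table (e.g. one
    ## metadata file for both cohorts); every table column must be annotated
    missing_ids <- setdiff(inj_ids, meta$injection_id)
    if (length(missing_ids))
        stopf("injections missing from metadata (e.g. %s)",
              paste(utils::head(missing_ids, 3), collapse = ", "))
    meta <- meta[match(inj_ids, meta$injection_id), , drop = FALSE]
    MetabExperiment(vals, df[, .FEATURE_COLS], meta, scale = scale)
}

#' @rdname metab-io
#' @param x a MetabExperiment
#' @param comment optional extra provenance appended to the header comment
#' @export
writeFeatureTable <- function(x, path, comment = NULL) {
    df <- data.frame(feature_id = rownames(x),
                     mz = rowData(x)$mz, rt = rowData(x)$rt,
                     ion_mode = as.character(rowData(x)$ion_mode))
    df <- cbind(df, as.data.frame(assay(x)))
    hdr <- paste0("scale=", intensityScale(x))
    if (!is.null(comment)) hdr <- paste(hdr, comment)
    writeTsv(df, path, header_comment = hdr)
}

.validateInjectionMeta <- function(meta) {
    need <- c("injection_id", "cohort", "sample_type", "injection_order")
    missing_cols <- setdiff(need, colnames(meta))
    if (length(missing_cols))
        stopf("injection metadata lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
    if (anyDuplicated(meta$injection_id))
        stopf("duplicated injection_id: %s", paste(
            unique(meta$injection_id[duplicated(meta$injection_id)]),
            collapse = ", "))
    bad_st <- !meta$sample_type %in% .VALID_SAMPLE_TYPES
    if (any(bad_st))
        stopf("unknown sample_type '%s' for injection '%s'",
              meta$sample_type[which(bad_st)[1]],
              meta$injection_id[which(bad_st)[1]])
    for (co in unique(meta$cohort)) {
        ord <- meta$injection_order[meta$cohort == co]
        if (anyDuplicated(ord))
            stopf("injection_order duplicated within cohort %s (order %s)",
                  co, ord[duplicated(ord)][1])
    }
    if ("group" %in% colnames(meta)) {
        no_grp <- meta$sample_type == "study" &
            (is.na(meta$group) | !nzchar(as.character(meta$group)))
        if (any(no_grp))
            stopf("study injection '%s' lacks a phenotype group",
                  meta$injection_id[which(no_grp)[1]])
    } else if (any(meta$sample_type == "study")) {
        stopf("study injections present but no 'group' column")
    }
    if ("dilution_volume" %in% colnames(meta)) {
        no_vol <- meta$sample_type == "dilution" & is.na(meta$dilution_volume)
        if (any(no_vol))
            stopf("dilution injection '%s' lacks dilution_volume",
                  meta$injection_id[which(no_vol)[1]])
    } else if (any(meta$sample_type == "dilution")) {
        stopf("dilution injections present but no 'dilution_volume' column")
    }
    invisible(meta)
}

#' @rdname metab-io
#' @export
readInjectionMeta <- function(path) {
    meta <- readTsv(path)
    .validateInjectionMeta(meta)
    meta
}

#' @rdname metab-io
#' @export
writeInjectionMeta <- function(meta, path, comment = NULL) {
    if (is(meta, "MetabExperiment")) meta <- injectionMeta(meta)
    drop <- vapply(meta, function(col) all(is.na(col)), logical(1))
    keep <- colnames(meta) %in% c("injection_id", "cohort", "sample_type",
                                  "injection_order") | !drop
    writeTsv(meta[, keep, drop = FALSE], path, header_comment = comment)
}
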