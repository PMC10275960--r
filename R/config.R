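#' Pipeline configuration
#'
#' A flat, validated key-value record of every threshold and seed the
#' pipeline consumes, so a run is fully determined by (data, config). The
#' defaults are the study settings: \code{ppm_max} 2.5 ppm and
#' \code{rt_max_s} 5 s matching windows, QC coefficient-of-variation cutoff
#' \code{cv_max} 0.20 (strict), presence cutoff \code{presence_min} 0.90,
#' blank-ratio cutoff \code{blank_ratio_min} 10, dilution-correlation and
#' age-association p cutoffs 0.05, LOESS span 0.2, elastic-net mixing
#' \code{alpha_mix} 0.5 with a 100-point lambda grid, balanced 7-fold CV with
#' five patients per phenotype per fold, a significance grid of
#' 0.001-0.50 (step 0.001) for the conformal curves, 999 ANOSIM permutations,
#' and 30 x 30 log-spaced (cost, gamma) bounds for the classifier grid.
#'
#' @param ... named overrides of any default
#' @return a list of class \code{pipeline_config}
#' @examples
#' cfg <- pipelineConfig(cv_max = 0.25, seed = 7)
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        ppm_max = 2.5, rt_max_s = 5,
        blank_ratio_min = 10, dilution_p_max = 0.05,
        loess_span = 0.2, cv_max = 0.20,
        age_p_max = 0.05, presence_min = 0.90,
        alpha_mix = 0.5, n_lambda = 100, lambda_min_ratio = 0.01,
        k_folds = 7, per_class_fold_size = 5,
        epsilon = 0.06,
        epsilon_min = 0.001, epsilon_max = 0.50, epsilon_step = 0.001,
        n_permutations = 999,
        n_cost = 30, n_gamma = 30,
        cost_log2_min = -5, cost_log2_max = 15,
        gamma_log2_min = -15, gamma_log2_max = 3,
        seed = 1L)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    .validateConfig(cfg)
    class(cfg) <- "pipeline_config"
    cfg
}

.validateConfig <- function(cfg) {
    chk <- function(ok, what) if (!ok) stopf("invalid config: %s", what)
    chk(cfg$ppm_max > 0, "ppm_max must be > 0")
    chk(cfg$rt_max_s > 0, "rt_max_s must be > 0")
    chk(cfg$blank_ratio_min > 0, "blank_ratio_min must be > 0")
    chk(cfg$dilution_p_max > 0 && cfg$dilution_p_max < 1,
        "dilution_p_max must be in (0,1)")
    chk(cfg$loess_span > 0 && cfg$loess_span <= 1, "loess_span in (0,1]")
    chk(cfg$cv_max > 0, "cv_max must be > 0")
    chk(cfg$age_p_max > 0 && cfg$age_p_max < 1, "age_p_max in (0,1)")
    chk(cfg$presence_min > 0 && cfg$presence_min <= 1, "presence_min in (0,1]")
    chk(cfg$alpha_mix >= 0 && cfg$alpha_mix <= 1, "alpha_mix in [0,1]")
    chk(cfg$k_folds >= 2, "k_folds must be >= 2")
    chk(cfg$epsilon > 0 && cfg$epsilon < 1, "epsilon in (0,1)")
    chk(cfg$n_permutations >= 1, "n_permutations must be >= 1")
    chk(!is.null(cfg$seed) && !is.na(cfg$seed), "master seed must be set")
    invisible(cfg)
}

#' @rdname pipelineConfig
#' @param path a flat key-value file (\code{key = value} or
#'   \code{key<TAB>value} per line, \code{#} comments allowed)
#' @param overrides named list applied on top of the file values (CLI flags)
#' @export
readPipelineConfig <- function(path, overrides = list()) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "[=\t]", perl = TRUE)
    vals <- lapply(kv, function(p) {
        if (length(p) < 2) stopf("malformed config line: %s", paste(p, collapse = ""))
        v <- trimws(paste(p[-1], collapse = "="))
        num <- suppressWarnings(as.numeric(v))
        if (!is.na(num)) num else v
    })
    names(vals) <- trimws(vapply(kv, `[[`, "", 1))
    vals[names(overrides)] <- overrides
    do.call(pipelineConfig, vals)
}

#' @rdname pipelineConfig
#' @param cfg a pipeline_config
#' @export
writePipelineConfig <- function(cfg, path) {
    writeLines(vapply(names(unclass(cfg)), function(k)
        sprintf("%s = %s", k, format(cfg[[k]], digits = 15)), ""), path)
    invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
    cat("pipeline_config:\n")
    for (k in names(unclass(x))) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
    invisible(x)
}

## short stable hash of the resolved configuration, recorded in output headers
configHash <- function(cfg) {
    s <- paste(names(unclass(cfg)), vapply(unclass(cfg), function(v)
        paste(format(v, digits = 15), collapse = ","), ""), collapse = ";")
    ## polynomial rolling hash over the serialized key=value string
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}
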