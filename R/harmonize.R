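#' Cross-cohort feature matching and harmonization
#'
#' Matches preprocessed log2 feature tables of the two cohorts within
#' \eqn{\pm}2.5 ppm mass and \eqn{\pm}5 s retention-time windows (ion modes
#' never mixed), filters matches on intensity consistency, removes
#' age-associated features (evaluated in cohort-1 healthy controls), applies
#' a 90% presence filter per cohort, mean-imputes remaining missing values
#' and centers every feature within each cohort, producing the analysis-ready
#' \linkS4class{HarmonizedExperiment}.
#'
#' @name harmonize
NULL

#' @describeIn harmonize Candidate pairs share ion mode and satisfy both
#'   windows; one-to-one assignment proceeds greedily in ascending combined
#'   score |ppm|/ppm_max + |drt|/rt_max. Returns a data.frame with
#'   feature_id_c1, feature_id_c2, ppm_delta, rt_delta, intensity_delta
#'   (mean log2 over study samples, cohort1 - cohort2) and score.
#' @param x1,x2 log2-scale MetabExperiment for cohort 1 and 2
#' @param ppm_max mass window in ppm (default 2.5)
#' @param rt_max_s retention-time window in seconds (default 5)
#' @export
matchFeatures <- function(x1, x2, ppm_max = 2.5, rt_max_s = 5) {
    stopifnot(is(x1, "MetabExperiment"), is(x2, "MetabExperiment"))
    mz1 <- mz(x1); mz2 <- mz(x2)
    rt1 <- rt(x1); rt2 <- rt(x2)
    m1 <- ionMode(x1); m2 <- ionMode(x2)
    cand <- list()
    for (i in seq_along(mz1)) {
        ppm <- (mz1[i] - mz2) / mz1[i] * 1e6
        drt <- rt1[i] - rt2
        hit <- which(m2 == m1[i] & abs(ppm) <= ppm_max & abs(drt) <= rt_max_s)
        if (length(hit))
            cand[[length(cand) + 1L]] <- data.frame(
                i = i, j = hit, ppm_delta = ppm[hit], rt_delta = drt[hit])
    }
    empty <- data.frame(feature_id_c1 = character(),
                        feature_id_c2 = character(),
                        ppm_delta = numeric(), rt_delta = numeric(),
                        intensity_delta = numeric(), score = numeric())
    if (!length(cand)) return(empty)
    cand <- do.call(rbind, cand)
    cand$score <- abs(cand$ppm_delta) / ppm_max + abs(cand$rt_delta) / rt_max_s
    ## greedy one-to-one assignment by ascending score, deterministic tie-break
    cand <- cand[order(cand$score, cand$i, cand$j), ]
    used1 <- logical(length(mz1)); used2 <- logical(length(mz2))
    take <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
        if (!used1[cand$i[r]] && !used2[cand$j[r]]) {
            take[r] <- TRUE
            used1[cand$i[r]] <- TRUE
            used2[cand$j[r]] <- TRUE
        }
    }
    cand <- cand[take, , drop = FALSE]
    s1 <- .studyCols(x1); s2 <- .studyCols(x2)
    mean1 <- rowMeans(assay(x1)[cand$i, s1, drop = FALSE], na.rm = TRUE)
    mean2 <- rowMeans(assay(x2)[cand$j, s2, drop = FALSE], na.rm = TRUE)
    out <- data.frame(feature_id_c1 = rownames(x1)[cand$i],
                      feature_id_c2 = rownames(x2)[cand$j],
                      ppm_delta = cand$ppm_delta, rt_delta = cand$rt_delta,
                      intensity_delta = mean1 - mean2, score = cand$score)
    out[order(out$feature_id_c1), , drop = FALSE]
}

#' @describeIn harmonize Keep matches whose mean log2 intensity difference
#'   d_i lies strictly within one standard deviation of the mean of all
#'   differences: |d_i - mean(d)| < sd(d), with mean and sd computed once
#'   over all input matches. A degenerate sd of 0 keeps all matches. With
#'   fewer than three matches the input is returned unchanged with a warning.
#' @param matches a match table from \code{matchFeatures}
#' @export
intensityConsistencyFilter <- function(matches) {
    if (nrow(matches) < 3) {
        warnf("fewer than 3 matches; intensity consistency filter skipped")
        return(matches)
    }
    d <- matches$intensity_delta
    s <- stats::sd(d)
    if (s == 0) return(matches)   # identical deviations carry no information
    matches[abs(d - mean(d)) < s, , drop = FALSE]
}

#' @describeIn harmonize Remove features whose log2 level is associated with
#'   age in the cohort-1 healthy controls (two-sided Pearson p <
#'   \code{p_max}). Constant features (r undefined) are kept and flagged.
#'   Returns a list with \code{removed}, \code{kept} (feature id vectors)
#'   and the per-feature test table \code{stats}.
#' @param x a log2-scale cohort-1 MetabExperiment
#' @param features feature ids to evaluate (default: all)
#' @param p_max two-sided age-association p cutoff (default 0.05)
#' @export
ageFilter <- function(x, features = rownames(x), p_max = 0.05) {
    stopifnot(is(x, "MetabExperiment"))
    hc <- .studyCols(x, groups = "HC")
    age <- colData(x)$age[hc]
    ok <- !is.na(age)
    hc <- hc[ok]; age <- age[ok]
    if (length(hc) < 10) stopf("need >= 10 cohort-1 HC samples with ages")
    res <- lapply(features, function(f) {
        v <- assay(x)[f, hc]
        use <- !is.na(v)
        if (sum(use) < 3 || stats::sd(v[use]) == 0)
            return(data.frame(feature_id = f, r = NA_real_, p = NA_real_,
                              flagged = TRUE))
        ct <- stats::cor.test(v[use], age[use], method = "pearson")
        data.frame(feature_id = f, r = unname(ct$estimate), p = ct$p.value,
                   flagged = FALSE)
    })
    res <- do.call(rbind, res)
    removed <- res$feature_id[!res$flagged & res$p < p_max]
    list(removed = removed, kept = setdiff(features, removed), stats = res)
}

#' @describeIn harmonize Keep features present (non-missing) in at least
#'   \code{min_frac} of study samples within each cohort separately
#'   (boundary inclusive).
#' @param f1,f2 feature id vectors naming the same matched feature in each
#'   cohort (parallel vectors)
#' @param min_frac presence fraction cutoff (default 0.90)
#' @export
presenceFilter <- function(x1, x2, f1, f2, min_frac = 0.90) {
    stopifnot(length(f1) == length(f2))
    s1 <- .studyCols(x1); s2 <- .studyCols(x2)
    pres <- function(x, f, cols)
        rowMeans(!is.na(assay(x)[f, cols, drop = FALSE]))
    keep <- pres(x1, f1, s1) >= min_frac & pres(x2, f2, s2) >= min_frac
    which(keep)
}

#' @describeIn harmonize Mean-impute (within cohort, over study samples) and
#'   center each matched feature within each cohort, returning a
#'   \linkS4class{HarmonizedExperiment} over the study samples of both
#'   cohorts with canonical cohort-1 feature ids.
#' @export
imputeAndCenter <- function(x1, x2, f1, f2) {
    stopifnot(length(f1) == length(f2))
    s1 <- .studyCols(x1); s2 <- .studyCols(x2)
    a1 <- assay(x1)[f1, s1, drop = FALSE]
    a2 <- assay(x2)[f2, s2, drop = FALSE]
    centerBlock <- function(a, cohort) {
        m <- rowMeans(a, na.rm = TRUE)
        if (anyNA(m) || any(is.nan(m)))
            stopf("feature entirely missing within cohort %d", cohort)
        for (i in seq_len(nrow(a))) a[i, is.na(a[i, ])] <- m[i]
        ## imputed entries equal the pre-centering mean, hence exactly 0 after
        ## centering; keep the centering means for projecting later samples
        list(a = sweep(a, 1, rowMeans(a)), means = rowMeans(a))
    }
    c1 <- centerBlock(a1, 1); c2 <- centerBlock(a2, 2)
    a1 <- c1$a; a2 <- c2$a
    rownames(a1) <- rownames(a2) <- f1
    cd <- rbind(colData(x1)[s1, ], colData(x2)[s2, ])
    rd <- rowData(x1)[f1, c("mz", "rt", "ion_mode")]
    se <- SummarizedExperiment(assays = list(log2centered = cbind(a1, a2)),
                               rowData = rd, colData = cd)
    obj <- new("HarmonizedExperiment", se)
    metadata(obj)$feature_id_c2 <- stats::setNames(f2, f1)
    metadata(obj)$cohort_means <- list(`1` = stats::setNames(c1$means, f1),
                                       `2` = stats::setNames(c2$means, f1))
    validObject(obj)
    obj
}

#' @describeIn harmonize Full harmonization: match, intensity-consistency
#'   filter, age filter (cohort-1 HC), presence filter, impute and center.
#'   Filter provenance lands in \code{metadata()} of the result
#'   (\code{matches}, \code{age_removed}, \code{presence_removed}).
#' @param config a \code{\link{pipelineConfig}}
#' @export
harmonizeCohorts <- function(x1, x2, config = pipelineConfig()) {
    matches <- matchFeatures(x1, x2, ppm_max = config$ppm_max,
                             rt_max_s = config$rt_max_s)
    matches <- intensityConsistencyFilter(matches)
    if (!nrow(matches)) stopf("no cross-cohort feature matches survive")
    af <- ageFilter(x1, matches$feature_id_c1, p_max = config$age_p_max)
    matches_kept <- matches[matches$feature_id_c1 %in% af$kept, , drop = FALSE]
    pk <- presenceFilter(x1, x2, matches_kept$feature_id_c1,
                         matches_kept$feature_id_c2,
                         min_frac = config$presence_min)
    presence_removed <-
        matches_kept$feature_id_c1[setdiff(seq_len(nrow(matches_kept)), pk)]
    matches_final <- matches_kept[pk, , drop = FALSE]
    h <- imputeAndCenter(x1, x2, matches_final$feature_id_c1,
                         matches_final$feature_id_c2)
    metadata(h)$matches <- matches
    metadata(h)$age_removed <- af$removed
    metadata(h)$presence_removed <- presence_removed
    h
}
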