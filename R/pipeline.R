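#' Pipeline-level helpers composing the modules end to end
#'
#' Convenience layers over the preprocessing, harmonization, signature,
#' conformal and monitoring modules for the common two-cohort workflow.
#'
#' @name pipeline
NULL

#' @describeIn pipeline Patient matrix of a HarmonizedExperiment: samples x
#'   features for the requested cohorts/groups (RRMS/PMS by default),
#'   baseline samples only unless \code{baseline_only = FALSE}.
#' @param h a \linkS4class{HarmonizedExperiment}
#' @param cohort cohorts to include (default both)
#' @param groups phenotype groups to include
#' @param baseline_only drop re-sampled follow-ups (timepoint > 0)
#' @return list with \code{X} (samples x features), \code{y} (group),
#'   \code{subjects}
#' @export
patientMatrix <- function(h, cohort = c(1, 2), groups = c("RRMS", "PMS"),
                          baseline_only = TRUE) {
    cd <- colData(h)
    sel <- cd$cohort %in% cohort & cd$group %in% groups
    if (baseline_only) {
        tp <- cd$timepoint_months
        sel <- sel & (is.na(tp) | tp == 0)
    }
    list(X = t(assay(h)[, sel, drop = FALSE]),
         y = as.character(cd$group[sel]),
         subjects = as.character(cd$subject_id[sel]))
}

#' @describeIn pipeline Express raw follow-up samples on the harmonized
#'   scale: log2 of the selected features minus the cohort-1 centering means
#'   stored on \code{h}. Follow-up tables must carry the cohort-1 feature
#'   ids.
#' @param followups a raw-scale MetabExperiment of follow-up injections over
#'   the cohort-1 feature panel
#' @return samples x features matrix aligned to \code{rownames(h)}
#' @export
followupMatrix <- function(h, followups) {
    stopifnot(is(h, "HarmonizedExperiment"), is(followups, "MetabExperiment"))
    f1 <- rownames(h)
    missing_f <- setdiff(f1, rownames(followups))
    if (length(missing_f))
        stopf("follow-up table lacks harmonized feature(s), e.g. %s",
              missing_f[1])
    a <- assay(followups)[f1, , drop = FALSE]
    if (intensityScale(followups) == "raw") a <- log2(a)
    means <- metadata(h)$cohort_means[["1"]][f1]
    t(a - means)
}

#' @describeIn pipeline Run preprocessing and harmonization on a simulated
#'   study and return the HarmonizedExperiment.
#' @param sim a \code{synth_sim} from \code{\link{generateCohorts}}
#' @param config a \code{\link{pipelineConfig}}
#' @export
harmonizeSim <- function(sim, config = pipelineConfig()) {
    p1 <- preprocessCohort(sim$cohort1, config)
    p2 <- preprocessCohort(sim$cohort2, config)
    harmonizeCohorts(p1, p2, config)
}
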