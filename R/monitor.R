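#' Longitudinal monitoring and feature characterization
#'
#' PCA of the selected features with projection of new samples, ANOSIM
#' permutation tests of group separation, paired Wilcoxon tests of
#' longitudinal PC1 shifts, sex-adjusted log2 fold changes, a Mann-Whitney
#' treatment check, multilevel (random-intercept) clinical associations with
#' signed -log10 p strengths, and Spearman hierarchical clustering of the
#' association matrix.
#'
#' @name monitor
NULL

#' @describeIn monitor Principal component analysis of a complete
#'   (no missing entries) matrix: SVD of the column-centered data, component
#'   signs fixed so the largest-magnitude loading of each component is
#'   positive. Returns a list of class \code{pca_model} with \code{center},
#'   orthonormal \code{loadings}, \code{explained} variance shares and
#'   training \code{scores}.
#' @param X numeric matrix, samples x features
#' @param n_components number of components to keep
#' @export
pcaFit <- function(X, n_components = 2) {
    if (anyNA(X)) stopf("PCA input must not contain missing entries")
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
    if (n_components > rank)
        stopf("n_components (%d) exceeds matrix rank (%d)", n_components, rank)
    load <- pc$rotation[, seq_len(n_components), drop = FALSE]
    scores <- pc$x[, seq_len(n_components), drop = FALSE]
    for (j in seq_len(n_components)) {
        i_max <- which.max(abs(load[, j]))
        if (load[i_max, j] < 0) {
            load[, j] <- -load[, j]
            scores[, j] <- -scores[, j]
        }
    }
    structure(list(center = pc$center, loadings = load,
                   explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
                   scores = scores),
              class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
    cat(sprintf("pca_model: %d components over %d features\n",
                ncol(x$loadings), nrow(x$loadings)))
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
    invisible(x)
}

#' @describeIn monitor Project new samples into a fitted PCA space:
#'   (X_new - center) %*% loadings. Feature order must match the model.
#' @param model a \code{pca_model}
#' @param X_new numeric matrix, samples x features
#' @export
pcaProject <- function(model, X_new) {
    if (is.null(dim(X_new))) X_new <- matrix(X_new, 1)
    if (ncol(X_new) != nrow(model$loadings))
        stopf("dimension mismatch: %d features, model expects %d",
              ncol(X_new), nrow(model$loadings))
    sweep(X_new, 2, model$center) %*% model$loadings
}

#' @describeIn monitor Analysis of similarities on Euclidean distances
#'   (configurable) with 999 label permutations: rank-based R in [-1, 1] and
#'   permutation p = (hits + 1)/(n_perm + 1). Requires >= 2 groups of >= 2.
#' @param groups group labels
#' @param n_perm number of permutations (default 999)
#' @param seed RNG seed for the permutations
#' @param distance a \code{dist} or the name of a \code{stats::dist} method
#' @return \code{anosimTest}: list of class \code{anosim_result} with
#'   \code{R}, \code{p}, \code{n_perm}, \code{seed}
#' @export
anosimTest <- function(X, groups, n_perm = 999, seed = 1,
                       distance = "euclidean") {
    groups <- as.factor(as.character(groups))
    if (nlevels(groups) < 2) stopf("need >= 2 groups")
    if (any(table(groups) < 2)) stopf("every group needs >= 2 members")
    d <- if (inherits(X, "dist")) X else stats::dist(X, method = distance)
    res <- withSeed(seed, vegan::anosim(d, groups, permutations = n_perm))
    structure(list(R = unname(res$statistic), p = res$signif,
                   n_perm = n_perm, seed = seed),
              class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
    cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
                x$R, x$p, x$n_perm))
    invisible(x)
}

#' @describeIn monitor Two-sided paired Wilcoxon signed-rank test; exact
#'   null distribution for n <= 25 without ties, normal approximation with
#'   tie correction otherwise; zero differences dropped. All-zero
#'   differences give p = 1 with a warning.
#' @param x2,y2 paired numeric vectors
#' @export
pairedWilcoxon <- function(x2, y2) {
    stopifnot(length(x2) == length(y2))
    d <- x2 - y2
    if (all(d == 0)) {
        warnf("all paired differences are zero")
        return(1)
    }
    suppressWarnings(
        stats::wilcox.test(x2, y2, paired = TRUE, alternative = "two.sided",
                           exact = sum(d != 0) <= 25 &&
                               !anyDuplicated(abs(d[d != 0])))$p.value)
}

#' @describeIn monitor Two-sided Mann-Whitney comparison of feature levels
#'   in treated versus untreated patients (exact for small samples without
#'   ties).
#' @param levels numeric feature levels
#' @param treated logical per sample
#' @export
treatmentCheck <- function(levels, treated) {
    treated <- as.logical(treated)
    if (!any(treated) || all(treated)) stopf("both groups must be nonempty")
    suppressWarnings(
        stats::wilcox.test(levels[treated], levels[!treated],
                           alternative = "two.sided")$p.value)
}

#' @describeIn monitor Sex-adjusted log2 fold change of a feature between
#'   PMS and RRMS: least squares of level ~ group + sex; the PMS
#'   coefficient is the adjusted log2 FC (equal to the marginal-means
#'   contrast for a two-level factor), with t-based p-values for both the
#'   group and sex terms.
#' @param group per-sample phenotype ("RRMS"/"PMS")
#' @param sex per-sample sex ("F"/"M")
#' @return \code{adjustedLog2fc}: list with estimate, p, sex_p
#' @export
adjustedLog2fc <- function(levels, group, sex) {
    group <- factor(as.character(group), levels = c("RRMS", "PMS"))
    sex <- factor(as.character(sex), levels = c("F", "M"))
    if (nlevels(droplevels(group)) < 2) stopf("both phenotype groups required")
    fit <- stats::lm(levels ~ group + sex)
    if (anyNA(stats::coef(fit)))
        stopf("confounded design: group and sex are not separable")
    sm <- summary(fit)$coefficients
    list(estimate = unname(sm["groupPMS", "Estimate"]),
         p = unname(sm["groupPMS", "Pr(>|t|)"]),
         sex_p = unname(sm["sexM", "Pr(>|t|)"]))
}

#' @describeIn monitor Multilevel clinical association of one metabolite
#'   with one clinical measure over repeated visits: a random-intercept
#'   linear mixed model level ~ clinical + time + sex + time:clinical +
#'   (1 | patient), fitted by maximum likelihood; reports the clinical
#'   coefficient, its t-based p-value and the signed strength
#'   sign(beta) * (-log10 p). Non-convergence is returned as a flagged
#'   entry.
#' @param clinical numeric clinical measure per visit
#' @param time_months numeric visit time in months
#' @param patient_id patient identifier per visit
#' @return \code{clinicalAssociation}: list with estimate, p, strength,
#'   converged
#' @export
clinicalAssociation <- function(levels, clinical, time_months, sex,
                                patient_id) {
    df <- data.frame(level = levels, clinical = clinical,
                     time = time_months,
                     sex = factor(as.character(sex), levels = c("F", "M")),
                     patient = factor(as.character(patient_id)))
    df <- df[stats::complete.cases(df), ]
    fit <- tryCatch(
        nlme::lme(level ~ clinical + time + sex + time:clinical,
                  random = ~ 1 | patient, data = df, method = "ML",
                  control = nlme::lmeControl(opt = "optim")),
        error = function(e) NULL)
    if (is.null(fit))
        return(list(estimate = NA_real_, p = NA_real_, strength = NA_real_,
                    converged = FALSE))
    tt <- summary(fit)$tTable
    est <- unname(tt["clinical", "Value"])
    p <- unname(tt["clinical", "p-value"])
    list(estimate = est, p = p, strength = sign(est) * (-log10(p)),
         converged = TRUE)
}

#' @describeIn monitor Hierarchical clustering of association-strength rows
#'   with distance 1 - Spearman rho and average linkage. Constant rows
#'   (undefined rho) are placed last and flagged. Returns a list with the
#'   \code{hclust} object (NULL if < 2 usable rows), the deterministic leaf
#'   \code{order} (row labels) and \code{flagged}.
#' @param strength numeric matrix of association strengths (rows clustered)
#' @export
spearmanHclust <- function(strength) {
    if (nrow(strength) < 2) stopf("need >= 2 rows to cluster")
    if (is.null(rownames(strength)))
        rownames(strength) <- paste0("row", seq_len(nrow(strength)))
    constant <- apply(strength, 1, function(r) stats::sd(r) == 0 || anyNA(r))
    usable <- strength[!constant, , drop = FALSE]
    if (nrow(usable) < 2)
        return(list(hclust = NULL, order = rownames(strength),
                    flagged = rownames(strength)[constant]))
    rho <- suppressWarnings(stats::cor(t(usable), method = "spearman"))
    d <- stats::as.dist(1 - rho)
    hc <- stats::hclust(d, method = "average")
    list(hclust = hc,
         order = c(rownames(usable)[hc$order], rownames(strength)[constant]),
         flagged = rownames(strength)[constant])
}
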