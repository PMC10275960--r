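# Shared fixture builders: tiny in-code tables and exchangeable Gaussian data.

# minimal feature/injection frames around a given intensity matrix
tinyExperiment <- function(values, sample_type = NULL, scale = "raw",
                           mz = NULL, rt = NULL, ion_mode = "positive",
                           group = NULL, age = NULL, sex = NULL,
                           dilution_volume = NULL, cohort = 1L) {
    nf <- nrow(values); ni <- ncol(values)
    feats <- data.frame(
        feature_id = rownames(values) %||% sprintf("F%03d", seq_len(nf)),
        mz = mz %||% (100 + seq_len(nf)),
        rt = rt %||% (60 + 10 * seq_len(nf)),
        ion_mode = ion_mode)
    st <- sample_type %||% rep("study", ni)
    inj <- data.frame(
        injection_id = colnames(values) %||% sprintf("I%03d", seq_len(ni)),
        subject_id = sprintf("S%03d", seq_len(ni)),
        cohort = cohort, sample_type = st,
        injection_order = seq_len(ni))
    inj$group <- if (!is.null(group)) group else
        ifelse(st == "study", "HC", NA)
    inj$age <- age %||% ifelse(st == "study", 40, NA)
    inj$sex <- sex %||% ifelse(st == "study", "F", NA)
    if (!is.null(dilution_volume)) inj$dilution_volume <- dilution_volume
    MetabExperiment(values, feats, inj, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exchangeable two-class Gaussian data for conformal checks
gaussTwoClass <- function(n, d = 5, shift = 0.7) {
    y <- sample(c("RRMS", "PMS"), n, replace = TRUE)
    X <- matrix(rnorm(n * d), n) + outer(as.integer(y == "PMS"), rep(shift, d))
    list(X = X, y = y)
}

# a vector with exact Pearson correlation r against x (given residual basis)
vectorWithCorrelation <- function(x, r) {
    n <- length(x)
    e <- rnorm(n)
    e <- residuals(lm(e ~ x))
    xs <- (x - mean(x)) / sd(x)
    y <- r * xs + sqrt(1 - r^2) * e / sd(e)
    y
}

# small synthetic config used where full study size is not needed
smallSynthConfig <- function(seed, ...) {
    synthConfig(n_features = 60L, n_contaminants = 5L, n_decoys = 8L,
                n_extra = 5L, seed = seed, ...)
}
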