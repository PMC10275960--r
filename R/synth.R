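#' Synthetic two-cohort study configuration
#'
#' Defines the generating model for synthetic data that emulate the
#' two-cohort CSF metabolomics study design: per-cohort HC/RRMS/PMS groups
#' (defaults 49/39/35 for cohort 1 and 10/30/16 for cohort 2), a shared panel
#' of quantified features of which a handful carry a planted PMS-vs-RRMS log2
#' effect, a fraction with an age-dependent slope, per-cohort systematic
#' shifts, sinusoidal run-order drift, interleaved QC and blank injections, a
#' two-fold dilution series, uniform missingness, blank-borne contaminants,
#' cross-cohort decoy features just outside the matching windows, and treated
#' PMS patients re-sampled at 3/6/12 months whose planted-feature means drift
#' toward the RRMS distribution.
#'
#' On the log2 scale a study injection of subject s for feature f is
#' \deqn{mu_f + delta_f I(PMS) + a_f age_s + s_f I(male) + c_f I(cohort 2) +
#'   g_f(order) + eps,  eps ~ N(0, sigma^2)}
#' and the raw table is 2^(log2 value) with missingness applied.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a list of class \code{synth_config}
#' @export
synthConfig <- function(...) {
    cfg <- list(
        n_hc = c(49L, 10L), n_rrms = c(39L, 30L), n_pms = c(35L, 16L),
        n_features = 500L,
        n_planted = 10L, planted_effect = 0.6,
        age_frac = 0.05, age_slope = 0.025,
        sex_frac = 0.10, sex_effect = 0.2,
        cohort_shift_global = 0.3, cohort_shift_tau = 0.15,
        cohort_shift_outlier_frac = 0.08, cohort_shift_outlier_sd = 1.5,
        drift_amplitude = 0.4, drift_cycles = 1.5,
        sigma = 0.5, sigma_qc = 0.15,
        missing_rate = 0.05,
        qc_every = 8L,
        n_contaminants = 15L, n_decoys = 40L, n_extra = 30L,
        dilution_volumes = c(0.5, 1, 2, 4, 8, 16, 32),
        blank_floor_log2 = 3, blank_floor_sd = 0.7, blank_missing_rate = 0.7,
        mu_log2_mean = 14, mu_log2_sd = 1.5,
        n_treated = 16L, timepoints = c(0L, 3L, 6L, 12L),
        drift_per_month = 0.06,
        clinical_beta = 1.0, clinical_intercept_sd = 0.5,
        clinical_noise_sd = 0.3,
        seed = 1L)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stopf("unknown synth_config key(s): %s", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    with(cfg, {
        if (any(c(n_hc, n_rrms, n_pms) <= 0)) stopf("group counts must be > 0")
        if (n_planted > n_features)
            stopf("n_planted (%d) exceeds n_features (%d)", n_planted, n_features)
        if (n_planted + round(age_frac * n_features) > n_features)
            stopf("planted and age-dependent features cannot be disjoint")
        if (!is.finite(planted_effect)) stopf("planted_effect must be finite")
        if (drift_per_month < 0 || drift_per_month * max(timepoints) > 1)
            stopf("drift_per_month times the last timepoint must lie in [0,1]")
        if (n_treated > n_pms[1])
            stopf("n_treated exceeds the cohort-1 PMS group")
        if (is.null(seed) || is.na(seed)) stopf("seed must be set")
    })
    class(cfg) <- "synth_config"
    cfg
}

## draw m/z, rt, mode panels with pairwise separation so that no accidental
## cross-cohort window overlap can contaminate the matching ground truth
.drawSeparatedFeatures <- function(n, avoid_mz = numeric(), avoid_rt = numeric(),
                                   avoid_mode = character()) {
    mz <- numeric(n); rtv <- numeric(n); mode <- character(n)
    for (i in seq_len(n)) {
        repeat {
            m <- stats::runif(1, 70, 800)
            r <- stats::runif(1, 30, 900)
            md <- sample(c("positive", "negative"), 1, prob = c(0.6, 0.4))
            prev_mz <- c(avoid_mz, mz[seq_len(i - 1L)])
            prev_rt <- c(avoid_rt, rtv[seq_len(i - 1L)])
            prev_md <- c(avoid_mode, mode[seq_len(i - 1L)])
            if (!length(prev_mz)) break
            ppm <- abs(m - prev_mz) / m * 1e6
            clash <- prev_md == md & ppm < 12 & abs(r - prev_rt) < 15
            if (!any(clash)) break
        }
        mz[i] <- m; rtv[i] <- r; mode[i] <- md
    }
    data.frame(mz = mz, rt = rtv, ion_mode = mode)
}

.drawAges <- function(group, cohort, n) {
    ## HC span the full adult age range so the age filter has power; patient
    ## ages follow the study's group means/SDs, truncated to adulthood
    pars <- list(`1` = list(RRMS = c(33, 9.10), PMS = c(50, 9.53)),
                 `2` = list(RRMS = c(39, 10.6), PMS = c(58, 9.3)))
    if (group == "HC") return(stats::runif(n, 18, 74))
    p <- pars[[as.character(cohort)]][[group]]
    pmin(pmax(stats::rnorm(n, p[1], p[2]), 18), 85)
}

.sexProbsF <- list(`1` = c(HC = 28/49, RRMS = 27/39, PMS = 22/35),
                   `2` = c(HC = 6/10, RRMS = 21/30, PMS = 10/16))

#' Generate the two synthetic cohorts
#'
#' Produces raw-scale \linkS4class{MetabExperiment} tables for both cohorts
#' plus a ground-truth record (planted effects, age slopes, true cross-cohort
#' match pairs, decoys, contaminants and drift parameters). Injection layout
#' per cohort: the two-fold dilution series first, then repeated blocks of
#' one QC, one blank and \code{qc_every} study injections in randomized
#' order, closed by a final QC/blank pair.
#'
#' @param config a \code{\link{synthConfig}}
#' @return a list of class \code{synth_sim} with elements \code{cohort1},
#'   \code{cohort2} (MetabExperiment, raw scale), \code{truth}
#'   (\code{synth_truth} list) and \code{config}
#' @examples
#' sim <- generateCohorts(synthConfig(n_features = 60, seed = 11))
#' sim$cohort1
#' @export
generateCohorts <- function(config = synthConfig()) {
    stopifnot(inherits(config, "synth_config"))
    seeds <- spawnSeeds(config$seed,
        c("features", "subjects", "noise1", "noise2", "missing1", "missing2",
          "drift", "blanks", "longitudinal", "clinical",
          "layout1", "layout2"))

    nF <- config$n_features
    nAge <- as.integer(round(config$age_frac * nF))
    truth <- withSeed(seeds["features"], {
        panel <- .drawSeparatedFeatures(nF)
        ## matched partner coordinates: inside +-2.5 ppm / +-5 s by construction
        mz2 <- panel$mz * (1 + stats::runif(nF, -1.5, 1.5) * 1e-6)
        rt2 <- panel$rt + stats::runif(nF, -3, 3)
        mu <- stats::rnorm(nF, config$mu_log2_mean, config$mu_log2_sd)
        delta <- numeric(nF)
        planted_idx <- seq_len(config$n_planted)
        delta[planted_idx] <- config$planted_effect *
            rep_len(c(1, -1), config$n_planted)
        slope <- numeric(nF)
        age_idx <- config$n_planted + seq_len(nAge)
        slope[age_idx] <- config$age_slope * rep_len(c(1, -1), nAge)
        sex_eff <- numeric(nF)
        sex_idx <- sample(setdiff(seq_len(nF), planted_idx),
                          round(config$sex_frac * nF))
        sex_eff[sex_idx] <- config$sex_effect * rep_len(c(1, -1), length(sex_idx))
        ## cross-batch shift: a shared component plus tight per-feature
        ## scatter, with a heavy-tailed outlier minority (features whose
        ## quantification differs qualitatively between batches); planted and
        ## age-dependent features stay in the well-behaved bulk
        shift <- config$cohort_shift_global +
            stats::rnorm(nF, 0, config$cohort_shift_tau)
        out_cand <- setdiff(seq_len(nF), c(planted_idx, age_idx))
        outlier_idx <- sample(out_cand,
                              round(config$cohort_shift_outlier_frac * nF))
        shift[outlier_idx] <- config$cohort_shift_global +
            stats::rnorm(length(outlier_idx), 0, config$cohort_shift_outlier_sd)

        ## decoys: cohort-2 features near a panel feature in one dimension but
        ## outside the window in the other; never inside both windows
        nd <- config$n_decoys
        tgt <- sample(nF, nd, replace = TRUE)
        by_ppm <- rep_len(c(TRUE, FALSE), nd)
        d_ppm <- ifelse(by_ppm, stats::runif(nd, 4, 10), stats::runif(nd, 0, 2)) *
            sample(c(-1, 1), nd, replace = TRUE)
        d_rt <- ifelse(by_ppm, stats::runif(nd, -4, 4),
                       stats::runif(nd, 7, 25) * sample(c(-1, 1), nd, replace = TRUE))
        decoy <- data.frame(mz = panel$mz[tgt] * (1 + d_ppm * 1e-6),
                            rt = panel$rt[tgt] + d_rt,
                            ion_mode = panel$ion_mode[tgt])
        ## guard against a decoy landing inside the windows of some other feature
        for (i in seq_len(nd)) {
            ppm <- abs(decoy$mz[i] - panel$mz) / decoy$mz[i] * 1e6
            while (any(panel$ion_mode == decoy$ion_mode[i] & ppm <= 3 &
                       abs(decoy$rt[i] - panel$rt) <= 6)) {
                decoy$rt[i] <- decoy$rt[i] + 40
            }
        }
        cont <- .drawSeparatedFeatures(config$n_contaminants,
                                       avoid_mz = c(panel$mz, decoy$mz),
                                       avoid_rt = c(panel$rt, decoy$rt),
                                       avoid_mode = c(panel$ion_mode,
                                                      decoy$ion_mode))
        extra1 <- .drawSeparatedFeatures(config$n_extra,
                                         avoid_mz = c(panel$mz, decoy$mz, cont$mz),
                                         avoid_rt = c(panel$rt, decoy$rt, cont$rt),
                                         avoid_mode = c(panel$ion_mode,
                                                        decoy$ion_mode,
                                                        cont$ion_mode))
        extra2 <- .drawSeparatedFeatures(config$n_extra,
                                         avoid_mz = c(panel$mz, decoy$mz, cont$mz,
                                                      extra1$mz),
                                         avoid_rt = c(panel$rt, decoy$rt, cont$rt,
                                                      extra1$rt),
                                         avoid_mode = c(panel$ion_mode,
                                                        decoy$ion_mode,
                                                        cont$ion_mode,
                                                        extra1$ion_mode))
        list(panel = panel, mz2 = mz2, rt2 = rt2, mu = mu, delta = delta,
             slope = slope, sex_eff = sex_eff, shift = shift,
             planted_idx = planted_idx, age_idx = age_idx, sex_idx = sex_idx,
             decoy = decoy, cont = cont, extra1 = extra1, extra2 = extra2,
             cont_mu = stats::rnorm(config$n_contaminants,
                                    config$mu_log2_mean, config$mu_log2_sd),
             decoy_mu = stats::rnorm(config$n_decoys, config$mu_log2_mean,
                                     config$mu_log2_sd),
             extra_mu1 = stats::rnorm(config$n_extra, config$mu_log2_mean,
                                      config$mu_log2_sd),
             extra_mu2 = stats::rnorm(config$n_extra, config$mu_log2_mean,
                                      config$mu_log2_sd))
    })

    subjects <- withSeed(seeds["subjects"], {
        out <- list()
        for (k in 1:2) {
            counts <- c(HC = config$n_hc[k], RRMS = config$n_rrms[k],
                        PMS = config$n_pms[k])
            df <- do.call(rbind, lapply(names(counts), function(g) {
                n <- counts[[g]]
                data.frame(
                    subject_id = sprintf("C%dS%s%03d", k, substr(g, 1, 1),
                                         seq_len(n)),
                    cohort = k, group = g,
                    age = .drawAges(g, k, n),
                    sex = ifelse(stats::runif(n) < .sexProbsF[[k]][g], "F", "M"))
            }))
            df$treated <- FALSE
            if (k == 1) {
                pms <- which(df$group == "PMS")
                df$treated[sample(pms, config$n_treated)] <- TRUE
            }
            out[[k]] <- df
        }
        out
    })

    drift_par <- withSeed(seeds["drift"], lapply(1:2, function(k) {
        ntot <- nF + config$n_contaminants + config$n_extra +
            if (k == 2) config$n_decoys else 0L
        list(amp = stats::runif(ntot, 0, config$drift_amplitude),
             phase = stats::runif(ntot, 0, 2 * pi))
    }))

    mkCohort <- function(k) {
        subj <- subjects[[k]]
        if (k == 1) {
            feats <- rbind(truth$panel, truth$cont, truth$extra1)
            ids <- c(sprintf("C1F%04d", seq_len(nF)),
                     sprintf("C1X%03d", seq_len(config$n_contaminants)),
                     sprintf("C1E%03d", seq_len(config$n_extra)))
            mu_all <- c(truth$mu, truth$cont_mu, truth$extra_mu1)
            delta_all <- c(truth$delta, numeric(config$n_contaminants + config$n_extra))
            slope_all <- c(truth$slope, numeric(config$n_contaminants + config$n_extra))
            sex_all <- c(truth$sex_eff, numeric(config$n_contaminants + config$n_extra))
            shift_all <- numeric(length(mu_all))
            is_cont <- c(rep(FALSE, nF), rep(TRUE, config$n_contaminants),
                         rep(FALSE, config$n_extra))
        } else {
            feats <- rbind(
                data.frame(mz = truth$mz2, rt = truth$rt2,
                           ion_mode = truth$panel$ion_mode),
                truth$cont, truth$extra2, truth$decoy)
            ids <- c(sprintf("C2F%04d", seq_len(nF)),
                     sprintf("C2X%03d", seq_len(config$n_contaminants)),
                     sprintf("C2E%03d", seq_len(config$n_extra)),
                     sprintf("C2D%03d", seq_len(config$n_decoys)))
            mu_all <- c(truth$mu, truth$cont_mu, truth$extra_mu2,
                        truth$decoy_mu)
            delta_all <- c(truth$delta,
                           numeric(config$n_contaminants + config$n_extra +
                                   config$n_decoys))
            slope_all <- c(truth$slope,
                           numeric(config$n_contaminants + config$n_extra +
                                   config$n_decoys))
            sex_all <- c(truth$sex_eff,
                         numeric(config$n_contaminants + config$n_extra +
                                 config$n_decoys))
            shift_all <- c(truth$shift,
                           numeric(config$n_contaminants),
                           numeric(config$n_extra),
                           numeric(config$n_decoys))
            is_cont <- c(rep(FALSE, nF), rep(TRUE, config$n_contaminants),
                         rep(FALSE, config$n_extra + config$n_decoys))
        }
        nfeat <- length(ids)
        ## injection layout
        ndil <- length(config$dilution_volumes)
        n_study <- nrow(subj)
        study_perm <- withSeed(seeds[paste0("layout", k)],
                               sample.int(n_study))
        inj <- data.frame(injection_id = character(), sample_type = character(),
                          study_row = integer(), dilution_volume = numeric())
        addRow <- function(inj, type, study_row = NA_integer_, vol = NA_real_) {
            rbind(inj, data.frame(
                injection_id = sprintf("C%dI%03d", k, nrow(inj) + 1L),
                sample_type = type, study_row = study_row,
                dilution_volume = vol))
        }
        for (v in config$dilution_volumes) inj <- addRow(inj, "dilution", vol = v)
        i <- 1L
        while (i <= n_study) {
            inj <- addRow(inj, "qc"); inj <- addRow(inj, "blank")
            for (j in i:min(i + config$qc_every - 1L, n_study))
                inj <- addRow(inj, "study", study_row = study_perm[j])
            i <- i + config$qc_every
        }
        inj <- addRow(inj, "qc"); inj <- addRow(inj, "blank")
        n_inj <- nrow(inj)
        inj$injection_order <- seq_len(n_inj)
        inj$cohort <- k

        ## pooled-QC expectation per feature (what a balanced pool would carry)
        qc_base <- mu_all + 0.5 * delta_all + slope_all * 45 + 0.4 * sex_all +
            shift_all
        dp <- drift_par[[k]]
        drift_at <- function(ord) vapply(ord, function(o)
            dp$amp * sin(2 * pi * config$drift_cycles * o / n_inj + dp$phase),
            numeric(nfeat))

        log2v <- matrix(NA_real_, nfeat, n_inj)
        noise_seed <- if (k == 1) seeds["noise1"] else seeds["noise2"]
        withSeed(noise_seed, {
            g <- drift_at(inj$injection_order)
            for (j in seq_len(n_inj)) {
                type <- inj$sample_type[j]
                if (type == "study") {
                    s <- subj[inj$study_row[j], ]
                    log2v[, j] <- mu_all +
                        delta_all * (s$group == "PMS") +
                        slope_all * s$age + sex_all * (s$sex == "M") +
                        shift_all + g[, j] +
                        stats::rnorm(nfeat, 0, config$sigma)
                } else if (type == "qc") {
                    log2v[, j] <- qc_base + g[, j] +
                        stats::rnorm(nfeat, 0, config$sigma_qc)
                } else if (type == "dilution") {
                    base <- qc_base + g[, j] +
                        stats::rnorm(nfeat, 0, config$sigma_qc)
                    scaled <- base + log2(inj$dilution_volume[j] / 10)
                    ## contaminants are volume-independent background
                    log2v[, j] <- ifelse(is_cont, base, scaled)
                } else { # blank
                    floorv <- stats::rnorm(nfeat, config$blank_floor_log2,
                                           config$blank_floor_sd)
                    contv <- qc_base + g[, j] +
                        stats::rnorm(nfeat, 0, config$sigma_qc)
                    miss <- stats::runif(nfeat) < config$blank_missing_rate
                    v <- ifelse(is_cont, contv, floorv)
                    v[!is_cont & miss] <- NA
                    log2v[, j] <- v
                }
            }
        })
        raw <- 2^log2v
        ## uniform missingness on study cells only; QC/blank/dilution stay
        ## complete so the drift correction and filters remain well-defined
        miss_seed <- if (k == 1) seeds["missing1"] else seeds["missing2"]
        withSeed(miss_seed, {
            sc <- which(inj$sample_type == "study")
            mask <- matrix(stats::runif(nfeat * length(sc)) < config$missing_rate,
                           nfeat)
            raw[, sc][mask] <- NA
        })
        meta <- data.frame(
            injection_id = inj$injection_id,
            subject_id = ifelse(is.na(inj$study_row), NA,
                                subj$subject_id[inj$study_row]),
            cohort = k,
            group = ifelse(is.na(inj$study_row), NA,
                           subj$group[inj$study_row]),
            sample_type = inj$sample_type,
            dilution_volume = inj$dilution_volume,
            injection_order = inj$injection_order,
            age = ifelse(is.na(inj$study_row), NA, subj$age[inj$study_row]),
            sex = ifelse(is.na(inj$study_row), NA, subj$sex[inj$study_row]),
            timepoint_months = ifelse(is.na(inj$study_row), NA, 0L),
            treated = ifelse(is.na(inj$study_row), NA,
                             subj$treated[inj$study_row]))
        features <- data.frame(feature_id = ids, feats)
        MetabExperiment(raw, features, meta, scale = "raw")
    }

    cohort1 <- mkCohort(1)
    cohort2 <- mkCohort(2)

    id1 <- sprintf("C1F%04d", seq_len(nF))
    id2 <- sprintf("C2F%04d", seq_len(nF))
    truth_out <- list(
        planted = data.frame(feature_id_c1 = id1[truth$planted_idx],
                             feature_id_c2 = id2[truth$planted_idx],
                             effect = truth$delta[truth$planted_idx]),
        age_dependent = data.frame(feature_id_c1 = id1[truth$age_idx],
                                   feature_id_c2 = id2[truth$age_idx],
                                   slope = truth$slope[truth$age_idx]),
        matches = data.frame(feature_id_c1 = id1, feature_id_c2 = id2),
        decoys = data.frame(feature_id_c2 = sprintf("C2D%03d",
                                                    seq_len(config$n_decoys))),
        contaminants = data.frame(
            feature_id = c(sprintf("C1X%03d", seq_len(config$n_contaminants)),
                           sprintf("C2X%03d", seq_len(config$n_contaminants))),
            cohort = rep(1:2, each = config$n_contaminants)),
        params = data.frame(feature_id_c1 = id1, mu = truth$mu,
                            effect = truth$delta, age_slope = truth$slope,
                            sex_effect = truth$sex_eff,
                            cohort2_shift = truth$shift),
        drift = do.call(rbind, lapply(1:2, function(k) data.frame(
            cohort = k,
            feature_index = seq_along(drift_par[[k]]$amp),
            amplitude = drift_par[[k]]$amp, phase = drift_par[[k]]$phase))),
        seeds = seeds)
    class(truth_out) <- "synth_truth"
    out <- list(cohort1 = cohort1, cohort2 = cohort2, truth = truth_out,
                config = config)
    class(out) <- "synth_sim"
    out
}

#' Generate longitudinal follow-up samples for treated PMS patients
#'
#' For every treated cohort-1 PMS patient and each post-baseline timepoint m
#' (months), planted-feature means move a fraction
#' \code{drift_per_month * m} of the way from the PMS toward the RRMS group
#' mean; all other features are generated unchanged. Follow-ups are returned
#' as a raw-scale MetabExperiment over the cohort-1 feature panel and
#' appended to the simulation as \code{$longitudinal}.
#'
#' @param sim a \code{synth_sim} from \code{\link{generateCohorts}}
#' @return \code{sim} with \code{$longitudinal} added
#' @export
generateLongitudinal <- function(sim) {
    stopifnot(inherits(sim, "synth_sim"))
    config <- sim$config
    seeds <- sim$truth$seeds
    meta1 <- injectionMeta(sim$cohort1)
    base <- meta1[meta1$sample_type == "study" & meta1$treated %in% TRUE, ]
    base <- base[!duplicated(base$subject_id), ]
    if (!nrow(base)) stopf("no treated PMS patients in cohort 1")
    months <- setdiff(sim$config$timepoints, 0L)

    fid <- rownames(sim$cohort1)
    params <- sim$truth$params
    idx <- match(params$feature_id_c1, fid)
    nfeat <- nrow(sim$cohort1)
    mu_all <- numeric(nfeat); delta_all <- numeric(nfeat)
    slope_all <- numeric(nfeat); sex_all <- numeric(nfeat)
    mu_all[idx] <- params$mu; delta_all[idx] <- params$effect
    slope_all[idx] <- params$age_slope; sex_all[idx] <- params$sex_effect
    ## contaminant / cohort-only features keep their baseline means
    other <- setdiff(seq_len(nfeat), idx)
    cont_ids <- sim$truth$contaminants$feature_id
    ## recover their mu from the realized QC mean as a close proxy
    qc_cols <- which(meta1$sample_type == "qc")
    mu_all[other] <- rowMeans(log2(assay(sim$cohort1)[other, qc_cols,
                                                      drop = FALSE]),
                              na.rm = TRUE)

    withSeed(seeds["longitudinal"], {
        rows <- expand.grid(si = seq_len(nrow(base)), m = months)
        n_inj <- nrow(rows)
        vals <- matrix(NA_real_, nfeat, n_inj)
        for (j in seq_len(n_inj)) {
            s <- base[rows$si[j], ]
            m <- rows$m[j]
            shrink <- 1 - config$drift_per_month * m
            vals[, j] <- mu_all + delta_all * shrink +
                slope_all * (s$age + m / 12) + sex_all * (s$sex == "M") +
                stats::rnorm(nfeat, 0, config$sigma)
        }
        meta <- data.frame(
            injection_id = sprintf("C1L%03d", seq_len(n_inj)),
            subject_id = base$subject_id[rows$si],
            cohort = 1L, group = "PMS", sample_type = "study",
            dilution_volume = NA_real_,
            injection_order = max(meta1$injection_order) + seq_len(n_inj),
            age = base$age[rows$si] + rows$m / 12,
            sex = base$sex[rows$si],
            timepoint_months = rows$m, treated = TRUE)
        feats <- data.frame(feature_id = fid,
                            mz = rowData(sim$cohort1)$mz,
                            rt = rowData(sim$cohort1)$rt,
                            ion_mode = as.character(rowData(sim$cohort1)$ion_mode))
        sim$longitudinal <- MetabExperiment(2^vals, feats, meta, scale = "raw")
    })
    sim
}

#' Generate synthetic clinical measures for the treated patients
#'
#' Eight clinical measures per treated patient at months 0, 6 and 12: each is
#' a linear combination of the realized log2 levels of chosen planted
#' features plus a patient random intercept and noise; two measures carry
#' all-zero coefficients (nulls). Coefficients are recorded in the truth.
#'
#' @param sim a \code{synth_sim} that already carries \code{$longitudinal}
#' @return \code{sim} with \code{$clinical} (data.frame) and
#'   \code{$truth$clinical_coef} added
#' @export
generateClinical <- function(sim) {
    stopifnot(inherits(sim, "synth_sim"))
    if (is.null(sim$longitudinal))
        stopf("run generateLongitudinal() first")
    config <- sim$config
    seeds <- sim$truth$seeds
    measures <- c("edss", "sdmt", "fsmc_cognitive", "fsmc_motor",
                  "walk_6mwt", "walk_25fwt", "hpt_dominant", "hpt_nondominant")
    planted <- sim$truth$planted$feature_id_c1
    meta1 <- injectionMeta(sim$cohort1)
    metaL <- injectionMeta(sim$longitudinal)

    level_at <- function(subject, month) {
        if (month == 0) {
            col <- which(meta1$subject_id %in% subject &
                         meta1$sample_type == "study")[1]
            log2(assay(sim$cohort1)[planted, col])
        } else {
            col <- which(metaL$subject_id %in% subject &
                         metaL$timepoint_months == month)[1]
            log2(assay(sim$longitudinal)[planted, col])
        }
    }

    withSeed(seeds["clinical"], {
        coef <- matrix(0, length(measures), length(planted),
                       dimnames = list(measures, planted))
        for (i in seq_len(6)) {
            f <- planted[(i - 1) %% length(planted) + 1]
            coef[measures[i], f] <- config$clinical_beta * c(1, -1)[i %% 2 + 1]
        }
        subjects <- unique(metaL$subject_id)
        u <- stats::rnorm(length(subjects), 0, config$clinical_intercept_sd)
        names(u) <- subjects
        months <- intersect(c(0, 6, 12), c(0, unique(metaL$timepoint_months)))
        grid <- expand.grid(subject_id = subjects, month = months,
                            stringsAsFactors = FALSE)
        vals <- matrix(NA_real_, nrow(grid), length(measures),
                       dimnames = list(NULL, measures))
        for (r in seq_len(nrow(grid))) {
            lv <- level_at(grid$subject_id[r], grid$month[r])
            ## centered planted levels keep the measures on a modest scale;
            ## the occasional missing measurement is taken at the mean
            lv <- lv - sim$truth$params$mu[match(planted,
                                                 sim$truth$params$feature_id_c1)]
            lv[is.na(lv)] <- 0
            vals[r, ] <- as.numeric(coef %*% lv) + u[grid$subject_id[r]] +
                stats::rnorm(length(measures), 0, config$clinical_noise_sd)
        }
        sexes <- meta1$sex[match(grid$subject_id, meta1$subject_id)]
        sim$clinical <- data.frame(subject_id = grid$subject_id,
                                   timepoint_months = grid$month,
                                   sex = sexes, vals)
        sim$truth$clinical_coef <- coef
    })
    sim
}

#' @export
print.synth_sim <- function(x, ...) {
    cat("synth_sim:\n  cohort 1: "); show(x$cohort1)
    cat("  cohort 2: "); show(x$cohort2)
    if (!is.null(x$longitudinal)) { cat("  longitudinal: "); show(x$longitudinal) }
    if (!is.null(x$clinical))
        cat(sprintf("  clinical: %d rows x %d measures\n",
                    nrow(x$clinical), ncol(x$clinical) - 3L))
    invisible(x)
}

#' Write a simulated study to disk in the package TSV formats
#'
#' @param sim a \code{synth_sim}
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
writeSynthData <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeFeatureTable(sim$cohort1, p("cohort1_features.tsv"))
    writeFeatureTable(sim$cohort2, p("cohort2_features.tsv"))
    writeInjectionMeta(rbind(injectionMeta(sim$cohort1),
                             injectionMeta(sim$cohort2)), p("injections.tsv"))
    writeTsv(sim$truth$planted, p("planted_features.tsv"))
    writeTsv(sim$truth$matches, p("true_matches.tsv"))
    writeTsv(sim$truth$drift, p("drift.tsv"))
    files <- c("cohort1_features.tsv", "cohort2_features.tsv",
               "injections.tsv", "planted_features.tsv", "true_matches.tsv",
               "drift.tsv")
    if (!is.null(sim$longitudinal)) {
        writeFeatureTable(sim$longitudinal, p("longitudinal_features.tsv"))
        writeInjectionMeta(injectionMeta(sim$longitudinal),
                           p("longitudinal_injections.tsv"))
        files <- c(files, "longitudinal_features.tsv",
                   "longitudinal_injections.tsv")
    }
    if (!is.null(sim$clinical)) {
        writeTsv(sim$clinical, p("clinical.tsv"))
        writeTsv(as.data.frame.table(sim$truth$clinical_coef,
                                     responseName = "coefficient",
                                     stringsAsFactors = FALSE),
                 p("clinical_truth.tsv"))
        files <- c(files, "clinical.tsv", "clinical_truth.tsv")
    }
    invisible(file.path(dir, files))
}
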