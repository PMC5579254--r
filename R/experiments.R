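#' Planted-effect recovery experiment
#'
#' Generates a two-group fixation cohort with a planted young > old SD_BOLD
#' effect region, runs the preprocessing + SD_BOLD + Task PLS chain (no
#' spatial smoothing, so the planted boundary stays sharp), and measures how
#' well bootstrap-thresholded voxels recover the planted region.
#'
#' @param seed Integer seed for the cohort and the resampling.
#' @param n_young,n_old Group sizes.
#' @param n_perm,n_boot Resampling counts.
#' @param bsr_threshold Threshold applied to |BSR|.
#' @return List: `permuted_p`, `recall` (fraction of planted voxels with
#'   BSR >= threshold), `false_positive_rate` (fraction of non-planted GM
#'   voxels above threshold), `n_subjects`, `n_voxels`.
#' @export
experiment_planted_recovery <- function(seed = 1L, n_young = 20L,
                                        n_old = 20L, n_perm = 200L,
                                        n_boot = 200L,
                                        bsr_threshold = 2.70) {
  spec <- cohort_spec(n_young = n_young, n_old = n_old, rng_seed = seed)
  cohort <- generate_cohort(spec, runs = "fixation")
  gm_vec <- as.vector(spec$masks$gm)
  sd_mat <- cohort_sd_matrix(cohort)
  groups <- factor(vapply(cohort$subjects, `[[`, "", "group"),
                   levels = c("young", "old"))
  perm <- permutation_test(sd_mat, groups, n_perm, seed = seed + 1L)
  boot <- bootstrap_bsr(sd_mat, groups, n_boot, seed = seed + 2L)
  planted <- cohort$truth$effect_region_gm
  hit <- boot$bsr >= bsr_threshold
  list(permuted_p = perm$p[1],
       recall = mean(hit[planted]),
       false_positive_rate = mean(abs(boot$bsr[!planted]) >= bsr_threshold),
       n_subjects = nrow(sd_mat), n_voxels = ncol(sd_mat))
}

#' SD_BOLD matrix of a cohort's fixation runs
#'
#' Runs surround addition, high-pass filtering (mean restored), block
#' normalization and SD_BOLD per subject over the GM mask. Smoothing is
#' omitted; used by the recovery experiments and available as a light-weight
#' alternative to [run_pipeline()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param highpass_hz High-pass cutoff, Hz.
#' @return Subject-by-GM-voxel matrix of SD_BOLD values.
#' @export
cohort_sd_matrix <- function(cohort, highpass_hz = 0.01) {
  gm_vec <- as.vector(cohort$masks$gm)
  t(vapply(cohort$subjects, function(sub) {
    fx <- sub$fixation
    bm <- as_voxel_matrix(surround_add(fx$echo2))$m
    carrier <- rowMeans(bm)
    bm <- highpass_filter(bm, highpass_hz, fx$params$tr) + carrier
    compute_sdbold(normalize_blocks(bm, fx$design, gm_vec))$sd
  }, numeric(sum(gm_vec))))
}

#' Headline vascular-control logic across seeded simulations
#'
#' Simulates subject-level cohorts under two generative scenarios and fits
#' the full model (SD level on age group + CBF + CVR + M). Under
#' `independent` coupling the age effect is direct and should survive
#' vascular control; under `fully_mediated` coupling the group difference
#' flows entirely through the vascular latent factor and the group
#' semi-partial should collapse.
#'
#' @param seed Integer seed.
#' @param n_sims Number of simulated cohorts per scenario.
#' @param n_boot Bootstrap resamples per model fit.
#' @return List: `ci_excludes_zero_rate` (independent scenario),
#'   `mean_semipartial_independent`, `mean_semipartial_mediated`,
#'   `semipartial_ratio` (mediated / independent), `n` (cohort size).
#' @export
experiment_headline_logic <- function(seed = 1L, n_sims = 100L,
                                      n_boot = 500L) {
  sp_ind <- numeric(n_sims); sp_med <- numeric(n_sims)
  excl <- logical(n_sims)
  n <- NA_integer_
  for (i in seq_len(n_sims)) {
    for (mode in c("independent", "fully_mediated")) {
      spec <- cohort_spec(coupling_mode = mode,
                          rng_seed = seed + 13L * i +
                            (mode == "fully_mediated"))
      tab <- simulate_cohort_subjects(spec)
      n <- nrow(tab)
      fit <- fit_vascular_model(tab, "sd_level",
                                c("group", "cbf_roi", "cvr_roi", "m_roi"),
                                n_boot = n_boot, seed = seed + i)
      g <- fit$coefficients[fit$coefficients$predictor == "group", ]
      if (mode == "independent") {
        sp_ind[i] <- g$semi_partial
        excl[i] <- g$ci_lower > 0 || g$ci_upper < 0
      } else {
        sp_med[i] <- g$semi_partial
      }
    }
  }
  list(ci_excludes_zero_rate = mean(excl),
       mean_semipartial_independent = mean(abs(sp_ind)),
       mean_semipartial_mediated = mean(abs(sp_med)),
       semipartial_ratio = mean(abs(sp_med)) / mean(abs(sp_ind)),
       n = n)
}

#' Type-I error calibration of the PLS permutation test
#'
#' Simulates label-independent Gaussian data and measures the rejection rate
#' of the LV1 permutation p-value at the nominal level.
#'
#' @param seed Integer seed.
#' @param n_sims Number of null simulations.
#' @param n_perm Permutations per simulation.
#' @param n_per_group Subjects per group.
#' @param n_voxels Voxels per simulation.
#' @param alpha Nominal level.
#' @return List: `type1_rate`, `n_sims`.
#' @export
experiment_permutation_calibration <- function(seed = 1L, n_sims = 200L,
                                               n_perm = 199L,
                                               n_per_group = 10L,
                                               n_voxels = 50L,
                                               alpha = 0.05) {
  groups <- factor(rep(c("young", "old"), each = n_per_group),
                   levels = c("young", "old"))
  rej <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(seed + 7L * i)
    x <- matrix(stats::rnorm(2 * n_per_group * n_voxels),
                2 * n_per_group, n_voxels)
    p <- permutation_test(x, groups, n_perm, seed = seed + 7L * i + 1L)$p[1]
    rej[i] <- p <= alpha
  }
  list(type1_rate = mean(rej), n_sims = n_sims)
}

#' Empirical coverage of the percentile bootstrap CI
#'
#' Simulates a two-predictor linear model at the study's sample size and
#' measures how often the 95% percentile bootstrap interval covers the
#' planted slope.
#'
#' @param seed Integer seed.
#' @param n_sims Number of simulations.
#' @param n Cases per simulation.
#' @param n_boot Bootstrap resamples.
#' @param b_true Planted slope.
#' @return List: `coverage`, `n_sims`, `n`.
#' @export
experiment_bootstrap_coverage <- function(seed = 1L, n_sims = 200L, n = 71L,
                                          n_boot = 199L, b_true = 0.5) {
  cover <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(seed + 11L * i)
    x <- stats::rnorm(n)
    y <- b_true * x + stats::rnorm(n)
    fit <- fit_vascular_model(data.frame(y = y, x = x), "y", "x",
                              n_boot = n_boot, seed = seed + 11L * i + 1L)
    cf <- fit$coefficients
    cover[i] <- cf$ci_lower <= b_true && b_true <= cf$ci_upper
  }
  list(coverage = mean(cover), n_sims = n_sims, n = n)
}
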