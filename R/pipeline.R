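#' Run the full SD_BOLD vascular-control analysis
#'
#' Orchestrates, per subject: dual-echo signal separation (surround addition
#' / subtraction), optional component-based denoising, spatial smoothing and
#' temporal high-pass filtering, block normalization and SD_BOLD; baseline
#' CBF from the fixation ASL signal; the hypercapnia GLM for CVR; then the
#' group-level Task PLS with permutation and bootstrap inference, the
#' bootstrap-thresholded young > old region, ROI-averaged vascular scalars
#' (CBF, CVR and the calibration-model M), and the regression suite
#' (Models 1-6) with outlier handling, log transforms and bootstrap CIs.
#'
#' Every stochastic stage is seeded from `config$rng_seed`, so the result
#' bundle is reproducible bit-for-bit at the level of all tables.
#'
#' @param config An [analysis_config()].
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or `NULL` to
#'   simulate the default cohort (seeded from the config).
#' @param spec Optional [cohort_spec()] used when `cohort` is `NULL`.
#' @param components Optional named list (by subject id) of component lists
#'   to classify and, when rejected, regress out of the fixation BOLD run.
#' @param out_dir Optional directory; when given, [write_bundle()] is called
#'   on the result.
#' @param verbose Emit one log line per stage.
#' @return List of class `pipeline_bundle`: `cohort_table`, `models`,
#'   `pls`, `bsr_map`, `region`, `sd_matrix`, `vascular`, `outliers`,
#'   `sex_table`, `coupling`, `config`, `log`.
#' @export
run_pipeline <- function(config = analysis_config(), cohort = NULL,
                         spec = NULL, components = NULL, out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  logline <- local({
    lines <- character(0)
    function(fmt = NULL, ...) {
      if (is.null(fmt)) return(lines)
      msg <- sprintf(fmt, ...)
      if (verbose) message(msg)
      lines <<- c(lines, msg)
      invisible(msg)
    }
  })
  if (is.null(cohort)) {
    if (is.null(spec)) spec <- cohort_spec(rng_seed = config$rng_seed)
    logline("stage simulate: generating cohort (n_young=%d, n_old=%d, grid=%s, coupling=%s, seed=%d)",
            spec$n_young, spec$n_old, paste(spec$grid, collapse = "x"),
            spec$coupling_mode, spec$rng_seed)
    cohort <- generate_cohort(spec)
  }
  stopifnot(inherits(cohort, "synthetic_cohort"))
  masks <- cohort$masks
  gm_vec <- as.vector(masks$gm)
  gm_idx <- which(gm_vec)
  n_sub <- length(cohort$subjects)
  groups <- factor(vapply(cohort$subjects, `[[`, "", "group"),
                   levels = c("young", "old"))
  sexes <- vapply(cohort$subjects, `[[`, "", "sex")
  ids <- vapply(cohort$subjects, `[[`, "", "id")
  have_hyper <- all(vapply(cohort$subjects,
                           function(s) !is.null(s$hypercapnia), TRUE))

  sd_mat <- matrix(NA_real_, n_sub, length(gm_idx))
  cbf_mat <- matrix(NA_real_, n_sub, length(gm_idx))
  cvr_mat <- frac_bold_mat <- frac_flow_mat <- NULL
  epi_base <- delta_base <- matrix(NA_real_, n_sub, length(gm_idx))
  split_half <- numeric(n_sub)
  if (have_hyper) {
    cvr_mat <- matrix(NA_real_, n_sub, length(gm_idx))
    bold_h_list <- flow_h_list <- vector("list", n_sub)
    hyper_design <- cohort$subjects[[1]]$hypercapnia$design
    dpco2 <- numeric(n_sub)
  }

  for (s in seq_len(n_sub)) {
    sub <- cohort$subjects[[s]]
    if (is.null(sub$fixation))
      stop("stage sdbold: subject ", sub$id, " has no fixation run")
    fx <- sub$fixation
    bold <- surround_add(fx$echo2)
    if (!is.null(components) && !is.null(components[[sub$id]])) {
      comps <- components[[sub$id]]
      flags <- lapply(comps, classify_component, masks = masks,
                      tr = fx$params$tr, highpass_hz = config$highpass_hz)
      rejected <- which(vapply(flags, `[[`, "", "decision") == "reject")
      logline("stage denoise: subject %s, %d/%d components rejected",
              sub$id, length(rejected), length(comps))
      if (length(rejected)) {
        courses <- do.call(cbind, lapply(comps, `[[`, "timecourse"))
        bold <- regress_out_components(bold, courses, rejected)
      }
    }
    if (config$smooth_fwhm_mm > 0)
      bold <- smooth_spatial(bold, config$smooth_fwhm_mm,
                             config$voxel_size_mm)
    bm <- as_voxel_matrix(bold)$m
    carrier <- rowMeans(bm)
    bm <- highpass_filter(bm, config$highpass_hz, fx$params$tr) + carrier
    norm <- normalize_blocks(bm, fx$design, gm_vec)
    sd_mat[s, ] <- compute_sdbold(norm)$sd
    fs <- block_frames(fx$design, ncol(bm), "fixation")
    split_half[s] <- split_half_reliability(bm[gm_vec, , drop = FALSE] *
                                              norm$scale, fs)$r

    flow <- as_voxel_matrix(surround_subtract(fx$echo1, fx$tag_parity))$m
    e1 <- as_voxel_matrix(fx$echo1)$m
    delta_base[s, ] <- rowMeans(flow[gm_vec, , drop = FALSE])
    epi_base[s, ] <- rowMeans(e1[gm_vec, , drop = FALSE])
    cbf_mat[s, ] <- quantify_cbf(delta_base[s, ], epi_base[s, ], fx$params)

    if (have_hyper) {
      hy <- sub$hypercapnia
      if (is.null(hy$endtidal))
        stop("stage vascular: subject ", sub$id,
             " has no end-tidal trace for the hypercapnia run")
      bold_h <- as_voxel_matrix(surround_add(hy$echo2))$m[gm_vec, , drop = FALSE]
      flow_h <- as_voxel_matrix(surround_subtract(hy$echo1,
                                                  hy$tag_parity))$m[gm_vec, , drop = FALSE]
      gb <- fit_block_glm(bold_h, hy$design, "hypercapnia")
      dpco2[s] <- max(hy$endtidal$pco2) - min(hy$endtidal$pco2)
      cvr_mat[s, ] <- compute_cvr(gb$fractional_change * 100, dpco2[s])
      bold_h_list[[s]] <- bold_h
      flow_h_list[[s]] <- flow_h
    }
  }
  logline("stage prep+sdbold: %d subjects, %d GM voxels, mean split-half r = %.3f",
          n_sub, length(gm_idx), mean(split_half))
  if (!have_hyper)
    warning("no hypercapnia runs: CVR and M stages skipped; Models 2-4 and 6 unavailable")

  pls <- task_pls(sd_mat, groups)
  perm <- permutation_test(sd_mat, groups, config$n_permutations,
                           seed = config$rng_seed + 1L)
  boot <- bootstrap_bsr(sd_mat, groups, config$n_bootstraps,
                        seed = config$rng_seed + 2L)
  bsr_arr <- array(0, dim(masks$gm))
  bsr_arr[gm_idx] <- boot$bsr
  bsr_map <- voxel_map(bsr_arr, masks$gm, "bsr")
  region <- threshold_regions(bsr_map, config$bsr_threshold, "young_higher")
  logline("stage pls: LV1 singular value %.3f, permuted p = %.4g, %d voxels above BSR %.2f",
          pls$s[1], perm$p[1], region$n_voxels, config$bsr_threshold)

  roi <- if (region$n_voxels > 0) {
    which(region$mask$values[gm_idx] > 0)
  } else integer(0)
  score <- if (length(roi)) brain_scores(pls$v[, 1], sd_mat, subset = roi)
           else rep(NA_real_, n_sub)

  tab <- data.frame(id = ids, group = groups, sex = sexes,
                    brain_score = score, stringsAsFactors = FALSE)
  if (length(roi)) {
    tab$cbf_roi <- quantify_cbf(rowMeans(delta_base[, roi, drop = FALSE]),
                                rowMeans(epi_base[, roi, drop = FALSE]),
                                cohort$subjects[[1]]$fixation$params)
  } else tab$cbf_roi <- NA_real_
  if (have_hyper && length(roi)) {
    # average the series over the ROI first, then one GLM and Eqs 1-2 once
    roi_frac <- function(lst) vapply(lst, function(m) {
      fit_block_glm(matrix(colMeans(m[roi, , drop = FALSE]), nrow = 1),
                    hyper_design, "hypercapnia")$fractional_change
    }, numeric(1))
    pct_roi <- roi_frac(bold_h_list) * 100
    tab$cvr_roi <- compute_cvr(pct_roi, dpco2)
    flow_ratio_roi <- pmax(1 + roi_frac(flow_h_list), 1.001)
    sv <- estimate_svo2(100, flow_ratio_roi, config$gcm_oef0)
    tab$m_roi <- compute_m(pct_roi / 100, flow_ratio_roi,
                           svo2 = sv$svo2, svo2_0 = sv$svo2_0,
                           alpha = config$gcm_alpha, beta = config$gcm_beta,
                           form = config$gcm_form)$m
  } else tab$cvr_roi <- tab$m_roi <- NA_real_
  tab$r_sd_cbf <- vapply(seq_len(n_sub), function(s)
    within_subject_coupling(sd_mat[s, ], cbf_mat[s, ]), numeric(1))
  tab$r_sd_cvr <- if (have_hyper)
    vapply(seq_len(n_sub), function(s)
      within_subject_coupling(sd_mat[s, ], cvr_mat[s, ]), numeric(1))
  else NA_real_

  models <- list()
  outliers <- list()
  sex_chi <- chi_square_2x2(table(tab$group, tab$sex))
  if (length(roi) && have_hyper) {
    uni <- univariate_outliers(tab[, c("brain_score", "cbf_roi", "cvr_roi",
                                       "m_roi")],
                               k = config$univariate_outlier_sd, id = tab$id)
    t2 <- tab[tab$id %in% uni$keep, , drop = FALSE]
    logline("stage outliers: univariate pass kept %d/%d cases",
            uni$n_after, uni$n_before)
    safe_transform <- function(x) {
      tryCatch(transform_to_gaussian(x), error = function(e) {
        logline("stage transform: transform skipped (%s)",
                conditionMessage(e))
        list(values = x, transformed = FALSE, ks_p_before = NA_real_,
             ks_p_after = NA_real_, skewness = sample_skewness(x))
      })
    }
    tr_cvr <- safe_transform(t2$cvr_roi)
    tr_m <- safe_transform(t2$m_roi)
    t2$cvr_model <- tr_cvr$values
    t2$m_model <- tr_m$values
    logline("stage transform: CVR %s (KS p %.3f), M %s (KS p %.3f)",
            if (tr_cvr$transformed) "log-transformed" else "untransformed",
            tr_cvr$ks_p_before,
            if (tr_m$transformed) "log-transformed" else "untransformed",
            tr_m$ks_p_before)
    pred4 <- cbind(group = as.numeric(t2$group == "young"),
                   cbf = t2$cbf_roi, cvr = t2$cvr_model, m = t2$m_model)
    mah <- mahalanobis_filter(pred4, df = 4, cap = config$mahalanobis_cap,
                              id = t2$id)
    t3 <- t2[t2$id %in% mah$keep, , drop = FALSE]
    logline("stage outliers: Mahalanobis filter kept %d/%d cases",
            mah$n_after, mah$n_before)
    outliers <- list(univariate = uni, transform_cvr = tr_cvr,
                     transform_m = tr_m, mahalanobis = mah)
    seed_m <- config$rng_seed + 3L
    models$model1 <- fit_vascular_model(t3, "brain_score",
                                        c("group", "cbf_roi"),
                                        config$n_bootstraps, seed_m)
    models$model2 <- fit_vascular_model(t3, "brain_score",
                                        c("group", "cvr_model"),
                                        config$n_bootstraps, seed_m + 1L)
    models$model3 <- fit_vascular_model(t3, "brain_score",
                                        c("group", "m_model"),
                                        config$n_bootstraps, seed_m + 2L)
    models$model4 <- fit_vascular_model(t3, "brain_score",
                                        c("group", "cbf_roi", "cvr_model",
                                          "m_model"),
                                        config$n_bootstraps, seed_m + 3L)
    models$model5 <- coupling_group_models(t3$r_sd_cbf, t3$group,
                                           config$n_bootstraps, seed_m + 4L)
    models$model6 <- coupling_group_models(t3$r_sd_cvr, t3$group,
                                           config$n_bootstraps, seed_m + 5L)
    logline("stage models: 6 models fit on n = %d", nrow(t3))
  } else if (length(roi)) {
    uni <- univariate_outliers(tab[, c("brain_score", "cbf_roi")],
                               k = config$univariate_outlier_sd, id = tab$id)
    t3 <- tab[tab$id %in% uni$keep, , drop = FALSE]
    outliers <- list(univariate = uni)
    seed_m <- config$rng_seed + 3L
    models$model1 <- fit_vascular_model(t3, "brain_score",
                                        c("group", "cbf_roi"),
                                        config$n_bootstraps, seed_m)
    models$model5 <- coupling_group_models(t3$r_sd_cbf, t3$group,
                                           config$n_bootstraps, seed_m + 4L)
    logline("stage models: models 1 and 5 fit on n = %d (no hypercapnia)",
            nrow(t3))
  } else {
    warning("empty PLS region: ROI-dependent stages skipped")
  }

  coupling <- list(
    sd_cbf = voxelwise_group_coupling(sd_mat, cbf_mat, groups))
  if (have_hyper)
    coupling$sd_cvr <- voxelwise_group_coupling(sd_mat, cvr_mat, groups)

  bundle <- structure(list(cohort_table = tab, models = models, pls = pls,
                           permutation = perm, bootstrap = boot,
                           bsr_map = bsr_map, region = region,
                           sd_matrix = sd_mat,
                           vascular = list(cbf = cbf_mat, cvr = cvr_mat),
                           split_half = split_half,
                           outliers = outliers, sex_chi = sex_chi,
                           coupling = coupling, masks = masks,
                           config = config, log = logline()),
                      class = "pipeline_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a pipeline bundle to disk
#'
#' Tables as TSV, maps as NIfTI, the effective configuration as YAML.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name)
    utils::write.table(x, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(bundle$cohort_table, "cohort_table.tsv")
  for (nm in names(bundle$models)) {
    res <- bundle$models[[nm]]
    wt(res$coefficients, paste0(nm, ".tsv"))
  }
  if (!is.null(bundle$region$clusters) && nrow(bundle$region$clusters))
    wt(bundle$region$clusters, "clusters.tsv")
  write_image(bundle$bsr_map, file.path(dir, "bsr.nii.gz"))
  if (!is.null(bundle$region$mask))
    write_image(bundle$region$mask, file.path(dir, "region.nii.gz"))
  write_config(bundle$config, file.path(dir, "config.yaml"))
  writeLines(bundle$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}
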