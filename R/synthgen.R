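#' Tissue masks on a synthetic acquisition grid
#'
#' Builds a deterministic brain box centered in the grid, a 1-voxel in-plane
#' edge shell, a small white-matter/CSF core, and the grey-matter mask
#' (brain minus edge minus core). The brain box is sized so the GM mask
#' covers approximately `gm_frac` of the grid.
#'
#' @param grid Integer vector (nx, ny, nz).
#' @param gm_frac Approximate grey-matter fraction of the grid.
#' @return List of 3D logical arrays: `brain`, `gm`, `wm_csf`, `edge`.
#' @export
make_grid_masks <- function(grid, gm_frac = 0.43) {
  stopifnot(length(grid) == 3L, all(grid >= 4L), gm_frac > 0, gm_frac < 1)
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  side <- round(sqrt(gm_frac * nx * ny * nz / nz)) + 2L
  bx <- min(nx - 2L, side); by <- min(ny - 2L, side)
  x0 <- floor((nx - bx) / 2) + 1L; y0 <- floor((ny - by) / 2) + 1L
  brain <- array(FALSE, grid)
  brain[x0:(x0 + bx - 1L), y0:(y0 + by - 1L), ] <- TRUE
  edge <- array(FALSE, grid)
  edge[c(x0, x0 + bx - 1L), y0:(y0 + by - 1L), ] <- TRUE
  edge[x0:(x0 + bx - 1L), c(y0, y0 + by - 1L), ] <- TRUE
  wm <- array(FALSE, grid)
  wx <- x0 + 1L; wy <- y0 + by - 3L; wz <- max(1L, floor(nz / 3))
  wm[wx:(wx + 1L), wy:(wy + 1L), wz:(wz + 1L)] <- TRUE
  gm <- brain & !edge & !wm
  list(brain = brain, gm = gm, wm_csf = wm, edge = edge)
}

#' Default contiguous effect region inside the grey-matter mask
#'
#' A centered box of at least 30 voxels where the young > old SD_BOLD
#' difference is planted.
#'
#' @param masks Output of [make_grid_masks()].
#' @return 3D logical array, a subset of `masks$gm`.
#' @export
default_effect_region <- function(masks) {
  d <- dim(masks$gm)
  cx <- round(d[1] / 2); cy <- round(d[2] / 2); cz <- round(d[3] / 2)
  reg <- array(FALSE, d)
  reg[(cx - 1):(cx + 2), (cy - 1):(cy + 2), max(1, cz - 1):min(d[3], cz + 1)] <- TRUE
  reg <- reg & masks$gm
  if (sum(reg) < 30) stop("grid too small for a >= 30-voxel effect region")
  reg
}

#' Specification of a synthetic two-group dual-echo cohort
#'
#' Defines the study conditions the generator emulates: group sizes and sex
#' composition of the emulated cohort (28 young: 20 M / 8 F; 43 old:
#' 11 M / 32 F), a small acquisition grid, the planted SD_BOLD levels inside
#' and outside the effect region, group means and between-subject SDs of
#' the vascular parameters, and the coupling structure linking a subject's
#' SD_BOLD level to a latent vascular factor.
#'
#' Coupling modes: `"independent"` draws SD levels independently of the
#' vascular factor (a direct age effect); `"fully_mediated"` makes the SD
#' level a deterministic function (plus small noise) of the absolute
#' vascular level, so the group SD difference is produced entirely through
#' the group difference in vascular means; `"partial"` mixes the two with
#' weight `coupling_rho`.
#'
#' @param n_young,n_old Group sizes.
#' @param grid Acquisition grid (nx, ny, nz).
#' @param gm_frac Approximate grey-matter fraction of the grid.
#' @param effect_region Optional 3D logical array (must lie inside the GM
#'   mask); defaults to [default_effect_region()].
#' @param sd_young,sd_old Planted SD_BOLD (normalized units, i.e. percent of
#'   the mean signal) inside the effect region, per group.
#' @param sd_background SD_BOLD outside the effect region.
#' @param sd_bs_sd Between-subject SD of the subject SD level.
#' @param cbf_mean_young,cbf_mean_old,cbf_bs_sd Baseline grey-matter CBF,
#'   ml/100g/min.
#' @param cvr_mean_young,cvr_mean_old,cvr_bs_sd BOLD CVR, %BOLD/mmHg.
#' @param m_mean_young,m_mean_old,m_bs_sd Maximum BOLD signal change M,
#'   fraction.
#' @param coupling_mode "independent", "partial" or "fully_mediated".
#' @param coupling_rho Correlation between the subject SD level and the
#'   latent vascular factor under `"partial"` coupling, in [-1, 1].
#' @param female_frac_young,female_frac_old Female fraction per group
#'   (female counts are `round(frac * n)`).
#' @param voxel_coupling_young,voxel_coupling_old Mean within-subject
#'   voxelwise correlation between the SD_BOLD and vascular spatial fields.
#' @param ar1_phi Lag-1 autocorrelation of the BOLD fluctuations at TR.
#' @param tr Repetition time, seconds.
#' @param rng_seed Integer seed; the cohort is a deterministic function of
#'   the spec.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 28L, n_old = 43L,
                        grid = c(12L, 12L, 6L), gm_frac = 0.43,
                        effect_region = NULL,
                        sd_young = 2.0, sd_old = 1.2, sd_background = 1.0,
                        sd_bs_sd = 0.25,
                        cbf_mean_young = 60, cbf_mean_old = 45, cbf_bs_sd = 10,
                        cvr_mean_young = 0.35, cvr_mean_old = 0.25,
                        cvr_bs_sd = 0.08,
                        m_mean_young = 0.08, m_mean_old = 0.06,
                        m_bs_sd = 0.018,
                        coupling_mode = c("independent", "partial",
                                          "fully_mediated"),
                        coupling_rho = 0.5,
                        female_frac_young = 8 / 28, female_frac_old = 32 / 43,
                        voxel_coupling_young = 0.25,
                        voxel_coupling_old = 0.35,
                        ar1_phi = 0.3, tr = 3.0, rng_seed = 1L) {
  coupling_mode <- match.arg(coupling_mode)
  if (n_young < 2L || n_old < 2L) stop("need at least 2 subjects per group")
  if (any(c(sd_young, sd_old, sd_background) < 0) || sd_bs_sd < 0)
    stop("SD levels must be non-negative")
  if (abs(coupling_rho) > 1) stop("coupling_rho must lie in [-1, 1]")
  masks <- make_grid_masks(grid, gm_frac)
  if (is.null(effect_region)) effect_region <- default_effect_region(masks)
  if (any(effect_region & !masks$gm))
    stop("effect_region must lie inside the grey-matter mask")
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 grid = as.integer(grid), gm_frac = gm_frac,
                 masks = masks, effect_region = effect_region,
                 sd_young = sd_young, sd_old = sd_old,
                 sd_background = sd_background, sd_bs_sd = sd_bs_sd,
                 cbf_mean_young = cbf_mean_young, cbf_mean_old = cbf_mean_old,
                 cbf_bs_sd = cbf_bs_sd,
                 cvr_mean_young = cvr_mean_young, cvr_mean_old = cvr_mean_old,
                 cvr_bs_sd = cvr_bs_sd,
                 m_mean_young = m_mean_young, m_mean_old = m_mean_old,
                 m_bs_sd = m_bs_sd,
                 coupling_mode = coupling_mode, coupling_rho = coupling_rho,
                 female_frac_young = female_frac_young,
                 female_frac_old = female_frac_old,
                 voxel_coupling_young = voxel_coupling_young,
                 voxel_coupling_old = voxel_coupling_old,
                 ar1_phi = ar1_phi, tr = tr,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Block designs and end-tidal traces for the synthetic runs
#'
#' `"fixation"`: an alternating fixation/task block design whose five 60-s
#' fixation blocks total 300 s. `"hypercapnia"`: alternating baseline and
#' hypercapnia plateaus (60 s baseline, two 120-s hypercapnia blocks) with
#' end-tidal PCO2 of 40 mmHg at baseline, 45 mmHg during hypercapnia, and
#' PO2 of 100 mmHg throughout.
#'
#' @param kind "fixation" or "hypercapnia".
#' @param tr Repetition time, seconds.
#' @param block_s Block duration, seconds (fixation design).
#' @param n_fixation Number of fixation blocks.
#' @param pco2_baseline,pco2_plateau,po2 End-tidal targets, mmHg.
#' @return List: `design` (a [block_design()]), `endtidal` (an
#'   [end_tidal_trace()] for the hypercapnia design, else `NULL`),
#'   `n_frames`.
#' @export
make_design <- function(kind = c("fixation", "hypercapnia"), tr = 3.0,
                        block_s = 60, n_fixation = 5L,
                        pco2_baseline = 40, pco2_plateau = 45, po2 = 100) {
  kind <- match.arg(kind)
  if (abs(block_s / tr - round(block_s / tr)) > 1e-9)
    stop("block duration must be a multiple of TR")
  if (kind == "fixation") {
    n_blocks <- 2L * n_fixation - 1L
    blocks <- data.frame(
      label = rep(c("fixation", "task"), length.out = n_blocks),
      onset = (seq_len(n_blocks) - 1L) * block_s,
      duration = block_s)
    design <- block_design(blocks, tr)
    n_frames <- as.integer(n_blocks * block_s / tr)
    return(list(design = design, endtidal = NULL, n_frames = n_frames))
  }
  blocks <- data.frame(
    label = c("baseline", "hypercapnia", "baseline", "hypercapnia",
              "baseline"),
    onset = c(0, 60, 180, 240, 360),
    duration = c(60, 120, 60, 120, 60))
  design <- block_design(blocks, tr)
  n_frames <- as.integer(sum(blocks$duration) / tr)
  pco2 <- rep(pco2_baseline, n_frames)
  for (fr in block_frames(design, n_frames, "hypercapnia"))
    pco2[fr] <- pco2_plateau
  list(design = design,
       endtidal = end_tidal_trace(pco2, rep(po2, n_frames)),
       n_frames = n_frames)
}

# Hypercapnia CBF ratio implied by a planted M value: inverts the
# deoxyhemoglobin-ratio calibration form (with Severinghaus venous
# saturation at PO2 = 100 mmHg) for the flow ratio.
flow_ratio_for_m <- function(m_target, dbold_frac, alpha = 0.18, beta = 1.5,
                             oef0 = 0.30, po2 = 100) {
  f <- function(r) {
    sv <- estimate_svo2(po2, r, oef0)
    compute_m(dbold_frac, r, svo2 = sv$svo2, svo2_0 = sv$svo2_0,
              alpha = alpha, beta = beta, form = "dhb_ratio")$m - m_target
  }
  stats::uniroot(f, c(1.005, 8), tol = 1e-10)$root
}

#' Draw the subject-level ground truth of a synthetic cohort
#'
#' Samples, per subject: group, sex, the latent vascular factor, the SD_BOLD
#' level in the effect region (per the spec's coupling mode), baseline CBF,
#' CVR and M (each loading on the latent factor with loading 0.9), the
#' within-subject voxelwise coupling, and the hypercapnia flow ratio implied
#' by the planted M. Deterministic given `spec$rng_seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per subject.
#' @export
simulate_cohort_subjects <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_young + spec$n_old
  group <- factor(rep(c("young", "old"), c(spec$n_young, spec$n_old)),
                  levels = c("young", "old"))
  nf_y <- round(spec$female_frac_young * spec$n_young)
  nf_o <- round(spec$female_frac_old * spec$n_old)
  sex <- c(rep(c("F", "M"), c(nf_y, spec$n_young - nf_y)),
           rep(c("F", "M"), c(nf_o, spec$n_old - nf_o)))

  z_v <- stats::rnorm(n)              # latent vascular factor (within group)
  lam <- 0.65                         # loading of each vascular indicator
  mix <- function(mean_y, mean_o, bs_sd) {
    mu <- ifelse(group == "young", mean_y, mean_o)
    x <- mu + bs_sd * (lam * z_v + sqrt(1 - lam^2) * stats::rnorm(n))
    pmax(x, 0.1 * mu)                 # physiological positivity
  }
  cbf <- mix(spec$cbf_mean_young, spec$cbf_mean_old, spec$cbf_bs_sd)
  cvr <- mix(spec$cvr_mean_young, spec$cvr_mean_old, spec$cvr_bs_sd)
  m <- mix(spec$m_mean_young, spec$m_mean_old, spec$m_bs_sd)

  sd_mu <- ifelse(group == "young", spec$sd_young, spec$sd_old)
  if (spec$coupling_mode == "independent") {
    sd_level <- sd_mu + spec$sd_bs_sd * stats::rnorm(n)
  } else if (spec$coupling_mode == "partial") {
    rho <- spec$coupling_rho
    sd_level <- sd_mu + spec$sd_bs_sd *
      (rho * z_v + sqrt(1 - rho^2) * stats::rnorm(n))
  } else {  # fully_mediated: SD is a function of the absolute vascular level
    delta <- mean(c((spec$cbf_mean_young - spec$cbf_mean_old) / spec$cbf_bs_sd,
                    (spec$cvr_mean_young - spec$cvr_mean_old) / spec$cvr_bs_sd,
                    (spec$m_mean_young - spec$m_mean_old) / spec$m_bs_sd))
    if (abs(delta) < 1e-8)
      stop("fully_mediated coupling needs a vascular group difference")
    slope <- (spec$sd_young - spec$sd_old) / delta
    offset <- ifelse(group == "young", delta / 2, -delta / 2)
    sd_level <- (spec$sd_young + spec$sd_old) / 2 +
      slope * (z_v + offset) + 0.3 * spec$sd_bs_sd * stats::rnorm(n)
  }
  sd_level <- pmax(sd_level, 0.05)

  vrho_mu <- ifelse(group == "young", spec$voxel_coupling_young,
                    spec$voxel_coupling_old)
  voxel_rho <- pmin(0.95, pmax(-0.95, vrho_mu + 0.15 * stats::rnorm(n)))

  dbold_frac <- cvr * 5 / 100         # 45 - 40 mmHg plateau step
  # M is the ceiling of the BOLD response, so it must exceed the response
  m <- pmax(m, 1.1 * dbold_frac)
  flow_ratio <- vapply(seq_len(n),
                       function(i) flow_ratio_for_m(m[i], dbold_frac[i]),
                       numeric(1))
  data.frame(id = sprintf("sub%03d", seq_len(n)), group = group, sex = sex,
             latent_vascular = z_v, sd_level = sd_level,
             cbf_roi = cbf, cvr_roi = cvr, m_roi = m,
             voxel_rho = voxel_rho, dbold_frac = dbold_frac,
             flow_ratio = flow_ratio, stringsAsFactors = FALSE)
}

# AR(1) process matrix (rows = voxels) with unit marginal variance,
# rescaled so every row has unit sample SD.
ar1_noise <- function(n_vox, n_frames, phi) {
  e <- matrix(stats::rnorm(n_vox * n_frames), n_vox, n_frames)
  for (t in 2:n_frames) e[, t] <- phi * e[, t - 1] + sqrt(1 - phi^2) * e[, t]
  e / apply(e, 1, stats::sd)
}

# Tag/control difference amplitude that makes quantify_cbf() recover `cbf`
# exactly given the carrier EPI signal (inverse of the closed form).
asl_delta_for_cbf <- function(cbf, epi, params) {
  m0 <- epi / (1 - exp(-params$tr / params$t1_gm))
  cbf * 2 * params$labeling_efficiency * params$t1_blood * m0 *
    (1 - exp(-params$tag_duration / params$t1_blood)) /
    (6000 * params$partition_coefficient *
       exp(params$post_label_delay / params$t1_blood))
}

#' Generate a synthetic dual-echo cohort with known ground truth
#'
#' For every subject, builds a fixation run and (optionally) a hypercapnia
#' run as [dual_echo_series()] objects. The echo-2 fixation series is a
#' uniform grey-matter carrier times `1 + (SD/100) * eta(t)` with `eta` an
#' AR(1) process of exactly unit sample SD, so the per-voxel sample SD of
#' the generated series equals the planted SD. The echo-1 series carries the
#' same BOLD-weighted fluctuations plus a tag/control alternation whose
#' amplitude encodes the planted voxel CBF through the inverse of the
#' quantification closed form. The hypercapnia echo-2 response is
#' CVR * dPCO2 convolved with the canonical HRF (plus a slow drift); its
#' echo-1 tag/control amplitude is modulated by the subject's flow ratio.
#'
#' @param spec A [cohort_spec()].
#' @param runs Character subset of `c("fixation", "hypercapnia")`.
#' @return List of class `synthetic_cohort`: `subjects` (one list per
#'   subject with elements `fixation` and/or `hypercapnia`), `truth`
#'   (subject table plus per-subject-by-voxel matrices `sd_true`,
#'   `cbf_true`, `cvr_true` over GM voxels), `masks`, `effect_region`,
#'   `spec`.
#' @export
generate_cohort <- function(spec, runs = c("fixation", "hypercapnia")) {
  stopifnot(inherits(spec, "cohort_spec"))
  runs <- match.arg(runs, several.ok = TRUE)
  subjects <- simulate_cohort_subjects(spec)
  masks <- spec$masks
  grid <- spec$grid
  n_vox <- prod(grid)
  gm_idx <- which(masks$gm)
  eff <- spec$effect_region[masks$gm]
  params <- acquisition_params(tr = spec$tr)
  fix <- make_design("fixation", tr = spec$tr)
  hyp <- make_design("hypercapnia", tr = spec$tr)
  reg <- build_task_regressor(hyp$design, hyp$n_frames, "hypercapnia")

  carrier_gm <- 600; carrier_other <- 450; carrier_air <- 10
  base <- array(carrier_air, grid)
  base[masks$brain] <- carrier_other
  base[masks$gm] <- carrier_gm
  base_vec <- as.vector(base)

  n <- nrow(subjects)
  sd_true <- cbf_true <- cvr_true <- matrix(NA_real_, n, length(gm_idx))
  out <- vector("list", n)
  for (s in seq_len(n)) {
    set.seed(spec$rng_seed + 1000L + s)
    row <- subjects[s, ]
    # per-voxel spatial fields over GM (lognormal, mean-one)
    f_sd <- stats::rnorm(length(gm_idx))
    mk_field <- function(rho, width) {
      w <- rho * f_sd + sqrt(1 - rho^2) * stats::rnorm(length(gm_idx))
      exp(width * w - width^2 / 2)
    }
    sd_gm <- ifelse(eff, row$sd_level, spec$sd_background) *
      exp(0.15 * f_sd - 0.15^2 / 2)
    cbf_gm <- row$cbf_roi * mk_field(row$voxel_rho, 0.20)
    cvr_gm <- row$cvr_roi * mk_field(row$voxel_rho, 0.20)
    sd_true[s, ] <- sd_gm; cbf_true[s, ] <- cbf_gm; cvr_true[s, ] <- cvr_gm

    sd_vec <- rep(0.2, n_vox)
    sd_vec[as.vector(masks$brain)] <- spec$sd_background
    sd_vec[gm_idx] <- sd_gm
    cbf_vec <- rep(0, n_vox)
    cbf_vec[as.vector(masks$brain)] <- 20
    cbf_vec[gm_idx] <- cbf_gm
    delta_vec <- asl_delta_for_cbf(cbf_vec, base_vec, params)
    sub <- list(id = row$id, group = as.character(row$group), sex = row$sex)

    if ("fixation" %in% runs) {
      nf <- fix$n_frames
      tag <- tag_frame_mask(nf, "even")
      asl_sign <- ifelse(tag, -0.5, 0.5)
      e2 <- base_vec * (1 + outer(sd_vec / 100,
                                  rep(1, nf)) * ar1_noise(n_vox, nf, spec$ar1_phi))
      e2 <- e2 + outer(base_vec * 0.001, asl_sign)
      e1 <- base_vec * (1 + outer(sd_vec / 300,
                                  rep(1, nf)) * ar1_noise(n_vox, nf, spec$ar1_phi))
      e1 <- e1 + outer(delta_vec, asl_sign)
      sub$fixation <- dual_echo_series(array(e1, c(grid, nf)),
                                       array(e2, c(grid, nf)),
                                       "even", params, fix$design)
    }
    if ("hypercapnia" %in% runs) {
      nh <- hyp$n_frames
      tag <- tag_frame_mask(nh, "even")
      asl_sign <- ifelse(tag, -0.5, 0.5)
      dbold_vec <- rep(0, n_vox)
      dbold_vec[gm_idx] <- cvr_gm * 5 / 100
      drift <- 0.002 * seq(-1, 1, length.out = nh)
      e2 <- base_vec * (1 + outer(dbold_vec, reg) + outer(rep(1, n_vox), drift) +
                          outer(sd_vec / 100, rep(1, nh)) *
                            ar1_noise(n_vox, nh, spec$ar1_phi))
      e2 <- e2 + outer(base_vec * 0.001, asl_sign)
      flow_mod <- 1 + (row$flow_ratio - 1) * reg
      e1 <- base_vec * (1 + outer(rep(1, n_vox), drift) +
                          outer(sd_vec / 300, rep(1, nh)) *
                            ar1_noise(n_vox, nh, spec$ar1_phi))
      e1 <- e1 + (delta_vec %o% flow_mod) * rep(asl_sign, each = n_vox)
      sub$hypercapnia <- dual_echo_series(array(e1, c(grid, nh)),
                                          array(e2, c(grid, nh)),
                                          "even", params, hyp$design,
                                          hyp$endtidal)
    }
    out[[s]] <- sub
  }
  structure(list(subjects = out,
                 truth = list(subjects = subjects, sd_true = sd_true,
                              cbf_true = cbf_true, cvr_true = cvr_true,
                              gm_index = gm_idx,
                              effect_region_gm = eff),
                 masks = masks, effect_region = spec$effect_region,
                 spec = spec),
            class = "synthetic_cohort")
}

# Isolated-voxel lattice (period 2) and 2x2x2 block lattice (period 3)
# patterns inside a mask: speckled layouts whose connected components stay
# below the 10-voxel cluster criterion by construction.
scatter_pattern <- function(mask, kind = c("sparse", "blocks"),
                            density = 0.08) {
  kind <- match.arg(kind)
  d <- dim(mask)
  sel <- array(FALSE, d)
  if (kind == "sparse") {
    sel[seq(1, d[1], by = 2), seq(1, d[2], by = 2), seq(1, d[3], by = 2)] <- TRUE
    sel <- sel & mask
    keep <- which(sel)
    want <- max(1L, round(density * sum(mask)))
    if (length(keep) > want)
      sel[sample(keep, length(keep) - want)] <- FALSE
  } else {
    bb <- apply(which(mask, arr.ind = TRUE), 2, range)
    for (x0 in seq(bb[1, 1], bb[2, 1], by = 3))
      for (y0 in seq(bb[1, 2], bb[2, 2], by = 3))
        for (z0 in seq(bb[1, 3], bb[2, 3], by = 3))
          sel[x0:min(x0 + 1, d[1]), y0:min(y0 + 1, d[2]),
              z0:min(z0 + 1, d[3])] <- TRUE
    sel <- sel & mask
  }
  sel
}

#' Inject ground-truth artifact components into a run
#'
#' Adds one component per requested artifact type to the echo-2 series and
#' returns both the corrupted series and the planted component time courses
#' and spatial maps, so the criteria-based classifier can be evaluated
#' against known truth. Types: `"spike"` (one >= 6 robust-SD frame),
#' `"drift"` (linear ramp), `"highfreq"` (0.15 Hz oscillation),
#' `"scattered"` (speckled spatial pattern covering >= 25% of the brain with
#' all clusters below 10 voxels).
#'
#' @param series A [dual_echo_series()].
#' @param types Character vector of artifact types.
#' @param masks Grid masks (see [make_grid_masks()]).
#' @param seed Integer RNG seed.
#' @param amplitude Component amplitude in signal units.
#' @return List: `series` (corrupted copy), `components` (list of lists with
#'   `timecourse`, `spatial_map`, `id`, `type`).
#' @export
inject_artifacts <- function(series, types, masks, seed = 1L,
                             amplitude = 8) {
  known <- c("spike", "drift", "highfreq", "scattered")
  bad <- setdiff(types, known)
  if (length(bad)) stop("unknown artifact type(s): ", paste(bad, collapse = ", "))
  if (!length(types)) return(list(series = series, components = list()))
  set.seed(seed)
  d <- dim(series$echo2)
  nf <- d[4]
  tt <- frame_times(nf, series$params$tr)
  comps <- list()
  e2 <- series$echo2
  for (ty in types) {
    if (ty == "spike") {
      tc <- stats::rnorm(nf, 0, 1)
      tc[sample(seq(3, nf - 2), 1)] <- 12
      map3 <- array(0, d[1:3])
      sel <- scatter_pattern(masks$brain, "sparse", 0.08)
      map3[sel] <- amplitude * sample(c(-1, 1), sum(sel), replace = TRUE)
      map3[masks$brain & !sel] <- stats::rnorm(sum(masks$brain & !sel), 0, 0.1)
    } else if (ty == "drift") {
      tc <- seq(-2, 2, length.out = nf) + stats::rnorm(nf, 0, 0.02)
      map3 <- array(0, d[1:3])
      map3[masks$brain] <- amplitude / 4 +
        stats::rnorm(sum(masks$brain), 0, 0.1)
    } else if (ty == "highfreq") {
      tc <- sin(2 * pi * 0.15 * tt) + stats::rnorm(nf, 0, 0.05)
      map3 <- array(0, d[1:3])
      sel <- scatter_pattern(masks$brain, "sparse", 0.08)
      map3[sel] <- amplitude * sample(c(-1, 1), sum(sel), replace = TRUE)
      map3[masks$brain & !sel] <- stats::rnorm(sum(masks$brain & !sel), 0, 0.1)
    } else {  # scattered
      tc <- sin(2 * pi * 0.05 * tt + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(nf, 0, 0.1)
      map3 <- array(0, d[1:3])
      sel <- scatter_pattern(masks$brain, "blocks")
      map3[sel] <- amplitude * sample(c(-1, 1), sum(sel), replace = TRUE)
      map3[masks$brain & !sel] <- stats::rnorm(sum(masks$brain & !sel), 0, 0.1)
    }
    id <- sprintf("ic_%s", ty)
    comps[[id]] <- list(timecourse = tc, spatial_map = map3, id = id,
                        type = ty)
    e2 <- e2 + array(outer(as.vector(map3), tc), d)
  }
  series$echo2 <- e2
  list(series = series, components = comps)
}
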