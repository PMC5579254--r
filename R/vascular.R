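#' Canonical hemodynamic response function (difference of gammas)
#'
#' Glover-style single-subject HRF: a gamma density peaking at 6 s minus
#' 1/6 of a gamma density peaking at 16 s (the undershoot), normalized to a
#' peak of 1.
#'
#' @param t Time points, seconds (t >= 0).
#' @return HRF values at `t`.
#' @export
glover_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 7, rate = 1) -
    (1 / 6) * stats::dgamma(t, shape = 17, rate = 1)
  tt <- seq(0, 32, by = 0.1)
  peak <- max(stats::dgamma(tt, shape = 7, rate = 1) -
                (1 / 6) * stats::dgamma(tt, shape = 17, rate = 1))
  h / peak
}

#' HRF-convolved block regressor
#'
#' Boxcar over the blocks carrying `label`, sampled at frame times and
#' convolved with [glover_hrf()]; the result is scaled so that a sustained
#' block reaches a plateau of 1.
#'
#' @param design A [block_design()].
#' @param n_frames Number of frames in the run.
#' @param label Block label to model (e.g. "hypercapnia").
#' @return Numeric vector of length `n_frames`.
#' @export
build_task_regressor <- function(design, n_frames, label = "hypercapnia") {
  tr <- design$tr
  box <- numeric(n_frames)
  for (fr in block_frames(design, n_frames, label)) box[fr] <- 1
  if (!any(box > 0)) stop("design has no '", label, "' blocks")
  h <- glover_hrf(seq(0, 32, by = tr))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_frames)]
  conv / sum(h)  # sustained-block plateau = sum of the sampled HRF
}

#' Fit the hypercapnia block GLM per voxel
#'
#' Least-squares fit of the design `[HRF-convolved boxcar, 1, t, t^2, t^3]`
#' (drift polynomials orthogonalized as Legendre polynomials over the run;
#' the effect and constant terms are invariant to this choice). The
#' fractional signal change is effect / constant.
#'
#' @param x 4D array or voxel-by-frame matrix.
#' @param design A [block_design()] containing at least one active block.
#' @param label Label of the active blocks (default "hypercapnia").
#' @param drift_order Highest drift polynomial degree (default 3).
#' @return List of class `glm_fit`: per-voxel vectors `effect`, `constant`,
#'   `fractional_change`, matrix `drift` of drift coefficients, and the
#'   `regressor` used.
#' @export
fit_block_glm <- function(x, design, label = "hypercapnia", drift_order = 3) {
  vm <- as_voxel_matrix(x)
  m <- vm$m
  n <- ncol(m)
  reg <- build_task_regressor(design, n, label)
  u <- seq(-1, 1, length.out = n)
  drifts <- stats::poly(u, degree = drift_order, raw = FALSE)
  X <- cbind(reg, 1, drifts)
  if (n < ncol(X) + 2L) stop("too few frames for the GLM design")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient GLM design")
  beta <- qr.coef(qx, t(m))
  effect <- beta[1, ]
  constant <- beta[2, ]
  frac <- ifelse(abs(constant) > .Machine$double.eps, effect / constant, NA_real_)
  structure(list(effect = effect, constant = constant,
                 fractional_change = frac,
                 drift = t(beta[-(1:2), , drop = FALSE]),
                 regressor = reg),
            class = "glm_fit")
}

#' Absolute CBF from the baseline ASL difference signal
#'
#' Single-compartment pCASL quantification. The baseline EPI signal serves as
#' a surrogate for the equilibrium magnetization and is corrected for
#' incomplete longitudinal recovery over the TR using the grey-matter T1:
#' `M0 = EPI / (1 - exp(-TR / T1_gm))`. Then
#' \deqn{CBF = \frac{6000\,\lambda\,\Delta M\,e^{PLD/T1_b}}
#'   {2\,\alpha\,T1_b\,M_0\,(1 - e^{-\tau/T1_b})}}
#' in ml/100g/min, with \eqn{\lambda} the partition coefficient, \eqn{\alpha}
#' the labeling efficiency, PLD the post-labeling delay and \eqn{\tau} the
#' tag duration.
#'
#' @param delta_m Baseline tag/control difference signal (scalar, vector or
#'   array).
#' @param epi_baseline Unsubtracted baseline EPI signal, same shape; must be
#'   strictly positive.
#' @param params An [acquisition_params()] object.
#' @return CBF in ml/100g/min, same shape as `delta_m`.
#' @export
quantify_cbf <- function(delta_m, epi_baseline, params) {
  stopifnot(inherits(params, "acquisition_params"))
  if (any(epi_baseline <= 0)) stop("baseline EPI signal must be positive")
  m0 <- epi_baseline / (1 - exp(-params$tr / params$t1_gm))
  6000 * params$partition_coefficient * delta_m *
    exp(params$post_label_delay / params$t1_blood) /
    (2 * params$labeling_efficiency * params$t1_blood * m0 *
       (1 - exp(-params$tag_duration / params$t1_blood)))
}

#' Cerebrovascular reactivity
#'
#' CVR = percent BOLD signal change during hypercapnia divided by the
#' end-tidal PCO2 increase, in %BOLD/mmHg.
#'
#' @param pct_bold_change Percent BOLD signal change (e.g. 2 for 2%).
#' @param delta_pco2 End-tidal PCO2 increase, mmHg; must be non-zero.
#' @return CVR, same shape as the inputs.
#' @export
compute_cvr <- function(pct_bold_change, delta_pco2) {
  if (any(delta_pco2 == 0))
    stop("delta_pco2 is zero: no hypercapnic stimulus to normalize by")
  pct_bold_change / delta_pco2
}

#' Venous oxygen saturation from end-tidal O2 and the CBF ratio
#'
#' Arterial saturation follows the Severinghaus dissociation curve,
#' `SaO2 = (23400 / (PO2^3 + 150 PO2) + 1)^-1`. Baseline venous saturation
#' is `SaO2 (1 - OEF0)`. Under iso-metabolic hypercapnia with constant
#' arterial content, oxygen extraction scales inversely with flow
#' (OEF = OEF0 / cbf_ratio), giving `SvO2 = SaO2 (1 - OEF0 / cbf_ratio)`.
#' Dissolved oxygen is neglected.
#'
#' @param po2 End-tidal PO2, mmHg (> 0).
#' @param cbf_ratio CBF during the manipulation relative to baseline (> 0).
#' @param oef0 Baseline oxygen extraction fraction, in (0, 1).
#' @return List: `svo2`, `svo2_0`, `sao2`.
#' @export
estimate_svo2 <- function(po2, cbf_ratio, oef0 = 0.30) {
  if (any(po2 <= 0)) stop("po2 must be positive")
  if (any(cbf_ratio <= 0)) stop("cbf_ratio must be positive")
  if (oef0 <= 0 || oef0 >= 1) stop("oef0 must lie in (0, 1)")
  sao2 <- 1 / (23400 / (po2^3 + 150 * po2) + 1)
  if (any(oef0 / cbf_ratio >= 1))
    stop("OEF0 / cbf_ratio >= 1: venous blood would be fully desaturated")
  list(svo2 = sao2 * (1 - oef0 / cbf_ratio),
       svo2_0 = sao2 * (1 - oef0),
       sao2 = sao2)
}

#' Maximum BOLD signal change (M) via the generalized calibration model
#'
#' With `form = "printed"` the denominator is
#' `1 - cbf_ratio^alpha - dhb_ratio^beta` where
#' `dhb_ratio = (1 - svo2) / (1 - svo2_0)`. For physiological hypercapnia
#' both subtracted terms are close to 1, so this form yields a negative M;
#' the result then carries `physiological = FALSE`. `form = "dhb_ratio"`
#' uses the standard deoxyhemoglobin-ratio denominator
#' `1 - cbf_ratio^(alpha - beta) * dhb_ratio^beta`, which is positive for
#' such inputs.
#'
#' @param dbold_over_bold0 Fractional BOLD change during hypercapnia.
#' @param cbf_ratio CBF during hypercapnia relative to baseline (> 0).
#' @param dhb_ratio Deoxyhemoglobin concentration ratio
#'   `(1 - svo2) / (1 - svo2_0)`; either supply it directly or supply `svo2`
#'   and `svo2_0`.
#' @param svo2,svo2_0 Venous saturation during the manipulation / at
#'   baseline, fractions in (0, 1).
#' @param alpha Flow-volume coupling exponent (default 0.18).
#' @param beta Deoxyhemoglobin transverse-relaxation exponent (default 1.5).
#' @param form "printed" or "dhb_ratio" (see Details).
#' @return List of class `gcm_m`: `m`, `denominator`, `physiological`
#'   (`TRUE` when m > 0), `form`.
#' @export
compute_m <- function(dbold_over_bold0, cbf_ratio, dhb_ratio = NULL,
                      svo2 = NULL, svo2_0 = NULL,
                      alpha = 0.18, beta = 1.5,
                      form = c("printed", "dhb_ratio")) {
  form <- match.arg(form)
  if (is.null(dhb_ratio)) {
    if (is.null(svo2) || is.null(svo2_0))
      stop("supply either dhb_ratio or both svo2 and svo2_0")
    if (any(svo2 <= 0 | svo2 >= 1) || any(svo2_0 <= 0 | svo2_0 >= 1))
      stop("saturations must lie in (0, 1)")
    dhb_ratio <- (1 - svo2) / (1 - svo2_0)
  }
  if (any(cbf_ratio <= 0)) stop("cbf_ratio must be positive")
  den <- if (form == "printed") {
    1 - cbf_ratio^alpha - dhb_ratio^beta
  } else {
    1 - cbf_ratio^(alpha - beta) * dhb_ratio^beta
  }
  if (any(abs(den) <= 1e-6))
    stop("calibration denominator is numerically zero")
  m <- dbold_over_bold0 / den
  structure(list(m = m, denominator = den,
                 physiological = m > 0, form = form),
            class = "gcm_m")
}
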