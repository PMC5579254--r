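#' Acquisition parameters for a dual-echo pCASL/BOLD sequence
#'
#' Bundles the sequence timing and the constants entering absolute CBF
#' quantification. Defaults correspond to a 3 T dual-echo pCASL protocol:
#' TR 3 s, TE1 10 ms (flow-weighted), TE2 30 ms (BOLD-weighted),
#' post-labeling delay 0.9 s, tagging duration 1.5 s, labeling efficiency
#' 0.80, blood-brain partition coefficient 0.9 ml/g, blood T1 1.49 s and
#' grey-matter T1 1.4 s.
#'
#' @param tr Repetition time, seconds.
#' @param te1,te2 Echo times, seconds; `te1 < te2`.
#' @param post_label_delay Post-labeling delay, seconds.
#' @param tag_duration Labeling (tag) duration, seconds.
#' @param labeling_efficiency Inversion efficiency, fraction in (0, 1].
#' @param partition_coefficient Blood-brain partition coefficient, ml/g.
#' @param t1_blood Longitudinal relaxation time of arterial blood, seconds.
#' @param t1_gm Longitudinal relaxation time of grey matter, seconds.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(tr = 3.0, te1 = 0.010, te2 = 0.030,
                               post_label_delay = 0.9, tag_duration = 1.5,
                               labeling_efficiency = 0.80,
                               partition_coefficient = 0.9,
                               t1_blood = 1.49, t1_gm = 1.4) {
  vals <- c(tr = tr, te1 = te1, te2 = te2,
            post_label_delay = post_label_delay, tag_duration = tag_duration,
            labeling_efficiency = labeling_efficiency,
            partition_coefficient = partition_coefficient,
            t1_blood = t1_blood, t1_gm = t1_gm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all acquisition parameters must be finite and strictly positive")
  if (te1 >= te2) stop("te1 must be shorter than te2")
  structure(as.list(vals), class = "acquisition_params")
}

#' Block design for a functional run
#'
#' @param blocks Data frame with columns `label` (one of "fixation", "task",
#'   "hypercapnia", "baseline"), `onset` (s) and `duration` (s).
#' @param tr Repetition time, seconds; block durations must be positive
#'   multiples of `tr`.
#' @return Object of class `block_design`.
#' @export
block_design <- function(blocks, tr) {
  stopifnot(is.data.frame(blocks),
            all(c("label", "onset", "duration") %in% names(blocks)))
  ok_labels <- c("fixation", "task", "hypercapnia", "baseline")
  if (!all(blocks$label %in% ok_labels))
    stop("unknown block label(s): ",
         paste(setdiff(blocks$label, ok_labels), collapse = ", "))
  blocks <- blocks[order(blocks$onset), , drop = FALSE]
  if (any(blocks$duration <= 0) ||
      any(abs(blocks$duration / tr - round(blocks$duration / tr)) > 1e-9))
    stop("block durations must be positive multiples of TR")
  ends <- blocks$onset + blocks$duration
  if (nrow(blocks) > 1 && any(blocks$onset[-1] < ends[-nrow(blocks)] - 1e-9))
    stop("blocks overlap")
  structure(list(blocks = blocks, tr = tr), class = "block_design")
}

#' End-tidal gas trace
#'
#' Per-frame end-tidal partial pressures of CO2 and O2 in mmHg.
#'
#' @param pco2,po2 Numeric vectors of equal length, values in (0, 800).
#' @return Object of class `end_tidal_trace`.
#' @export
end_tidal_trace <- function(pco2, po2) {
  if (length(pco2) != length(po2))
    stop("pco2 and po2 must have the same length")
  if (any(!is.finite(c(pco2, po2))) ||
      any(c(pco2, po2) <= 0) || any(c(pco2, po2) >= 800))
    stop("end-tidal values must lie in (0, 800) mmHg")
  structure(list(pco2 = pco2, po2 = po2), class = "end_tidal_trace")
}

#' Dual-echo acquisition series
#'
#' Holds the 4D echo-1 (flow-weighted) and echo-2 (BOLD-weighted) frames of a
#' dual-echo pCASL run together with tag/control parity and acquisition
#' metadata. Frames are indexed along the fourth dimension; `tag_parity`
#' refers to 0-based acquisition numbering ("even" means frames 0, 2, 4, ...
#' are tag frames).
#'
#' @param echo1,echo2 4D arrays (x, y, z, frame) of identical dimension; the
#'   frame count must be even so that tag/control pairing is complete.
#' @param tag_parity "even" or "odd".
#' @param params An [acquisition_params()] object.
#' @param design A [block_design()] object.
#' @param endtidal Optional [end_tidal_trace()] with one value per frame.
#' @return Object of class `dual_echo_series`.
#' @export
dual_echo_series <- function(echo1, echo2, tag_parity = c("even", "odd"),
                             params, design, endtidal = NULL) {
  tag_parity <- match.arg(tag_parity)
  if (length(dim(echo1)) != 4L || !identical(dim(echo1), dim(echo2)))
    stop("echo1 and echo2 must be 4D arrays of identical dimension")
  if (dim(echo1)[4] %% 2L != 0L)
    stop("frame count must be even for tag/control pairing")
  if (!inherits(params, "acquisition_params")) stop("invalid params")
  if (!inherits(design, "block_design")) stop("invalid design")
  if (!is.null(endtidal)) {
    if (!inherits(endtidal, "end_tidal_trace")) stop("invalid endtidal trace")
    if (length(endtidal$pco2) != dim(echo1)[4])
      stop("end-tidal trace length must equal frame count")
  }
  structure(list(echo1 = echo1, echo2 = echo2, tag_parity = tag_parity,
                 params = params, design = design, endtidal = endtidal),
            class = "dual_echo_series")
}

#' Per-voxel scalar map over a mask
#'
#' @param values 3D numeric array; must be finite on every mask voxel.
#' @param mask 3D logical array of the same dimension, at least one `TRUE`.
#' @param name Label for the quantity (e.g. "sd_bold", "cbf", "bsr").
#' @return Object of class `voxel_map`.
#' @export
voxel_map <- function(values, mask, name = "map") {
  if (!identical(dim(values), dim(mask)))
    stop("values and mask must share dimensions")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask is empty")
  if (any(!is.finite(values[mask])))
    stop("values must be finite on the mask")
  structure(list(values = values, mask = mask, name = name),
            class = "voxel_map")
}

#' Analysis configuration
#'
#' Central container for the pipeline's tunable thresholds. Defaults: BSR
#' threshold 2.70 (beyond the two-sided 99% normal critical value), 1000
#' permutations and 1000 bootstrap resamples, 0.01 Hz high-pass cutoff, 8 mm
#' FWHM spatial smoothing, univariate outliers beyond 2.5 SD, at most 5% of
#' cases removed by the multivariate (Mahalanobis) filter, and calibration
#' constants alpha = 0.18 (flow-volume coupling) and beta = 1.5
#' (deoxyhemoglobin exponent).
#'
#' @param bsr_threshold Bootstrap-ratio threshold for region definition.
#' @param n_permutations,n_bootstraps Resampling counts for PLS inference.
#' @param highpass_hz Temporal high-pass cutoff, Hz.
#' @param smooth_fwhm_mm Spatial smoothing kernel FWHM, mm (0 disables).
#' @param univariate_outlier_sd Univariate outlier cut in SD units.
#' @param mahalanobis_cap Maximum fraction of cases the multivariate filter
#'   may remove, in (0, 0.5).
#' @param gcm_alpha,gcm_beta Calibration-model exponents.
#' @param gcm_oef0 Baseline oxygen extraction fraction used for venous
#'   saturation, in (0, 1).
#' @param gcm_form Which calibration denominator [compute_m()] uses in the
#'   pipeline; the "dhb_ratio" default keeps M positive for physiological
#'   hypercapnia inputs so the downstream log transform is defined.
#' @param voxel_size_mm Isotropic voxel size assumed for smoothing, mm.
#' @param rng_seed Integer seed controlling every stochastic stage.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(bsr_threshold = 2.70,
                            n_permutations = 1000L,
                            n_bootstraps = 1000L,
                            highpass_hz = 0.01,
                            smooth_fwhm_mm = 8,
                            univariate_outlier_sd = 2.5,
                            mahalanobis_cap = 0.05,
                            gcm_alpha = 0.18,
                            gcm_beta = 1.5,
                            gcm_oef0 = 0.30,
                            gcm_form = c("dhb_ratio", "printed"),
                            voxel_size_mm = 4,
                            rng_seed = 1L) {
  gcm_form <- match.arg(gcm_form)
  pos <- c(bsr_threshold, n_permutations, n_bootstraps, highpass_hz,
           univariate_outlier_sd, mahalanobis_cap, gcm_alpha, gcm_beta,
           gcm_oef0, voxel_size_mm)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all thresholds must be positive")
  if (smooth_fwhm_mm < 0) stop("smooth_fwhm_mm must be non-negative")
  if (mahalanobis_cap >= 0.5) stop("mahalanobis_cap must lie in (0, 0.5)")
  if (gcm_oef0 >= 1) stop("gcm_oef0 must lie in (0, 1)")
  structure(list(bsr_threshold = bsr_threshold,
                 n_permutations = as.integer(n_permutations),
                 n_bootstraps = as.integer(n_bootstraps),
                 highpass_hz = highpass_hz,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 univariate_outlier_sd = univariate_outlier_sd,
                 mahalanobis_cap = mahalanobis_cap,
                 gcm_alpha = gcm_alpha, gcm_beta = gcm_beta,
                 gcm_oef0 = gcm_oef0, gcm_form = gcm_form,
                 voxel_size_mm = voxel_size_mm,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' Any key present in the file overrides the corresponding
#' [analysis_config()] default; unknown keys are an error.
#'
#' @param path File path.
#' @return `read_config` returns an `analysis_config`; `write_config`
#'   invisibly returns `path`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config An `analysis_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Frame acquisition times (s), 0-based convention: frame f starts at (f-1)*tr.
frame_times <- function(n_frames, tr) (seq_len(n_frames) - 1) * tr

# Indices of frames falling inside blocks with the given label
# (half-open intervals [onset, onset + duration)).
block_frames <- function(design, n_frames, label) {
  t0 <- frame_times(n_frames, design$tr)
  b <- design$blocks[design$blocks$label == label, , drop = FALSE]
  lapply(seq_len(nrow(b)), function(i) {
    which(t0 >= b$onset[i] - 1e-9 & t0 < b$onset[i] + b$duration[i] - 1e-9)
  })
}

# Logical vector marking tag frames (0-based parity convention).
tag_frame_mask <- function(n_frames, tag_parity) {
  a <- seq_len(n_frames) - 1L
  if (tag_parity == "even") a %% 2L == 0L else a %% 2L == 1L
}

# Coerce a 4D array or voxel-by-frame matrix to matrix form; returns the
# matrix plus a restore function, so signal operations can be written once.
as_voxel_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    m <- as.matrix(x)
    list(m = m, restore = function(y) y)
  } else if (length(d) == 4L) {
    m <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
    list(m = m, restore = function(y) array(y, dim = d))
  } else {
    stop("expected a voxel-by-frame matrix or a 4D array")
  }
}
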