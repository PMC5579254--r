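#' Isolate the perfusion-weighted signal by linear surround subtraction
#'
#' For a tag/control interleaved ASL series, frame i is replaced by the
#' signed difference between frame i and the mean of its temporal neighbours,
#' with the sign chosen per frame so that control minus tag is positive.
#' Endpoints use their single available neighbour. The tag/control modulation
#' (amplitude Delta around the carrier) is thereby recovered at every frame
#' while the slowly varying BOLD carrier cancels.
#'
#' @param x 4D array (x, y, z, frame) or voxel-by-frame matrix with at least
#'   3 frames.
#' @param tag_parity "even" or "odd": which 0-based frame parity carries the
#'   tag (label) condition.
#' @return Flow-weighted series of the same shape as `x`.
#' @export
surround_subtract <- function(x, tag_parity = c("even", "odd")) {
  tag_parity <- match.arg(tag_parity)
  vm <- as_voxel_matrix(x)
  m <- vm$m
  n <- ncol(m)
  if (n < 3L) stop("surround subtraction needs at least 3 frames")
  nb <- neighbour_mean(m)
  s <- ifelse(tag_frame_mask(n, tag_parity), -1, 1)
  out <- sweep(m - nb, 2, s, `*`)
  vm$restore(out)
}

#' Extract the BOLD-weighted signal by linear surround addition
#'
#' Frame i becomes the mean of frame i and the mean of its temporal
#' neighbours, averaging out the tag/control modulation; endpoints use the
#' single available neighbour.
#'
#' @inheritParams surround_subtract
#' @return BOLD series of the same shape as `x`.
#' @export
surround_add <- function(x) {
  vm <- as_voxel_matrix(x)
  m <- vm$m
  if (ncol(m) < 3L) stop("surround addition needs at least 3 frames")
  vm$restore((m + neighbour_mean(m)) / 2)
}

# Mean of temporal neighbours per frame; endpoints use the single neighbour.
neighbour_mean <- function(m) {
  n <- ncol(m)
  nb <- m
  nb[, 2:(n - 1)] <- (m[, 1:(n - 2), drop = FALSE] +
                      m[, 3:n, drop = FALSE]) / 2
  nb[, 1] <- m[, 2]
  nb[, n] <- m[, n - 1]
  nb
}

#' Temporal high-pass filter
#'
#' Zero-phase (forward-backward) order-5 Butterworth high-pass applied per
#' voxel. The temporal mean and fluctuations below the cutoff are removed;
#' frequencies at twice the cutoff and above pass essentially unattenuated.
#'
#' @inheritParams surround_subtract
#' @param cutoff_hz Cutoff frequency, Hz; must be below the Nyquist
#'   frequency `1/(2 tr)`.
#' @param tr Repetition time, seconds.
#' @return Filtered series, same shape as `x`.
#' @export
highpass_filter <- function(x, cutoff_hz, tr) {
  nyq <- 1 / (2 * tr)
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("cutoff must lie in (0, Nyquist = ", signif(nyq, 4), " Hz)")
  vm <- as_voxel_matrix(x)
  m <- vm$m
  bf <- signal::butter(5, cutoff_hz / nyq, type = "high")
  out <- t(apply(m, 1, function(v) signal::filtfilt(bf, v - mean(v))))
  vm$restore(out)
}

#' Spatial Gaussian smoothing
#'
#' Per-frame separable Gaussian convolution with sigma = FWHM / 2.3548
#' (converted to voxels). Kernels are truncated at 3 sigma and renormalized
#' at the volume edges so that constant volumes are preserved exactly.
#' `fwhm_mm = 0` is the identity.
#'
#' @param x 3D volume or 4D series.
#' @param fwhm_mm Kernel full width at half maximum, mm.
#' @param voxel_size_mm Voxel edge length, mm; scalar or length-3.
#' @return Smoothed array, same shape as `x`.
#' @export
smooth_spatial <- function(x, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(x)
  d <- dim(x)
  if (length(d) == 3L) {
    return(smooth_volume(x, fwhm_mm, rep(voxel_size_mm, length.out = 3)))
  }
  if (length(d) != 4L) stop("expected a 3D or 4D array")
  vs <- rep(voxel_size_mm, length.out = 3)
  out <- x
  for (f in seq_len(d[4])) out[, , , f] <- smooth_volume(x[, , , f], fwhm_mm, vs)
  out
}

# 1D Gaussian kernel at the given sigma (voxels), truncated at 3 sigma.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w / sum(w)
}

smooth_volume <- function(vol, fwhm_mm, voxel_size_mm) {
  for (ax in 1:3) {
    sigma <- fwhm_mm / 2.3548 / voxel_size_mm[ax]
    vol <- convolve_axis(vol, gaussian_kernel_1d(sigma), ax)
  }
  vol
}

# Separable convolution along one axis with edge renormalization.
convolve_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  r <- (length(kernel) - 1L) / 2L
  acc <- array(0, d)
  wsum <- array(0, d)
  n <- d[axis]
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    idx_dst <- which(ok)
    idx_src <- src[ok]
    sl_dst <- slice_index(d, axis, idx_dst)
    sl_src <- slice_index(d, axis, idx_src)
    acc[sl_dst$i, sl_dst$j, sl_dst$k] <- acc[sl_dst$i, sl_dst$j, sl_dst$k] +
      kernel[k] * vol[sl_src$i, sl_src$j, sl_src$k]
    wsum[sl_dst$i, sl_dst$j, sl_dst$k] <-
      wsum[sl_dst$i, sl_dst$j, sl_dst$k] + kernel[k]
  }
  acc / wsum
}

slice_index <- function(d, axis, idx) {
  out <- list(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  out[[axis]] <- idx
  out
}

#' Label connected components of a 3D logical mask
#'
#' @param mask 3D logical array.
#' @param connectivity 26 (default, faces + edges + corners) or 6 (faces).
#' @return Integer array of cluster labels (0 = background).
#' @export
label_clusters <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6, 26))
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  labels <- array(0L, d)
  nextlab <- 0L
  coords <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(coords))) {
    v <- coords[s, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    nextlab <- nextlab + 1L
    queue <- matrix(v, nrow = 1)
    labels[v[1], v[2], v[3]] <- nextlab
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      cand <- sweep(offs, 2, cur, `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      for (q in seq_len(nrow(cand))) {
        w <- cand[q, ]
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- nextlab
          queue <- rbind(queue, w)
        }
      }
    }
  }
  labels
}

# Robust z-scores (median / scaled MAD); falls back to mean/sd if MAD is 0.
robust_z <- function(v) {
  med <- stats::median(v)
  s <- stats::mad(v)
  if (s < .Machine$double.eps) s <- stats::sd(v)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(v)))
  (v - med) / s
}

# Raw periodogram of the demeaned course: frequencies (Hz) and power.
periodogram_power <- function(tc, tr) {
  n <- length(tc)
  v <- tc - mean(tc)
  p <- Mod(stats::fft(v))^2
  nf <- floor(n / 2)
  list(freq = (1:nf) / (n * tr), power = p[2:(nf + 1)])
}

#' Classify an independent component as signal or noise
#'
#' Operationalizes the conservative criteria-based rejection used in manual
#' ICA denoising of fMRI runs:
#' \itemize{
#'   \item spike: maximum robust |z| (median/MAD) of the time course >= 6;
#'   \item highfreq: >= 75% of periodogram power above 0.13 Hz;
#'   \item drift: >= 50% of power below the high-pass cutoff;
#'   \item scattered: suprathreshold voxels (robust |z| >= 2 of the spatial
#'     map over the brain mask) cover >= 25% of the brain with < 5% of them
#'     in clusters of >= 10 contiguous voxels;
#'   \item wm_csf / edge: >= 50% of suprathreshold voxels inside the
#'     respective mask.
#' }
#' A component that fires a criterion is nevertheless kept when its
#' suprathreshold map lies >= 60% in grey matter and contains a dominant
#' cluster of >= 10 voxels (keep-on-ambiguity: apparent signal and noise
#' co-occur, and conservative practice is to keep).
#'
#' @param component List with elements `timecourse` (per-frame weights),
#'   `spatial_map` (3D array) and `id`.
#' @param masks List of 3D logical arrays `brain`, `gm`, `wm_csf`, `edge`
#'   on the data grid.
#' @param tr Repetition time, seconds.
#' @param highpass_hz High-pass cutoff used for the drift criterion.
#' @param map_z_threshold Robust-z threshold defining suprathreshold voxels.
#' @param connectivity Cluster connectivity (26 or 6).
#' @return List of class `component_flags`: logical flags, the computed
#'   metrics, and `decision` ("keep" or "reject").
#' @export
classify_component <- function(component, masks, tr, highpass_hz = 0.01,
                               map_z_threshold = 2, connectivity = 26) {
  tc <- component$timecourse
  map <- component$spatial_map
  if (!identical(dim(map), dim(masks$brain)))
    stop("component map and masks must share the data grid")
  brain <- masks$brain

  z_tc <- robust_z(tc)
  spike <- max(abs(z_tc)) >= 6

  pg <- periodogram_power(tc, tr)
  tot <- sum(pg$power)
  hf_frac <- if (tot > 0) sum(pg$power[pg$freq > 0.13]) / tot else 0
  lf_frac <- if (tot > 0) sum(pg$power[pg$freq < highpass_hz]) / tot else 0
  highfreq <- hf_frac >= 0.75
  drift <- lf_frac >= 0.50

  zmap <- array(0, dim(map))
  zmap[brain] <- robust_z(map[brain])
  supra <- abs(zmap) >= map_z_threshold & brain
  n_supra <- sum(supra)
  brain_frac <- n_supra / sum(brain)

  labs <- label_clusters(supra, connectivity)
  sizes <- if (n_supra > 0) tabulate(labs[supra]) else integer(0)
  largest <- if (length(sizes)) max(sizes) else 0L
  in_big <- if (n_supra > 0) sum(sizes[sizes >= 10]) / n_supra else 0
  scattered <- brain_frac >= 0.25 && in_big < 0.05

  wm_frac <- if (n_supra > 0) sum(supra & masks$wm_csf) / n_supra else 0
  edge_frac <- if (n_supra > 0) sum(supra & masks$edge) / n_supra else 0
  gm_frac <- if (n_supra > 0) sum(supra & masks$gm) / n_supra else 0
  wm_csf <- wm_frac >= 0.5
  edge <- edge_frac >= 0.5

  flags <- c(spike = spike, highfreq = highfreq, scattered = scattered,
             wm_csf = wm_csf, edge = edge, drift = drift)
  keep_rule <- gm_frac >= 0.60 && largest >= 10L
  decision <- if (any(flags) && !keep_rule) "reject" else "keep"

  structure(list(id = component$id, flags = flags, decision = decision,
                 metrics = list(max_abs_z = max(abs(z_tc)),
                                highfreq_power_fraction = hf_frac,
                                lowfreq_power_fraction = lf_frac,
                                suprathreshold_brain_fraction = brain_frac,
                                suprathreshold_gm_fraction = gm_frac,
                                suprathreshold_wm_csf_fraction = wm_frac,
                                suprathreshold_edge_fraction = edge_frac,
                                largest_cluster = largest,
                                fraction_in_big_clusters = in_big)),
            class = "component_flags")
}

#' Remove rejected component contributions by partial regression
#'
#' All component time courses are fit jointly per voxel (with an intercept),
#' and only the rejected components' fitted contributions are subtracted, so
#' that variance shared with kept components is protected (the `fsl_regfilt`
#' behaviour).
#'
#' @inheritParams surround_subtract
#' @param courses Frame-by-component numeric matrix of all component time
#'   courses.
#' @param reject Indices (or ids matching `colnames(courses)`) of the
#'   components to remove.
#' @return Cleaned series, same shape as `x`.
#' @export
regress_out_components <- function(x, courses, reject) {
  vm <- as_voxel_matrix(x)
  m <- vm$m
  courses <- as.matrix(courses)
  if (nrow(courses) != ncol(m))
    stop("component courses must span the run's frames")
  if (is.character(reject)) {
    miss <- setdiff(reject, colnames(courses))
    if (length(miss)) stop("unknown component id(s): ",
                           paste(miss, collapse = ", "))
    reject <- match(reject, colnames(courses))
  }
  if (length(reject) == 0) return(x)
  if (any(reject < 1 | reject > ncol(courses)))
    stop("rejected component index out of range")
  X <- cbind(1, courses)
  beta <- solve(crossprod(X), crossprod(X, t(m)))
  fitted_rej <- X[, reject + 1L, drop = FALSE] %*%
    beta[reject + 1L, , drop = FALSE]
  vm$restore(m - t(fitted_rej))
}

#' Center each voxel's fixation blocks and concatenate them
#'
#' Per voxel and per block, the block mean is subtracted; blocks are then
#' concatenated in temporal order. This is the centering step of the SD_BOLD
#' normalization, exposed separately because it is invariant to per-block
#' additive offsets.
#'
#' @param m Voxel-by-frame matrix.
#' @param frame_sets List of integer vectors of frame indices, one per block.
#' @return Voxel-by-(total block frames) matrix of centered, concatenated
#'   data, with attribute `"block_id"` giving each column's block.
#' @export
center_blocks <- function(m, frame_sets) {
  parts <- lapply(frame_sets, function(fr) {
    blk <- m[, fr, drop = FALSE]
    blk - rowMeans(blk)
  })
  out <- do.call(cbind, parts)
  attr(out, "block_id") <- rep(seq_along(frame_sets),
                               vapply(frame_sets, length, 1L))
  out
}

#' Normalize fixation blocks for SD_BOLD computation
#'
#' Step 1: all fixation-block data are scaled so the overall 4D mean over
#' mask voxels and block frames equals 100. Step 2: per voxel and block, the
#' block mean is subtracted. Step 3: blocks are concatenated in temporal
#' order. The output has grand mean 0 over the mask and zero per-voxel
#' per-block means.
#'
#' @param x 4D array or voxel-by-frame matrix of the BOLD run.
#' @param design A [block_design()]; its fixation blocks are used.
#' @param mask 3D logical array (or logical vector matching the rows of a
#'   matrix input) defining the brain voxels entering the grand mean.
#' @return List: `series` (mask-voxel-by-frame matrix of normalized,
#'   centered, concatenated data), `block_id` (block index per column),
#'   `scale` (the step-1 factor), `mask`.
#' @export
normalize_blocks <- function(x, design, mask) {
  vm <- as_voxel_matrix(x)
  m <- vm$m
  mv <- as.logical(mask)
  if (length(mv) != nrow(m)) stop("mask does not match the data grid")
  frame_sets <- block_frames(design, ncol(m), "fixation")
  frame_sets <- frame_sets[vapply(frame_sets, length, 1L) > 0]
  if (!length(frame_sets)) stop("design contains no fixation frames")
  msub <- m[mv, , drop = FALSE]
  all_fr <- unlist(frame_sets)
  g <- mean(msub[, all_fr])
  if (!is.finite(g) || g <= 0)
    stop("grand mean over mask and fixation frames must be positive")
  scale <- 100 / g
  centered <- center_blocks(msub * scale, frame_sets)
  list(series = centered, block_id = attr(centered, "block_id"),
       scale = scale, mask = mv)
}
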