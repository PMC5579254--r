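#' Voxelwise SD_BOLD from a normalized, concatenated fixation series
#'
#' Computes the per-voxel sample standard deviation (n - 1 denominator) over
#' all concatenated block frames produced by [normalize_blocks()].
#'
#' @param normalized Either the list returned by [normalize_blocks()] or a
#'   voxel-by-frame matrix of already block-centered data.
#' @return List of class `sdbold_result`: `sd` (per-voxel vector over the
#'   mask), `n_frames`, `n_blocks`.
#' @export
compute_sdbold <- function(normalized) {
  if (is.list(normalized) && !is.null(normalized$series)) {
    m <- normalized$series
    n_blocks <- length(unique(normalized$block_id))
  } else {
    m <- as.matrix(normalized)
    n_blocks <- length(unique(attr(m, "block_id"))) %||% NA_integer_
  }
  if (ncol(m) < 2L) stop("need at least 2 frames to compute an SD")
  sdv <- sqrt(rowSums(m^2) / (ncol(m) - 1L) -
                ncol(m) * rowMeans(m)^2 / (ncol(m) - 1L))
  structure(list(sd = sdv, n_frames = ncol(m), n_blocks = n_blocks),
            class = "sdbold_result")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Split-half reliability of SD_BOLD
#'
#' SD_BOLD is computed separately from the concatenated first halves and the
#' concatenated second halves of each fixation block (each half centered on
#' its own mean); the Pearson correlation of the two voxel vectors is the
#' reliability. Odd-length blocks drop their final frame so halves are
#' balanced.
#'
#' @param m Voxel-by-frame matrix of the (normalized) run, mask voxels only.
#' @param frame_sets List of per-block frame index vectors.
#' @return List: `r` (Pearson correlation across voxels), `sd_first`,
#'   `sd_second`.
#' @export
split_half_reliability <- function(m, frame_sets) {
  firsts <- list(); seconds <- list()
  for (fr in frame_sets) {
    if (length(fr) %% 2L == 1L) fr <- fr[-length(fr)]
    if (length(fr) < 4L) stop("blocks must have at least 4 usable frames")
    h <- length(fr) / 2L
    firsts[[length(firsts) + 1L]] <- fr[seq_len(h)]
    seconds[[length(seconds) + 1L]] <- fr[h + seq_len(h)]
  }
  sd1 <- compute_sdbold(center_blocks(m, firsts))$sd
  sd2 <- compute_sdbold(center_blocks(m, seconds))$sd
  list(r = stats::cor(sd1, sd2), sd_first = sd1, sd_second = sd2)
}
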