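#' Task PLS of group versus voxelwise SD_BOLD
#'
#' Builds the group-by-voxel matrix of group mean SD_BOLD values, removes
#' the grand mean over group means per voxel (standard Task PLS centering
#' for a one-condition, two-group design), and decomposes it by SVD:
#' `COV = U S V'`. `U` holds the group saliences, `V` the voxel saliences,
#' `S` the singular values. With two groups and one condition exactly one
#' latent variable is estimable; its voxel pattern is proportional to the
#' per-voxel (young mean - old mean) / 2. The sign of each LV is fixed so
#' that the first group's salience in `U` is non-negative.
#'
#' @param x Subject-by-voxel numeric matrix.
#' @param groups Factor (or vector) of group labels, one per subject; each
#'   group needs at least 2 subjects.
#' @return List of class `pls_result`: `u`, `s`, `v`, `groups` (level
#'   order), `n_lv` (number of estimable LVs), `cov` (the centered
#'   group-by-voxel matrix).
#' @export
task_pls <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (ncol(x) < 2L) stop("need at least 2 voxels")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 subjects")
  gm <- group_means(x, groups)
  R <- sweep(gm, 2, colMeans(gm))
  sv <- svd(R)
  # sign convention: first group's LV1 salience non-negative
  for (k in seq_along(sv$d)) {
    if (sv$u[1, k] < 0) {
      sv$u[, k] <- -sv$u[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  structure(list(u = sv$u, s = sv$d, v = sv$v,
                 groups = levels(groups), n_lv = nlevels(groups) - 1L,
                 cov = R),
            class = "pls_result")
}

group_means <- function(x, groups) {
  t(vapply(levels(groups),
           function(g) colMeans(x[groups == g, , drop = FALSE]),
           numeric(ncol(x))))
}

#' Permutation test of the PLS singular values
#'
#' Group labels are shuffled without restriction across subjects; the
#' singular value of each LV is recomputed on every permutation. The
#' permuted p-value is `(#{permuted S >= observed S} + 1) / (n_perm + 1)`.
#'
#' @inheritParams task_pls
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer RNG seed.
#' @return List: `p` (per LV), `observed_s`, `n_perm`.
#' @export
permutation_test <- function(x, groups, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  x <- as.matrix(x)
  groups <- as.factor(groups)
  obs <- task_pls(x, groups)$s
  n_lv <- min(nlevels(groups) - 1L, length(obs))
  obs <- obs[seq_len(n_lv)]
  exceed <- numeric(n_lv)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    gp <- sample(groups)
    sp <- task_pls(x, gp)$s[seq_len(n_lv)]
    exceed <- exceed + (sp >= obs)
  }
  list(p = (exceed + 1) / (n_perm + 1), observed_s = obs, n_perm = n_perm)
}

#' Bootstrap ratios of the PLS voxel saliences
#'
#' Subjects are resampled with replacement within group; the scaled voxel
#' salience pattern `V1 * S1` (the LV's covariance pattern) is recomputed on
#' each resample and sign-aligned to the original by correlation. The
#' bootstrap ratio is the original scaled salience divided by the standard
#' deviation of the aligned bootstrap saliences — a pseudo-z of robustness.
#' Degenerate resamples in which a group collapses to a single unique
#' subject are redrawn (counted in `n_redrawn`).
#'
#' @inheritParams task_pls
#' @param n_boot Number of bootstrap resamples (>= 50).
#' @param seed Integer RNG seed.
#' @return List of class `bsr_result`: `bsr` (per voxel), `salience`
#'   (original scaled salience), `se` (bootstrap SD), `n_boot`, `n_redrawn`.
#' @export
bootstrap_bsr <- function(x, groups, n_boot = 1000L, seed = 1L) {
  stopifnot(n_boot >= 50L)
  x <- as.matrix(x)
  groups <- as.factor(groups)
  orig <- task_pls(x, groups)
  sal0 <- orig$v[, 1] * orig$s[1]
  idx_by_group <- split(seq_len(nrow(x)), groups)
  boot <- matrix(NA_real_, n_boot, ncol(x))
  n_redrawn <- 0L
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- unlist(lapply(idx_by_group,
                           function(i) sample(i, length(i), replace = TRUE)))
      if (all(vapply(idx_by_group,
                     function(i) length(unique(idx[idx %in% i])) >= 2L,
                     TRUE))) break
      n_redrawn <- n_redrawn + 1L
    }
    pb <- task_pls(x[idx, , drop = FALSE], groups[idx])
    sal <- pb$v[, 1] * pb$s[1]
    if (stats::cor(sal, sal0) < 0) sal <- -sal
    boot[b, ] <- sal
  }
  se <- apply(boot, 2, stats::sd)
  bsr <- ifelse(se > .Machine$double.eps, sal0 / se, 0)
  structure(list(bsr = bsr, salience = sal0, se = se,
                 n_boot = n_boot, n_redrawn = n_redrawn),
            class = "bsr_result")
}

#' Subject brain scores for a latent variable
#'
#' The brain score is the dot product of the LV's voxel saliences with the
#' subject's voxel vector of SD_BOLD values, optionally restricted to a
#' voxel subset (e.g. a bootstrap-thresholded region).
#'
#' @param v Voxel salience vector.
#' @param x Subject-by-voxel matrix (or a single subject's vector).
#' @param subset Optional logical or integer index of voxels to restrict to.
#' @return Numeric vector of one score per subject.
#' @export
brain_scores <- function(v, x, subset = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(v)) stop("dimension mismatch between v and x")
  if (!is.null(subset)) {
    v2 <- numeric(length(v))
    v2[subset] <- v[subset]
    v <- v2
  }
  drop(x %*% v)
}

#' Threshold a BSR map into regions and a cluster table
#'
#' With the [task_pls()] sign convention (first group's `U` salience
#' positive), voxels with `BSR >= threshold` express higher SD_BOLD in the
#' first group ("young_higher" when young is the first level); `sign =
#' "old_higher"` selects `BSR <= -threshold`. Clusters are connected
#' components of the thresholded mask.
#'
#' @param bsr_map A [voxel_map()] of bootstrap ratios.
#' @param threshold Positive BSR threshold (e.g. 2.70).
#' @param sign "young_higher" or "old_higher".
#' @param connectivity Cluster connectivity, 26 or 6.
#' @return List of class `region_mask`: `mask` (logical [voxel_map()]),
#'   `sign`, `clusters` (data frame: cluster id, peak x/y/z, peak BSR,
#'   size; sorted by |peak BSR|), `n_voxels`.
#' @export
threshold_regions <- function(bsr_map, threshold, sign = c("young_higher",
                                                           "old_higher"),
                              connectivity = 26) {
  sign <- match.arg(sign)
  stopifnot(inherits(bsr_map, "voxel_map"), threshold > 0)
  v <- bsr_map$values
  sel <- if (sign == "young_higher") v >= threshold else v <= -threshold
  sel <- sel & bsr_map$mask
  if (!any(sel)) {
    warning("no voxels survive |BSR| >= ", threshold, " (", sign, ")")
    return(structure(list(mask = NULL, sign = sign,
                          clusters = data.frame(), n_voxels = 0L),
                     class = "region_mask"))
  }
  labs <- label_clusters(sel, connectivity)
  ids <- sort(unique(labs[labs > 0]))
  rows <- lapply(ids, function(id) {
    vox <- which(labs == id, arr.ind = TRUE)
    vals <- v[labs == id]
    pk <- which.max(abs(vals))
    data.frame(cluster = id, peak_x = vox[pk, 1], peak_y = vox[pk, 2],
               peak_z = vox[pk, 3], peak_bsr = vals[pk], size = nrow(vox))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-abs(tab$peak_bsr)), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(mask = voxel_map(array(as.numeric(sel), dim(sel)),
                                  bsr_map$mask, name = paste0("region_", sign)),
                 sign = sign, clusters = tab, n_voxels = sum(sel)),
            class = "region_mask")
}
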