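#' Single-pass univariate outlier removal
#'
#' Means and SDs are computed once on the full sample per variable; any
#' subject with |z| > k on any variable is removed. The pass is not
#' iterated, so a gross outlier that inflates the SD can mask itself — this
#' mirrors the common single-pass practice.
#'
#' @param tab Data frame of numeric variables (one row per subject).
#' @param k Cut in SD units (default 2.5).
#' @param id Optional subject identifiers (default row numbers).
#' @return List of class `outlier_report`: `keep` (ids retained),
#'   `removed` (data frame: id, variable, z), `n_before`, `n_after`.
#' @export
univariate_outliers <- function(tab, k = 2.5, id = NULL) {
  tab <- as.data.frame(tab)
  if (nrow(tab) < 3L) stop("need at least 3 cases")
  if (is.null(id)) id <- seq_len(nrow(tab))
  removed <- data.frame(id = character(0), variable = character(0),
                        z = numeric(0))
  drop <- rep(FALSE, nrow(tab))
  for (v in names(tab)) {
    x <- tab[[v]]
    s <- stats::sd(x)
    if (!is.finite(s) || s < .Machine$double.eps) {
      warning("variable '", v, "' has zero variance; skipped")
      next
    }
    z <- (x - mean(x)) / s
    hit <- which(abs(z) > k)
    if (length(hit)) {
      removed <- rbind(removed, data.frame(id = as.character(id[hit]),
                                           variable = v, z = z[hit]))
      drop[hit] <- TRUE
    }
  }
  structure(list(keep = id[!drop], removed = removed,
                 n_before = nrow(tab), n_after = sum(!drop)),
            class = "outlier_report")
}

sample_skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / (mean(z^2)^1.5)
}

#' Log-transform a right-skewed variable when it fails a normality test
#'
#' A one-sample Kolmogorov-Smirnov test against a normal distribution with
#' sample-estimated mean and SD decides; if p < `alpha` and the sample is
#' right-skewed, natural-log values are returned together with the
#' post-transform KS result. With `lilliefors = TRUE` the Lilliefors
#' correction (via a parametric bootstrap of the KS statistic) replaces the
#' naive p-value.
#'
#' @param x Numeric vector.
#' @param alpha Test level (default 0.05).
#' @param lilliefors Use the Lilliefors-corrected p-value.
#' @return List: `values`, `transformed` (logical), `ks_p_before`,
#'   `ks_p_after` (NA when no transform), `skewness`.
#' @export
transform_to_gaussian <- function(x, alpha = 0.05, lilliefors = FALSE) {
  ks_p <- function(v) {
    if (lilliefors) {
      d0 <- ks_stat(v)
      sims <- replicate(500, ks_stat(stats::rnorm(length(v))))
      mean(sims >= d0)
    } else {
      suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
    }
  }
  p0 <- ks_p(x)
  sk <- sample_skewness(x)
  if (p0 >= alpha || sk <= 0)
    return(list(values = x, transformed = FALSE, ks_p_before = p0,
                ks_p_after = NA_real_, skewness = sk))
  if (any(x <= 0))
    stop("cannot log transform: non-positive values at indices ",
         paste(which(x <= 0), collapse = ", "))
  lx <- log(x)
  list(values = lx, transformed = TRUE, ks_p_before = p0,
       ks_p_after = ks_p(lx), skewness = sk)
}

ks_stat <- function(v) {
  suppressWarnings(stats::ks.test(v, "pnorm", mean(v),
                                  stats::sd(v))$statistic)
}

#' Multivariate outlier filter via Mahalanobis distance
#'
#' Squared Mahalanobis distances from the sample mean and covariance are
#' compared to a chi-squared reference with `df` degrees of freedom. The
#' maximum-distance case is removed while its distance exceeds the
#' chi-squared quantile at probability 1 - 1/(2n) (an extreme-tail rule
#' standing in for visual Q-Q departure) and the removed fraction stays at
#' or below `cap`; distances are recomputed after each removal.
#'
#' @param x Numeric matrix or data frame of predictors (cases in rows).
#' @param df Degrees of freedom of the reference distribution (number of
#'   predictors).
#' @param cap Maximum fraction of cases that may be removed.
#' @param id Optional case identifiers.
#' @return List of class `outlier_report`: `keep`, `removed` (id, d2,
#'   quantile), `d2` (final distances of kept cases), `n_before`,
#'   `n_after`.
#' @export
mahalanobis_filter <- function(x, df = ncol(x), cap = 0.05, id = NULL) {
  x <- as.matrix(x)
  n0 <- nrow(x)
  if (n0 <= df + 2) stop("too few cases for a ", df, "-predictor filter")
  if (is.null(id)) id <- seq_len(n0)
  keep <- rep(TRUE, n0)
  removed <- data.frame(id = character(0), d2 = numeric(0),
                        quantile = numeric(0))
  max_remove <- floor(cap * n0)
  repeat {
    xs <- x[keep, , drop = FALSE]
    cv <- stats::cov(xs)
    if (rcond_ok(cv) < 1e-12)
      stop("singular predictor covariance; reduce the predictor set")
    d2 <- stats::mahalanobis(xs, colMeans(xs), cv)
    qref <- stats::qchisq(1 - 1 / (2 * nrow(xs)), df)
    worst <- which.max(d2)
    if (nrow(removed) >= max_remove || d2[worst] <= qref) break
    wid <- id[keep][worst]
    removed <- rbind(removed, data.frame(id = as.character(wid),
                                         d2 = d2[worst], quantile = qref))
    keep[match(wid, id)] <- FALSE
  }
  xs <- x[keep, , drop = FALSE]
  d2 <- stats::mahalanobis(xs, colMeans(xs), stats::cov(xs))
  structure(list(keep = id[keep], removed = removed, d2 = d2,
                 n_before = n0, n_after = sum(keep)),
            class = "outlier_report")
}

rcond_ok <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Ordinary least squares with bootstrap CIs and effect-size decomposition
#'
#' Fits `outcome ~ predictors` by OLS and reports, per predictor: the
#' unstandardized coefficient, a percentile bootstrap 95% CI over case
#' resampling, SE, t, p, the zero-order Pearson correlation with the
#' outcome, partial and semi-partial correlations derived from the fitted
#' model, and the VIF. The model-level output includes n, R-squared and
#' Levene's test of outcome variance across groups (when a group column is
#' present). A factor `group` predictor is coded young = 1, old = 0 so a
#' negative coefficient means lower outcome in the young.
#'
#' @param tab Data frame containing the outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @param n_boot Bootstrap resamples; 0 skips the CI columns.
#' @param seed Integer RNG seed for the bootstrap.
#' @param group_col Column used for the Levene check (default "group" when
#'   present).
#' @return Object of class `regression_result`: data frame `coefficients`
#'   (one row per predictor) plus attributes `n`, `r_squared`, `levene_p`,
#'   `intercept`.
#' @export
fit_vascular_model <- function(tab, outcome, predictors, n_boot = 1000L,
                               seed = 1L, group_col = NULL) {
  tab <- as.data.frame(tab)
  stopifnot(outcome %in% names(tab), all(predictors %in% names(tab)))
  if (is.null(group_col) && "group" %in% names(tab)) group_col <- "group"
  use <- stats::complete.cases(tab[, c(outcome, predictors)])
  tab <- tab[use, , drop = FALSE]
  X <- vapply(predictors, function(p) code_predictor(tab[[p]]),
              numeric(nrow(tab)))
  X <- as.matrix(X)
  colnames(X) <- predictors
  y <- tab[[outcome]]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L)
    stop("perfectly collinear predictors among: ",
         paste(predictors, collapse = ", "))
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  cf <- sm$coefficients[-1, , drop = FALSE]
  dfres <- fit$df.residual
  r2 <- sm$r.squared
  tvals <- cf[, "t value"]
  partial <- tvals / sqrt(tvals^2 + dfres)
  semipartial <- tvals * sqrt((1 - r2) / dfres)
  zero <- apply(X, 2, function(p) stats::cor(y, p))
  vif <- vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1L) return(1)
    r2j <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2j)
  }, numeric(1))

  ci_lo <- ci_hi <- rep(NA_real_, ncol(X))
  if (n_boot > 0) {
    set.seed(seed)
    bb <- matrix(NA_real_, n_boot, ncol(X))
    Xf <- cbind(1, X)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      cb <- tryCatch(stats::lm.fit(Xf[idx, , drop = FALSE], y[idx])$coefficients,
                     error = function(e) rep(NA_real_, ncol(Xf)))
      bb[b, ] <- cb[-1]
    }
    ci_lo <- apply(bb, 2, stats::quantile, 0.025, na.rm = TRUE)
    ci_hi <- apply(bb, 2, stats::quantile, 0.975, na.rm = TRUE)
  }

  levene_p <- NA_real_
  if (!is.null(group_col) && group_col %in% names(tab) &&
      nlevels(as.factor(tab[[group_col]])) > 1L) {
    lv <- car::leveneTest(y ~ as.factor(tab[[group_col]]))
    levene_p <- lv[1, "Pr(>F)"]
  }

  out <- data.frame(predictor = predictors,
                    b = cf[, "Estimate"],
                    ci_lower = ci_lo, ci_upper = ci_hi,
                    se = cf[, "Std. Error"],
                    t = tvals, p = cf[, "Pr(>|t|)"],
                    zero_order = zero, partial = partial,
                    semi_partial = semipartial, vif = vif,
                    row.names = NULL)
  structure(list(coefficients = out, n = nrow(tab), r_squared = r2,
                 levene_p = levene_p,
                 intercept = sm$coefficients[1, "Estimate"]),
            class = "regression_result")
}

# young = 1, old = 0; other factors use their first level as 1.
code_predictor <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  f <- as.factor(p)
  if (all(c("young", "old") %in% levels(f))) return(as.numeric(f == "young"))
  if (nlevels(f) != 2L) stop("non-numeric predictors must have 2 levels")
  as.numeric(f == levels(f)[1])
}

#' Pearson chi-squared test of a 2x2 contingency table
#'
#' No continuity correction, df = 1.
#'
#' @param counts 2x2 matrix of non-negative integers with positive margins.
#' @return List: `statistic`, `p`, `df`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: a margin is zero")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value, df = unname(ct$parameter))
}

#' Within-subject voxelwise coupling between SD_BOLD and a vascular map
#'
#' Pearson correlation across mask voxels between one subject's SD_BOLD map
#' and a vascular map (CBF or CVR).
#'
#' @param sd_vals,vascular_vals Numeric vectors over the same mask voxels
#'   (or `voxel_map` objects sharing a mask).
#' @return Pearson r.
#' @export
within_subject_coupling <- function(sd_vals, vascular_vals) {
  if (inherits(sd_vals, "voxel_map") && inherits(vascular_vals, "voxel_map")) {
    if (!identical(sd_vals$mask, vascular_vals$mask))
      stop("maps must share a mask")
    vascular_vals <- vascular_vals$values[vascular_vals$mask]
    sd_vals <- sd_vals$values[sd_vals$mask]
  }
  if (length(sd_vals) != length(vascular_vals) || length(sd_vals) < 3L)
    stop("need >= 3 paired voxels")
  if (stats::sd(sd_vals) < .Machine$double.eps ||
      stats::sd(vascular_vals) < .Machine$double.eps)
    stop("zero variance: correlation undefined")
  stats::cor(sd_vals, vascular_vals)
}

#' Group regression of per-subject coupling values
#'
#' Regresses each subject's within-subject coupling r on age group (the
#' Model 5/6 structure). Partial-correlation columns do not apply to a
#' single-predictor model and are marked NA.
#'
#' @param r_values Per-subject coupling correlations.
#' @param groups Group factor ("young"/"old").
#' @inheritParams fit_vascular_model
#' @return A `regression_result` (see [fit_vascular_model()]).
#' @export
coupling_group_models <- function(r_values, groups, n_boot = 1000L,
                                  seed = 1L) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) stop("each group needs at least 2 subjects")
  tab <- data.frame(r = r_values, group = groups)
  res <- fit_vascular_model(tab, "r", "group", n_boot = n_boot, seed = seed)
  res$coefficients$partial <- NA_real_
  res$coefficients$semi_partial <- NA_real_
  res$coefficients$vif <- NA_real_
  res
}

#' Voxelwise across-subject coupling and its group difference map
#'
#' Per voxel, the Pearson correlation across subjects within each group
#' between SD_BOLD and a vascular measure; the difference map is
#' young minus old.
#'
#' @param sd_mat,vasc_mat Subject-by-voxel matrices over the same voxels.
#' @param groups Group factor, one entry per subject.
#' @return List: `r_young`, `r_old`, `difference` (per-voxel vectors),
#'   `histogram` (counts of the difference over bins of width 0.1 in
#'   [-2, 2]).
#' @export
voxelwise_group_coupling <- function(sd_mat, vasc_mat, groups) {
  groups <- as.factor(groups)
  stopifnot(identical(dim(sd_mat), dim(vasc_mat)))
  if (any(table(groups) < 3L)) stop("each group needs at least 3 subjects")
  col_cor <- function(a, b) {
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    colSums(ac * bc) / sqrt(colSums(ac^2) * colSums(bc^2))
  }
  ry <- col_cor(sd_mat[groups == "young", , drop = FALSE],
                vasc_mat[groups == "young", , drop = FALSE])
  ro <- col_cor(sd_mat[groups == "old", , drop = FALSE],
                vasc_mat[groups == "old", , drop = FALSE])
  diffs <- ry - ro
  br <- seq(-2, 2, by = 0.1)
  h <- graphics::hist(diffs[is.finite(diffs)], breaks = br, plot = FALSE)
  list(r_young = ry, r_old = ro, difference = diffs,
       histogram = data.frame(lower = utils::head(br, -1),
                              upper = br[-1], count = h$counts))
}
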