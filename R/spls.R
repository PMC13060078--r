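#' One-component sparse PLS regression (single response)
#'
#' Fits the first sparse partial least squares component of a continuous
#' response on a feature matrix. With one component and one response the
#' sparse loading-weight vector is the soft-thresholded cross-covariance
#' X'y keeping exactly the `keep` largest-magnitude entries, renormalized to
#' unit length; the latent score is t = Xw and the response is regressed on
#' t for the fit statistics. This makes "top-|covariance| selection" an
#' exact independent oracle for the selected set.
#'
#' Columns are centered and (by default) scaled to unit variance; `NA`
#' entries (RCLR non-detects) are mean-filled per feature before fitting and
#' the fill values are recorded so new data can be projected consistently.
#'
#' @param X numeric matrix, samples x features, with column names.
#' @param y numeric response (resilience score per sample).
#' @param keep number of features to retain (1..ncol(X)).
#' @param scale. scale columns to unit variance (default TRUE; recorded).
#' @return object of class `spls_fit`: `w` (named loading weights, 0 for
#'   unselected, unit norm), `selected` (feature ids), `scores` (t = Xw),
#'   `y_coefficient`, `intercept`, `r2`, `rmse`, `p_value` (F-test of y on
#'   t), `keep`, `n_components = 1`, plus the centering/scaling/fill
#'   vectors.
#' @export
fit_spls1 <- function(X, y, keep, scale. = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (keep < 1 || keep > p) stop("`keep` must be in 1..", p)
  if (stats::var(y) == 0) stop("zero-variance response")
  fill <- colMeans(X, na.rm = TRUE)
  na_idx <- which(is.na(X))
  if (length(na_idx)) X[na_idx] <- fill[((na_idx - 1) %/% n) + 1]
  centers <- colMeans(X)
  scales <- if (scale.) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else rep(1, p)
  Xs <- sweep(sweep(X, 2, centers), 2, scales, "/")
  yc <- y - mean(y)

  cv <- drop(crossprod(Xs, yc)) / (n - 1)
  a <- abs(cv)
  lambda <- if (keep < p) sort(a, decreasing = TRUE)[keep + 1] else 0
  w <- sign(cv) * pmax(a - lambda, 0)
  # guard against ties at the threshold producing more than `keep` entries
  if (sum(w != 0) > keep) {
    ord <- order(a, decreasing = TRUE)
    w[-ord[seq_len(keep)]] <- 0
  }
  w <- w / sqrt(sum(w^2))
  t_score <- drop(Xs %*% w)
  reg <- stats::lm(yc ~ t_score)
  # perfect fits trigger a harmless precision warning in summary/anova
  r2 <- suppressWarnings(summary(reg)$r.squared)
  pval <- suppressWarnings(stats::anova(reg)[["Pr(>F)"]][1])
  yhat <- stats::fitted(reg) + mean(y)
  structure(list(
    w = stats::setNames(w, colnames(X)),
    selected = colnames(X)[w != 0],
    scores = t_score,
    y_coefficient = unname(stats::coef(reg)["t_score"]),
    intercept = unname(stats::coef(reg)["(Intercept)"]) + mean(y),
    r2 = r2,
    rmse = sqrt(mean((y - yhat)^2)),
    p_value = pval,
    keep = keep, n_components = 1L,
    scaled = scale., centers = centers, scales = scales, fill = fill,
    y_mean = mean(y)
  ), class = "spls_fit")
}

#' @export
print.spls_fit <- function(x, ...) {
  cat(sprintf("<spls_fit> 1 component, keep = %d of %d features\n",
              x$keep, length(x$w)))
  cat(sprintf("  R2 = %.3f (p = %.3g), RMSE = %.3f\n", x$r2, x$p_value, x$rmse))
  invisible(x)
}

#' Project new samples onto a fitted sparse PLS component
#'
#' @param object a [fit_spls1()] result.
#' @param newdata matrix with the fit's feature universe as columns.
#' @param ... unused.
#' @return list: `scores` (latent t), `predicted` (response scale).
#' @export
predict.spls_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(names(object$w), colnames(newdata))
  if (length(missing))
    stop("newdata lacks feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  newdata <- newdata[, names(object$w), drop = FALSE]
  n <- nrow(newdata)
  na_idx <- which(is.na(newdata))
  if (length(na_idx)) newdata[na_idx] <- object$fill[((na_idx - 1) %/% n) + 1]
  Xs <- sweep(sweep(newdata, 2, object$centers), 2, object$scales, "/")
  t_new <- drop(Xs %*% object$w)
  list(scores = t_new,
       predicted = object$intercept + object$y_coefficient * t_new)
}

#' Cross-validated performance and stability
#'
#' K-fold cross-validation of the one-component sparse fit: out-of-fold
#' predictions are assembled over all folds, the observed r is the Pearson
#' correlation between the response and those predictions, cv R-squared is
#' its square, and RMSE is computed on the out-of-fold predictions. Each
#' fold's refit also records which features it selected; a feature's
#' stability score is the fraction of folds that selected it.
#'
#' @param X samples x features matrix.
#' @param y response.
#' @param keep sparsity level.
#' @param k number of folds (default 10); requires n >= 2k.
#' @param seed fold-assignment seed.
#' @param groups optional grouping vector (e.g. participant ids); groups are
#'   kept within one fold.
#' @param scale. passed to [fit_spls1()].
#' @return list: `cv_r`, `cv_r2`, `rmse`, `stability` (named vector in
#'   {0, 1/k, ..., 1}), `fold_selected` (list of per-fold selected sets),
#'   `oof` (out-of-fold predictions).
#' @export
cross_validate <- function(X, y, keep, k = 10, seed = 1, groups = NULL,
                           scale. = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 * k) stop("need n >= 2k samples for ", k, "-fold CV")
  set.seed(seed)
  if (is.null(groups)) {
    fold <- sample(rep(seq_len(k), length.out = n))
  } else {
    g <- unique(groups)
    gf <- sample(rep(seq_len(k), length.out = length(g)))
    fold <- gf[match(groups, g)]
  }
  oof <- rep(NA_real_, n)
  sel <- vector("list", k)
  counts <- stats::setNames(numeric(ncol(X)), colnames(X))
  used <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    if (stats::var(y[tr]) == 0) next
    fit <- fit_spls1(X[tr, , drop = FALSE], y[tr], keep, scale. = scale.)
    sel[[f]] <- fit$selected
    counts[fit$selected] <- counts[fit$selected] + 1
    oof[!tr] <- predict(fit, X[!tr, , drop = FALSE])$predicted
    used <- used + 1L
  }
  ok <- !is.na(oof)
  r <- stats::cor(y[ok], oof[ok])
  list(cv_r = r, cv_r2 = r^2,
       rmse = sqrt(mean((y[ok] - oof[ok])^2)),
       stability = counts / used, fold_selected = sel, oof = oof,
       folds_used = used)
}

# unit-invariant knee of a decreasing curve: the point farthest from the
# chord joining the endpoints after normalizing both axes to [0, 1]
knee_point <- function(values) {
  v <- sort(values, decreasing = TRUE)
  m <- length(v)
  if (m < 3 || diff(range(v)) == 0) return(NA_integer_)
  x <- (seq_len(m) - 1) / (m - 1)
  yv <- (v - v[m]) / (v[1] - v[m])
  d <- yv - (1 - x) # distance to the descending diagonal (up to a constant)
  which.min(d) # most-below-the-chord point
}

#' Choose the sparsity level
#'
#' Ranks features by the magnitude of their covariance with the response,
#' locates the knee of the ranked-magnitude curve (unit-invariant
#' farthest-from-chord criterion), and scores a grid of candidate `keep`
#' values around the knee by cross-validated RMSE. The smallest candidate
#' within one standard error of the minimum RMSE wins. A degenerate flat
#' curve (no knee) falls back to CV-only selection over the supplied or
#' default grid, flagged in the result.
#'
#' @param X samples x features matrix.
#' @param y response.
#' @param grid optional candidate `keep` values; default is the knee scaled
#'   by 1/4, 1/2, 1, 2, 4 (clipped to 1..p).
#' @param folds CV folds.
#' @param seed CV seed.
#' @param scale. passed to [fit_spls1()].
#' @return list: `keep` (chosen), `knee`, `grid`, `cv_rmse`, `cv_se`,
#'   `fallback` (TRUE when the knee was undefined).
#' @export
tune_keep <- function(X, y, grid = NULL, folds = 10, seed = 1, scale. = TRUE) {
  X <- as.matrix(X)
  p <- ncol(X)
  Xf <- X
  n <- nrow(X)
  na_idx <- which(is.na(Xf))
  if (length(na_idx)) {
    fill <- colMeans(Xf, na.rm = TRUE)
    Xf[na_idx] <- fill[((na_idx - 1) %/% n) + 1]
  }
  cv <- abs(drop(crossprod(scale(Xf), y - mean(y))))
  cv[is.na(cv)] <- 0 # zero-variance columns carry no signal
  knee <- knee_point(cv)
  fallback <- is.na(knee)
  if (is.null(grid)) {
    grid <- if (fallback) unique(pmax(1, pmin(p, round(p * c(0.02, 0.05, 0.1, 0.25)))))
            else unique(pmax(1, pmin(p, round(knee * c(0.25, 0.5, 1, 2, 4)))))
  }
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1 | grid > p)) stop("grid values must be in 1..", p)
  if (length(grid) == 1)
    return(list(keep = grid, knee = knee, grid = grid,
                cv_rmse = NA_real_, cv_se = NA_real_, fallback = fallback))
  res <- lapply(grid, function(kp) {
    cvr <- cross_validate(X, y, kp, k = folds, seed = seed, scale. = scale.)
    err <- (y - cvr$oof)^2
    c(rmse = cvr$rmse, se = stats::sd(err, na.rm = TRUE) /
        (2 * cvr$rmse * sqrt(sum(!is.na(err)))))
  })
  rmse <- vapply(res, `[[`, numeric(1), "rmse")
  se <- vapply(res, `[[`, numeric(1), "se")
  best <- which.min(rmse)
  within <- which(rmse <= rmse[best] + se[best])
  keep <- grid[min(within)] # one-SE rule, toward smaller keep
  list(keep = keep, knee = knee, grid = grid, cv_rmse = rmse, cv_se = se,
       fallback = fallback)
}

#' Permutation test of the sparse PLS fit
#'
#' Refits the model on `n_perm` permutations of the response; the p-value is
#' (1 + #{R2_perm >= R2_obs}) / (n_perm + 1), bounded below by
#' 1/(n_perm + 1).
#'
#' @inheritParams cross_validate
#' @param n_perm number of permutations (default 100, must be >= 1).
#' @return list: `p_value`, `r2_obs`, `r2_perm`.
#' @export
permutation_test <- function(X, y, keep, n_perm = 100, seed = 1,
                             scale. = TRUE) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  fit <- fit_spls1(X, y, keep, scale. = scale.)
  set.seed(seed)
  r2p <- vapply(seq_len(n_perm), function(i) {
    fit_spls1(X, sample(y), keep, scale. = scale.)$r2
  }, numeric(1))
  list(p_value = (1 + sum(r2p >= fit$r2)) / (n_perm + 1),
       r2_obs = fit$r2, r2_perm = r2p)
}

#' Jaccard similarity of two feature sets
#'
#' @param a,b character vectors of feature ids; both empty is an error.
#' @return |intersection| / |union| in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0)
    stop("Jaccard similarity of two empty sets is undefined")
  length(intersect(a, b)) / length(union(a, b))
}

#' External validation of a sparse PLS fit
#'
#' Validates a fitted model on a held-out dataset sharing the same feature
#' universe (here: a different study visit per participant): (a) projects
#' the external data on the fitted weights and regresses the external
#' response on the projected score (r2_ext and its F-test p); (b) k-fold CV
#' observed r on the external data at the same `keep`; (c) refits the sparse
#' model on the external data with identical parameters and reports the
#' Jaccard similarity of the selected sets, the Pearson correlation of
#' loading weights over the union of both selected sets (unselected
#' entries contribute 0), and the fraction of the original top 5% by |w|
#' that is reselected.
#'
#' @param fit a [fit_spls1()] result.
#' @param X_ext,y_ext external data over the same features.
#' @param folds,seed CV parameters for the external CV.
#' @return list of class `external_validation`: `r2_ext`, `p_ext`,
#'   `cv_r_ext`, `jaccard`, `loading_correlation`, `top_weight_reselected`,
#'   `overall_overlap`, `fit_ext`.
#' @export
external_validate <- function(fit, X_ext, y_ext, folds = 10, seed = 1) {
  X_ext <- as.matrix(X_ext)
  missing <- setdiff(names(fit$w), colnames(X_ext))
  if (length(missing))
    stop("external data lacks feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  X_ext <- X_ext[, names(fit$w), drop = FALSE]
  proj <- predict(fit, X_ext)
  reg <- stats::lm(y_ext ~ proj$scores)
  cvr <- cross_validate(X_ext, y_ext, fit$keep, k = folds, seed = seed,
                        scale. = fit$scaled)
  fit_ext <- fit_spls1(X_ext, y_ext, fit$keep, scale. = fit$scaled)
  union_set <- union(fit$selected, fit_ext$selected)
  lc <- stats::cor(fit$w[union_set], fit_ext$w[union_set])
  n_top <- max(1, ceiling(0.05 * fit$keep))
  top <- names(sort(abs(fit$w[fit$selected]), decreasing = TRUE))[seq_len(n_top)]
  structure(list(
    r2_ext = suppressWarnings(summary(reg)$r.squared),
    p_ext = suppressWarnings(stats::anova(reg)[["Pr(>F)"]][1]),
    cv_r_ext = cvr$cv_r,
    jaccard = jaccard(fit$selected, fit_ext$selected),
    loading_correlation = lc,
    top_weight_reselected = mean(top %in% fit_ext$selected),
    overall_overlap = mean(fit$selected %in% fit_ext$selected),
    fit_ext = fit_ext
  ), class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat("<external_validation>\n")
  cat(sprintf("  r2_ext = %.3f (p = %.3g), cv r = %.3f\n",
              x$r2_ext, x$p_ext, x$cv_r_ext))
  cat(sprintf("  Jaccard = %.3f, loading correlation = %.3f\n",
              x$jaccard, x$loading_correlation))
  cat(sprintf("  top-5%% reselected = %.0f%%, overall overlap = %.0f%%\n",
              100 * x$top_weight_reselected, 100 * x$overall_overlap))
  invisible(x)
}
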