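#' Transform and scale a sample-by-feature matrix
#'
#' Log2-transforms (optionally) and scales each feature column:
#' `"none"` leaves values centered only by downstream methods,
#' `"uv"` is unit-variance (autoscaling, (x - mean)/sd),
#' `"pareto"` divides the centered values by the square root of the SD —
#' the usual compromise for omics, which shrinks dominant features
#' without amplifying noise the way autoscaling does — and
#' `"standardize"` is a per-feature z-score (alias of `"uv"`).
#'
#' @param x samples x features numeric matrix (linear scale if
#'   `log2 = TRUE`).
#' @param log2 apply log2 first.
#' @param scaling one of `"none"`, `"uv"`, `"pareto"`, `"standardize"`.
#' @return scaled matrix with attributes recording the transform.
#' @export
scale_features <- function(x, log2 = TRUE,
                           scaling = c("none", "uv", "pareto",
                                       "standardize")) {
  scaling <- match.arg(scaling)
  if (log2) x <- base::log2(x)
  if (scaling != "none") {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    div <- if (scaling == "pareto") sqrt(sdv) else sdv
    x <- sweep(sweep(x, 2, mu), 2, div, "/")
  }
  attr(x, "transform") <- list(log2 = log2, scaling = scaling)
  x
}

fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis with deterministic sign convention
#'
#' Column-centered SVD of the sample-by-feature matrix; each component's
#' sign is fixed by making its largest-magnitude loading positive so
#' repeated runs are directly comparable.
#'
#' @param x samples x features matrix (already transformed/scaled).
#' @param n_components number of components to return (default: all).
#' @return list with `scores`, `loadings`, `explained` (variance
#'   fractions over the full rank) and `sdev`.
#' @export
run_pca <- function(x, n_components = NULL) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components %||% length(pc$sdev), length(pc$sdev))
  fx <- fix_signs(pc$x[, seq_len(k), drop = FALSE],
                  pc$rotation[, seq_len(k), drop = FALSE])
  list(scores = fx$scores, loadings = fx$loadings,
       explained = expl[seq_len(k)], sdev = pc$sdev[seq_len(k)])
}

#' Ward hierarchical clustering on Euclidean distances
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`hclust` method `"ward.D2"`, which operates on unsquared Euclidean
#' distances) and an optional flat cut.
#'
#' @param x samples x features matrix.
#' @param k optional number of flat clusters.
#' @return list with `hclust` (the dendrogram) and `labels` (flat
#'   assignment, `NULL` when `k` is missing).
#' @export
ward_cluster <- function(x, k = NULL) {
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  list(hclust = hc,
       labels = if (!is.null(k)) stats::cutree(hc, k = k) else NULL)
}

# Predict class score for centered new observations.
opls_predict_core <- function(fit_env, Xnew) {
  X <- Xnew
  if (!is.null(fit_env$orth)) {
    for (j in seq_along(fit_env$orth)) {
      o <- fit_env$orth[[j]]
      t_o <- X %*% o$w_o
      X <- X - t_o %*% t(o$p_o)
    }
  }
  as.numeric((X %*% fit_env$w) * fit_env$q)
}

opls_fit_full <- function(X, y, n_ortho) {
  X0 <- X
  orth <- list()
  for (j in seq_len(n_ortho)) {
    w <- crossprod(X, y); w <- w / sqrt(sum(w^2))
    t_ <- X %*% w
    p <- crossprod(X, t_) / sum(t_^2)
    w_o <- p - as.numeric(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break
    w_o <- w_o / nw
    t_o <- X %*% w_o
    p_o <- crossprod(X, t_o) / sum(t_o^2)
    X <- X - t_o %*% t(p_o)
    orth[[j]] <- list(w_o = w_o, p_o = p_o, t_o = t_o)
  }
  w <- crossprod(X, y); w <- w / sqrt(sum(w^2))
  t_ <- X %*% w
  p <- crossprod(X, t_) / sum(t_^2)
  q <- as.numeric(crossprod(y, t_) / sum(t_^2))
  ss_pred <- sum((t_ %*% t(p))^2)
  ss_orth <- sum(vapply(orth, function(o)
    sum((o$t_o %*% t(o$p_o))^2), 0))
  list(w = w, t = t_, p = p, q = q, orth = orth,
       r2x = (ss_pred + ss_orth) / sum(X0^2),
       r2y = 1 - sum((y - t_ * q)^2) / sum(y^2))
}

opls_loocv_q2 <- function(X, y, n_ortho) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    mu <- colMeans(Xtr); my <- mean(ytr)
    fit <- opls_fit_full(sweep(Xtr, 2, mu), ytr - my, n_ortho)
    pred <- opls_predict_core(fit, matrix(X[i, ] - mu, 1)) + my
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Orthogonal projections to latent structures discriminant analysis
#'
#' Fits an OPLS-DA model with one predictive component and a number of
#' orthogonal components chosen by leave-one-out cross-validation: the
#' count grows from 0 while the LOOCV Q2 improves by at least
#' `q2_floor`, up to `max_ortho`. R2X and R2Y come from the fitted
#' model; Q2 = 1 - PRESS/TSS from the held-out predictions. VIP scores
#' are computed over the predictive component (their mean square is 1 by
#' construction).
#'
#' @param x samples x features matrix, already log2-transformed and
#'   Pareto-scaled (see [scale_features()]).
#' @param labels two-class factor/vector aligned with rows of `x`.
#' @param max_ortho cap on orthogonal components (default
#'   `min(5, n - 2)`).
#' @param q2_floor minimum Q2 improvement to accept one more orthogonal
#'   component.
#' @return object of class `opls_model`: scores, loadings, weights,
#'   `n_ortho`, `R2X`, `R2Y`, `Q2`, `vip`.
#' @export
opls_da <- function(x, labels, max_ortho = NULL, q2_floor = 0.01) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("OPLS-DA requires exactly two classes", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("each class needs at least 2 samples", call. = FALSE)
  if (ncol(x) < 1L) stop("no features", call. = FALSE)
  n <- nrow(x)
  max_ortho <- max_ortho %||% min(5L, n - 2L)
  y <- ifelse(labels == levels(labels)[1], 1, -1)
  yc <- y - mean(y)
  Xc <- sweep(x, 2, colMeans(x))
  q2 <- opls_loocv_q2(x, y, 0L)
  n_ortho <- 0L
  while (n_ortho < max_ortho) {
    q2_next <- opls_loocv_q2(x, y, n_ortho + 1L)
    if (q2_next - q2 < q2_floor) break
    q2 <- q2_next
    n_ortho <- n_ortho + 1L
  }
  fit <- opls_fit_full(Xc, yc, n_ortho)
  # deterministic orientation: class coded +1 gets positive mean score
  if (mean(fit$t[y > 0]) < 0) {
    fit$t <- -fit$t; fit$w <- -fit$w; fit$p <- -fit$p; fit$q <- -fit$q
  }
  p_feat <- ncol(x)
  vip <- sqrt(p_feat) * abs(fit$w[, 1]) / sqrt(sum(fit$w^2))
  structure(list(scores = fit$t, ortho_scores =
                   do.call(cbind, lapply(fit$orth, `[[`, "t_o")),
                 weights = fit$w, loadings = fit$p, q = fit$q,
                 n_ortho = n_ortho, R2X = fit$r2x, R2Y = fit$r2y,
                 Q2 = q2, vip = stats::setNames(vip, colnames(x)),
                 labels = labels),
            class = "opls_model")
}

#' Permutation test for a model statistic
#'
#' Recomputes `statistic(x, labels)` under `n_perm` random relabelings
#' and returns the add-one empirical p-value
#' `(1 + #{perm >= observed}) / (1 + n_perm)`, whose floor is
#' `1/(n_perm + 1)`.
#'
#' @param statistic function of `(x, labels)` returning one number.
#' @param x data matrix.
#' @param labels class labels.
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed.
#' @return list with `observed`, `p`, `null` (the permuted statistics).
#' @export
permutation_test <- function(statistic, x, labels, n_perm = 200L,
                             seed = 1L) {
  obs <- statistic(x, labels)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i)
      statistic(x, sample(labels)), 0)
    list(observed = obs, p = (1 + sum(null >= obs)) / (1 + n_perm),
         null = null)
  })
}

rv_coefficient <- function(x, y) {
  Xc <- sweep(x, 2, colMeans(x))
  Yc <- sweep(y, 2, colMeans(y))
  Sx <- tcrossprod(Xc)
  Sy <- tcrossprod(Yc)
  sum(Sx * Sy) / sqrt(sum(Sx * Sx) * sum(Sy * Sy))
}

#' Co-inertia analysis of two omics blocks on common samples
#'
#' Finds pairs of axes (one per block) maximizing the covariance of the
#' projected sample configurations, from the SVD of the cross-covariance
#' of the two column-centered blocks. The overall similarity of the two
#' configurations is the RV coefficient, a multivariate extension of the
#' squared Pearson correlation in \[0,1\], tested by row permutation of
#' one block.
#'
#' @param x,y samples x features matrices with identical row order,
#'   each already transformed/scaled (conventionally log2 + Pareto).
#' @param n_axes number of co-inertia axes to keep.
#' @param n_perm permutations for the RV test (default 200).
#' @param seed integer seed.
#' @return object of class `cia_result`: `rv`, `p_rv`, `axis_fractions`
#'   (co-inertia variance fractions, non-increasing), `scores_x`,
#'   `scores_y`.
#' @export
coinertia <- function(x, y, n_axes = 2L, n_perm = 200L, seed = 1L) {
  if (nrow(x) != nrow(y))
    stop("blocks must share samples (same rows, same order)",
         call. = FALSE)
  Xc <- sweep(x, 2, colMeans(x))
  Yc <- sweep(y, 2, colMeans(y))
  cc <- crossprod(Xc, Yc)
  sv <- svd(cc)
  k <- min(n_axes, length(sv$d))
  fr <- sv$d^2 / sum(sv$d^2)
  sx <- Xc %*% sv$u[, seq_len(k), drop = FALSE]
  sy <- Yc %*% sv$v[, seq_len(k), drop = FALSE]
  fx <- fix_signs(sx, sv$u[, seq_len(k), drop = FALSE])
  sy <- sy %*% diag(ifelse(colSums(fx$loadings * sv$u[, seq_len(k),
                                                      drop = FALSE]) < 0,
                           -1, 1), k)
  rv <- rv_coefficient(x, y)
  pt <- with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i)
      rv_coefficient(x[sample(nrow(x)), , drop = FALSE], y), 0)
    (1 + sum(null >= rv)) / (1 + n_perm)
  })
  structure(list(rv = rv, p_rv = pt, axis_fractions = fr[seq_len(k)],
                 scores_x = fx$scores, scores_y = sy,
                 singular_values = sv$d[seq_len(k)]),
            class = "cia_result")
}
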