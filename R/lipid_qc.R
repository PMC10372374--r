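#' Dispersion ratio (D-ratio)
#'
#' The D-ratio relates technical to total variation of a feature:
#' \deqn{D = \sigma_{tech} / \sqrt{\sigma_{biol}^2 + \sigma_{tech}^2}}
#' where the technical SD is estimated from repeated QC-pool injections
#' and the biological SD from the study samples. A D-ratio above 50%
#' means technical variance exceeds biological variance, so the feature
#' cannot carry a reliable biological signal.
#'
#' @param sigma_tech technical standard deviation (QC pools), >= 0.
#' @param sigma_biol biological standard deviation, >= 0.
#' @return D-ratio in \[0,1\]; the degenerate 0/0 case returns 0 with a
#'   warning.
#' @examples
#' d_ratio(3, 4)          # 0.6
#' d_ratio(1, 1)          # 1/sqrt(2)
#' @export
d_ratio <- function(sigma_tech, sigma_biol) {
  if (any(sigma_tech < 0, na.rm = TRUE) || any(sigma_biol < 0, na.rm = TRUE))
    stop("standard deviations must be non-negative", call. = FALSE)
  denom <- sqrt(sigma_biol^2 + sigma_tech^2)
  out <- ifelse(denom == 0, 0, sigma_tech / denom)
  if (any(denom == 0, na.rm = TRUE))
    warning("zero technical and biological variance; D-ratio set to 0")
  out
}

qc_roles <- function(t, design) {
  check_design_matrix(t, design)
  i <- match(colnames(t), design$sample)
  list(pool = colnames(t)[design$role[i] == "qc_pool"],
       bio = colnames(t)[design$role[i] == "biological"],
       group = design$group[i][design$role[i] == "biological"])
}

#' Stage 1: remove species with excessive QC-pool missingness
#'
#' @param t species x sample matrix (linear concentrations, `NA` missing).
#' @param design a [study_design()] table covering the columns of `t`.
#' @param max_frac maximum tolerated missing fraction among QC-pool
#'   samples; removal uses a strict `>` comparison.
#' @return list(`table`, `removed` character vector of species ids).
#' @export
filter_pool_missingness <- function(t, design, max_frac = 0.35) {
  r <- qc_roles(t, design)
  frac <- rowMeans(is.na(t[, r$pool, drop = FALSE]))
  removed <- rownames(t)[frac > max_frac]
  list(table = t[!rownames(t) %in% removed, , drop = FALSE], removed = removed)
}

#' Stage 2: remove species missing in at least half of every group
#'
#' A species is discarded only when its missing fraction reaches
#' `max_frac` in every biological group (boundary inclusive); pools and
#' blanks are ignored. A species absent from one group but well observed
#' in the other is informative and kept.
#'
#' @inheritParams filter_pool_missingness
#' @param max_frac per-group missing fraction triggering removal (`>=`).
#' @export
filter_group_missingness <- function(t, design, max_frac = 0.50) {
  r <- qc_roles(t, design)
  bio <- t[, r$bio, drop = FALSE]
  fracs <- vapply(split(seq_along(r$bio), r$group),
                  function(ix) rowMeans(is.na(bio[, ix, drop = FALSE])),
                  numeric(nrow(t)))
  if (is.null(dim(fracs))) fracs <- matrix(fracs, nrow = 1)
  removed <- rownames(t)[apply(fracs >= max_frac, 1, all)]
  list(table = t[!rownames(t) %in% removed, , drop = FALSE], removed = removed)
}

#' Stage 3: remove species with high QC-pool coefficient of variation
#'
#' CV = sample SD / mean over the observed QC-pool values, on the linear
#' concentration scale; removal is strict (`> max_cv`).
#'
#' @inheritParams filter_pool_missingness
#' @param max_cv CV threshold (default 25%).
#' @export
filter_cv <- function(t, design, max_cv = 0.25) {
  r <- qc_roles(t, design)
  pool <- t[, r$pool, drop = FALSE]
  cv <- apply(pool, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / mean(x)
  })
  removed <- rownames(t)[!is.na(cv) & cv > max_cv]
  list(table = t[!rownames(t) %in% removed, , drop = FALSE], removed = removed)
}

#' Stage 4: remove species whose technical variance dominates (D-ratio)
#'
#' Technical SD comes from the observed QC-pool values, biological SD
#' from the observed biological samples; species with
#' [d_ratio()] > `max_d` are removed (strict).
#'
#' @inheritParams filter_pool_missingness
#' @param max_d D-ratio threshold (default 50%).
#' @export
filter_d_ratio <- function(t, design, max_d = 0.50) {
  r <- qc_roles(t, design)
  st <- apply(t[, r$pool, drop = FALSE], 1, sd_obs)
  sb <- apply(t[, r$bio, drop = FALSE], 1, sd_obs)
  dr <- rep(NA_real_, nrow(t))
  ok <- !is.na(st) & !is.na(sb)
  nonzero <- ok & (st > 0 | sb > 0)
  dr[nonzero] <- st[nonzero] / sqrt(st[nonzero]^2 + sb[nonzero]^2)
  dr[ok & !nonzero] <- 0
  removed <- rownames(t)[!is.na(dr) & dr > max_d]
  list(table = t[!rownames(t) %in% removed, , drop = FALSE], removed = removed)
}

#' k-nearest-neighbour imputation over species profiles
#'
#' For each missing cell, candidate neighbours are other species with an
#' observed value in the target sample. Distances are root-mean-square
#' Euclidean distances between row-standardized profiles over the
#' jointly observed samples, so species of different absolute abundance
#' but similar shape are close. The `k` nearest eligible neighbours vote
#' by an inverse-distance-weighted mean of their raw values in the
#' target sample; neighbours at exactly zero distance share the vote
#' equally and dominate. Observed entries are never modified.
#'
#' @param t species x sample matrix with `NA` for missing entries.
#' @param k number of neighbours (default 10).
#' @return matrix with all missing entries filled.
#' @export
knn_impute <- function(t, k = 10L) {
  if (!anyNA(t)) return(t)
  z <- t(scale(t(t)))            # row-standardized profiles
  z[is.nan(z)] <- 0              # constant rows
  out <- t
  nas <- which(is.na(t), arr.ind = TRUE)
  for (target in unique(nas[, 1])) {
    cols <- nas[nas[, 1] == target, 2]
    zi <- z[target, ]
    obs_i <- !is.na(zi)
    d2 <- rowMeans(sweep(z[, obs_i, drop = FALSE], 2, zi[obs_i])^2,
                   na.rm = TRUE)
    njoint <- rowSums(!is.na(z[, obs_i, drop = FALSE])) # joint with target
    d <- sqrt(d2)
    d[target] <- NA
    d[njoint == 0] <- NA
    for (j in cols) {
      elig <- which(!is.na(d) & !is.na(t[, j]))
      if (length(elig) == 0L) {
        warning("no eligible neighbour for ", rownames(t)[target],
                " in ", colnames(t)[j], "; species mean used")
        out[target, j] <- mean(t[target, ], na.rm = TRUE)
        next
      }
      if (length(elig) < k)
        warning("fewer than k eligible neighbours for ",
                rownames(t)[target], "; using all ", length(elig))
      nb <- elig[order(d[elig])][seq_len(min(k, length(elig)))]
      dn <- d[nb]
      vals <- t[nb, j]
      if (any(dn == 0)) {
        out[target, j] <- mean(vals[dn == 0])
      } else {
        w <- 1 / dn
        out[target, j] <- sum(w * vals) / sum(w)
      }
    }
  }
  out
}

#' Run the full four-stage lipidomics QC with kNN imputation
#'
#' Applies the stages sequentially — pool missingness, group-wise
#' missingness, QC-pool CV, D-ratio — so a species failing several
#' criteria is counted only at the first stage that removes it, then
#' imputes the survivors' remaining missing values by [knn_impute()].
#'
#' @inheritParams filter_pool_missingness
#' @param max_pool_missing,max_group_missing,max_cv,max_d stage
#'   thresholds, defaulting to the conventional 35%/50%/25%/50%.
#' @param k neighbours for imputation.
#' @return object of class `lipid_qc_report`: per-stage removal lists and
#'   counts, survivor count, number of imputed cells, the cleaned table
#'   (`$table`) and the pre-imputation table (`$table_unimputed`).
#' @export
run_lipid_qc <- function(t, design,
                         max_pool_missing = 0.35, max_group_missing = 0.50,
                         max_cv = 0.25, max_d = 0.50, k = 10L) {
  n_in <- nrow(t)
  s1 <- filter_pool_missingness(t, design, max_pool_missing)
  s2 <- filter_group_missingness(s1$table, design, max_group_missing)
  s3 <- filter_cv(s2$table, design, max_cv)
  s4 <- filter_d_ratio(s3$table, design, max_d)
  r <- qc_roles(s4$table, design)
  n_missing <- sum(is.na(s4$table[, c(r$bio, r$pool), drop = FALSE]))
  imputed <- knn_impute(s4$table, k)
  structure(list(
    n_in = n_in,
    removed = list(pool_missing = s1$removed, group_missing = s2$removed,
                   cv = s3$removed, d_ratio = s4$removed),
    counts = c(pool_missing = length(s1$removed),
               group_missing = length(s2$removed),
               cv = length(s3$removed), d_ratio = length(s4$removed)),
    n_out = nrow(s4$table),
    n_imputed = n_missing,
    table = imputed,
    table_unimputed = s4$table),
    class = "lipid_qc_report")
}

#' @export
print.lipid_qc_report <- function(x, ...) {
  cat("Lipidomics QC report\n")
  cat("  species in:        ", x$n_in, "\n")
  cat("  pool missingness:  -", x$counts[["pool_missing"]], "\n")
  cat("  group missingness: -", x$counts[["group_missing"]], "\n")
  cat("  QC-pool CV:        -", x$counts[["cv"]], "\n")
  cat("  D-ratio:           -", x$counts[["d_ratio"]], "\n")
  cat("  species out:       ", x$n_out,
      " (", x$n_imputed, " cells imputed)\n", sep = "")
  invisible(x)
}
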