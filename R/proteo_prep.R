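#' Filter a precursor-level quantification report
#'
#' Applies the standard post-quantification filters to a long-format
#' precursor report (one row per precursor x run): 1% FDR on precursor
#' global and run-specific q-values and on protein-group global q-values,
#' removal of contaminants and non-proteotypic peptides, and an optional
#' floor on the report's signal-quality column. Removal counts per
#' criterion are attached as the `"removals"` attribute.
#'
#' @param t data.frame with columns `precursor_id`, `peptide`, `charge`,
#'   `protein`, `run`, `intensity`, `q_value`, `run_q_value`,
#'   `pg_q_value`, `proteotypic` (logical), `contaminant` (logical) and
#'   optionally `quality`.
#' @param q_threshold FDR threshold applied to all three q-values.
#' @param min_quality signal-quality floor; `NULL` (default) disables the
#'   criterion, which is only meaningful when the report carries a
#'   quality column.
#' @return the filtered data.frame.
#' @export
filter_precursors <- function(t, q_threshold = 0.01, min_quality = NULL) {
  req <- c("precursor_id", "peptide", "charge", "protein", "run",
           "intensity", "q_value", "run_q_value", "pg_q_value",
           "proteotypic", "contaminant")
  miss <- setdiff(req, names(t))
  if (length(miss))
    stop_schema(paste("precursor table lacks columns:",
                      paste(miss, collapse = ", ")))
  crit <- list(
    q_value = t$q_value <= q_threshold,
    run_q_value = t$run_q_value <= q_threshold,
    pg_q_value = t$pg_q_value <= q_threshold,
    contaminant = !t$contaminant,
    proteotypic = as.logical(t$proteotypic))
  if (!is.null(min_quality)) {
    if (!"quality" %in% names(t))
      stop_schema("`min_quality` set but no `quality` column present")
    crit$quality <- t$quality >= min_quality
  }
  keep <- Reduce(`&`, crit)
  removals <- vapply(crit, function(ok) sum(!ok, na.rm = TRUE), 0L)
  out <- t[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removals") <- removals
  out
}

#' Sum precursor charge states into peptide intensities
#'
#' Different charge states of the same peptide are summed per run; a
#' missing charge state contributes nothing (absence, not zero), and a
#' peptide with no observed charge state in a run stays missing.
#'
#' @param t a filtered precursor table (see [filter_precursors()]).
#' @return list with `matrix` (peptide x run intensities, `NA` when
#'   unobserved) and `peptides` (data.frame mapping rows to `protein`,
#'   `peptide`).
#' @export
aggregate_peptides <- function(t) {
  key <- paste(t$protein, t$peptide, sep = "\r")
  runs <- sort(unique(t$run))
  keys <- unique(key)
  m <- matrix(NA_real_, length(keys), length(runs),
              dimnames = list(keys, runs))
  ok <- !is.na(t$intensity)
  sums <- tapply(t$intensity[ok],
                 list(factor(key[ok], levels = keys),
                      factor(t$run[ok], levels = runs)),
                 sum)
  m[] <- sums
  parts <- strsplit(keys, "\r", fixed = TRUE)
  pep <- data.frame(protein = vapply(parts, `[`, "", 1),
                    peptide = vapply(parts, `[`, "", 2))
  rownames(m) <- paste(pep$protein, pep$peptide, sep = "|")
  list(matrix = m, peptides = pep)
}

# Median of log-ratios; with an even count this is the arithmetic mean of
# the central pair in log space, i.e. the geometric midpoint on the
# linear scale.
pairwise_log_ratios <- function(lp, min_pairs) {
  ns <- ncol(lp)
  r <- matrix(NA_real_, ns, ns)
  for (j in seq_len(ns - 1)) for (k in (j + 1):ns) {
    shared <- !is.na(lp[, j]) & !is.na(lp[, k])
    if (sum(shared) >= min_pairs) {
      r[j, k] <- stats::median(lp[shared, j] - lp[shared, k])
      r[k, j] <- -r[j, k]
    }
  }
  r
}

#' MaxLFQ protein quantification
#'
#' Reconstructs per-sample protein abundances from peptide intensities by
#' the MaxLFQ principle: for every sample pair sharing at least
#' `min_pairs` peptides the protein-level log2 ratio is the median of
#' peptide log2 ratios; per protein, sample log2 abundances are the
#' least-squares solution of the system of all valid pairwise ratios.
#' The solution is anchored so that, within each connected block of
#' samples, the mean log2 protein abundance equals the mean log2 of the
#' per-sample peptide sums; samples participating in no valid pair stay
#' missing.
#'
#' @param peptides output of [aggregate_peptides()], or a peptide x
#'   sample matrix plus `peptide_info` with a `protein` column.
#' @param min_pairs minimum number of shared peptides for a valid pair.
#' @return list of class `protein_matrix`: `matrix` (protein x sample,
#'   linear scale), `n_peptides`, `detection_rate`.
#' @export
maxlfq <- function(peptides, min_pairs = 1L) {
  m <- peptides$matrix
  info <- peptides$peptides
  prots <- unique(info$protein)
  ns <- ncol(m)
  out <- matrix(NA_real_, length(prots), ns,
                dimnames = list(prots, colnames(m)))
  npep <- integer(length(prots))
  for (pi in seq_along(prots)) {
    sub <- m[info$protein == prots[pi], , drop = FALSE]
    npep[pi] <- nrow(sub)
    lp <- log2(sub)
    r <- pairwise_log_ratios(lp, min_pairs)
    in_pair <- apply(!is.na(r), 1, any)
    if (!any(in_pair)) next
    idx <- which(in_pair)
    # connected blocks of the ratio graph
    gadj <- !is.na(r[idx, idx, drop = FALSE])
    comp <- ratio_components(gadj)
    a <- rep(NA_real_, ns)
    for (cid in unique(comp)) {
      sidx <- idx[comp == cid]
      if (length(sidx) < 2) next
      pairs <- which(upper.tri(r[sidx, sidx, drop = FALSE]) &
                       !is.na(r[sidx, sidx, drop = FALSE]), arr.ind = TRUE)
      np <- nrow(pairs)
      A <- matrix(0, np + 1, length(sidx))
      b <- numeric(np + 1)
      for (e in seq_len(np)) {
        A[e, pairs[e, 1]] <- 1
        A[e, pairs[e, 2]] <- -1
        b[e] <- r[sidx[pairs[e, 1]], sidx[pairs[e, 2]]]
      }
      # anchor: mean log2 abundance = mean log2 peptide sum over block
      anchor <- mean(log2(colSums(sub[, sidx, drop = FALSE], na.rm = TRUE)))
      A[np + 1, ] <- sqrt(np)        # weighted so the constraint binds
      b[np + 1] <- sqrt(np) * length(sidx) * anchor
      sol <- tryCatch(stats::lsfit(A, b, intercept = FALSE)$coefficients,
                      error = function(e) rep(NA_real_, length(sidx)))
      a[sidx] <- sol
    }
    out[pi, ] <- 2^a
  }
  structure(list(matrix = out, n_peptides = stats::setNames(npep, prots),
                 detection_rate = rowMeans(!is.na(out))),
            class = "protein_matrix")
}

# Connected components of a small logical adjacency matrix.
ratio_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

#' Keep proteins detected in a minimum fraction of samples
#'
#' @param m a `protein_matrix` from [maxlfq()].
#' @param min_rate minimum observed fraction over all samples (inclusive
#'   boundary; 60% by convention for a 19-sample study means 12+
#'   detections).
#' @return the filtered `protein_matrix`.
#' @export
detection_filter <- function(m, min_rate = 0.60) {
  rate <- rowMeans(!is.na(m$matrix))
  keep <- rate >= min_rate
  structure(list(matrix = m$matrix[keep, , drop = FALSE],
                 n_peptides = m$n_peptides[keep],
                 detection_rate = rate[keep]),
            class = "protein_matrix")
}

#' Iterative regression imputation of missing protein abundances
#'
#' Fills missing values on the log2 scale by iterated regression: each
#' protein with missing entries is regressed on its most-correlated
#' predictor proteins (a capped set, because the sample count is far
#' smaller than the protein count), missing cells are replaced by the
#' fitted values, and the cycle repeats until the largest change in an
#' imputed value falls below `tol` or `max_iter` is reached. Observed
#' values are never altered; the result is deterministic for a fixed
#' seed (the seed only breaks ties in predictor selection).
#'
#' @param m a `protein_matrix`; every protein must have at least one
#'   observed value.
#' @param seed integer seed.
#' @param n_predictors cap on predictor proteins per regression.
#' @param min_abs_cor minimum absolute correlation for a protein to act
#'   as predictor; targets with no strong predictor keep their row mean,
#'   which guards against overfitting spurious correlations when samples
#'   are few.
#' @param tol convergence tolerance on log2 imputed values.
#' @param max_iter iteration cap.
#' @return the completed `protein_matrix`.
#' @export
impute_iterative <- function(m, seed = 1L, n_predictors = 5L,
                             min_abs_cor = 0.4, tol = 1e-4,
                             max_iter = 10L) {
  x <- log2(m$matrix)
  if (any(rowSums(!is.na(x)) == 0))
    stop("impute_iterative: protein with no observed value", call. = FALSE)
  if (!anyNA(x)) return(m)
  with_seed(seed, {
    nas <- is.na(x)
    # start from row means
    xf <- x
    rm_ <- rowMeans(x, na.rm = TRUE)
    for (i in which(rowSums(nas) > 0)) xf[i, nas[i, ]] <- rm_[i]
    targets <- which(rowSums(nas) > 0)
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (i in targets) {
        others <- setdiff(seq_len(nrow(xf)), i)
        if (!length(others)) next
        cc <- abs(stats::cor(xf[i, ], t(xf[others, , drop = FALSE])))
        cc[is.na(cc)] <- 0
        obs <- !nas[i, ]
        # keep the regression overdetermined on the observed samples
        np_use <- min(n_predictors, length(others), max(1L, sum(obs) - 2L))
        pred <- others[order(-cc, stats::runif(length(cc)))][seq_len(np_use)]
        pred <- pred[cc[match(pred, others)] >= min_abs_cor]
        if (!length(pred)) next     # no informative predictor: keep mean
        df_tr <- data.frame(y = x[i, obs], t(xf[pred, obs, drop = FALSE]))
        fit <- stats::lm(y ~ ., data = df_tr)
        newv <- stats::predict(
          fit, newdata = data.frame(t(xf[pred, nas[i, ], drop = FALSE])))
        delta <- max(delta, max(abs(newv - xf[i, nas[i, ]])))
        xf[i, nas[i, ]] <- newv
      }
      if (delta < tol) break
    }
    res <- 2^xf
    res[!nas] <- m$matrix[!nas]   # observed entries stay bit-identical
    structure(list(matrix = res, n_peptides = m$n_peptides,
                   detection_rate = m$detection_rate),
              class = "protein_matrix")
  })
}

#' Run the full proteomics post-quantification pipeline
#'
#' filter -> charge-state aggregation -> MaxLFQ -> detection filter ->
#' iterative imputation, the fixed order of the post-processing chain.
#'
#' @inheritParams filter_precursors
#' @inheritParams detection_filter
#' @inheritParams impute_iterative
#' @param min_pairs passed to [maxlfq()].
#' @return a completed `protein_matrix` with a `"removals"` attribute.
#' @export
run_proteo_prep <- function(t, q_threshold = 0.01, min_quality = NULL,
                            min_pairs = 1L, min_rate = 0.60, seed = 1L) {
  ft <- filter_precursors(t, q_threshold, min_quality)
  pep <- aggregate_peptides(ft)
  pm <- maxlfq(pep, min_pairs)
  pm <- detection_filter(pm, min_rate)
  out <- impute_iterative(pm, seed)
  attr(out, "removals") <- attr(ft, "removals")
  out
}
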