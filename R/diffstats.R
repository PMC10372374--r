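#' Feature-wise two-way ANOVA (group, sex, interaction)
#'
#' Fits the 2x2 linear model `value ~ group + sex + group:sex` to every
#' feature of a log2 abundance matrix and returns F-test p-values for
#' the group and sex main effects and their interaction. Because the
#' design is unbalanced (e.g. 6/4 vs 5/4 animals per cell), sums of
#' squares are Type II by default: each main effect is adjusted for the
#' other, the interaction for both. The computation is vectorized over
#' features via projection matrices, so thousands of features cost a
#' handful of matrix products.
#'
#' @param m feature x sample matrix of log2 abundances (no missing
#'   values; impute upstream).
#' @param design a [study_design()] covering the columns of `m`.
#' @param ss_type `"II"` (default), `"I"` or `"III"`.
#' @return data.frame with one row per feature: `p_group`, `p_sex`,
#'   `p_interaction`. Constant features get p = 1 with a warning.
#' @export
two_way_anova <- function(m, design, ss_type = c("II", "I", "III")) {
  ss_type <- match.arg(ss_type)
  d <- bio_design(design)
  d <- d[match(colnames(m), d$sample), , drop = FALSE]
  if (anyNA(d$sample))
    stop("matrix contains samples absent from the design", call. = FALSE)
  if (anyNA(m))
    stop("two_way_anova requires a complete matrix; impute first",
         call. = FALSE)
  n <- ncol(m)
  g <- d$group; s <- d$sex
  X_full <- stats::model.matrix(~ g * s)
  X_gs <- stats::model.matrix(~ g + s)
  X_g <- stats::model.matrix(~ g)
  X_s <- stats::model.matrix(~ s)
  X_1 <- matrix(1, n, 1)
  rss <- function(X) {
    Q <- qr.Q(qr(X))
    fit <- Q %*% (t(Q) %*% t(m))
    colSums((t(m) - fit)^2)
  }
  r_full <- rss(X_full)
  r_gs <- rss(X_gs)
  df_res <- n - qr(X_full)$rank
  if (df_res <= 0) stop("no residual degrees of freedom", call. = FALSE)
  if (ss_type == "II") {
    ss_g <- rss(X_s) - r_gs
    ss_s <- rss(X_g) - r_gs
  } else if (ss_type == "I") {
    r_1 <- rss(X_1)
    ss_g <- r_1 - rss(X_g)
    ss_s <- rss(X_g) - r_gs
  } else { # III: each term adjusted for all others, contr.sum coding
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old))
    Xf <- stats::model.matrix(~ g * s)
    asn <- attr(Xf, "assign")
    r_f <- rss(Xf)
    drop_rss <- function(term) rss(Xf[, asn != term, drop = FALSE])
    ss_g <- drop_rss(1) - r_f
    ss_s <- drop_rss(2) - r_f
    r_full <- r_f
  }
  ss_i <- r_gs - r_full
  mse <- r_full / df_res
  pf_safe <- function(ss) {
    p <- stats::pf(ss / mse, 1, df_res, lower.tail = FALSE)
    p
  }
  out <- data.frame(feature = rownames(m),
                    p_group = pf_safe(ss_g), p_sex = pf_safe(ss_s),
                    p_interaction = pf_safe(ss_i))
  const <- apply(m, 1, function(x) stats::var(x) == 0)
  if (any(const)) {
    warning(sum(const), " constant feature(s); p-values set to 1")
    out[const, c("p_group", "p_sex", "p_interaction")] <- 1
  }
  zerovar <- mse == 0 & !const
  if (any(zerovar)) {
    # perfect cell fit: effects with zero SS are null (p = 1), others 0
    for (cn in c("p_group", "p_sex", "p_interaction")) {
      ss <- switch(cn, p_group = ss_g, p_sex = ss_s, p_interaction = ss_i)
      out[zerovar, cn] <- ifelse(ss[zerovar] <= 1e-12, 1, 0)
    }
  }
  rownames(out) <- NULL
  out
}

#' Pool and Benjamini-Hochberg adjust all ANOVA p-values of one dataset
#'
#' The group, sex and interaction p-values of all features of a single
#' omics dataset enter one BH step-up together (3 x n_features tests),
#' and the adjusted values are mapped back to their effects. Missing
#' p-values (inestimable effects) are excluded from the family size.
#'
#' @param stats output of [two_way_anova()].
#' @return `stats` with added columns `padj_group`, `padj_sex`,
#'   `padj_interaction`.
#' @export
pool_bh <- function(stats) {
  p <- c(stats$p_group, stats$p_sex, stats$p_interaction)
  adj <- stats::p.adjust(p, method = "BH")
  k <- nrow(stats)
  stats$padj_group <- adj[seq_len(k)]
  stats$padj_sex <- adj[k + seq_len(k)]
  stats$padj_interaction <- adj[2 * k + seq_len(k)]
  stats
}

#' Tukey HSD post-hoc comparisons among the four group x sex cells
#'
#' For a feature with a significant interaction, compares all pairs of
#' the four cells with the studentized-range correction; unbalanced
#' cells use the Tukey-Kramer standard error.
#'
#' @param values numeric vector of (log2) abundances for one feature.
#' @param design a [study_design()]; `values` must follow
#'   `design$sample` order for biological samples.
#' @return data.frame of pairwise comparisons: `contrast`, `diff`,
#'   `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, design) {
  d <- bio_design(design)
  if (length(values) != nrow(d))
    stop("`values` must have one entry per biological sample",
         call. = FALSE)
  cell <- interaction(d$group, d$sex, sep = ":")
  fit <- stats::aov(values ~ cell)
  tk <- stats::TukeyHSD(fit)$cell
  data.frame(contrast = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL)
}

#' Per-feature log2 fold change between groups
#'
#' log2 of the ratio of linear-scale group means, computed after
#' imputation; positive values mean higher abundance in `case_group`
#' (first group level by default, PHG in the reference design).
#'
#' @param m feature x sample matrix on the linear scale.
#' @param design a [study_design()].
#' @param case_group,ref_group group labels for numerator/denominator;
#'   defaults are the first and second group level.
#' @return named numeric vector of log2 fold changes.
#' @export
fold_change <- function(m, design, case_group = NULL, ref_group = NULL) {
  d <- bio_design(design)
  d <- d[match(colnames(m), d$sample), , drop = FALSE]
  lev <- levels(d$group)
  case_group <- case_group %||% lev[1]
  ref_group <- ref_group %||% lev[2]
  mc <- rowMeans(m[, d$group == case_group, drop = FALSE], na.rm = TRUE)
  mr <- rowMeans(m[, d$group == ref_group, drop = FALSE], na.rm = TRUE)
  log2(mc / mr)
}

#' Call differential abundance from adjusted p-values and fold changes
#'
#' A feature is flagged for an effect when its pooled-BH adjusted
#' p-value is at most `p_max` and its absolute linear fold change is at
#' least `min_fold` (both boundaries inclusive). The fold-change filter
#' applies to all three effects; up/down is split by the sign of the
#' group fold change.
#'
#' @param stats output of [pool_bh()].
#' @param l2fc log2 fold-change vector aligned with `stats$feature`.
#' @param p_max adjusted-p threshold (default 0.05).
#' @param min_fold minimum linear fold change (default 1.5, i.e.
#'   |log2 fc| >= 0.585).
#' @return list with `stats` (flag columns added) and `summary` (counts
#'   total/up/down per effect).
#' @export
call_significance <- function(stats, l2fc, p_max = 0.05, min_fold = 1.5) {
  lt <- log2(min_fold)
  fc_ok <- abs(l2fc) >= lt
  stats$l2fc <- l2fc
  stats$sig_group <- stats$padj_group <= p_max & fc_ok
  stats$sig_sex <- stats$padj_sex <= p_max & fc_ok
  stats$sig_interaction <- stats$padj_interaction <= p_max & fc_ok
  summ <- lapply(c(group = "sig_group", sex = "sig_sex",
                   interaction = "sig_interaction"), function(cn) {
    f <- stats[[cn]] %in% TRUE
    c(total = sum(f), up = sum(f & l2fc > 0), down = sum(f & l2fc < 0))
  })
  list(stats = stats, summary = summ)
}

#' Insulin-resistance indices
#'
#' `homa_ir()` = insulin (uU/mL) x glucose (mg/dL) / 405.
#' `quicki()` = 1 / (log10 insulin (mU/L) + log10 glucose (mg/dL));
#' values below 0.45 flag decreased insulin sensitivity in neonates.
#'
#' @param insulin fasting insulin, uU/mL (identically mU/L).
#' @param glucose fasting glucose, mg/dL.
#' @return numeric index vector; `quicki()` carries a `"flag_low"`
#'   attribute marking values < 0.45.
#' @examples
#' homa_ir(10, 81)   # 2.0
#' quicki(10, 100)   # 1/3
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(insulin <= 0) || any(glucose <= 0))
    stop("insulin and glucose must be positive", call. = FALSE)
  insulin * glucose / 405
}

#' @rdname homa_ir
#' @export
quicki <- function(insulin, glucose) {
  if (any(insulin <= 0) || any(glucose <= 0))
    stop("insulin and glucose must be positive", call. = FALSE)
  denom <- log10(insulin) + log10(glucose)
  if (any(denom <= 0))
    stop("QUICKI undefined: log10(insulin) + log10(glucose) <= 0",
         call. = FALSE)
  out <- 1 / denom
  attr(out, "flag_low") <- out < 0.45
  out
}

#' Two-tailed Student's t-test between two groups
#'
#' @param values numeric vector.
#' @param groups two-level grouping vector aligned with `values`.
#' @return list with `t`, `df`, `p`.
#' @export
group_t_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("`groups` must have exactly two levels", call. = FALSE)
  ht <- stats::t.test(values ~ groups, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
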