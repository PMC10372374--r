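#' Construct a two-factor study design table
#'
#' Builds the sample sheet for a 2 (group) x 2 (sex) offspring study with
#' optional QC-pool and blank samples, the layout used throughout the
#' package. The default cell sizes mirror the unbalanced design of a
#' diabetic-pregnancy pig cohort: PHG (offspring of hyperglycemic mothers)
#' with 5 females and 4 males, PNG (normoglycemic mothers) with 6 females
#' and 4 males, plus 5 QC-pool injections and 3 blanks for lipidomics.
#'
#' @param n_per_cell named integer vector of biological sample counts per
#'   group x sex cell; names are `"<group>.<sex>"`.
#' @param n_pool number of QC-pool samples (pooled aliquot of all study
#'   samples, injected repeatedly; estimates technical variance).
#' @param n_blank number of blank samples.
#' @return A `data.frame` with columns `sample`, `group`, `sex`, `role`
#'   (one of `"biological"`, `"qc_pool"`, `"blank"`), of class
#'   `study_design`.
#' @examples
#' d <- study_design()
#' table(d$group, d$sex)
#' @export
study_design <- function(n_per_cell = c(PHG.F = 5L, PHG.M = 4L,
                                        PNG.F = 6L, PNG.M = 4L),
                         n_pool = 5L, n_blank = 3L) {
  if (any(n_per_cell < 0) || n_pool < 0 || n_blank < 0)
    stop("sample counts must be non-negative", call. = FALSE)
  cells <- strsplit(names(n_per_cell), ".", fixed = TRUE)
  if (any(lengths(cells) != 2L))
    stop("names of `n_per_cell` must be '<group>.<sex>'", call. = FALSE)
  rows <- lapply(seq_along(n_per_cell), function(i) {
    n <- n_per_cell[[i]]
    if (n == 0L) return(NULL)
    g <- cells[[i]][1]; s <- cells[[i]][2]
    data.frame(sample = sprintf("%s_%s_%02d", g, s, seq_len(n)),
               group = g, sex = s, role = "biological")
  })
  pool <- if (n_pool > 0)
    data.frame(sample = sprintf("POOL_%02d", seq_len(n_pool)),
               group = NA_character_, sex = NA_character_, role = "qc_pool")
  blank <- if (n_blank > 0)
    data.frame(sample = sprintf("BLANK_%02d", seq_len(n_blank)),
               group = NA_character_, sex = NA_character_, role = "blank")
  out <- do.call(rbind, c(rows, list(pool, blank)))
  rownames(out) <- NULL
  class(out) <- c("study_design", "data.frame")
  out
}

# Biological subset of a design, with group/sex as factors.
bio_design <- function(design) {
  d <- design[design$role == "biological", , drop = FALSE]
  d$group <- factor(d$group)
  d$sex <- factor(d$sex)
  d
}

check_design_matrix <- function(m, design) {
  miss <- setdiff(colnames(m), design$sample)
  if (length(miss))
    stop("samples in matrix but not in design: ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Specify planted effects for the synthetic omics generator
#'
#' Collects the parameters that control how many features carry true
#' group, sex or interaction effects and how strong those effects are.
#' Defaults give a feature population in which a fifth of features differ
#' between groups with linear fold changes between 1.5 and 5.3 (the range
#' spanned by the strongest hits in neonatal liver proteomes), a tenth
#' differ between sexes, and a twentieth carry a pure interaction.
#'
#' @param n_features number of features to simulate.
#' @param frac_group_affected,frac_sex_affected,frac_interaction_affected
#'   proportions of features carrying each effect; must sum to at most 1.
#' @param fold_change_range linear fold-change interval for planted
#'   effects; lower bound must exceed 1.
#' @param baseline_log2_mean mean of per-feature baseline log2 abundance.
#' @param baseline_log2_sd spread of baselines across features.
#' @param sigma_bio biological standard deviation on the log2 scale.
#' @param missing_rate overall missing-value rate; dropouts are
#'   left-censored (low-intensity values go missing preferentially).
#' @return A validated list of class `effect_spec`.
#' @export
effect_spec <- function(n_features = 100L,
                        frac_group_affected = 0.20,
                        frac_sex_affected = 0.10,
                        frac_interaction_affected = 0.05,
                        fold_change_range = c(1.5, 5.3),
                        baseline_log2_mean = 20,
                        baseline_log2_sd = 1.5,
                        sigma_bio = 0.3,
                        missing_rate = 0) {
  fr <- c(frac_group_affected, frac_sex_affected, frac_interaction_affected)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("affected fractions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  if (length(fold_change_range) != 2L || fold_change_range[1] <= 1 ||
      diff(fold_change_range) < 0)
    stop("`fold_change_range` must be an interval with lower bound > 1",
         call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1)
    stop("`missing_rate` must be a probability", call. = FALSE)
  if (sigma_bio <= 0) stop("`sigma_bio` must be positive", call. = FALSE)
  structure(list(n_features = as.integer(n_features),
                 frac_group_affected = frac_group_affected,
                 frac_sex_affected = frac_sex_affected,
                 frac_interaction_affected = frac_interaction_affected,
                 fold_change_range = fold_change_range,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 sigma_bio = sigma_bio,
                 missing_rate = missing_rate),
            class = "effect_spec")
}
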