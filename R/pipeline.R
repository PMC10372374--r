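#' Default configuration for an end-to-end synthetic run
#'
#' All per-stage parameters default to the conventional analysis values
#' (QC thresholds 35%/50%/25%/50% with k = 10, FDR 0.05 with linear fold
#' 1.5, OPLS-DA with LOOCV and 200 permutations, RWR alpha 0.9 with 90%
#' target coverage, GDA cutoff 0.3). Per-stage seeds are derived from
#' the global seed by a stable counter scheme so adding a stage never
#' shifts another stage's random stream.
#'
#' @param seed global seed.
#' @param out_dir output directory (`NULL` disables file output).
#' @param ... overrides for any top-level entry.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    design = study_design(),
    omics_spec = effect_spec(n_features = 100L, missing_rate = 0),
    lipids = list(enabled = TRUE, n_species = 1204L,
                  planted_counts = c(pool_missing = 136L,
                                     group_missing = 7L,
                                     cv = 22L, d_ratio = 43L)),
    diffstats = list(p_max = 0.05, min_fold = 1.5, ss_type = "II"),
    multivar = list(n_perm = 200L),
    network = list(enabled = TRUE, n_nodes = 2000L, module_size = 10L,
                   n_diseases = 50L, n_random = 1000L, score_min = 0),
    clinical = list(enabled = TRUE))
  utils::modifyList(cfg, list(...))
}

#' Validate the consistency of configured inputs
#'
#' Checks that matrices and design tables agree on samples and that
#' feature identifiers are unique; returns a character vector of issues
#' (empty when everything is consistent).
#'
#' @param m abundance matrix (or `NULL`).
#' @param design a study design table.
#' @return character vector of issues.
#' @export
validate_inputs <- function(m, design) {
  issues <- character(0)
  req <- c("sample", "group", "sex", "role")
  if (!all(req %in% names(design)))
    issues <- c(issues, "design lacks required columns")
  if (!is.null(m)) {
    extra <- setdiff(colnames(m), design$sample)
    if (length(extra))
      issues <- c(issues, paste("samples in matrix but not in design:",
                                paste(extra, collapse = ", ")))
    if (anyDuplicated(rownames(m)))
      issues <- c(issues, "duplicate feature IDs in matrix")
  }
  issues
}

#' Run the full synthetic multi-omics analysis pipeline
#'
#' Generates synthetic proteome-like and metabolome-like matrices, a raw
#' lipidome, a PPI graph with a planted module and a disease catalogue,
#' then runs every analysis stage: lipid QC, feature-wise two-way ANOVA
#' with pooled BH and significance calls, OPLS-DA and co-inertia,
#' LCC/core/proximity network statistics, and clinical indices. All
#' randomness derives from the global seed, so an identical
#' configuration reproduces every output exactly.
#'
#' @param config a [run_config()].
#' @return a `pipeline_report` list of per-stage results plus a
#'   `manifest` of parameters and seeds.
#' @export
run_pipeline <- function(config = run_config()) {
  seed <- config$seed
  design <- config$design
  report <- list(manifest = list(seed = seed,
                                 timestamp = format(Sys.time()),
                                 params = config[setdiff(names(config),
                                                         c("design"))]))

  # --- omics matrices with planted effects -------------------------------
  om <- gen_omics_matrix(design, config$omics_spec,
                         derive_seed(seed, "omics"))
  issues <- validate_inputs(om$matrix, design)
  if (length(issues)) stop(paste(issues, collapse = "; "), call. = FALSE)
  mat <- om$matrix
  if (anyNA(mat)) {
    pm <- structure(list(matrix = mat, n_peptides = NULL,
                         detection_rate = rowMeans(!is.na(mat))),
                    class = "protein_matrix")
    mat <- impute_iterative(pm, derive_seed(seed, "impute"))$matrix
  }
  st <- two_way_anova(log2(mat), design, ss_type = config$diffstats$ss_type)
  st <- pool_bh(st)
  l2fc <- fold_change(mat, design)
  sig <- call_significance(st, l2fc, config$diffstats$p_max,
                           config$diffstats$min_fold)
  report$omics <- list(truth = om$truth, stats = sig$stats,
                       summary = sig$summary)

  # --- lipidomics QC -----------------------------------------------------
  if (isTRUE(config$lipids$enabled)) {
    lip <- gen_lipid_raw(design, config$lipids$n_species,
                         config$lipids$planted_counts,
                         seed = derive_seed(seed, "lipids"))
    report$lipid_qc <- run_lipid_qc(lip$table, design)
    report$lipid_truth <- lip$truth
  }

  # --- multivariate ------------------------------------------------------
  d <- bio_design(design)
  xs <- scale_features(t(mat), log2 = TRUE, scaling = "pareto")
  labels <- d$group[match(rownames(xs), d$sample)]
  model <- opls_da(xs, labels)
  perm <- permutation_test(function(x, l) {
    m <- tryCatch(opls_da(x, l), error = function(e) NULL)
    if (is.null(m)) -Inf else m$Q2
  }, xs, labels, n_perm = config$multivar$n_perm,
  seed = derive_seed(seed, "perm"))
  report$multivar <- list(pca = run_pca(scale_features(t(mat))),
                          opls = model, p_q2 = perm$p)

  # --- network -----------------------------------------------------------
  if (isTRUE(config$network$enabled)) {
    net <- gen_ppi(config$network$n_nodes, 2L,
                   planted_modules = list(
                     list(size = config$network$module_size,
                          p_internal = 0.9)),
                   seed = derive_seed(seed, "ppi"))
    module <- net$truth$node[!is.na(net$truth$module)]
    g <- net$graph
    lcc <- lcc_zscore(module, g, n_random = config$network$n_random,
                      seed = derive_seed(seed, "lcc"))
    catalog <- gen_disease_catalog(
      config$network$n_diseases, igraph::V(g)$name,
      overlap = stats::setNames(
        list(module[seq_len(min(5, length(module)))]), "1"),
      module_genes = module,
      seed = derive_seed(seed, "diseases"))
    screen <- disease_screen(module, catalog, g,
                             n_random = config$network$n_random,
                             seed = derive_seed(seed, "proximity"),
                             min_bin = 50L)
    report$network <- list(truth = net$truth, lcc = lcc, screen = screen)
  }

  # --- clinical ----------------------------------------------------------
  if (isTRUE(config$clinical$enabled)) {
    cl <- gen_clinical(design, seed = derive_seed(seed, "clinical"))
    cl$homa_ir <- homa_ir(cl$insulin, cl$glucose)
    q <- quicki(cl$insulin, cl$glucose)
    cl$quicki <- as.numeric(q)
    report$clinical <- list(
      table = cl,
      t_homa = group_t_test(cl$homa_ir, cl$group),
      t_quicki = group_t_test(cl$quicki, cl$group))
  }

  # --- optional file outputs --------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(mat, file.path(config$out_dir, "omics_matrix.tsv"))
    write_design_tsv(design, file.path(config$out_dir, "design.tsv"))
    utils::write.table(sig$stats,
                       file.path(config$out_dir, "feature_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed,
           significant = report$omics$summary,
           lipid_counts = if (!is.null(report$lipid_qc))
             as.list(report$lipid_qc$counts),
           lipid_survivors = report$lipid_qc$n_out,
           opls = list(R2X = model$R2X, R2Y = model$R2Y, Q2 = model$Q2,
                       n_ortho = model$n_ortho, p_q2 = perm$p)),
      file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  class(report) <- "pipeline_report"
  report
}
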