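#' Generate a synthetic omics abundance matrix with planted effects
#'
#' Simulates a feature-by-sample matrix of linear-scale intensities for
#' the biological samples of a 2x2 design. Log2 intensities are Normal
#' around a per-feature baseline, shifted by planted group, sex and
#' interaction effects; which features carry which effect is recorded in
#' a truth ledger so downstream differential statistics can be validated
#' against ground truth. Missing values, when requested, are
#' left-censored: dropout probability rises as the underlying intensity
#' falls below a low quantile of the feature population, the mechanism
#' that dominates mass-spectrometry missingness.
#'
#' @param design a [study_design()] table.
#' @param spec an [effect_spec()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `matrix` (features x biological samples, linear
#'   scale, `NA` for dropouts), `design`, and `truth`, a data.frame with
#'   one row per feature giving the planted effect label
#'   (`group`/`sex`/`interaction`/`null`) and the true log2 fold changes.
#' @export
gen_omics_matrix <- function(design, spec, seed) {
  stopifnot(inherits(spec, "effect_spec"))
  d <- bio_design(design)
  n <- nrow(d)
  if (n < 4L) stop("need at least one sample per cell", call. = FALSE)
  p <- spec$n_features
  with_seed(seed, {
    n_g <- round(spec$frac_group_affected * p)
    n_s <- round(spec$frac_sex_affected * p)
    n_i <- round(spec$frac_interaction_affected * p)
    lab <- rep("null", p)
    idx <- sample.int(p)
    if (n_g > 0) lab[idx[seq_len(n_g)]] <- "group"
    if (n_s > 0) lab[idx[n_g + seq_len(n_s)]] <- "sex"
    if (n_i > 0) lab[idx[n_g + n_s + seq_len(n_i)]] <- "interaction"

    draw_l2fc <- function(k) {
      if (k == 0) return(numeric(0))
      mag <- log2(stats::runif(k, spec$fold_change_range[1],
                               spec$fold_change_range[2]))
      mag * sample(c(-1, 1), k, replace = TRUE)
    }
    l2fc_group <- l2fc_sex <- l2fc_inter <- rep(0, p)
    l2fc_group[lab == "group"] <- draw_l2fc(sum(lab == "group"))
    l2fc_sex[lab == "sex"] <- draw_l2fc(sum(lab == "sex"))
    l2fc_inter[lab == "interaction"] <- draw_l2fc(sum(lab == "interaction"))

    baseline <- stats::rnorm(p, spec$baseline_log2_mean, spec$baseline_log2_sd)
    # first group level is the "case" group (PHG by default ordering)
    gref <- levels(d$group)[1]
    sref <- levels(d$sex)[1]
    is_g <- d$group == gref
    is_s <- d$sex == sref
    mu <- matrix(baseline, p, n) +
      outer(l2fc_group, as.numeric(is_g)) +
      outer(l2fc_sex, as.numeric(is_s)) +
      outer(l2fc_inter, as.numeric(is_g & is_s))
    y <- mu + matrix(stats::rnorm(p * n, 0, spec$sigma_bio), p, n)
    dimnames(y) <- list(sprintf("feat_%04d", seq_len(p)), d$sample)

    if (spec$missing_rate > 0) {
      # left-censoring: logistic dropout around a low quantile of the
      # realized log2 intensities, scaled so the overall rate matches
      thr <- stats::quantile(y, 0.25)
      w <- stats::plogis((thr - y) / 1.0)
      pr <- w * (spec$missing_rate / mean(w))
      y[stats::runif(p * n) < pmin(pr, 1)] <- NA
    }
    truth <- data.frame(feature = rownames(y), effect = lab,
                        l2fc_group = l2fc_group, l2fc_sex = l2fc_sex,
                        l2fc_interaction = l2fc_inter)
    list(matrix = 2^y, design = d, truth = truth)
  })
}

#' Generate a raw lipidomics table with planted QC violations
#'
#' Builds a species-by-sample concentration table (nmol/g) that includes
#' biological, QC-pool and blank samples, in which a chosen number of
#' species violate each stage of the four-step quality-control procedure
#' (pool missingness > 35%, group-wise missingness >= 50% in every group,
#' QC-pool CV > 25%, D-ratio > 50%) while passing all earlier stages, and
#' all remaining species pass every stage. Each species is verified
#' post hoc against the realized finite-sample criteria and resampled up
#' to `max_retry` times until its planted assignment holds exactly, so the
#' sequential QC of [run_lipid_qc()] recovers the planted per-stage counts
#' deterministically.
#'
#' @param design a [study_design()] with at least 2 pool samples.
#' @param n_species total number of lipid species (default 1204, the size
#'   of a shotgun liver lipidome before QC).
#' @param planted_counts named counts of species to plant per stage, in
#'   order `pool_missing`, `group_missing`, `cv`, `d_ratio`.
#' @param clean_missing_rate missing-value rate among biological cells of
#'   clean species (kept well clear of the group-missingness rule).
#' @param seed integer seed.
#' @param max_retry resampling budget per species.
#' @return list with `table` (species x samples), `design`, and `truth`
#'   (per-species planted stage, `"none"` for clean species).
#' @export
gen_lipid_raw <- function(design,
                          n_species = 1204L,
                          planted_counts = c(pool_missing = 136L,
                                             group_missing = 7L,
                                             cv = 22L, d_ratio = 43L),
                          clean_missing_rate = 0.02,
                          seed = 1L, max_retry = 1000L) {
  req <- c("pool_missing", "group_missing", "cv", "d_ratio")
  if (!all(req %in% names(planted_counts)))
    stop("`planted_counts` must name stages ",
         paste(req, collapse = ", "), call. = FALSE)
  planted_counts <- planted_counts[req]
  if (sum(planted_counts) > n_species)
    stop("sum of planted counts exceeds `n_species`", call. = FALSE)
  pools <- design$sample[design$role == "qc_pool"]
  blanks <- design$sample[design$role == "blank"]
  bio <- bio_design(design)
  if (length(pools) < 2L)
    stop("design must include at least 2 qc_pool samples", call. = FALSE)

  stage_of <- rep(c(req, "none"),
                  c(planted_counts, n_species - sum(planted_counts)))
  n_bio <- nrow(bio)
  grp <- as.character(bio$group)
  grp_sizes <- table(grp)

  # Realized-sample criteria, identical to the sequential QC rules.
  fails_stage <- function(pool_v, bio_v) {
    c(pool_missing = mean(is.na(pool_v)) > 0.35,
      group_missing = all(vapply(split(is.na(bio_v), grp), mean, 0) >= 0.5),
      cv = {
        v <- pool_v[!is.na(pool_v)]
        length(v) >= 2 && stats::sd(v) / mean(v) > 0.25
      },
      d_ratio = {
        st <- sd_obs(pool_v); sb <- sd_obs(bio_v)
        !is.na(st) && !is.na(sb) && (st > 0 || sb > 0) &&
          st / sqrt(st^2 + sb^2) > 0.5
      })
  }

  make_species <- function(stage) {
    m <- 2^stats::runif(1, log2(5), log2(500))
    clip <- function(x) pmax(x, 0.02 * m)
    pool_v <- clip(m * (1 + stats::rnorm(length(pools), 0, 0.05)))
    bio_v <- clip(m * (1 + stats::rnorm(n_bio, 0, 0.30)))
    if (stage == "pool_missing") {
      pool_v[sample.int(length(pools), max(2L, ceiling(0.4 * length(pools))))] <- NA
    } else if (stage == "group_missing") {
      for (g in names(grp_sizes)) {
        ids <- which(grp == g)
        k <- ceiling(0.5 * length(ids)) + sample(0:1, 1)
        bio_v[sample(ids, min(k, length(ids)))] <- NA
      }
    } else if (stage == "cv") {
      pool_v <- clip(m * (1 + stats::rnorm(length(pools), 0, 0.45)))
    } else if (stage == "d_ratio") {
      pool_v <- clip(m * (1 + stats::rnorm(length(pools), 0, 0.20)))
      bio_v <- clip(m * (1 + stats::rnorm(n_bio, 0, 0.10)))
    } else {
      # sparse biological missingness, capped far below the group rule
      k <- stats::rbinom(1, n_bio, clean_missing_rate)
      if (k > 0) {
        cand <- sample.int(n_bio, min(k, 2L))
        bio_v[cand] <- NA
      }
    }
    list(pool = pool_v, bio = bio_v)
  }

  ok_for <- function(flags, stage) {
    if (stage == "none") return(!any(flags))
    i <- match(stage, req)
    flags[i] && !any(flags[seq_len(i - 1L)])
  }

  with_seed(seed, {
    tab <- matrix(NA_real_, n_species, n_bio + length(pools) + length(blanks),
                  dimnames = list(sprintf("lipid_%04d", seq_len(n_species)),
                                  c(bio$sample, pools, blanks)))
    for (i in seq_len(n_species)) {
      st <- stage_of[i]
      done <- FALSE
      for (try in seq_len(max_retry)) {
        sp <- make_species(st)
        if (ok_for(fails_stage(sp$pool, sp$bio), st)) { done <- TRUE; break }
      }
      if (!done)
        stop("retry budget exhausted while planting stage '", st,
             "' for species ", i, call. = FALSE)
      tab[i, bio$sample] <- sp$bio
      tab[i, pools] <- sp$pool
      if (length(blanks))
        tab[i, blanks] <- stats::runif(length(blanks), 0, 0.02) *
          mean(sp$bio, na.rm = TRUE)
    }
    truth <- data.frame(species = rownames(tab), planted_stage = stage_of)
    list(table = tab, design = design, truth = truth)
  })
}

#' Generate a scale-free protein-protein interaction graph with planted
#' modules
#'
#' Grows an undirected graph by preferential attachment (so the degree
#' sequence is heavy-tailed, as in curated interactomes), then plants
#' dense modules by adding internal edges among randomly chosen node
#' sets. Every edge carries a combined confidence score in \[0,1\];
#' planted-module edges score above 0.7 so they survive high-confidence
#' filtering.
#'
#' @param n_nodes number of proteins.
#' @param attachment_parameter edges added per new node during growth.
#' @param planted_modules list of `list(size =, p_internal =)` entries.
#' @param seed integer seed.
#' @return list with `graph` (igraph, edge attribute `combined_score`,
#'   vertex names `G<number>`) and `truth` (node, module id or `NA`).
#' @export
gen_ppi <- function(n_nodes, attachment_parameter = 2L,
                    planted_modules = list(), seed = 1L) {
  if (any(vapply(planted_modules, function(m) m$size, 0) > n_nodes))
    stop("module sizes must not exceed `n_nodes`", call. = FALSE)
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attachment_parameter,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("G%05d", seq_len(n_nodes))
    module_of <- rep(NA_integer_, n_nodes)
    avail <- seq_len(n_nodes)
    extra <- list()
    for (k in seq_along(planted_modules)) {
      mod <- planted_modules[[k]]
      nodes <- sample(avail, mod$size)
      avail <- setdiff(avail, nodes)
      module_of[nodes] <- k
      prs <- utils::combn(sort(nodes), 2)
      keep <- stats::runif(ncol(prs)) < mod$p_internal
      if (any(keep)) extra[[length(extra) + 1L]] <- prs[, keep, drop = FALSE]
    }
    if (length(extra)) {
      ee <- do.call(cbind, extra)
      g <- igraph::add_edges(g, as.vector(ee))
    }
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    sc <- stats::runif(nrow(el))
    in_mod <- !is.na(module_of[el[, 1]]) & !is.na(module_of[el[, 2]]) &
      module_of[el[, 1]] == module_of[el[, 2]]
    sc[in_mod] <- stats::runif(sum(in_mod), 0.701, 1)
    igraph::E(g)$combined_score <- sc
    truth <- data.frame(node = igraph::V(g)$name, module = module_of)
    list(graph = g, truth = truth)
  })
}

#' Generate a synthetic gene-disease catalogue
#'
#' Produces a DisGeNET-style long table of (disease, gene, GDA score)
#' rows. Diseases named in `overlap` share a chosen number of genes with
#' a planted PPI module; those shared associations are scored above the
#' conventional 0.3 confidence cutoff so they survive screening.
#'
#' @param n_diseases number of diseases.
#' @param gene_pool character vector of candidate gene symbols (usually
#'   the PPI graph's vertex names).
#' @param overlap named list: `overlap[[disease_index]]` is a character
#'   vector of module genes that disease must contain.
#' @param module_genes genes that non-overlap diseases must avoid
#'   (default: the union of all `overlap` entries); pass the full
#'   planted-module membership to keep background diseases disjoint
#'   from the module.
#' @param size_range disease gene-set size range.
#' @param seed integer seed.
#' @return data.frame with columns `disease_id`, `gene`, `gda_score`.
#' @export
gen_disease_catalog <- function(n_diseases, gene_pool, overlap = list(),
                                module_genes = NULL,
                                size_range = c(5L, 30L), seed = 1L) {
  with_seed(seed, {
    module_genes <- unique(c(unlist(overlap), module_genes))
    bg <- setdiff(gene_pool, module_genes)
    rows <- lapply(seq_len(n_diseases), function(i) {
      sz <- sample(size_range[1]:size_range[2], 1)
      shared <- overlap[[as.character(i)]] %||% character(0)
      rest <- sample(bg, max(0L, sz - length(shared)))
      genes <- c(shared, rest)
      sc <- stats::runif(length(genes))
      sc[genes %in% shared] <- stats::runif(length(shared), 0.35, 1)
      data.frame(disease_id = sprintf("D%04d", i), gene = genes,
                 gda_score = sc)
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic clinical table (insulin, glucose)
#'
#' Draws per-animal fasting insulin (uU/mL) and glucose (mg/dL) from
#' Normal distributions whose means and SDs are given per group x sex
#' cell, emulating the serum chemistry of neonatal piglets.
#'
#' @param design a [study_design()].
#' @param cell_params data.frame with columns `group`, `sex`,
#'   `insulin_mean`, `insulin_sd`, `glucose_mean`, `glucose_sd`. Defaults
#'   give normoglycemic-mother offspring near insulin 10 uU/mL and
#'   glucose 90 mg/dL, hyperglycemic-mother offspring elevated on both.
#' @param seed integer seed.
#' @return data.frame with `sample`, `group`, `sex`, `insulin`, `glucose`.
#' @export
gen_clinical <- function(design, cell_params = NULL, seed = 1L) {
  d <- bio_design(design)
  if (is.null(cell_params)) {
    cells <- unique(d[, c("group", "sex")])
    hg <- cells$group == levels(d$group)[1]
    cell_params <- data.frame(
      group = cells$group, sex = cells$sex,
      insulin_mean = ifelse(hg, 18, 10), insulin_sd = 3,
      glucose_mean = ifelse(hg, 115, 90), glucose_sd = 12)
  }
  with_seed(seed, {
    key <- paste(d$group, d$sex)
    pk <- paste(cell_params$group, cell_params$sex)
    i <- match(key, pk)
    if (anyNA(i)) stop("`cell_params` missing a design cell", call. = FALSE)
    ins <- stats::rnorm(nrow(d), cell_params$insulin_mean[i],
                        cell_params$insulin_sd[i])
    glu <- stats::rnorm(nrow(d), cell_params$glucose_mean[i],
                        cell_params$glucose_sd[i])
    data.frame(sample = d$sample, group = as.character(d$group),
               sex = as.character(d$sex),
               insulin = pmax(ins, 0.5), glucose = pmax(glu, 20))
  })
}
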