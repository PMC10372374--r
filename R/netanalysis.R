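#' Load a STRING-style protein-links table as an undirected graph
#'
#' Accepts a data.frame or TSV path with columns `protein1`, `protein2`,
#' `combined_score`. Scores on the STRING 0-1000 integer dialect (any
#' score above 1) are divided by 1000. Edges are kept when the score
#' strictly exceeds `score_min`; self-loops are dropped and duplicate
#' edges collapsed keeping the highest score.
#'
#' @param edges data.frame or path to a tab-separated edge list.
#' @param score_min confidence cutoff, strict `>` (0.7 for the
#'   high-confidence variant; 0 keeps the full network).
#' @return igraph object with edge attribute `combined_score`; node and
#'   edge counts are attached as attributes.
#' @export
load_graph <- function(edges, score_min = 0.7) {
  if (is.character(edges)) {
    edges <- utils::read.delim(edges, stringsAsFactors = FALSE)
  }
  req <- c("protein1", "protein2", "combined_score")
  if (!all(req %in% names(edges)))
    stop_schema(paste("edge table needs columns:",
                      paste(req, collapse = ", ")))
  bad <- which(is.na(edges$protein1) | is.na(edges$protein2) |
                 !is.finite(edges$combined_score))
  if (length(bad))
    stop_schema(paste("malformed edge rows at lines:",
                      paste(utils::head(bad, 10), collapse = ", ")))
  sc <- edges$combined_score
  if (any(sc > 1)) sc <- sc / 1000
  keep <- sc > score_min & edges$protein1 != edges$protein2
  df <- data.frame(from = edges$protein1[keep], to = edges$protein2[keep],
                   combined_score = sc[keep])
  # collapse duplicates (either direction), keep max score
  key <- ifelse(df$from < df$to, paste(df$from, df$to),
                paste(df$to, df$from))
  o <- order(key, -df$combined_score)
  df <- df[o[!duplicated(key[o])], , drop = FALSE]
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  attr(g, "n_nodes") <- igraph::vcount(g)
  attr(g, "n_edges") <- igraph::ecount(g)
  g
}

#' Map a gene list onto the graph's node set
#'
#' Case-insensitive symbol matching; reports the mapped subset, the
#' unmapped symbols and the coverage fraction.
#'
#' @param genes character vector of gene symbols.
#' @param g PPI graph.
#' @param direction optional label (`"up"`, `"down"`, `"all"`) carried
#'   through for bookkeeping.
#' @return list of class `seed_set`: `mapped` (graph-cased symbols),
#'   `unmapped`, `coverage`, `direction`.
#' @export
map_seeds <- function(genes, g, direction = "all") {
  vn <- igraph::V(g)$name
  i <- match(toupper(genes), toupper(vn))
  structure(list(mapped = vn[i[!is.na(i)]],
                 unmapped = genes[is.na(i)],
                 coverage = mean(!is.na(i)),
                 direction = direction),
            class = "seed_set")
}

lcc_size <- function(g, nodes) {
  if (length(nodes) == 0) return(0L)
  sub <- igraph::induced_subgraph(g, nodes)
  as.integer(max(igraph::components(sub)$csize))
}

#' Largest-connected-component significance of a gene set
#'
#' Measures how clustered a gene set is on the interactome: the observed
#' statistic is the size of the largest connected component of the
#' subgraph induced by the mapped genes, compared with the same
#' statistic for `n_random` uniformly drawn node sets of identical size.
#' Reports the z-score, the add-one empirical p-value and (since
#' empirical counts cannot resolve extreme significance) a normal-tail
#' p-value from the null mean and SD.
#'
#' @param seeds a `seed_set` from [map_seeds()] or a character vector of
#'   node names.
#' @param g PPI graph.
#' @param n_random number of random sets (default 10000).
#' @param seed integer seed.
#' @param null_sets optional list of pre-drawn node sets replacing the
#'   internal uniform sampling (e.g. to share one random stream with an
#'   independent oracle).
#' @return list of class `lcc_result`: `observed`, `null_mean`,
#'   `null_sd`, `z`, `p_empirical`, `p_normal`, `null`, `n_random`,
#'   `seed`.
#' @export
lcc_zscore <- function(seeds, g, n_random = 10000L, seed = 1L,
                       null_sets = NULL) {
  nodes <- if (inherits(seeds, "seed_set")) seeds$mapped else seeds
  if (length(nodes) < 2L)
    stop("need at least 2 mapped seeds", call. = FALSE)
  obs <- lcc_size(g, nodes)
  vn <- igraph::V(g)$name
  if (!is.null(null_sets)) n_random <- length(null_sets)
  with_seed(seed, {
    null <- if (is.null(null_sets))
      vapply(seq_len(n_random), function(i)
        lcc_size(g, sample(vn, length(nodes))), 0L)
    else vapply(null_sets, function(s) lcc_size(g, s), 0L)
    mu <- mean(null); sdv <- stats::sd(null)
    z <- if (sdv > 0) (obs - mu) / sdv else NA_real_
    structure(list(observed = obs, null_mean = mu, null_sd = sdv, z = z,
                   p_empirical = (1 + sum(null >= obs)) / (1 + n_random),
                   p_normal = if (!is.na(z))
                     stats::pnorm(z, lower.tail = FALSE) else NA_real_,
                   null = null, n_random = n_random, seed = seed),
              class = "lcc_result")
  })
}

#' Extract connected cores of a seed set with per-core significance
#'
#' Decomposes the seed-induced subgraph into connected components of at
#' least `min_size` nodes and scores each against random node sets of
#' its own size (the LCC null), reporting empirical and normal-tail
#' p-values.
#'
#' @inheritParams lcc_zscore
#' @param min_size minimum component size to report (default 2).
#' @return list of cores, each with `nodes`, `size`, `z`, `p_empirical`,
#'   `p_normal`; ordered by decreasing size.
#' @export
extract_cores <- function(seeds, g, min_size = 2L, n_random = 1000L,
                          seed = 1L) {
  nodes <- if (inherits(seeds, "seed_set")) seeds$mapped else seeds
  sub <- igraph::induced_subgraph(g, nodes)
  comp <- igraph::components(sub)
  ids <- which(comp$csize >= min_size)
  ids <- ids[order(-comp$csize[ids])]
  lapply(seq_along(ids), function(k) {
    members <- igraph::V(sub)$name[comp$membership == ids[k]]
    res <- lcc_zscore(members, g, n_random = n_random,
                      seed = derive_seed(seed, paste0("core", k)))
    list(nodes = members, size = length(members), z = res$z,
         p_empirical = res$p_empirical, p_normal = res$p_normal)
  })
}

#' Random walk with restart over a PPI graph
#'
#' Iterates `p <- alpha * p0 + (1 - alpha) * W p` with `W` the
#' column-normalized adjacency matrix and `p0` uniform over the seeds,
#' until the L1 change drops below `tol`. A high restart probability
#' (`alpha` 0.9 by convention here) keeps the propagation close to the
#' seeds. Columns of isolated nodes redistribute their mass to the
#' restart distribution so scores always sum to 1.
#'
#' @param g PPI graph.
#' @param seeds character vector of seed node names (or `seed_set`).
#' @param alpha restart probability in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return named numeric vector of stationary visiting probabilities
#'   (sums to 1), with an `"iterations"` attribute.
#' @export
rwr <- function(g, seeds, alpha = 0.9, tol = 1e-8, max_iter = 1000L) {
  nodes <- if (inherits(seeds, "seed_set")) seeds$mapped else seeds
  vn <- igraph::V(g)$name
  if (length(nodes) == 0L) stop("empty seed set", call. = FALSE)
  if (!all(nodes %in% vn)) stop("seeds not in graph", call. = FALSE)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- Matrix::colSums(A)
  p0 <- stats::setNames(rep(0, length(vn)), vn)
  p0[nodes] <- 1 / length(nodes)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  p <- p0
  it <- 0L
  repeat {
    it <- it + 1L
    walk <- as.numeric(A %*% (p * inv_deg))
    dangling <- sum(p[deg == 0])
    p_new <- alpha * p0 + (1 - alpha) * (walk + dangling * p0)
    if (sum(abs(p_new - p)) < tol || it >= max_iter) { p <- p_new; break }
    p <- p_new
  }
  out <- stats::setNames(as.numeric(p), vn)
  attr(out, "iterations") <- it
  out
}

seed_connectivity <- function(g, seeds, added) {
  sub <- igraph::induced_subgraph(g, c(seeds, added))
  comp <- igraph::components(sub)
  big <- which.max(comp$csize)
  in_lcc <- igraph::V(sub)$name[comp$membership == big]
  mean(seeds %in% in_lcc)
}

#' Expand a seed set by random-walk ranking until the seeds connect
#'
#' Ranks non-seed nodes by their [rwr()] score and adds them greedily
#' (ties broken by higher degree, then lexicographic name); after every
#' addition the fraction of seeds inside the largest connected component
#' of the induced subgraph is recomputed, and expansion stops when that
#' fraction reaches `target_coverage` (90% by convention) or the
#' additions cap is hit.
#'
#' @inheritParams rwr
#' @param target_coverage required fraction of seeds in one component.
#' @param max_additions cap on added nodes (flagged when reached).
#' @return list of class `expansion_result`: `expanded` (seeds plus
#'   additions), `added`, `scores`, `seed_connectivity`, `reached`,
#'   `alpha`.
#' @export
rwr_expand <- function(g, seeds, alpha = 0.9, target_coverage = 0.9,
                       max_additions = 500L) {
  nodes <- if (inherits(seeds, "seed_set")) seeds$mapped else seeds
  frac <- seed_connectivity(g, nodes, character(0))
  added <- character(0)
  if (frac < target_coverage) {
    sc <- rwr(g, nodes, alpha = alpha)
    cand <- setdiff(names(sc), nodes)
    deg <- igraph::degree(g, cand)
    ord <- cand[order(-sc[cand], -deg, cand)]
    for (v in ord) {
      added <- c(added, v)
      frac <- seed_connectivity(g, nodes, added)
      if (frac >= target_coverage || length(added) >= max_additions) break
    }
  } else sc <- NULL
  structure(list(expanded = c(nodes, added), added = added, scores = sc,
                 seed_connectivity = frac,
                 reached = frac >= target_coverage, alpha = alpha),
            class = "expansion_result")
}

#' Jaccard index of two sets
#'
#' @param s1,s2 vectors treated as sets.
#' @return `|s1 intersect s2| / |s1 union s2|`; 0 when both are empty.
#' @export
jaccard <- function(s1, s2) {
  u <- length(union(s1, s2))
  if (u == 0) return(0)
  length(intersect(s1, s2)) / u
}

# Logarithmic degree bins merged upward until each holds >= min_bin nodes.
degree_bins <- function(g, min_bin = 100L) {
  deg <- igraph::degree(g)
  b <- floor(log2(pmax(deg, 1)))
  lev <- sort(unique(b))
  # merge sparse bins upward (into the next-lower-degree bin at the top)
  repeat {
    cnt <- table(factor(b, levels = lev))
    small <- which(cnt < min_bin)
    if (!length(small) || length(lev) == 1L) break
    i <- small[length(small)]
    j <- if (i == length(lev)) i - 1L else i + 1L
    b[b == lev[i]] <- lev[j]
    lev <- lev[-i]
  }
  split(igraph::V(g)$name, b)
}

sample_degree_matched <- function(set, bins, bin_of) {
  unlist(lapply(split(set, bin_of[set]), function(members) {
    sample(bins[[as.character(bin_of[members[1]])]], length(members))
  }), use.names = FALSE)
}

#' Network proximity of two gene sets with a degree-matched null
#'
#' The closest distance `d_c` is the average over `s1` of the minimum
#' shortest-path length to any node of `s2` (0 when the sets intersect).
#' The null replaces both sets with random sets drawn from logarithmic
#' degree bins (merged until each bin holds at least `min_bin`
#' candidates), preserving each set's size and bin-degree composition,
#' which corrects for the interactome's heavy-tailed degree
#' distribution. Pairs in different components are excluded from the
#' average with a warning (or assigned `unreachable_penalty`).
#'
#' @param s1,s2 character vectors of node names (query set and disease
#'   set); `s1` is the averaged set.
#' @param g PPI graph.
#' @param n_random number of null draws (default 10000).
#' @param seed integer seed.
#' @param min_bin minimum degree-bin occupancy.
#' @param unreachable_penalty distance for disconnected pairs; `NULL`
#'   (default) excludes them.
#' @param dist_matrix optional precomputed `igraph::distances(g)` to
#'   amortize shortest paths over many screens.
#' @param null_sets optional list of `list(s1 =, s2 =)` pre-drawn set
#'   pairs replacing the internal degree-matched sampling.
#' @return list of class `proximity_result`: `d_c`, `null_mean`,
#'   `null_sd`, `z`, `p_empirical` (small distance = proximal), `null`,
#'   `n_random`, `seed`.
#' @export
network_proximity <- function(s1, s2, g, n_random = 10000L, seed = 1L,
                              min_bin = 100L, unreachable_penalty = NULL,
                              dist_matrix = NULL, null_sets = NULL) {
  if (length(s1) == 0L || length(s2) == 0L)
    stop("both sets must be non-empty on the graph", call. = FALSE)
  vn <- igraph::V(g)$name
  if (!all(c(s1, s2) %in% vn))
    stop("all set members must be graph nodes (map first)", call. = FALSE)
  dmat <- dist_matrix %||% igraph::distances(g)
  closest <- function(a, b) {
    d <- apply(dmat[a, b, drop = FALSE], 1, min)
    inf <- !is.finite(d)
    if (any(inf)) {
      if (is.null(unreachable_penalty)) {
        warning(sum(inf), " unreachable pair(s) excluded from d_c")
        d <- d[!inf]
        if (!length(d)) return(NA_real_)
      } else d[inf] <- unreachable_penalty
    }
    mean(d)
  }
  obs <- closest(s1, s2)
  bins <- degree_bins(g, min_bin)
  bin_of <- stats::setNames(rep(names(bins), lengths(bins)),
                            unlist(bins, use.names = FALSE))
  if (!is.null(null_sets)) n_random <- length(null_sets)
  with_seed(seed, {
    # unreachable pairs inside null draws are routine; only the observed
    # statistic warns
    null <- suppressWarnings(if (is.null(null_sets))
      vapply(seq_len(n_random), function(i) {
        r1 <- sample_degree_matched(s1, bins, bin_of)
        r2 <- sample_degree_matched(s2, bins, bin_of)
        closest(r1, r2)
      }, 0)
    else vapply(null_sets, function(p) closest(p$s1, p$s2), 0))
    mu <- mean(null, na.rm = TRUE); sdv <- stats::sd(null, na.rm = TRUE)
    structure(list(d_c = obs, null_mean = mu, null_sd = sdv,
                   z = if (!is.na(sdv) && sdv > 0) (obs - mu) / sdv
                       else NA_real_,
                   p_empirical = (1 + sum(null <= obs, na.rm = TRUE)) /
                     (1 + n_random),
                   null = null, n_random = n_random, seed = seed,
                   min_bin = min_bin),
              class = "proximity_result")
  })
}

#' Screen a disease catalogue against protein cores
#'
#' Filters a gene-disease table at a strict GDA confidence cutoff,
#' collapses duplicate (disease, gene) pairs keeping the highest score,
#' and computes for every disease the Jaccard index with the query set
#' and its network proximity; empirical proximity p-values are BH
#' adjusted across diseases.
#'
#' @param core character vector of query proteins (e.g. a dysregulated
#'   core), already graph nodes.
#' @param catalog data.frame with `disease_id`, `gene`, `gda_score`.
#' @param g PPI graph.
#' @param gda_min GDA cutoff, strict `>` (default 0.3).
#' @param n_random,seed,min_bin passed to [network_proximity()].
#' @return data.frame: one row per screened disease with `n_genes`,
#'   `jaccard`, `d_c`, `z`, `p_empirical`, `padj`.
#' @export
disease_screen <- function(core, catalog, g, gda_min = 0.3,
                           n_random = 1000L, seed = 1L, min_bin = 100L) {
  keep <- catalog$gda_score > gda_min
  cat2 <- catalog[keep, , drop = FALSE]
  key <- paste(cat2$disease_id, cat2$gene)
  o <- order(key, -cat2$gda_score)
  cat2 <- cat2[o[!duplicated(key[o])], , drop = FALSE]
  vn <- igraph::V(g)$name
  dmat <- igraph::distances(g)
  dis <- split(cat2$gene, cat2$disease_id)
  rows <- lapply(seq_along(dis), function(i) {
    genes <- unique(dis[[i]])
    on_g <- intersect(genes, vn)
    jc <- jaccard(core, genes)
    if (length(on_g) == 0L)
      return(data.frame(disease_id = names(dis)[i],
                        n_genes = length(genes), jaccard = jc,
                        d_c = NA_real_, z = NA_real_,
                        p_empirical = NA_real_))
    pr <- network_proximity(core, on_g, g, n_random = n_random,
                            seed = derive_seed(seed, names(dis)[i]),
                            min_bin = min_bin, dist_matrix = dmat)
    data.frame(disease_id = names(dis)[i], n_genes = length(genes),
               jaccard = jc, d_c = pr$d_c, z = pr$z,
               p_empirical = pr$p_empirical)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p_empirical, method = "BH")
  out
}

#' Over-representation analysis against GMT gene sets
#'
#' Hypergeometric upper-tail test P(X >= k) for every gene set, with BH
#' correction across sets and the usual enrichment ratio
#' `(k/|query|) / (K/|universe|)`.
#'
#' @param query character vector of significant genes.
#' @param universe background gene vector.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @return data.frame per set: `set`, `k`, `K`, `n_query`, `enrichment`,
#'   `p`, `padj`.
#' @export
ora <- function(query, universe, gene_sets) {
  query <- intersect(unique(query), universe)
  N <- length(unique(universe))
  nq <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
    enr <- if (nq > 0 && K > 0) (k / nq) / (K / N) else NA_real_
    data.frame(set = nm, k = k, K = K, n_query = nq,
               enrichment = enr, p = p)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}
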