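path_graph <- function() {
  # a - b - c - d plus an isolated pair e - f
  load_graph(data.frame(protein1 = c("a", "b", "c", "e"),
                        protein2 = c("b", "c", "d", "f"),
                        combined_score = 1), score_min = 0)
}

test_that("graph loading handles dialects, duplicates and thresholds", {
  df <- data.frame(protein1 = c("A", "B", "C", "A", "D"),
                   protein2 = c("B", "C", "D", "B", "D"),
                   combined_score = c(900, 700, 500, 850, 800))
  g <- load_graph(df, score_min = 0.7)    # 0-1000 dialect, strict >
  # A-B kept (max of duplicate 0.9/0.85), B-C = 0.7 dropped (strict),
  # C-D dropped, D-D self-loop dropped
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(as.vector(igraph::ends(g, 1)), c("A", "B"))
  expect_equal(igraph::E(g)$combined_score, 0.9)

  df2 <- data.frame(protein1 = c("x", "y", "z"),
                    protein2 = c("y", "z", "x"),
                    combined_score = c(0.9, 0.7, 0.5))
  expect_equal(igraph::ecount(load_graph(df2, score_min = 0.7)), 1)
  expect_error(load_graph(data.frame(protein1 = "a", protein2 = NA,
                                     combined_score = 1)), "malformed")
})

test_that("seed mapping is case-insensitive with correct coverage", {
  g <- path_graph()
  s <- map_seeds(c("A", "b", "zz"), g)
  expect_setequal(s$mapped, c("a", "b"))
  expect_equal(s$unmapped, "zz")
  expect_equal(s$coverage, 2 / 3)
  expect_equal(map_seeds(c("q", "r"), g)$coverage, 0)
  expect_equal(map_seeds(c("a", "b", "c"), g)$coverage, 1)
})

test_that("LCC statistic counts induced components correctly", {
  g <- path_graph()
  expect_equal(lcc_zscore(c("a", "b"), g, n_random = 50,
                          seed = 1)$observed, 2L)
  expect_equal(lcc_zscore(c("a", "c"), g, n_random = 50,
                          seed = 1)$observed, 1L)
  r <- lcc_zscore(c("a", "b"), g, n_random = 100, seed = 3)
  r2 <- lcc_zscore(c("a", "b"), g, n_random = 100, seed = 3)
  expect_identical(r$null, r2$null)     # seeded reproducibility
  expect_gte(r$p_empirical, 1 / 101); expect_lte(r$p_empirical, 1)
})

test_that("LCC null matches a union-find oracle on shared random sets", {
  net <- gen_ppi(40, 2, list(), seed = 9)
  g <- net$graph
  edges <- igraph::as_data_frame(g)
  vn <- igraph::V(g)$name
  set.seed(77)
  sets <- replicate(60, sample(vn, 6), simplify = FALSE)
  res <- lcc_zscore(sample(vn, 6), g, null_sets = sets, seed = 1)
  oracle <- vapply(sets, function(s) lcc_size_oracle(edges, s), 0)
  expect_equal(res$null, as.integer(oracle))
  expect_equal(res$null_mean, mean(oracle))
})

test_that("core extraction returns each component with its own null", {
  # two planted cliques joined to a sparse background
  el <- rbind(t(utils::combn(paste0("u", 1:5), 2)),
              t(utils::combn(paste0("v", 1:4), 2)),
              cbind(paste0("u", 1:5), paste0("w", 1:5)),
              cbind(paste0("v", 1:4), paste0("x", 1:4)),
              cbind(paste0("w", 1:5), paste0("x", c(2:5, 1))))
  g <- load_graph(data.frame(protein1 = el[, 1], protein2 = el[, 2],
                             combined_score = 1), score_min = 0)
  seeds <- c(paste0("u", 1:5), paste0("v", 1:4), "zz_absent")
  cores <- extract_cores(map_seeds(seeds, g), g, n_random = 100, seed = 2)
  expect_equal(vapply(cores, `[[`, 0L, "size"), c(5L, 4L))
  expect_setequal(cores[[1]]$nodes, paste0("u", 1:5))
  # isolated seeds produce no cores
  none <- extract_cores(c("u1", "v1"), g, n_random = 50, seed = 1)
  expect_length(none, 0)
})

test_that("random walk with restart matches closed forms", {
  g2 <- load_graph(data.frame(protein1 = "a", protein2 = "b",
                              combined_score = 1), score_min = 0)
  p <- rwr(g2, "a", alpha = 0.9)
  expect_equal(unname(p["a"]), 10 / 11, tolerance = 1e-7)
  expect_equal(unname(p["b"]), 1 / 11, tolerance = 1e-7)
  expect_equal(sum(p), 1, tolerance = 1e-10)
  # pure restart returns the seed distribution
  g <- path_graph()
  p1 <- rwr(g, c("a", "c"), alpha = 1)
  expect_equal(unname(p1[c("a", "c")]), c(0.5, 0.5))
  expect_equal(sum(p1), 1)
  # symmetric graph + symmetric seeds -> symmetric scores
  tri <- load_graph(data.frame(protein1 = c("a", "b", "c"),
                               protein2 = c("b", "c", "a"),
                               combined_score = 1), score_min = 0)
  ps <- rwr(tri, c("a", "b"), alpha = 0.7)
  expect_equal(unname(ps["a"]), unname(ps["b"]), tolerance = 1e-9)
  expect_error(rwr(g, character(0)), "empty")
})

test_that("RWR expansion connects seeds through forced topology", {
  # star: hub h with leaves l1..l5; seeds = two leaves
  star <- load_graph(data.frame(protein1 = "h",
                                protein2 = paste0("l", 1:5),
                                combined_score = 1), score_min = 0)
  ex <- rwr_expand(star, c("l1", "l2"))
  expect_equal(ex$added, "h")
  expect_equal(ex$seed_connectivity, 1)
  expect_true(ex$reached)
  # already-connected seeds need no additions
  g <- path_graph()
  ex2 <- rwr_expand(g, c("a", "b"))
  expect_length(ex2$added, 0)
  # articulation node: module split by a removed hub is restored first
  el <- rbind(cbind("hub", paste0("m", 1:6)),
              t(utils::combn(paste0("m", 1:3), 2)),
              t(utils::combn(paste0("m", 4:6), 2)),
              cbind(paste0("bg", 1:4), paste0("bg", c(2, 3, 4, 1))),
              c("bg1", "hub"))
  ga <- load_graph(data.frame(protein1 = el[, 1], protein2 = el[, 2],
                              combined_score = 1), score_min = 0)
  ex3 <- rwr_expand(ga, paste0("m", 1:6), target_coverage = 0.9)
  expect_equal(ex3$added[1], "hub")
  expect_equal(ex3$seed_connectivity, 1)
})

test_that("jaccard index follows set arithmetic", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(character(0), character(0)), 0)
})

test_that("network proximity matches BFS oracle and degree-matched null", {
  g <- path_graph()
  expect_equal(network_proximity(c("a", "b"), c("a", "b", "c"), g,
                                 n_random = 20, seed = 1,
                                 min_bin = 2)$d_c, 0)
  expect_equal(network_proximity("a", "c", g, n_random = 20, seed = 1,
                                 min_bin = 2)$d_c, 2)

  net <- gen_ppi(50, 2, list(), seed = 13)
  gg <- net$graph
  edges <- igraph::as_data_frame(gg)
  vn <- igraph::V(gg)$name
  dor <- bfs_distances(edges, vn)
  set.seed(55)
  s1 <- sample(vn, 5); s2 <- sample(setdiff(vn, s1), 7)
  pairs <- replicate(50, list(s1 = sample(vn, 5), s2 = sample(vn, 7)),
                     simplify = FALSE)
  res <- network_proximity(s1, s2, gg, null_sets = pairs, seed = 1,
                           min_bin = 10)
  d_oracle <- function(a, b) mean(apply(dor[a, b, drop = FALSE], 1, min))
  expect_equal(res$d_c, d_oracle(s1, s2), tolerance = 1e-12)
  expect_equal(res$null,
               vapply(pairs, function(p) d_oracle(p$s1, p$s2), 0),
               tolerance = 1e-12)

  # degree-matched sampling preserves size and bin-degree composition
  bins <- perinatomics:::degree_bins(gg, min_bin = 10)
  bin_of <- stats::setNames(rep(names(bins), lengths(bins)),
                            unlist(bins, use.names = FALSE))
  set.seed(2)
  r1 <- perinatomics:::sample_degree_matched(s1, bins, bin_of)
  expect_length(r1, length(s1))
  expect_equal(table(bin_of[r1]), table(bin_of[s1]))

  # adding to s2 a node adjacent to s1 cannot increase d_c
  nb <- igraph::neighbors(gg, s1[1])$name[1]
  res2 <- network_proximity(s1, c(s2, nb), gg, n_random = 10, seed = 1,
                            min_bin = 10)
  expect_lte(res2$d_c, res$d_c)
})

test_that("unreachable pairs are excluded with a warning or penalized", {
  g <- path_graph()    # e-f disconnected from a-b-c-d
  expect_warning(
    res <- network_proximity(c("a", "e"), "c", g, n_random = 10,
                             seed = 1, min_bin = 2),
    "unreachable")
  expect_equal(res$d_c, 2)       # only a->c contributes
  res2 <- suppressWarnings(
    network_proximity(c("a", "e"), "c", g, n_random = 10, seed = 1,
                      min_bin = 2, unreachable_penalty = 10))
  expect_equal(res2$d_c, 6)      # (2 + 10) / 2
})

test_that("disease screening filters strictly and finds planted overlap", {
  cat <- data.frame(disease_id = c("d1", "d2", "d3"),
                    gene = c("g1", "g2", "g3"),
                    gda_score = c(0.2, 0.3, 0.31))
  keep <- cat[cat$gda_score > 0.3, ]
  expect_equal(keep$disease_id, "d3")     # strict boundary

  net <- gen_ppi(300, 2, list(list(size = 8, p_internal = 1)), seed = 6)
  g <- net$graph
  module <- net$truth$node[!is.na(net$truth$module)]
  catalog <- gen_disease_catalog(
    10, igraph::V(g)$name, overlap = list("1" = module[1:4]),
    module_genes = module, seed = 8)
  scr <- disease_screen(module, catalog, g, n_random = 100, seed = 3,
                        min_bin = 30)
  expect_equal(nrow(scr), 10)
  best <- scr$disease_id[which.min(scr$padj)]
  expect_equal(best, "D0001")
  expect_gt(scr$jaccard[scr$disease_id == "D0001"], 0)
  expect_true(all(scr$padj >= scr$p_empirical, na.rm = TRUE))
  # identical disease: jaccard 1 and d_c 0
  cat2 <- data.frame(disease_id = "same", gene = module, gda_score = 0.9)
  scr2 <- disease_screen(module, cat2, g, n_random = 20, seed = 1,
                         min_bin = 30)
  expect_equal(scr2$jaccard, 1)
  expect_equal(scr2$d_c, 0)
})

test_that("ORA equals exhaustive hypergeometric enumeration", {
  universe <- paste0("g", 1:20)
  set5 <- paste0("g", 1:5)
  query <- c("g1", "g2", "g3", "g10", "g11")   # k = 3
  res <- ora(query, universe, list(S = set5))
  draws <- utils::combn(20, 5)
  overlap <- colSums(draws <= 5)
  expect_equal(res$p, mean(overlap >= 3), tolerance = 1e-12)
  expect_equal(res$enrichment, (3 / 5) / (5 / 20))
  # disjoint query: k = 0 and p = 1 under the upper tail
  res0 <- ora(paste0("g", 11:14), universe, list(S = set5))
  expect_equal(res0$p, 1)
  # query = set = universe
  res1 <- ora(universe, universe, list(S = universe))
  expect_equal(res1$p, 1)
  expect_equal(res1$enrichment, 1)
})
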