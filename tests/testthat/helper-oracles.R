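# Independent oracles used across the suite. Each is deliberately
# written with a different algorithm than the implementation it checks.

# All-pairs shortest paths by plain BFS on an adjacency list.
bfs_distances <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v])))
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# LCC size of a node set by union-find over the induced edges.
lcc_size_oracle <- function(edges, set) {
  parent <- stats::setNames(seq_along(set), set)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- edges$from %in% set & edges$to %in% set
  for (e in which(keep)) {
    a <- find(match(edges$from[e], set))
    b <- find(match(edges$to[e], set))
    if (a != b) parent[a] <- b
  }
  if (!length(set)) return(0L)
  max(table(vapply(seq_along(set), find, 0L)))
}

# Exhaustive Ward agglomeration: merge the cluster pair with the
# smallest increase in within-cluster sum of squares; report heights on
# the ward.D2 scale, sqrt(2 * delta ESS).
ward_oracle_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      a <- x[clusters[[i]], , drop = FALSE]
      b <- x[clusters[[j]], , drop = FALSE]
      dess <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) *
        sum((colMeans(a) - colMeans(b))^2)
      if (dess < best[1]) best <- c(dess, i, j)
    }
    heights <- c(heights, sqrt(2 * best[1]))
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# One-component NIPALS PLS1: returns the predictive weight vector and
# scores for centered X, y.
pls1_oracle <- function(X, y) {
  w <- crossprod(X, y)
  w <- w / sqrt(sum(w^2))
  t_ <- X %*% w
  list(w = as.numeric(w), t = as.numeric(t_))
}

# Toy long-format precursor table used by the proteomics tests.
toy_precursors <- function() {
  base <- expand.grid(peptide = c("PEPA", "PEPB"), charge = 2:3,
                      run = c("s1", "s2"), stringsAsFactors = FALSE)
  data.frame(precursor_id = paste0(base$peptide, base$charge),
             peptide = base$peptide, charge = base$charge,
             protein = "P1", run = base$run,
             intensity = 100, q_value = 0, run_q_value = 0,
             pg_q_value = 0, proteotypic = TRUE, contaminant = FALSE)
}

# Peptide matrix wrapper matching aggregate_peptides() output.
pep_input <- function(m, proteins) {
  rownames(m) <- paste(proteins, seq_len(nrow(m)), sep = "|")
  list(matrix = m,
       peptides = data.frame(protein = proteins,
                             peptide = paste0("pep", seq_len(nrow(m)))))
}

tiny_design <- function(n = 3L, n_pool = 0L, n_blank = 0L)
  study_design(c(PHG.F = n, PHG.M = n, PNG.F = n, PNG.M = n),
               n_pool = n_pool, n_blank = n_blank)
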