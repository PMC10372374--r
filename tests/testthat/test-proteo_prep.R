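test_that("precursor filtering enforces each criterion and is idempotent", {
  t <- toy_precursors()
  expect_identical(nrow(filter_precursors(t)), nrow(t))  # all clean

  t10 <- toy_precursors()[rep(1, 10), ]
  t10$precursor_id <- paste0("p", 1:10)
  t10$run_q_value[2] <- 0.02      # run-specific q violation
  t10$contaminant[5] <- TRUE
  t10$proteotypic[8] <- FALSE
  out <- filter_precursors(t10)
  expect_equal(nrow(out), 7)
  expect_equal(unname(attr(out, "removals")[c("run_q_value",
                                              "contaminant",
                                              "proteotypic")]),
               c(1L, 1L, 1L))
  expect_identical(nrow(filter_precursors(out)), nrow(out))  # idempotent

  expect_error(filter_precursors(t10[, -3]), "lacks columns")
  expect_error(filter_precursors(t10, min_quality = 2), "quality")
})

test_that("charge-state aggregation sums observed and keeps absence", {
  t <- toy_precursors()          # 2 peptides x 2 charges x 2 runs, all 100
  t$intensity[t$peptide == "PEPA" & t$charge == 2 & t$run == "s1"] <- 100
  t$intensity[t$peptide == "PEPA" & t$charge == 3 & t$run == "s1"] <- 50
  t$intensity[t$peptide == "PEPB" & t$run == "s1"] <- NA  # both missing
  agg <- aggregate_peptides(t)
  expect_equal(agg$matrix["P1|PEPA", "s1"], 150)
  expect_true(is.na(agg$matrix["P1|PEPB", "s1"]))     # absence, not zero
  expect_equal(agg$matrix["P1|PEPB", "s2"], 200)
  # three charges sum
  t3 <- toy_precursors()[1:3, ]
  t3$charge <- 2:4; t3$run <- "s1"; t3$peptide <- "PEPA"
  t3$intensity <- c(10, 20, 30)
  expect_equal(unname(aggregate_peptides(t3)$matrix[1, 1]), 60)
})

test_that("maxlfq reproduces exact ratios and the least-squares anchor", {
  # single peptide: profile is the peptide itself
  one <- pep_input(matrix(c(10, 20), 1), "P1")
  pm <- maxlfq(one)
  prof <- pm$matrix["P1", ]
  expect_equal(unname(prof[2] / prof[1]), 2)

  # consistent pair of peptides: ratio preserved, level anchored at the
  # closed-form solution (mean log2 abundance = mean log2 peptide sum)
  two <- pep_input(rbind(c(10, 20), c(30, 60)), c("P1", "P1"))
  pm2 <- maxlfq(two)
  a <- log2(pm2$matrix["P1", ])
  expect_equal(unname(a[2] - a[1]), 1)
  expect_equal(mean(a), mean(log2(c(40, 80))))

  # inconsistent ratios: median over {2, 1} is the geometric midpoint
  inc <- pep_input(rbind(c(10, 20), c(30, 30)), c("P1", "P1"))
  pm3 <- maxlfq(inc)
  r <- pm3$matrix["P1", 2] / pm3$matrix["P1", 1]
  expect_equal(unname(r), sqrt(2))
})

test_that("maxlfq is scale-equivariant and leaves unpaired samples missing", {
  set.seed(5)
  m <- matrix(2^stats::rnorm(12, 20), 3, 4)
  inp <- pep_input(m, rep("P1", 3))
  base <- log2(maxlfq(inp)$matrix[1, ])
  m2 <- m; m2[, 2] <- m2[, 2] * 8
  shifted <- log2(maxlfq(pep_input(m2, rep("P1", 3)))$matrix[1, ])
  delta <- shifted - base
  expect_equal(unname(delta[2]) - mean(delta[-2]), 3, tolerance = 1e-9)

  # a sample observing no shared peptide stays missing
  m3 <- rbind(c(10, 20, NA), c(5, 10, NA), c(NA, NA, 7))
  pm <- maxlfq(pep_input(m3, rep("P1", 3)))
  expect_true(is.na(pm$matrix[1, 3]))
  expect_false(anyNA(pm$matrix[1, 1:2]))
})

test_that("detection filter applies an inclusive boundary over all samples", {
  mk <- function(n_obs) {
    m <- matrix(NA_real_, 1, 19, dimnames = list("P", paste0("s", 1:19)))
    m[1, seq_len(n_obs)] <- 100
    structure(list(matrix = m, n_peptides = c(P = 1L),
                   detection_rate = n_obs / 19),
              class = "protein_matrix")
  }
  expect_equal(nrow(detection_filter(mk(12))$matrix), 1)   # 12/19 = 63%
  expect_equal(nrow(detection_filter(mk(11))$matrix), 0)   # 11/19 = 58%
  expect_equal(nrow(detection_filter(mk(1), min_rate = 0)$matrix), 1)
})

test_that("iterative imputation fills predictably and beats mean imputation", {
  m0 <- matrix(2^stats::rnorm(20, 20), 4, 5)
  rownames(m0) <- paste0("P", 1:4); colnames(m0) <- paste0("s", 1:5)
  pm0 <- structure(list(matrix = m0, n_peptides = NULL,
                        detection_rate = rep(1, 4)),
                   class = "protein_matrix")
  expect_identical(impute_iterative(pm0, seed = 1), pm0)  # no missing

  # duplicate-profile neighbour: the hole is recovered almost exactly
  base <- 2^seq(18, 22, length.out = 6)
  m <- rbind(P1 = base, P2 = base * 1.001, P3 = rev(base), P4 = base^0.99)
  colnames(m) <- paste0("s", 1:6)
  truth <- m["P1", 3]
  m["P1", 3] <- NA
  pm <- structure(list(matrix = m, n_peptides = NULL,
                       detection_rate = rowMeans(!is.na(m))),
                  class = "protein_matrix")
  got <- impute_iterative(pm, seed = 1)$matrix["P1", 3]
  expect_equal(log2(got), log2(truth), tolerance = 1e-3)
  # observed cells never altered
  expect_identical(impute_iterative(pm, seed = 1)$matrix[!is.na(m)],
                   m[!is.na(m)])

  # planted missingness: regression imputation beats row-mean imputation
  d <- study_design()
  wins <- 0L
  for (s in 1:10) {
    om <- gen_omics_matrix(d, effect_spec(n_features = 30,
                                          frac_group_affected = 0.3,
                                          fold_change_range = c(3, 4)),
                           seed = s)
    x <- log2(om$matrix)
    set.seed(1000 + s)
    holes <- cbind(sample(nrow(x), 25, replace = TRUE),
                   sample(ncol(x), 25, replace = TRUE))
    holes <- holes[!duplicated(holes), , drop = FALSE]
    truth <- x[holes]
    xm <- x; xm[holes] <- NA
    keep <- rowSums(!is.na(xm)) > 0
    pm <- structure(list(matrix = 2^xm, n_peptides = NULL,
                         detection_rate = rowMeans(!is.na(xm))),
                    class = "protein_matrix")
    imp <- log2(impute_iterative(pm, seed = s)$matrix)[holes]
    mean_imp <- rowMeans(xm, na.rm = TRUE)[holes[, 1]]
    rmse <- function(a) sqrt(mean((a - truth)^2))
    wins <- wins + (rmse(imp) < rmse(mean_imp))
  }
  expect_gte(wins, 8)
})

test_that("precursor reports round-trip through the dialect reader", {
  t <- toy_precursors()
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  t2 <- t
  names(t2)[names(t2) == "q_value"] <- "Q.Value"
  names(t2)[names(t2) == "run"] <- "Run"
  utils::write.table(t2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_precursors_tsv(f, col_map = c(q_value = "Q.Value",
                                            run = "Run"))
  expect_equal(got$q_value, t$q_value)
  expect_setequal(names(t), intersect(names(got), names(t)))
  expect_error(read_precursors_tsv(f), "lacks columns")
  expect_error(read_precursors_tsv(f, col_map = c(q_value = "nope")),
               "not found")
})

test_that("the full proteomics chain runs in the fixed order", {
  # build a small synthetic precursor report: 6 proteins x 2 peptides
  # x 2 charges over 8 runs
  set.seed(7)
  runs <- paste0("s", 1:8)
  rows <- list()
  for (p in 1:6) for (pep in 1:2) {
    lev <- stats::rnorm(1, 20, 1)
    for (ch in 2:3) {
      frac <- stats::runif(1, 0.2, 0.6)
      int <- 2^(lev + stats::rnorm(8, 0, 0.2)) * frac
      if (p == 6) int[1:6] <- NA     # protein 6 under-detected
      rows[[length(rows) + 1L]] <- data.frame(
        precursor_id = sprintf("P%d_%d_%d", p, pep, ch),
        peptide = sprintf("PEP%d_%d", p, pep), charge = ch,
        protein = paste0("PROT", p), run = runs, intensity = int,
        q_value = 0.001, run_q_value = 0.001, pg_q_value = 0.001,
        proteotypic = TRUE, contaminant = FALSE)
    }
  }
  t <- do.call(rbind, rows)
  out <- run_proteo_prep(t, min_rate = 0.6, seed = 3)
  expect_false(anyNA(out$matrix))
  expect_false("PROT6" %in% rownames(out$matrix))  # 2/8 detection dropped
  expect_equal(nrow(out$matrix), 5)
})
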