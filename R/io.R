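#' Read / write feature-by-sample abundance matrices as TSV
#'
#' The on-disk convention used throughout: features in rows, first
#' column `feature_id`, one column per sample.
#'
#' @param path file path.
#' @return numeric matrix with feature row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]]))
    stop_schema("duplicate feature IDs in matrix file")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param m matrix to write.
#' @param id_name header for the feature-ID column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a study design table
#'
#' @param path TSV with columns `sample`, `group`, `sex`, `role`.
#' @return a `study_design` data.frame.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "group", "sex", "role")
  if (!all(req %in% names(df)))
    stop_schema(paste("design file needs columns:",
                      paste(req, collapse = ", ")))
  df$group[df$group == ""] <- NA
  df$sex[df$sex == ""] <- NA
  class(df) <- c("study_design", "data.frame")
  df
}

#' @rdname read_design_tsv
#' @param design design table to write.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a precursor-level quantification report
#'
#' Long-format TSV, one row per precursor x run. Column names vary
#' between report dialects, so a name mapping from canonical names to
#' the file's headers can be supplied; unmapped optional columns
#' (`quality`) are simply absent.
#'
#' @param path TSV path.
#' @param col_map named character vector mapping canonical column names
#'   (`precursor_id`, `peptide`, `charge`, `protein`, `run`,
#'   `intensity`, `q_value`, `run_q_value`, `pg_q_value`,
#'   `proteotypic`, `contaminant`, optionally `quality`) to the file's
#'   headers; defaults to the identity mapping.
#' @return data.frame in the canonical layout expected by
#'   [filter_precursors()].
#' @export
read_precursors_tsv <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("precursor_id", "peptide", "charge", "protein", "run",
           "intensity", "q_value", "run_q_value", "pg_q_value",
           "proteotypic", "contaminant")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df))
        stop_schema(paste0("mapped column '", col_map[[canon]],
                           "' not found in file"))
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_schema(paste("precursor file lacks columns:",
                      paste(miss, collapse = ", ")))
  df$proteotypic <- as.logical(df$proteotypic)
  df$contaminant <- as.logical(df$contaminant)
  df
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member
#' genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop_schema(paste("GMT lines with fewer than 3 fields:",
                      paste(utils::head(bad, 5), collapse = ", ")))
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, "", 1))
}

#' @rdname read_gmt
#' @param sets named list of gene vectors to write.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Write an edge list / disease catalogue as TSV
#'
#' @param g igraph object with `combined_score` edge attribute.
#' @param path output path.
#' @export
write_edges_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(protein1 = el[, 1], protein2 = el[, 2],
                   combined_score = igraph::E(g)$combined_score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
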