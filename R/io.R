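#' Read a miRNA-disease association table
#'
#' Parses a two-column text file of known miRNA-disease association pairs.
#' Fields are separated by tabs or commas (auto-detected from the first data
#' line), lines starting with `#` are comments, and exact duplicate pairs are
#' dropped with a message reporting how many were removed.
#'
#' @param path Path to the association file. Each non-comment line must have
#'   at least two fields: miRNA id, disease id.
#' @return A tibble with columns `mirna` and `disease`, one row per unique
#'   pair, in order of first appearance.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("mir-1\tcolon", "mir-1\tcolon", "mir-2\tcolon"), f)
#' read_association_table(f)
#' @export
read_association_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    stop("association file is empty: ", path, call. = FALSE)
  }
  sep <- detect_separator(lines[[1]])
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1]
    stop("malformed association line ", lineno[bad], " (fewer than 2 fields): ",
         lines[bad], call. = FALSE)
  }
  tab <- tibble::tibble(
    mirna = trimws(vapply(fields, `[[`, "", 1L)),
    disease = trimws(vapply(fields, `[[`, "", 2L))
  )
  if (any(!nzchar(tab$mirna)) || any(!nzchar(tab$disease))) {
    stop("association file contains empty ids", call. = FALSE)
  }
  n_raw <- nrow(tab)
  tab <- dplyr::distinct(tab, .data$mirna, .data$disease)
  if (nrow(tab) < n_raw) {
    message(n_raw - nrow(tab), " duplicate association record(s) removed")
  }
  tab
}

detect_separator <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

#' Build the binary association matrix from an association table
#'
#' Rows are miRNAs, columns are diseases, both ordered by first appearance in
#' the table; entry (i, j) is 1 when the pair is a known association.
#'
#' @param table A tibble with columns `mirna` and `disease`
#'   (see [read_association_table()]).
#' @return A binary numeric matrix with miRNA ids as rownames and disease ids
#'   as colnames; its entry sum equals the number of unique pairs.
#' @examples
#' tab <- tibble::tibble(mirna = c("m1", "m2"), disease = c("d1", "d1"))
#' build_association_matrix(tab)
#' @export
build_association_matrix <- function(table) {
  stopifnot(is.data.frame(table), all(c("mirna", "disease") %in% names(table)))
  if (nrow(table) == 0) stop("association table is empty", call. = FALSE)
  mirnas <- unique(table$mirna)
  diseases <- unique(table$disease)
  A <- matrix(0, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  A[cbind(match(table$mirna, mirnas), match(table$disease, diseases))] <- 1
  A
}

#' Write and read a labelled score matrix
#'
#' Scores are written as TSV with disease ids as the header row and miRNA ids
#' in the first column, at full double precision so that a read-back
#' reproduces the matrix to at least 12 significant digits.
#'
#' @param SS Numeric matrix with rownames (miRNA ids) and colnames
#'   (disease ids); all entries must be finite.
#' @param path Output file path.
#' @return `write_score_matrix` returns `path` invisibly; `read_matrix`
#'   returns the labelled numeric matrix.
#' @export
write_score_matrix <- function(SS, path) {
  stopifnot(is.matrix(SS), !is.null(rownames(SS)), !is.null(colnames(SS)))
  if (any(!is.finite(SS))) {
    stop("score matrix contains non-finite entries", call. = FALSE)
  }
  df <- tibble::as_tibble(SS, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(mirna = rownames(SS)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write an association table to TSV
#'
#' @param table Tibble with columns `mirna` and `disease`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  readr::write_tsv(table[, c("mirna", "disease")], path, col_names = FALSE)
  invisible(path)
}

#' Read a miRNA expression profile matrix
#'
#' The file is TSV with tissue ids in the header row, miRNA ids in the first
#' column, and real-valued expression levels in the remaining cells. miRNAs
#' of the association universe that have no row here are treated as lacking a
#' profile (their similarities are mean-imputed downstream).
#'
#' @param path Path to the expression TSV.
#' @return A numeric matrix (miRNAs x tissues) with id dimnames.
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) stop("expression file needs >= 1 tissue column", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- trimws(as.character(df[[1]]))
  if (anyDuplicated(rownames(m))) {
    stop("duplicate miRNA ids in expression file", call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  m
}

#' Write an expression profile matrix to TSV
#'
#' @param expr Numeric matrix, miRNAs x tissues, with id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- dplyr::bind_cols(
    tibble::tibble(mirna = rownames(expr)),
    tibble::as_tibble(expr, .name_repair = "minimal")
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read disease term hierarchies from an edge-list file
#'
#' The file is TSV (or comma-separated) with columns `disease`, `child`,
#' `parent`: one row per child-to-parent edge of the disease's DAG of
#' MeSH-style terms. The disease's own term appears as a child of its parent
#' terms. Lines starting with `#` are comments.
#'
#' @param path Path to the DAG edge-list file.
#' @return A tibble with columns `disease`, `child`, `parent`.
#' @export
read_dag_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("DAG file is empty: ", path, call. = FALSE)
  sep <- detect_separator(lines[[1]])
  if (grepl("^disease[\t,]", lines[[1]])) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1]
    stop("malformed DAG line ", lineno[bad], " (fewer than 3 fields)",
         call. = FALSE)
  }
  tibble::tibble(
    disease = trimws(vapply(fields, `[[`, "", 1L)),
    child = trimws(vapply(fields, `[[`, "", 2L)),
    parent = trimws(vapply(fields, `[[`, "", 3L))
  )
}

#' Write a DAG edge-list table to TSV
#'
#' @param dags Tibble with columns `disease`, `child`, `parent`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dag_table <- function(dags, path) {
  readr::write_tsv(dags[, c("disease", "child", "parent")], path)
  invisible(path)
}
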