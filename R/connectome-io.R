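# Reading, validating and writing subject connectomes, cohort tables and
# per-subject measure tables.

#' Construct a validated signed connectome
#'
#' A signed connectome is one subject's square symmetric matrix of
#' correlation-like connection weights between network nodes (for example the
#' full normalized temporal correlations between resting-state networks).
#' Weights are dimensionless and expected in \[-1, 1\]; the diagonal
#' (self-connection) is undefined for correlation networks and is forced to
#' zero.
#'
#' Small numerical asymmetries (at most `sym_tol`) are repaired by averaging
#' the matrix with its transpose; larger asymmetries are an error, since
#' correlation matrices are symmetric by construction. Entries marginally
#' outside \[-1, 1\] (by at most 1e-9) are clipped with a warning.
#'
#' @param weights square numeric matrix of signed connection weights.
#' @param subject_id subject identifier.
#' @param nodes optional character vector of node labels; defaults to the
#'   matrix rownames or `node1..n`.
#' @param sym_tol maximum tolerated absolute asymmetry before averaging.
#' @return an object of class `signed_connectome`: a list with elements
#'   `subject_id`, `nodes` and `weights`.
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 0.5
#' w[2, 3] <- w[3, 2] <- -0.2
#' signed_connectome(w, "demo")
#' @export
signed_connectome <- function(weights, subject_id = "subject", nodes = NULL,
                              sym_tol = 1e-6) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix")
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("connectivity matrix must be square (got ", n, " x ", ncol(weights), ")")
  if (n < 3)
    stop("a connectome needs at least 3 nodes")
  if (any(!is.finite(weights)))
    stop("connectivity matrix contains NaN/Inf/NA entries")
  asym <- max(abs(weights - t(weights)))
  if (asym > sym_tol)
    stop(sprintf("matrix asymmetry %.3g exceeds the tolerance %.3g", asym, sym_tol))
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  mx <- max(abs(w))
  if (mx > 1 + 1e-9)
    stop(sprintf("|weight| = %.6g exceeds the correlation bound of 1", mx))
  if (mx > 1) {
    warning("weights marginally outside [-1, 1]; clipping")
    w <- pmin(pmax(w, -1), 1)
  }
  if (is.null(nodes)) {
    nodes <- if (!is.null(rownames(weights))) rownames(weights)
             else paste0("node", seq_len(n))
  }
  if (length(nodes) != n)
    stop("`nodes` must have one label per row")
  dimnames(w) <- list(nodes, nodes)
  structure(list(subject_id = as.character(subject_id),
                 nodes = as.character(nodes),
                 weights = w),
            class = "signed_connectome")
}

#' @export
print.signed_connectome <- function(x, ...) {
  n <- length(x$nodes)
  cat("<signed_connectome> subject:", x$subject_id, "-", n, "nodes,",
      sum(x$weights[upper.tri(x$weights)] < 0), "negative /",
      sum(x$weights[upper.tri(x$weights)] > 0), "positive connections\n")
  invisible(x)
}

#' Read a signed connectivity matrix from delimited text
#'
#' Reads a square matrix of signed connection weights from a CSV or TSV file
#' (delimiter autodetected from the first line when not given) with an
#' optional header row of node labels, and validates it via
#' [signed_connectome()]. Loading an already-validated matrix is idempotent.
#'
#' @param path path to the matrix file.
#' @param delimiter field delimiter; `NULL` autodetects tab versus comma.
#' @param node_labels optional node labels overriding any header.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return a `signed_connectome`.
#' @export
read_connectome_matrix <- function(path, delimiter = NULL, node_labels = NULL,
                                   subject_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(delimiter))
    delimiter <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  toks <- strsplit(first, delimiter, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks))))
  df <- utils::read.table(path, sep = delimiter, header = has_header,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("non-numeric cells in matrix file: ", path)
  if (is.null(node_labels) && has_header) node_labels <- colnames(df)
  signed_connectome(unname(m), subject_id = subject_id, nodes = node_labels)
}

#' Write a connectome matrix as delimited text
#'
#' @param x a `signed_connectome` or square numeric matrix.
#' @param path output file path.
#' @param delimiter field delimiter.
#' @param header write the node labels as a header row.
#' @return `path`, invisibly.
#' @export
write_connectome_matrix <- function(x, path, delimiter = ",", header = TRUE) {
  w <- if (inherits(x, "signed_connectome")) x$weights else x
  lines <- apply(w, 1L, function(r) paste(sprintf("%.12g", r), collapse = delimiter))
  if (header)
    lines <- c(paste(colnames(w), collapse = delimiter), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read and filter a cohort table
#'
#' Reads a CSV with columns `subject_id`, `sex` (`female`/`male`) and `age`
#' (integer years), plus optional phenotype columns. Subjects in (age, sex)
#' cells with fewer than `min_group_size` members are dropped, so that every
#' retained per-age group comparison has adequate size.
#'
#' @param path cohort CSV path.
#' @param min_group_size minimum subjects per (age, sex) cell (default 50).
#' @param age_range optional integer pair; ages outside it are an error.
#' @return a `data.frame` of the retained rows, with `sex` as a factor with
#'   levels `c("female", "male")` (coded 0/1 in downstream models) and the
#'   dropped cells reported via `message()`.
#' @export
read_cohort_table <- function(path, min_group_size = 50, age_range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(df, min_group_size = min_group_size,
                        age_range = age_range)
}

#' Validate and cell-filter an in-memory cohort table
#'
#' @param df data.frame with columns `subject_id`, `sex`, `age`.
#' @inheritParams read_cohort_table
#' @return the filtered data.frame (see [read_cohort_table()]).
#' @export
validate_cohort_table <- function(df, min_group_size = 50, age_range = NULL) {
  req <- c("subject_id", "sex", "age")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort table is missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("cohort table has no rows")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id values in cohort table")
  bad_sex <- setdiff(unique(as.character(df$sex)), c("female", "male"))
  if (length(bad_sex))
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "),
         " (expected 'female'/'male')")
  if (!is.numeric(df$age) || any(df$age != round(df$age)))
    stop("age must be integer years")
  if (!is.null(age_range) &&
      (any(df$age < age_range[1]) || any(df$age > age_range[2])))
    stop("ages outside the declared range [", age_range[1], ", ", age_range[2], "]")
  df$sex <- factor(as.character(df$sex), levels = c("female", "male"))
  cell <- interaction(df$age, df$sex, drop = TRUE)
  sizes <- table(cell)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small)) {
    message("dropping ", sum(cell %in% small), " subjects in ", length(small),
            " (age, sex) cell(s) below min_group_size = ", min_group_size, ": ",
            paste(small, collapse = ", "))
    df <- df[!(cell %in% small), , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no rows remain after cell-size filtering")
  rownames(df) <- NULL
  df
}

#' Write a tidy per-subject measure table
#'
#' One row per subject x measure (x interlayer coupling sigma where
#' applicable); values are written with 12 significant digits so that a
#' write/read round trip is lossless to 1e-12 relative precision. The `sigma`
#' field is empty for measures that do not depend on the interlayer coupling.
#'
#' @param table data.frame with columns `subject_id`, `measure`, `sigma`
#'   (NA allowed) and `value`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measure_table <- function(table, path) {
  req <- c("subject_id", "measure", "sigma", "value")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("measure table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(table) == 0) stop("measure table is empty")
  key <- paste(table$subject_id, table$measure, table$sigma, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, measure, sigma) keys in measure table")
  out <- data.frame(
    subject_id = as.character(table$subject_id),
    measure = as.character(table$measure),
    sigma = ifelse(is.na(table$sigma), "", sprintf("%.15g", table$sigma)),
    value = sprintf("%.15g", table$value),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy measure table written by [write_measure_table()]
#'
#' @param path CSV path.
#' @return data.frame with columns `subject_id`, `measure`, `sigma`, `value`.
#' @export
read_measure_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       measure = "character"))
  df$sigma <- suppressWarnings(as.numeric(df$sigma))
  df$value <- as.numeric(df$value)
  df
}
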