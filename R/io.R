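#' Read a gene expression table
#'
#' Parses a delimited text file with gene identifiers in the first column and
#' one sample per remaining column (header row = sample names). Duplicated
#' gene identifiers are dropped after their first occurrence and rows with
#' missing expression values are removed, each with a warning, so the result
#' holds one complete record per unique gene in order of first appearance.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field separator, `"\t"` by default.
#' @return A numeric genes x samples matrix with unique gene IDs as rownames
#'   and a logical `normalized` attribute (initially `FALSE`).
#' @seealso [normalize_rows()]
#' @export
read_expression_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("expression file is empty or has no sample columns: ", path)
  ids <- raw[[1L]]
  num <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L)
  for (j in seq_len(ncol(raw) - 1L)) {
    col <- raw[[j + 1L]]
    missing_cell <- is.na(col) | col == "" | toupper(col) == "NA"
    parsed <- suppressWarnings(as.numeric(col))
    bad <- which(!missing_cell & is.na(parsed))
    if (length(bad))
      stop(sprintf("non-numeric expression value '%s' at row '%s', column '%s'",
                   col[bad[1L]], ids[bad[1L]], colnames(raw)[j + 1L]))
    num[, j] <- parsed
  }
  colnames(num) <- colnames(raw)[-1L]
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sum(dup), " duplicated gene ID(s) dropped: ",
            paste(unique(ids[dup]), collapse = ", "))
    num <- num[!dup, , drop = FALSE]
    ids <- ids[!dup]
  }
  incomplete <- rowSums(is.na(num)) > 0L
  if (any(incomplete)) {
    warning(sum(incomplete), " row(s) with missing values removed: ",
            paste(ids[incomplete], collapse = ", "))
    num <- num[!incomplete, , drop = FALSE]
    ids <- ids[!incomplete]
  }
  if (nrow(num) == 0L) stop("no complete gene records left after filtering")
  rownames(num) <- ids
  expression_matrix(num, normalized = FALSE)
}

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, genes x samples, with unique rownames.
#' @param normalized Logical; whether rows already have mean 0 / variance 1.
#' @return The matrix with class `expression_matrix` and a `normalized`
#'   attribute.
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("gene IDs (rownames) are required")
  if (anyDuplicated(rownames(values))) stop("gene IDs must be unique")
  if (anyNA(values)) stop("expression matrix must not contain missing values")
  if (isTRUE(normalized)) {
    mu <- rowMeans(values)
    v <- apply(values, 1L, stats::var)
    if (any(abs(mu) > 1e-9) || any(abs(v - 1) > 1e-9))
      stop("normalized = TRUE but rows are not mean 0 / variance 1")
  }
  structure(values, normalized = isTRUE(normalized),
            class = c("expression_matrix", "matrix", "array"))
}

#' Standardise expression rows to mean 0, variance 1
#'
#' Constant (zero-variance) rows cannot be standardised (and have undefined
#' Pearson correlation); they are removed with a warning.
#'
#' @param X An [expression_matrix()].
#' @return The row-standardised matrix with the `normalized` flag set.
#' @export
normalize_rows <- function(X) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (ncol(X) < 2L) stop("at least 2 samples are required to normalize rows")
  v <- apply(X, 1L, stats::var)
  const <- v == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) removed (zero variance): ",
            paste(rownames(X)[const], collapse = ", "))
    X <- X[!const, , drop = FALSE]
    v <- v[!const]
  }
  if (nrow(X) == 0L) stop("all rows were constant; nothing to normalize")
  out <- (X - rowMeans(X)) / sqrt(v)
  expression_matrix(unclass(out), normalized = TRUE)
}

#' Construct a labelled distance matrix
#'
#' @param values Symmetric numeric matrix with zero diagonal and identical
#'   row/column gene IDs.
#' @param source Either `"EB"` (expression-based) or `"BB"` (biology-based).
#' @return The matrix with class `distance_matrix` and a `source` attribute.
#' @export
distance_matrix <- function(values, source = c("EB", "BB")) {
  source <- match.arg(source)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values)) || !identical(rownames(values), colnames(values)))
    stop("distance matrix requires identical row and column gene IDs")
  if (max(abs(values - t(values))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be zero")
  structure(values, source = source,
            class = c("distance_matrix", "matrix", "array"))
}

#' Write / read a square distance matrix as TSV
#'
#' The format is a square table with identical row and column gene-ID labels;
#' values are written with 10 significant digits.
#'
#' @param D A [distance_matrix()].
#' @param path Output (or input) file path.
#' @param source Tag to attach when reading, `"EB"` or `"BB"`.
#' @return `write_distance_tsv` returns `path` invisibly; `read_distance_tsv`
#'   returns a [distance_matrix()].
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(gene = rownames(D),
                   signif(unclass(D), 10L), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path, source = c("EB", "BB")) {
  source <- match.arg(source)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- raw[[1L]]
  storage.mode(m) <- "double"
  # symmetrise away the rounding introduced by the 10-digit text round-trip
  m <- (m + t(m)) / 2
  diag(m) <- 0
  distance_matrix(m, source = source)
}

#' Write an expression matrix as TSV
#'
#' @param X An [expression_matrix()].
#' @param path Output file path.
#' @export
write_expression_tsv <- function(X, path) {
  df <- data.frame(gene = rownames(X), unclass(X), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
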