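# Readers/writers for the three input formats and the ranked-output format.
# Association file: 2-column TSV/CSV (mirna_id, disease_id), '#' comments.
# Similarity file: (n+1) x (n+1) TSV/CSV with labels in first row and column.
# Ranked output: TSV with columns rank, mirna, score.

#' Construct an association set
#'
#' An `association_set` holds the experimentally known miRNA-disease pairs
#' together with deterministic (lexicographically sorted) label vectors for
#' the miRNAs and diseases they mention. It is the in-memory form of an
#' association table such as an HMDD dump.
#'
#' @param mirna character vector of miRNA ids, parallel to `disease`.
#' @param disease character vector of disease ids.
#' @return An object of class `association_set`: a list with elements
#'   `pairs` (a data.frame with columns `mirna`, `disease`, deduplicated and
#'   sorted), `mirna_labels` and `disease_labels` (sorted unique ids).
#' @export
association_set <- function(mirna, disease) {
  stopifnot(is.character(mirna), is.character(disease),
            length(mirna) == length(disease))
  mirna <- trimws(mirna)
  disease <- trimws(disease)
  if (any(mirna == "" | disease == ""))
    stop("association ids must be non-empty strings")
  pairs <- unique(data.frame(mirna = mirna, disease = disease,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$mirna, pairs$disease), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 mirna_labels = sort(unique(pairs$mirna)),
                 disease_labels = sort(unique(pairs$disease))),
            class = "association_set")
}

#' @export
print.association_set <- function(x, ...) {
  cat(sprintf("association_set: %d pairs, %d miRNAs, %d diseases\n",
              nrow(x$pairs), length(x$mirna_labels),
              length(x$disease_labels)))
  invisible(x)
}

# Detect tab vs comma on the first data line; tab wins when both appear
# (MISIM/HMDD dumps circulate in both dialects).
detect_delim <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a miRNA-disease association table
#'
#' Parses a two-column delimited text file of known miRNA-disease pairs.
#' The delimiter (tab, then comma) is auto-detected, `#`-comment and blank
#' lines are skipped, surrounding whitespace is stripped, and duplicate
#' pairs collapse to one. Labels are case-sensitive and never normalized.
#'
#' @param path path to a 2-column TSV/CSV file (`mirna_id`, `disease_id`).
#' @param quiet suppress the summary message.
#' @return An [association_set()].
#' @export
read_association_table <- function(path, quiet = FALSE) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L)
    stop("no associations: ", path, " contains no data lines")
  delim <- detect_delim(dat$lines[1L])
  fields <- strsplit(dat$lines, delim, fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad) > 0L)
    stop(sprintf("malformed association line %d in %s: expected 2 fields",
                 dat$lineno[bad[1L]], path))
  assoc <- association_set(vapply(fields, `[[`, "", 1L),
                           vapply(fields, `[[`, "", 2L))
  if (!quiet)
    message(sprintf("read %d association pairs (%d miRNAs, %d diseases) from %s",
                    nrow(assoc$pairs), length(assoc$mirna_labels),
                    length(assoc$disease_labels), path))
  assoc
}

#' Construct a similarity matrix
#'
#' A `similarity_matrix` is a labeled symmetric matrix of pairwise
#' similarity scores in \[0, 1\] with unit diagonal, as produced by
#' MISIM-style miRNA functional similarity or MimMiner-style disease
#' phenotype similarity pipelines. Asymmetries up to `1e-6` are averaged
#' out with a warning; anything larger is an error.
#'
#' @param labels character vector of node labels (unique).
#' @param values square numeric matrix, `length(labels)` on each side.
#' @return An object of class `similarity_matrix`: a numeric matrix with
#'   `labels` as dimnames.
#' @export
similarity_matrix <- function(labels, values) {
  labels <- as.character(labels)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("similarity matrix must be square, got ",
         nrow(values), "x", ncol(values))
  if (length(labels) != nrow(values))
    stop("label count does not match matrix dimension")
  if (anyDuplicated(labels)) stop("duplicate similarity labels")
  if (!is.numeric(values) || anyNA(values))
    stop("similarity values must be numeric and non-missing")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-6)
    stop(sprintf("similarity matrix asymmetric (max |S - t(S)| = %.3g)", asym))
  if (asym > 0) {
    warning(sprintf("symmetrizing similarity matrix (max asymmetry %.3g)", asym))
    values <- (values + t(values)) / 2
  }
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9)
    stop(sprintf("similarity values outside [0, 1]: range %.4g..%.4g",
                 min(values), max(values)))
  values <- pmin(pmax(values, 0), 1)
  if (max(abs(diag(values) - 1)) > 1e-6)
    stop("similarity diagonal entries must equal 1")
  diag(values) <- 1
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("similarity_matrix", "matrix"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d x %d labeled nodes\n", nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Read a labeled similarity matrix
#'
#' Parses a delimited `(n+1) x (n+1)` file whose first row and first column
#' carry identical label sets. Validation (symmetry, range, unit diagonal)
#' follows [similarity_matrix()].
#'
#' @param path path to the TSV/CSV file.
#' @return A [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) < 2L)
    stop("similarity file ", path, " has no data")
  delim <- detect_delim(dat$lines[1L])
  rows <- strsplit(dat$lines, delim, fixed = TRUE)
  header <- trimws(rows[[1L]])
  # allow either an empty or a named top-left corner cell
  col_labels <- if (header[1L] == "" || length(header) == length(rows) - 1L)
    header[header != ""] else header[-1L]
  n <- length(rows) - 1L
  if (length(col_labels) != n)
    stop("similarity file ", path, " is not square: ",
         n, " data rows vs ", length(col_labels), " column labels")
  row_labels <- character(n)
  values <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    r <- trimws(rows[[i + 1L]])
    if (length(r) != n + 1L)
      stop(sprintf("malformed similarity line %d in %s: expected %d fields",
                   dat$lineno[i + 1L], path, n + 1L))
    row_labels[i] <- r[1L]
    values[i, ] <- suppressWarnings(as.numeric(r[-1L]))
  }
  if (anyNA(values))
    stop("non-numeric similarity values in ", path)
  if (!identical(sort(row_labels), sort(col_labels)))
    stop("row/column label mismatch in ", path)
  # align columns to row order if the file permuted them
  values <- values[, match(row_labels, col_labels), drop = FALSE]
  similarity_matrix(row_labels, values)
}

#' Write a similarity matrix
#'
#' Inverse of [read_similarity_matrix()]: labels in the first row and
#' column, tab-delimited.
#'
#' @param S a [similarity_matrix()].
#' @param path output path.
#' @export
write_similarity_matrix <- function(S, path) {
  stopifnot(inherits(S, "similarity_matrix"))
  labels <- rownames(S)
  header <- paste(c("", labels), collapse = "\t")
  # %.17g round-trips doubles exactly, keeping the written matrix symmetric
  body <- vapply(seq_along(labels), function(i)
    paste(c(labels[i], sprintf("%.17g", unclass(S)[i, ])), collapse = "\t"),
    "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write an association set
#'
#' Writes the pair list as a 2-column TSV readable by
#' [read_association_table()].
#'
#' @param assoc an [association_set()].
#' @param path output path.
#' @export
write_association_table <- function(assoc, path) {
  stopifnot(inherits(assoc, "association_set"))
  writeLines(paste(assoc$pairs$mirna, assoc$pairs$disease, sep = "\t"), path)
  invisible(path)
}

#' Write a ranked candidate list
#'
#' Writes a [rank_candidates()] result as a TSV with header
#' `rank<TAB>mirna<TAB>score`; ranks start at 1, scores carry at least six
#' significant digits, and re-reading the file reproduces the ranking order.
#'
#' @param ranking a `ranked_list` data.frame (`rank`, `mirna`, `score`).
#' @param path output path.
#' @export
write_ranked_list <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranked_list"))
  if (nrow(ranking) == 0L) stop("empty ranking: nothing to write")
  lines <- c("rank\tmirna\tscore",
             sprintf("%d\t%s\t%.8g", ranking$rank, ranking$mirna,
                     ranking$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranked candidate list
#'
#' @param path path written by [write_ranked_list()].
#' @return A `ranked_list` data.frame.
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(df), c("rank", "mirna", "score")))
  structure(df, class = c("ranked_list", "data.frame"))
}
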