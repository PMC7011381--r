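#' Construct a count table
#'
#' A count table is the universal input of the package: a nonnegative
#' integer matrix of sequencing read counts with samples as rows and OTUs
#' (operational taxonomic units) as columns. All downstream operations
#' address samples and OTUs by id, never by position.
#'
#' @param counts integer matrix, samples x OTUs. Dimnames, if present, are
#'   overridden by `sample_ids` / `otu_ids` when those are supplied.
#' @param sample_ids character vector of unique sample identifiers.
#' @param otu_ids character vector of unique OTU identifiers.
#' @return An object of class `count_table`: the integer matrix with
#'   row/column names set.
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (any(!is.finite(counts))) stop("non-finite count")
  if (any(counts < 0)) stop("negative count")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("non-integer count (use allow_float = TRUE in read_count_table to round)")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  class(counts) <- c("count_table", "matrix", "array")
  counts
}

#' Test for count_table
#' @param x object
#' @return logical
#' @export
is_count_table <- function(x) inherits(x, "count_table")

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d OTUs, total reads %s\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read a tab-separated OTU count table
#'
#' Reads a TSV file with a header row and a leading row-label column,
#' orientation either samples-as-rows or OTUs-as-rows; the result is
#' always normalized to samples x OTUs.
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default) or `"otus_as_rows"`.
#' @param allow_float round non-integer cells to the nearest integer with a
#'   warning instead of erroring (some denoising pipelines emit floats).
#' @return A [count_table()].
#' @export
read_count_table <- function(path,
                             orientation = c("samples_as_rows", "otus_as_rows"),
                             allow_float = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in count table: ", path)
  if (any(m < 0)) stop("negative count in ", path)
  if (any(abs(m - round(m)) > 1e-8)) {
    if (!allow_float) stop("non-integer count in ", path,
                           " (set allow_float = TRUE to round)")
    warning("non-integer counts rounded to nearest integer")
  }
  m <- round(m)
  if (orientation == "otus_as_rows") m <- t(m)
  count_table(m)
}

#' Write a count table to TSV
#'
#' @param table a [count_table()].
#' @param path file path.
#' @param orientation row orientation of the written file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path,
                              orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  m <- unclass(table)
  label <- "sample_id"
  if (orientation == "otus_as_rows") {
    m <- t(m)
    label <- "otu_id"
  }
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param table a [count_table()] or numeric matrix (samples x OTUs).
#' @return Numeric matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(table) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    bad <- rownames(m)[tot <= 0]
    if (is.null(bad)) bad <- which(tot <= 0)
    stop("zero-total sample(s): ", paste(bad, collapse = ", "))
  }
  m / tot
}
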