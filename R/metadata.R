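#' Factor levels of the experimental design
#'
#' Exposure regimes, habitats and sampling timepoints of the
#' cadmium-recovery design: three regimes (Ctrl = no exposure, CC =
#' constant cadmium concentration, CV = variable/gradual concentration),
#' three habitats (tank water, skin mucosa, gut), and seven timepoints
#' spanning the exposure phase (T0 to T3) and the recovery phase (TR1 to
#' TR4, ending at T5).
#'
#' @name design_levels
#' @keywords internal
NULL

TREATMENT_LEVELS <- c("Ctrl", "CC", "CV")
HABITAT_LEVELS <- c("water", "skin", "gut")
TIMEPOINT_LEVELS <- c("T0", "T3", "TR1", "TR2", "TR3", "TR4", "T5")

#' Construct sample metadata
#'
#' Validates per-sample design factors: treatment in Ctrl/CC/CV, habitat
#' in water/skin/gut, timepoint in T0/T3/TR1..TR4/T5, tank in 1..8,
#' replicate >= 1.
#'
#' @param df data.frame with columns sample_id, treatment, habitat,
#'   timepoint, tank, replicate.
#' @return A validated data.frame of class `sample_metadata` with factor
#'   columns in canonical level order.
#' @export
sample_metadata <- function(df) {
  required <- c("sample_id", "treatment", "habitat", "timepoint",
                "tank", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  check_levels <- function(x, levels, what) {
    x <- as.character(x)
    bad <- setdiff(unique(x), levels)
    if (length(bad))
      stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "))
    factor(x, levels = levels)
  }
  df$treatment <- check_levels(df$treatment, TREATMENT_LEVELS, "treatment")
  df$habitat <- check_levels(df$habitat, HABITAT_LEVELS, "habitat")
  df$timepoint <- check_levels(df$timepoint, TIMEPOINT_LEVELS, "timepoint")
  df$tank <- as.integer(df$tank)
  if (any(is.na(df$tank)) || any(df$tank < 1L) || any(df$tank > 8L))
    stop("tank must be an integer in 1..8")
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop("replicate must be a positive integer")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read a sample metadata TSV
#'
#' @param path tab-separated file with columns sample_id, treatment,
#'   habitat, timepoint, tank, replicate.
#' @return A [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "")
  sample_metadata(df)
}

#' Write sample metadata to TSV
#' @param metadata a [sample_metadata()] data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align metadata to a count table
#'
#' Subsets and reorders metadata rows to the table's samples; errors if a
#' sample lacks metadata.
#'
#' @param metadata a [sample_metadata()].
#' @param table a [count_table()].
#' @return metadata rows in the table's sample order.
#' @export
align_metadata <- function(metadata, table) {
  idx <- match(rownames(table), metadata$sample_id)
  if (anyNA(idx))
    stop("samples without metadata: ",
         paste(rownames(table)[is.na(idx)], collapse = ", "))
  out <- metadata[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
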