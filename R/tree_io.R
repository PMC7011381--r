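#' Read a rooted phylogenetic tree from Newick
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the
#' downstream UniFrac computation relies on: unique leaf labels,
#' nonnegative branch lengths, and a root. Missing branch lengths are set
#' to 0 with a warning (interior zero-length branches are common in
#' denoised amplicon trees); unrooted input is rooted at its first
#' internal node with a warning.
#'
#' @param path Newick file path.
#' @return An [ape] `phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch length(s) set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  # a basal multifurcation is accepted as the root: the branch-proportion
  # traversal only needs a unique basal node, which any phylo object has
  tree
}

#' Write a tree to Newick
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Construct a sample distance matrix
#'
#' Container for symmetric nonnegative pairwise distances with a zero
#' diagonal; symmetry is enforced to 1e-12 and the diagonal is set to
#' exactly 0.
#'
#' @param values square numeric matrix.
#' @param ids sample ids (defaults to the matrix rownames).
#' @return A `dist_matrix`: the matrix with class attribute and dimnames.
#' @export
dist_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids in distance matrix")
  if (any(!is.finite(values))) stop("non-finite distance")
  if (max(abs(values - t(values))) > 1e-12)
    stop("distance matrix not symmetric within 1e-12")
  if (any(values < -1e-15)) stop("negative distance")
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  diag(values) <- 0
  dimnames(values) <- list(ids, ids)
  class(values) <- c("dist_matrix", "matrix", "array")
  values
}

#' Read / write a square distance matrix TSV
#' @param path file path.
#' @return A [dist_matrix()].
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, quote = "")
  dist_matrix(as.matrix(df))
}

#' @rdname read_dist_matrix
#' @param dm a [dist_matrix()].
#' @export
write_dist_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), unclass(dm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a distance matrix by sample id
#' @param dm a [dist_matrix()].
#' @param ids sample ids to keep, in order.
#' @return A [dist_matrix()] over `ids`.
#' @export
subset_dist <- function(dm, ids) {
  missing <- setdiff(ids, rownames(dm))
  if (length(missing))
    stop("ids not in distance matrix: ", paste(missing, collapse = ", "))
  dist_matrix(unclass(dm)[ids, ids, drop = FALSE])
}
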