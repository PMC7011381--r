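#' Per-sample alpha diversity
#'
#' Richness (OTUs detected at >= 1 read), Shannon entropy H on relative
#' abundances (natural log, with 0 log 0 = 0), the Shannon effective
#' number exp(H) (diversity as an equivalent count of equally abundant
#' taxa), Pielou evenness H / ln(richness) (undefined, NA, when richness
#' <= 1), and the richness / effective-number ratio.
#'
#' @param table a [count_table()].
#' @return data.frame with one row per sample: sample_id, richness,
#'   shannon, shannon_effective, evenness, ratio_richness_over_effective.
#' @export
alpha_diversity <- function(table) {
  R <- relative_abundance(table)
  richness <- rowSums(unclass(table) >= 1L)
  shannon <- apply(R, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  eff <- exp(shannon)
  evenness <- ifelse(richness > 1, shannon / log(richness), NA_real_)
  data.frame(sample_id = rownames(table), richness = as.integer(richness),
             shannon = shannon, shannon_effective = eff,
             evenness = evenness,
             ratio_richness_over_effective = richness / eff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample branch proportions on a rooted tree
#'
#' For every branch (edge) of the tree, the fraction of each sample's
#' reads carried by tips descending from that branch: the quantity the
#' whole UniFrac family is computed from. One postorder accumulation.
#'
#' @param table a [count_table()].
#' @param tree rooted `phylo` tree whose tips cover the table's detected
#'   OTUs.
#' @param prune drop table OTUs absent from the tree (and renormalize)
#'   instead of erroring.
#' @return List: `P` (n_samples x n_edges matrix), `lens` (branch
#'   lengths).
#' @keywords internal
branch_proportions <- function(table, tree, prune = FALSE) {
  tree <- validate_tree(tree)
  m <- unclass(table)
  detected <- colnames(m)[colSums(m) > 0]
  missing <- setdiff(detected, tree$tip.label)
  if (length(missing)) {
    if (!prune)
      stop("OTU(s) not in tree: ", paste(missing, collapse = ", "),
           " (set prune = TRUE to drop them)")
    m <- m[, setdiff(colnames(m), missing), drop = FALSE]
  }
  if (any(rowSums(m) == 0))
    stop("all-zero sample(s) after pruning: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  R <- m / rowSums(m)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  n <- nrow(R)
  node_prop <- matrix(0, n, ntip + nnode)
  hit <- match(tree$tip.label, colnames(R))
  ok <- !is.na(hit)
  node_prop[, which(ok)] <- R[, hit[ok], drop = FALSE]
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- nrow(tr$edge)
  P <- matrix(0, n, E)
  for (e in seq_len(E)) {
    child <- tr$edge[e, 2]
    P[, e] <- node_prop[, child]
    node_prop[, tr$edge[e, 1]] <- node_prop[, tr$edge[e, 1]] + node_prop[, child]
  }
  list(P = P, lens = tr$edge.length, ids = rownames(m))
}

#' Generalized UniFrac distance
#'
#' Phylogenetic beta diversity between every pair of samples:
#'   d(A, B) = sum_b l_b (p_A + p_B)^alpha |p_A - p_B| / (p_A + p_B)
#'           / sum_b l_b (p_A + p_B)^alpha,
#' over branches b with l_b the branch length and p_A, p_B the fractions
#' of each sample's reads descending from b (branches carrying no reads
#' from either sample are skipped). The exponent alpha interpolates the
#' weight placed on abundant (alpha = 1) versus rare (alpha = 0)
#' lineages; 0.5 is the conventional compromise.
#'
#' @param table a [count_table()].
#' @param tree rooted `phylo` tree over the table's OTUs.
#' @param alpha abundance exponent in [0, 1].
#' @param prune drop OTUs missing from the tree instead of erroring.
#' @return A [dist_matrix()] with entries in [0, 1].
#' @export
gunifrac <- function(table, tree, alpha = 0.5, prune = FALSE) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  bp <- branch_proportions(table, tree, prune = prune)
  d <- gunifrac_pairwise(bp$P, bp$lens, alpha)
  dist_matrix(d, ids = bp$ids)
}

#' Generalized UniFrac over a family of alpha values
#'
#' Shares the single tree traversal across all requested exponents.
#'
#' @inheritParams gunifrac
#' @param alphas numeric vector of exponents in [0, 1].
#' @return Named list of [dist_matrix()], one per alpha.
#' @export
gunifrac_alpha_family <- function(table, tree, alphas = c(0, 0.5, 1),
                                  prune = FALSE) {
  if (any(alphas < 0 | alphas > 1)) stop("alpha must be in [0, 1]")
  bp <- branch_proportions(table, tree, prune = prune)
  out <- lapply(alphas, function(a)
    dist_matrix(gunifrac_pairwise(bp$P, bp$lens, a), ids = bp$ids))
  names(out) <- as.character(alphas)
  out
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth.
#' Exposed as an option because the source protocols differ on whether
#' tables are rarefied before diversity analysis; default workflows here
#' do not rarefy.
#'
#' @param table a [count_table()].
#' @param depth target depth; default the minimum sample total.
#' @param seed integer seed.
#' @return A rarefied [count_table()] (samples below `depth` are dropped
#'   with a warning).
#' @export
rarefy_table <- function(table, depth = NULL, seed = 1L) {
  m <- unclass(table)
  tot <- rowSums(m)
  if (is.null(depth)) depth <- min(tot)
  keep <- tot >= depth
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth)
    m <- m[keep, , drop = FALSE]
  }
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    set.seed(seed_stream(seed, i))
    reads <- rep.int(seq_len(ncol(m)), m[i, ])
    picked <- sample(reads, depth)
    tb <- tabulate(picked, nbins = ncol(m))
    out[i, ] <- tb
  }
  count_table(out)
}
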