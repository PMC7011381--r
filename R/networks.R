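#' Spearman correlation between samples
#'
#' Pairwise Spearman rho between sample abundance profiles (tie-corrected,
#' Pearson on average ranks) with p-values from the t approximation on
#' S - 2 degrees of freedom, S being the number of OTUs. Samples whose
#' abundance vector is constant have no defined rank correlation; their
#' pairs are flagged NA.
#'
#' @param table a [count_table()] (>= 3 OTUs).
#' @return List: `rho` and `p` (n_samples x n_samples matrices, diagonal
#'   rho = 1, p = 0).
#' @export
spearman_matrix <- function(table) {
  m <- t(relative_abundance(table))   # OTUs x samples
  S <- nrow(m)
  if (S < 3) stop("need at least 3 OTUs")
  constant <- apply(m, 2, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  r2 <- pmin(rho^2, 1 - 1e-15)
  tstat <- rho * sqrt((S - 2) / (1 - r2))
  p <- 2 * stats::pt(-abs(tstat), df = S - 2)
  p[abs(rho) >= 1 - 1e-15] <- 0
  diag(rho) <- 1
  diag(p) <- 0
  list(rho = rho, p = p)
}

#' Build a filtered sample-correlation network
#'
#' Keeps an edge between two samples when |rho| is at least `rho_min`
#' and its Benjamini-Hochberg adjusted p (over all sample pairs) is at
#' most `fdr_alpha`. Node attributes (richness from [alpha_diversity()],
#' plus any metadata columns) are attached for reporting. Negative
#' correlations are retained with a sign attribute.
#'
#' @param table a [count_table()].
#' @param rho_min minimum |rho| in [0, 1]; the study's conventions are
#'   0.5 for water networks and 0.3 for host (skin/gut) networks.
#' @param fdr_alpha maximum adjusted p for an edge.
#' @param metadata optional [sample_metadata()] for node attributes.
#' @param positive_only drop negative-rho edges entirely.
#' @return A list of class `sample_network`: `nodes` (data.frame),
#'   `edges` (data.frame: from, to, rho, p, p_adj, sign), `graph`
#'   (igraph object over all nodes).
#' @export
build_network <- function(table, rho_min = 0.5, fdr_alpha = 0.05,
                          metadata = NULL, positive_only = FALSE) {
  if (rho_min < 0 || rho_min > 1) stop("rho_min must be in [0, 1]")
  sm <- spearman_matrix(table)
  ids <- rownames(table)
  ut <- upper.tri(sm$rho)
  idx <- which(ut, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      rho = sm$rho[ut], p = sm$p[ut],
                      stringsAsFactors = FALSE)
  edges$p_adj <- bh_adjust(edges$p)
  keep <- !is.na(edges$rho) & abs(edges$rho) >= rho_min &
    !is.na(edges$p_adj) & edges$p_adj <= fdr_alpha
  if (positive_only) keep <- keep & edges$rho > 0
  edges <- edges[keep, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, "+", "-")
  rownames(edges) <- NULL
  nodes <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  nodes$richness <- alpha_diversity(table)$richness
  if (!is.null(metadata)) {
    meta <- align_metadata(metadata, table)
    nodes$treatment <- meta$treatment
    nodes$habitat <- meta$habitat
    nodes$timepoint <- meta$timepoint
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 rho_min = rho_min, fdr_alpha = fdr_alpha),
            class = "sample_network")
}

#' Betweenness centrality of network nodes
#'
#' Unnormalized shortest-path betweenness on the unweighted undirected
#' graph: for each unordered pair of other nodes, the fraction of their
#' shortest paths passing through the node. Isolated nodes score 0.
#'
#' @param net a [build_network()] result (or an igraph graph).
#' @return Named numeric vector, one entry per node.
#' @export
betweenness_centrality <- function(net) {
  g <- if (inherits(net, "sample_network")) net$graph else net
  if (igraph::vcount(g) == 0) return(stats::setNames(numeric(0), character(0)))
  igraph::betweenness(g, directed = FALSE, weights = NA)
}

#' Eigenvector centrality of network nodes
#'
#' Principal-eigenvector scores of the adjacency matrix, computed on the
#' largest connected component and L2-normalized; nodes outside that
#' component are reported NA (flagged, not silently zeroed).
#'
#' @param net a [build_network()] result (or an igraph graph).
#' @return Named numeric vector; NA outside the largest component.
#' @export
eigenvector_centrality <- function(net) {
  g <- if (inherits(net, "sample_network")) net$graph else net
  nv <- igraph::vcount(g)
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(nv)))
  out <- stats::setNames(rep(NA_real_, nv), igraph::V(g)$name)
  if (nv == 0) return(out)
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  members <- which(comp$membership == main)
  if (length(members) == 1) {
    out[members] <- 1
    return(out)
  }
  sub <- igraph::induced_subgraph(g, members)
  sc <- igraph::eigen_centrality(sub, directed = FALSE)$vector
  sc <- abs(sc)
  sc <- sc / sqrt(sum(sc^2))
  out[members] <- sc[match(igraph::V(g)$name[members],
                           igraph::V(sub)$name)]
  out
}

#' Centrality shift summary across design cells
#'
#' Medians and means of betweenness and eigenvector centrality per
#' (treatment, timepoint) network, with a Wilcoxon rank-sum p for each
#' treatment's betweenness against the control network at the same
#' timepoint.
#'
#' @param nets named list of [build_network()] results; names of the
#'   form `"<treatment>.<timepoint>"` (or supply `cells`).
#' @param cells optional data.frame with columns treatment, timepoint in
#'   the order of `nets`.
#' @return data.frame, one row per cell: treatment, timepoint, n_nodes,
#'   n_edges, median/mean betweenness, median eigenvector, p_vs_ctrl.
#' @export
centrality_shift_summary <- function(nets, cells = NULL) {
  if (is.null(cells)) {
    parts <- strsplit(names(nets), ".", fixed = TRUE)
    cells <- data.frame(treatment = vapply(parts, `[`, "", 1),
                        timepoint = vapply(parts, `[`, "", 2),
                        stringsAsFactors = FALSE)
  }
  btw <- lapply(nets, function(nt)
    if (is.null(nt)) numeric(0) else betweenness_centrality(nt))
  eig <- lapply(nets, function(nt)
    if (is.null(nt)) numeric(0) else eigenvector_centrality(nt))
  rows <- lapply(seq_along(nets), function(i) {
    b <- btw[[i]]; e <- eig[[i]]
    p_vs_ctrl <- NA_real_
    if (cells$treatment[i] != "Ctrl") {
      j <- which(cells$treatment == "Ctrl" &
                   cells$timepoint == cells$timepoint[i])
      if (length(j) == 1 && length(b) && length(btw[[j]])) {
        if (length(unique(c(b, btw[[j]]))) == 1) p_vs_ctrl <- 1
        else p_vs_ctrl <- wilcoxon_rank_sum(btw[[j]], b)$p_value
      }
    }
    data.frame(treatment = cells$treatment[i],
               timepoint = cells$timepoint[i],
               n_nodes = length(b),
               n_edges = if (is.null(nets[[i]])) 0L else nrow(nets[[i]]$edges),
               median_betweenness = if (length(b)) stats::median(b) else NA_real_,
               mean_betweenness = if (length(b)) mean(b) else NA_real_,
               median_eigenvector = if (length(e)) stats::median(e, na.rm = TRUE) else NA_real_,
               p_vs_ctrl = p_vs_ctrl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-group centrality comparison within one joint network
#'
#' For a network built over samples of several treatment groups at one
#' timepoint (the study's figures mix all regimes in one network, with
#' treatments appearing as modules), summarizes betweenness and
#' eigenvector centrality per group and tests each treatment's
#' betweenness against the control nodes by Wilcoxon rank-sum. Control
#' samples sitting between treatment modules bridge them, which shows up
#' as higher control betweenness.
#'
#' @param net a [build_network()] result whose nodes carry a `treatment`
#'   attribute (built with metadata), or supply `groups`.
#' @param groups optional factor of group labels in node order.
#' @param reference group compared against (default `"Ctrl"`).
#' @return data.frame: group, n_nodes, median/mean betweenness, median
#'   eigenvector, p_vs_ref.
#' @export
centrality_by_group <- function(net, groups = NULL, reference = "Ctrl") {
  if (is.null(groups)) groups <- net$nodes$treatment
  if (is.null(groups)) stop("no group labels available")
  groups <- as.character(groups)
  btw <- betweenness_centrality(net)
  eig <- eigenvector_centrality(net)
  ref_b <- btw[groups == reference]
  rows <- lapply(unique(groups), function(g) {
    b <- btw[groups == g]
    p <- NA_real_
    if (g != reference && length(ref_b) && length(b)) {
      p <- if (length(unique(c(b, ref_b))) == 1) 1
           else wilcoxon_rank_sum(ref_b, b)$p_value
    }
    data.frame(group = g, n_nodes = length(b),
               median_betweenness = stats::median(b),
               mean_betweenness = mean(b),
               median_eigenvector = stats::median(eig[groups == g],
                                                  na.rm = TRUE),
               p_vs_ref = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a network as edge and node TSVs
#' @param net a [build_network()] result.
#' @param edge_path,node_path output file paths.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(net, edge_path, node_path) {
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}
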