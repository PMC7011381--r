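# Independent oracles used across the suite. Each recomputes a quantity by
# the most direct route available (enumeration, quadrature, brute force),
# sharing no code with the implementation it checks.

# random small count table
random_table <- function(n, S, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(stats::rpois(n * S, lambda), n, S)
  m[rowSums(m) == 0, 1] <- 1L
  count_table(m, paste0("s", seq_len(n)), paste0("OTU", seq_len(S)))
}

# brute-force generalized UniFrac: enumerate every branch's descendant tip
# set by recursion on the edge list, then apply the formula term by term
oracle_gunifrac <- function(table, tree, alpha) {
  R <- unclass(table)
  R <- R / rowSums(R)
  tips <- tree$tip.label
  desc_tips <- function(node) {
    if (node <= length(tips)) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  E <- nrow(tree$edge)
  n <- nrow(R)
  d <- matrix(0, n, n)
  branch_sets <- lapply(seq_len(E), function(e) desc_tips(tree$edge[e, 2]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    num <- 0; den <- 0
    for (e in seq_len(E)) {
      tt <- intersect(branch_sets[[e]], colnames(R))
      pA <- sum(R[i, tt]); pB <- sum(R[j, tt])
      s <- pA + pB
      l <- tree$edge.length[e]
      if (s > 0 && l > 0) {
        den <- den + l * s^alpha
        num <- num + l * s^alpha * abs(pA - pB) / s
      }
    }
    d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
  }
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

# exhaustive two-group permutation p for an arbitrary statistic function:
# enumerate every distinct assignment of group labels via combn
oracle_exact_p <- function(stat_fn, n, n1, lower = FALSE) {
  splits <- utils::combn(n, n1, simplify = FALSE)
  stats_all <- vapply(splits, stat_fn, numeric(1))
  obs <- stat_fn(seq_len(n1))
  if (lower) mean(stats_all <= obs + 1e-12)
  else mean(stats_all >= obs - 1e-12)
}

# all-pairs BFS betweenness: enumerate every shortest path explicitly
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  shortest_paths_st <- function(s, t) {
    # BFS layers from s
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] > 0)) if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    if (!is.finite(dist[t])) return(list())
    # enumerate paths backwards from t along strictly decreasing dist
    walk <- function(v) {
      if (v == s) return(list(v))
      preds <- which(adj[v, ] > 0 & dist == dist[v] - 1)
      out <- list()
      for (p in preds) for (pp in walk(p)) out <- c(out, list(c(pp, v)))
      out
    }
    walk(t)
  }
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    paths <- shortest_paths_st(s, t)
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      bc[inner] <- bc[inner] + 1 / length(paths)
    }
  }
  bc
}

# Gini coefficient by the direct mean-absolute-difference formula
oracle_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

small_metadata <- function(ids, treatment = "Ctrl", habitat = "gut",
                           timepoint = "T0") {
  n <- length(ids)
  sample_metadata(data.frame(
    sample_id = ids,
    treatment = rep_len(treatment, n), habitat = rep_len(habitat, n),
    timepoint = rep_len(timepoint, n),
    tank = rep_len(1:8, n), replicate = 1L, stringsAsFactors = FALSE))
}
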