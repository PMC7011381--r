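#' @useDynLib recoverymics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

perm_result <- function(name, stat, p, n_perm, permuted, groups) {
  structure(list(statistic_name = name, statistic = stat, p_value = p,
                 n_permutations = n_perm, permuted_stats = permuted,
                 groups = groups),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s = %.5g, p = %.4g (%d permutations)\n",
              x$statistic_name, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

check_groups <- function(dm, groups) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(dm))
    stop("group vector length does not match distance matrix")
  groups <- droplevels(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("singleton group(s): ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  groups
}

# label permutations: exhaustive (all n! orderings) or random, optionally
# restricted to permute within strata
make_permutations <- function(n, n_perm, seed, exact = FALSE, strata = NULL) {
  if (exact) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    perms <- function(v) {
      if (length(v) <= 1) return(matrix(v, nrow = 1))
      do.call(rbind, lapply(seq_along(v), function(i)
        cbind(v[i], perms(v[-i]))))
    }
    return(perms(seq_len(n)))
  }
  set.seed(seed_stream(seed, 0L))
  t(vapply(seq_len(n_perm), function(b) {
    if (is.null(strata)) sample.int(n)
    else {
      idx <- seq_len(n)
      for (s in unique(strata)) {
        w <- which(strata == s)
        idx[w] <- w[sample.int(length(w))]
      }
      idx
    }
  }, integer(n)))
}

perm_pvalue <- function(obs, permuted, exact, lower = FALSE) {
  hits <- if (lower) sum(permuted <= obs + 1e-12)
          else sum(permuted >= obs - 1e-12)
  if (exact) hits / length(permuted)
  else (1 + hits) / (1 + length(permuted))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix: the total sum of squared
#' distances is partitioned into within- and among-group parts,
#'   SS_total = sum_{i<j} d_ij^2 / n,
#'   SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g,
#' and the pseudo-F statistic
#'   F = ((SS_total - SS_within) / (a - 1)) / (SS_within / (n - a))
#' is compared to its distribution under permutation of group labels.
#' p = (1 + #permuted >= observed) / (1 + n_perm), never exactly 0.
#'
#' @param dm a [dist_matrix()].
#' @param groups factor of group labels, in `dm` sample order.
#' @param n_perm number of random permutations (ignored when `exact`).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all label permutations (n <= 8); p is then the
#'   exact fraction of arrangements at least as extreme (observed
#'   included).
#' @param strata optional factor; permutations are restricted to shuffle
#'   labels within strata (e.g. tanks).
#' @return A `perm_test` result (statistic, p_value, permuted_stats).
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1L, exact = FALSE,
                      strata = NULL) {
  groups <- check_groups(dm, groups)
  D2 <- unclass(dm)^2
  n <- nrow(D2)
  a <- nlevels(groups)
  ss_tot <- sum(D2) / (2 * n)
  fstat <- function(idx) {
    g <- groups[idx]
    ss_w <- 0
    for (lev in levels(g)) {
      w <- which(g == lev)
      ss_w <- ss_w + sum(D2[w, w]) / (2 * length(w))
    }
    ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  obs <- fstat(seq_len(n))
  P <- make_permutations(n, n_perm, seed, exact, strata)
  permuted <- apply(P, 1, fstat)
  perm_result("pseudo-F", obs, perm_pvalue(obs, permuted, exact),
              nrow(P), permuted, levels(groups))
}

#' Multi-response permutation procedure (MRPP)
#'
#' The observed statistic is the group-size-weighted mean within-group
#' distance, delta = sum_g (n_g / n) * mean d(i, j | i, j in g); small
#' delta means tight groups, so significance is the lower tail of the
#' permutation distribution. The chance-corrected effect size is
#' A = 1 - delta_obs / mean(delta_perm).
#'
#' @inheritParams permanova
#' @return A `perm_test` result; `$A` holds the chance-corrected effect
#'   size and `$statistic` the observed delta.
#' @export
mrpp <- function(dm, groups, n_perm = 999, seed = 1L, exact = FALSE,
                 strata = NULL) {
  groups <- check_groups(dm, groups)
  D <- unclass(dm)
  n <- nrow(D)
  wts <- table(groups) / n
  delta <- function(idx) {
    g <- groups[idx]
    s <- 0
    for (lev in levels(g)) {
      w <- which(g == lev)
      ng <- length(w)
      s <- s + wts[[lev]] * sum(D[w, w]) / (ng * (ng - 1))
    }
    s
  }
  obs <- delta(seq_len(n))
  P <- make_permutations(n, n_perm, seed, exact, strata)
  permuted <- apply(P, 1, delta)
  res <- perm_result("MRPP delta", obs,
                     perm_pvalue(obs, permuted, exact, lower = TRUE),
                     nrow(P), permuted, levels(groups))
  res$A <- 1 - obs / mean(permuted)
  res
}

#' Principal coordinates analysis with negative-eigenvalue bookkeeping
#'
#' Eigendecomposition of the Gower-centered matrix B = -J D^2 J / 2.
#' Axes with negative eigenvalues (non-Euclidean distances) are retained
#' and flagged imaginary: squared distances are then reconstructed as the
#' difference of real-axis and imaginary-axis squared coordinate gaps.
#'
#' @param dm a [dist_matrix()].
#' @param tol relative eigenvalue magnitude below which an axis is
#'   treated as null and dropped.
#' @return List: `points` (n x k coordinate matrix, columns scaled by
#'   sqrt(|eigenvalue|)), `eig` (kept eigenvalues), `imaginary` (logical
#'   per axis).
#' @export
pcoa <- function(dm, tol = 1e-9) {
  D <- unclass(dm)
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix not symmetric")
  n <- nrow(D)
  A <- -0.5 * D^2
  B <- A - rowMeans(A)
  B <- t(t(B) - colMeans(B))   # = A - row means - col means + grand mean
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values), 1e-300)
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  pts <- sweep(vecs, 2, sqrt(abs(vals)), `*`)
  rownames(pts) <- rownames(D)
  list(points = pts, eig = vals, imaginary = vals < 0)
}

#' Homogeneity of multivariate dispersions
#'
#' Each sample's distance to its group centroid is computed in principal
#' coordinate space, subtracting squared gaps on imaginary axes and
#' clamping at zero; the statistic is the one-way ANOVA F on those
#' distances. Significance is by permutation of group labels with the
#' whole statistic — centroids and distances — recomputed for every
#' relabeling, so the test is exact under exchangeability.
#'
#' @inheritParams permanova
#' @return A `perm_test` result; `$distances` holds the per-sample
#'   distances to group centroids.
#' @export
betadisper <- function(dm, groups, n_perm = 999, seed = 1L, exact = FALSE,
                       strata = NULL) {
  groups <- check_groups(dm, groups)
  pc <- pcoa(dm)
  pts <- pc$points
  sgn <- ifelse(pc$imaginary, -1, 1)
  n <- nrow(pts)
  disp_z <- function(g) {
    z <- numeric(n)
    for (lev in levels(g)) {
      w <- which(g == lev)
      centroid <- colMeans(pts[w, , drop = FALSE])
      d2 <- sweep(pts[w, , drop = FALSE], 2, centroid)^2 %*% sgn
      z[w] <- sqrt(pmax(0, d2))
    }
    z
  }
  anova_f <- function(vals, g) {
    gm <- mean(vals)
    ssb <- sum(tapply(vals, g, function(v) length(v) * (mean(v) - gm)^2))
    ssw <- sum(tapply(vals, g, function(v) sum((v - mean(v))^2)))
    a <- nlevels(g)
    if (ssw <= 0) return(if (ssb <= 0) 0 else Inf)
    (ssb / (a - 1)) / (ssw / (length(vals) - a))
  }
  stat <- function(idx) {
    g <- groups[idx]
    anova_f(disp_z(g), g)
  }
  z_obs <- disp_z(groups)
  obs <- anova_f(z_obs, groups)
  P <- make_permutations(n, n_perm, seed, exact, strata)
  permuted <- apply(P, 1, stat)
  res <- perm_result("dispersion F", obs, perm_pvalue(obs, permuted, exact),
                     nrow(P), permuted, levels(groups))
  res$distances <- stats::setNames(z_obs, rownames(pts))
  res
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-square p (df = groups - 1); the degenerate
#' all-tied case returns H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups factor of the same length with >= 2 levels.
#' @return List with `statistic` and `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p_value = 1))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p for small samples without ties (min n <= 8),
#' otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param x,y numeric vectors.
#' @return List with `statistic` (rank-sum W of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty input")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= 8
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p summing hypergeometric probabilities no larger than the
#' observed table's.
#'
#' @param tab 2x2 nonnegative integer matrix.
#' @return List with `odds_ratio` (conditional MLE) and `p_value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (any(tab < 0)) stop("negative entries")
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; NA entries are passed through.
#'
#' @param p numeric p-values in [0, 1].
#' @return Adjusted p-values, elementwise >= input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-taxon differential abundance between groups
#'
#' Rank tests (Wilcoxon for a two-level contrast, Kruskal-Wallis for
#' any number of levels) on relative abundances, or a Fisher exact test
#' on presence/absence, with Benjamini-Hochberg correction across taxa.
#' Every taxon yields a row; taxa a test cannot score (e.g. constant
#' zero) carry NA p-values rather than being dropped.
#'
#' @param table a [count_table()].
#' @param metadata a [sample_metadata()] covering the table's samples.
#' @param factor_name metadata column defining the groups.
#' @param contrast optional pair (or subset) of levels to compare;
#'   default all levels present.
#' @param test `"wilcoxon"`, `"kruskal"`, or `"fisher_presence"`.
#' @return data.frame: otu_id, statistic, p, p_adj.
#' @export
differential_abundance <- function(table, metadata,
                                   factor_name = "treatment",
                                   contrast = NULL,
                                   test = c("wilcoxon", "kruskal",
                                            "fisher_presence")) {
  test <- match.arg(test)
  meta <- align_metadata(metadata, table)
  g <- as.character(meta[[factor_name]])
  if (!is.null(contrast)) {
    missing_lev <- setdiff(contrast, unique(g))
    if (length(missing_lev))
      stop("contrast level(s) absent: ", paste(missing_lev, collapse = ", "))
    keep <- g %in% contrast
    table <- count_table(unclass(table)[keep, , drop = FALSE])
    g <- g[keep]
  }
  g <- factor(g)
  if (test %in% c("wilcoxon", "fisher_presence") && nlevels(g) != 2)
    stop(test, " requires exactly 2 groups; give a contrast")
  R <- relative_abundance(table)
  pres <- unclass(table) >= 1L
  res <- lapply(seq_len(ncol(R)), function(j) {
    out <- tryCatch({
      if (test == "wilcoxon") {
        r <- wilcoxon_rank_sum(R[g == levels(g)[1], j], R[g == levels(g)[2], j])
        if (length(unique(R[, j])) == 1) r <- list(statistic = r$statistic,
                                                   p_value = NA_real_)
        r
      } else if (test == "kruskal") {
        if (length(unique(R[, j])) == 1)
          list(statistic = NA_real_, p_value = NA_real_)
        else kruskal_wallis(R[, j], g)
      } else {
        tb <- table(factor(pres[, j], c(FALSE, TRUE)), g)
        f <- fisher_exact_2x2(tb)
        list(statistic = f$odds_ratio, p_value = f$p_value)
      }
    }, error = function(e) list(statistic = NA_real_, p_value = NA_real_))
    c(out$statistic, out$p_value)
  })
  res <- do.call(rbind, res)
  data.frame(otu_id = colnames(R), statistic = res[, 1], p = res[, 2],
             p_adj = bh_adjust(res[, 2]), stringsAsFactors = FALSE)
}
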