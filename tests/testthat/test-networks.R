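test_that("Spearman rho and p follow the rank formula", {
  # monotone transform preserves ranks; reversal negates rho
  tab <- count_table(rbind(a = c(1L, 2L, 3L, 4L, 5L),
                           b = c(2L, 4L, 8L, 16L, 32L),
                           c = c(5L, 4L, 3L, 2L, 1L)),
                     c("a", "b", "c"), paste0("OTU", 1:5))
  sm <- spearman_matrix(tab)
  expect_equal(sm$rho["a", "b"], 1)
  expect_equal(sm$rho["a", "c"], -1)
  expect_equal(sm$p["a", "b"], 0)

  # tie-corrected rank formula, checked by direct computation
  x <- c(1, 2, 3, 4, 5); y <- c(5, 6, 7, 8, 7)
  tab2 <- count_table(rbind(s1 = as.integer(x * 10), s2 = as.integer(y * 10)),
                      c("s1", "s2"), paste0("OTU", 1:5))
  r1 <- relative_abundance(tab2)
  hand <- stats::cor(rank(r1[1, ]), rank(r1[2, ]))
  expect_equal(spearman_matrix(tab2)$rho["s1", "s2"], hand, tolerance = 1e-12)

  expect_error(spearman_matrix(count_table(rbind(c(1L, 2L), c(2L, 1L)))),
               "at least 3")
})

test_that("edge filtering is correct, monotone, and flags undefined pairs", {
  tab <- random_table(8, 40, seed = 21)
  net_all <- build_network(tab, rho_min = 0, fdr_alpha = 1)
  expect_equal(nrow(net_all$edges), choose(8, 2))
  net_none <- build_network(tab, rho_min = 1, fdr_alpha = 0.05)
  expect_equal(nrow(net_none$edges), 0)

  # monotone: raising rho_min never adds edges
  e1 <- nrow(build_network(tab, rho_min = 0.2, fdr_alpha = 1)$edges)
  e2 <- nrow(build_network(tab, rho_min = 0.5, fdr_alpha = 1)$edges)
  e3 <- nrow(build_network(tab, rho_min = 0.8, fdr_alpha = 1)$edges)
  expect_true(e1 >= e2 && e2 >= e3)

  # two internally correlated blocks split into two components
  set.seed(22)
  base1 <- rpois(60, 20); base2 <- rpois(60, 20)
  mk <- function(base) t(sapply(1:4, function(i)
    pmax(0L, as.integer(base + rpois(60, 2) - rpois(60, 2)))))
  m <- rbind(mk(base1), mk(base2))
  tabb <- count_table(m, paste0("s", 1:8), paste0("OTU", 1:60))
  net <- build_network(tabb, rho_min = 0.5, fdr_alpha = 0.05)
  comp <- igraph::components(net$graph)
  expect_equal(comp$no, 2)
  # thresholding oracle: edges are exactly the pairs passing both filters
  sm <- spearman_matrix(tabb)
  padj <- matrix(NA_real_, 8, 8)
  padj[upper.tri(padj)] <- bh_adjust(sm$p[upper.tri(sm$p)])
  want <- sum(abs(sm$rho[upper.tri(sm$rho)]) >= 0.5 &
                padj[upper.tri(padj)] <= 0.05, na.rm = TRUE)
  expect_equal(nrow(net$edges), want)
})

test_that("betweenness matches all-pairs BFS enumeration", {
  path3 <- igraph::make_graph(~ A - B, B - C)
  bc <- betweenness_centrality(path3)
  expect_equal(unname(bc[c("A", "B", "C")]), c(0, 1, 0))
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  expect_equal(unname(betweenness_centrality(star))[1], choose(4, 2))
  expect_equal(unname(betweenness_centrality(
    igraph::make_full_graph(5))), rep(0, 5))

  for (s in 1:20) {
    set.seed(330 + s)
    n <- sample(4:8, 1)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- rbinom(choose(n, 2), 1, 0.45)
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(adj),
                 tolerance = 1e-10)
  }
})

test_that("eigenvector centrality matches dense eigen-decomposition", {
  p3 <- igraph::make_graph(~ A - B, B - C)
  ec <- eigenvector_centrality(p3)
  expect_equal(unname(ec / ec[1]), c(1, sqrt(2), 1), tolerance = 1e-6)

  ring <- igraph::make_ring(6)
  ec <- eigenvector_centrality(ring)
  expect_equal(unname(ec), rep(1 / sqrt(6), 6), tolerance = 1e-6)

  # disconnected graph: only the largest component is scored
  g2 <- igraph::make_graph(~ A - B, B - C, D - E)
  ec2 <- eigenvector_centrality(g2)
  expect_true(all(is.na(ec2[c("D", "E")])))
  expect_true(all(!is.na(ec2[c("A", "B", "C")])))

  for (s in 1:10) {
    set.seed(440 + s)
    n <- sample(5:9, 1)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- rbinom(choose(n, 2), 1, 0.6)
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    main <- which(comp$membership == which.max(comp$csize))
    sub <- adj[main, main, drop = FALSE]
    ev <- eigen(sub, symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / sqrt(sum(ev^2))
    got <- eigenvector_centrality(g)[main]
    expect_equal(unname(got), ev, tolerance = 1e-8)
  }
})

test_that("control nodes bridge diverged treatment modules", {
  # treatments drawn from source pools shifted in different directions,
  # control from the unshifted pool: in the joint network the treatment
  # samples form modules and the control sits between them, so control
  # betweenness is highest
  wins <- 0
  for (s in 1:20) {
    q0 <- make_source_pool(100, "lognormal", list(sigma = 1.5), seed = s)$q
    set.seed(s)
    mk <- function() { q <- q0 * exp(rnorm(100, 0, 1.5)); q / sum(q) }
    qcc <- mk(); qcv <- mk()
    sim1 <- function(q, sd) {
      pool <- structure(list(taxon_ids = paste0("OTU", 1:100), q = q),
                        class = "source_pool")
      unclass(simulate_neutral_community(
        pool, sim_config(100, 8, N_local = 1000, m = 0.7, depth = 1000,
                         seed = sd)))
    }
    m <- rbind(sim1(q0, 10 * s), sim1(qcc, 1000 + 10 * s),
               sim1(qcv, 2000 + 10 * s))
    rownames(m) <- paste0(rep(c("Ctrl", "CC", "CV"), each = 8), "_", 1:8)
    net <- build_network(count_table(m), rho_min = 0.5, fdr_alpha = 0.05)
    cg <- centrality_by_group(net, groups = rep(c("Ctrl", "CC", "CV"),
                                                each = 8))
    wins <- wins + (cg$median_betweenness[cg$group == "Ctrl"] >
                      max(cg$median_betweenness[cg$group != "Ctrl"]))
  }
  expect_gte(wins, 16)
})

test_that("centrality summaries compare treatments against control", {
  tab <- random_table(10, 50, seed = 61)
  net <- build_network(tab, rho_min = 0, fdr_alpha = 1)
  nets <- list(Ctrl.T3 = net, CC.T3 = net)
  smry <- centrality_shift_summary(nets)
  expect_equal(nrow(smry), 2)
  expect_equal(smry$median_betweenness[1], smry$median_betweenness[2])
  expect_gte(smry$p_vs_ctrl[2], 0.99)
  expect_true(is.na(smry$p_vs_ctrl[1]))
})
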