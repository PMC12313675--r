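test_that("top-N abundance filtering ranks totals with a lexicographic tie rule", {
  m <- rbind(S1 = c(t1 = 5, t2 = 5, t3 = 4, t4 = 1, t5 = 0),
             S2 = c(t1 = 5, t2 = 4, t3 = 4, t4 = 1, t5 = 1))
  tab <- abundance_table(m)
  top3 <- filter_top_asvs(tab, 3)
  expect_setequal(colnames(top3$counts), c("t1", "t2", "t3"))
  # tie between t2 (9) and t3 (8)? totals: t1=10, t2=9, t3=8 -> forced order
  tie <- abundance_table(rbind(S1 = c(a = 3, b = 2, zz = 2),
                               S2 = c(a = 2, b = 3, zz = 3)))
  # totals: a = 5, b = 5, zz = 5: lexicographically smaller ids win
  top2 <- filter_top_asvs(tie, 2)
  expect_setequal(colnames(top2$counts), c("a", "b"))
  expect_warning(keep_all <- filter_top_asvs(tab, 10), "keeping all")
  expect_equal(ncol(keep_all$counts), 5)
  expect_error(filter_top_asvs(tab, 1), ">= 2")
})

test_that("network edges exactly match a brute-force correlation oracle", {
  set.seed(50)
  m <- matrix(rpois(6 * 8, 20) + 1, 6, 8,
              dimnames = list(paste0("S", 1:6), paste0("t", 1:8)))
  # implant a strong positive and a strong negative pair
  m[, 2] <- m[, 1] + rpois(6, 2)
  m[, 4] <- max(m[, 3]) - m[, 3] + rpois(6, 1)
  tab <- abundance_table(m)
  net <- build_network(tab, rho_min = 0.3, p_max = 0.05)
  lm_ <- log1p(m)
  oracle <- NULL
  for (i in 1:7) for (j in (i + 1):8) {
    ct <- cor.test(lm_[, i], lm_[, j])
    if (abs(ct$estimate) > 0.3 && ct$p.value < 0.05)
      oracle <- rbind(oracle, data.frame(a = colnames(m)[i],
                                         b = colnames(m)[j],
                                         rho = unname(ct$estimate)))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(net$edges$source, net$edges$target),
                  key(oracle$a, oracle$b))
  expect_equal(sort(net$edges$rho), sort(oracle$rho), tolerance = 1e-12)
})

test_that("edge sets shrink monotonically as thresholds tighten", {
  set.seed(51)
  m <- matrix(rpois(8 * 12, 15), 8, 12,
              dimnames = list(paste0("S", 1:8), paste0("t", 1:12)))
  tab <- abundance_table(m + 1)
  key <- function(net) paste(net$edges$source, net$edges$target)
  loose <- build_network(tab, rho_min = 0.2, p_max = 0.2)
  mid <- build_network(tab, rho_min = 0.5, p_max = 0.2)
  strict <- suppressWarnings(build_network(tab, rho_min = 0.5, p_max = 0.02))
  expect_true(all(key(mid) %in% key(loose)))
  expect_true(all(key(strict) %in% key(mid)))
  expect_warning(build_network(tab, rho_min = 0.999), "empty")
  expect_error(build_network(abundance_table(m[1:2, ] + 1)), "3 samples")
})

test_that("identical abundance profiles always produce an edge", {
  m <- rbind(S1 = c(a = 1, b = 1, c = 9), S2 = c(a = 5, b = 5, c = 2),
             S3 = c(a = 2, b = 2, c = 7), S4 = c(a = 8, b = 8, c = 1),
             S5 = c(a = 3, b = 3, c = 5), S6 = c(a = 6, b = 6, c = 9))
  net <- build_network(abundance_table(m))
  e <- net$edges
  hit <- (e$source == "a" & e$target == "b") | (e$source == "b" & e$target == "a")
  expect_true(any(hit))
  expect_equal(e$rho[hit], 1)
})

test_that("topology metrics match closed forms on K_n, S_n, P_n and C_n", {
  for (n in 3:8) {
    k <- topology_metrics(graph_complete(n))
    expect_equal(k$n_edges, n * (n - 1) / 2)
    expect_equal(k$connectance, 1)
    expect_equal(k$avg_degree, n - 1)
    expect_equal(k$gcc, 1); expect_equal(k$acc, 1)
    expect_equal(k$cd, 0)
    expect_equal(k$ec, 0, tolerance = 1e-8)
    expect_equal(k$an, n - 1)

    s <- topology_metrics(graph_star(n))
    expect_equal(s$n_edges, n - 1)
    expect_equal(s$connectance, 2 / n)
    expect_equal(s$gcc, 0); expect_equal(s$acc, 0)
    expect_equal(s$cd, 1)
    expect_equal(s$ec, 1, tolerance = 1e-8)

    p <- topology_metrics(graph_path(n))
    expect_equal(p$n_edges, n - 1)
    expect_equal(p$avg_degree, 2 * (n - 1) / n)
    expect_equal(p$gcc, 0); expect_equal(p$acc, 0)
    expect_equal(p$cd, 2 / ((n - 1) * (n - 2)))

    if (n >= 4) {
      cy <- topology_metrics(graph_cycle(n))
      expect_equal(cy$n_edges, n)
      expect_equal(cy$avg_degree, 2)
      expect_equal(cy$gcc, 0); expect_equal(cy$acc, 0)
      expect_equal(cy$cd, 0)
      expect_equal(cy$an, 2)
    }
  }
})

test_that("average neighborhood connectivity matches the P3 enumeration", {
  # path a-b-c: ends see degree 2, the middle sees mean(1, 1) = 1 -> wait:
  # neighbor-degree means are (2, 1, 2)/... ends' neighbour is b (deg 2);
  # b's neighbours are a and c (deg 1 each) -> mean 1; AN = (2 + 1 + 2)/3
  expect_equal(topology_metrics(graph_path(3))$an, 5 / 3)
})

test_that("Louvain modules are deterministic with hand-checkable modularity", {
  g <- igraph::disjoint_union(graph_complete(3), graph_complete(3))
  igraph::V(g)$name <- paste0("t", 1:6)
  mod <- louvain_modules(g, seed = 3, min_module_size = 3)
  expect_equal(length(mod$sizes), 2)
  expect_equal(mod$modularity, 0.5)    # 2 * (1/2 - 1/4)
  expect_equal(mod$large_modules, 1:2)
  k4 <- graph_complete(4); igraph::V(k4)$name <- paste0("t", 1:4)
  expect_equal(length(louvain_modules(k4, seed = 1)$sizes), 1)
  mod2 <- louvain_modules(g, seed = 3, min_module_size = 3)
  expect_identical(mod$membership, mod2$membership)
  # reported Q equals the modularity formula on the returned partition
  expect_equal(mod$modularity,
               igraph::modularity(g, mod$membership))
  expect_true(mod$modularity >= -0.5 && mod$modularity <= 1)
  expect_error(louvain_modules(igraph::make_empty_graph(3, directed = FALSE)),
               "no edges")
})

test_that("cohesion signs, block structure and equivariance behave as built", {
  set.seed(52)
  # one tightly co-varying block (a1-a3) against an incoherent block (b1-b3)
  x <- c(10, 2, 9, 1, 8, 2, 9, 1)
  m <- cbind(a1 = x, a2 = 2 * x, a3 = 3 * x,
             b1 = sample(x), b2 = sample(x), b3 = sample(x))
  rownames(m) <- paste0("S", 1:8)
  tab <- abundance_table(m)
  coh <- cohesion(tab, n_null = 200, seed = 5)
  expect_true(all(coh$samples$positive_cohesion >= 0))
  expect_true(all(coh$samples$negative_cohesion <= 0))
  # samples dominated by the coherent block are more positively cohesive
  ra <- rel_abund(tab)
  dominance <- rowSums(ra[, 1:3])
  expect_gt(cor(dominance, coh$samples$positive_cohesion), 0.8)
  # permutation equivariance (up to Monte-Carlo error in the null)
  perm <- c(3, 1, 4, 2, 8, 5, 7, 6)
  coh_p <- cohesion(abundance_table(m[perm, ]), n_null = 600, seed = 6)
  reord <- match(coh$samples$sample[perm], coh_p$samples$sample)
  expect_equal(coh_p$samples$positive_cohesion[reord],
               cohesion(tab, n_null = 600, seed = 7)$samples$positive_cohesion[perm],
               tolerance = 0.05)
})

test_that("near-independent taxa yield near-zero cohesion", {
  # wide table so the compositional-closure bias -1/(k-1) is negligible
  set.seed(53)
  m <- matrix(rpois(200 * 60, 10) + 1, nrow = 200)
  coh <- cohesion(make_table(m), n_null = 60, seed = 1)
  expect_lt(max(abs(coh$samples$positive_cohesion)), 0.15)
  expect_lt(max(abs(coh$samples$negative_cohesion)), 0.15)
})

test_that("complexity scores min-max standardise across the network set", {
  metrics <- data.frame(n_nodes = c(10, 20, 30), n_edges = c(5, 25, 45),
                        gcc = c(0.1, 0.5, 0.3), cd = c(1, 1, 1))
  expect_warning(cx <- complexity_index(metrics,
                                        properties = names(metrics)), "cd")
  expect_equal(cx$complexity[3], mean(c(1, 1, 0.5)))
  expect_equal(cx$complexity[1], 0)       # minimal in every used property
  expect_equal(cx$n_edges, c(0, 0.5, 1))
  # affine rescaling of one property leaves scores unchanged
  metrics2 <- metrics
  metrics2$gcc <- 100 * metrics2$gcc - 3
  expect_warning(cx2 <- complexity_index(metrics2,
                                         properties = names(metrics)), "cd")
  expect_equal(cx2$complexity, cx$complexity)
  expect_error(complexity_index(metrics[1, , drop = FALSE]), ">= 2")
})

test_that("module-environment correlations recover exact dependencies", {
  set.seed(54)
  m <- matrix(rpois(8 * 6, 10) + 1, 8, 6,
              dimnames = list(paste0("S", 1:8), paste0("t", 1:6)))
  tab <- abundance_table(m)
  modules <- stats::setNames(c(1, 1, 1, 2, 2, 2), colnames(m))
  ra <- rel_abund(tab)
  env <- data.frame(mirror = rowSums(ra[, 1:3]), noise = rnorm(8),
                    row.names = rownames(m))
  res <- module_env_correlation(modules, tab, env, min_module_size = 3)
  hit <- res[res$module == "1" & res$variable == "mirror", ]
  expect_equal(hit$r, 1, tolerance = 1e-12)
  expect_equal(res$p_adj, bh_adjust(res$p))
  expect_error(module_env_correlation(modules, tab, env,
                                      min_module_size = 10), "min_module_size")
})
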