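test_that("betaMNTD matches the hand-evaluated four-tip case", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- rbind(S1 = c(A = 10, B = 0, C = 0, D = 0),
             S2 = c(A = 0, B = 0, C = 5, D = 5))
  tab <- abundance_table(m)
  expect_equal(as.matrix(beta_mntd(tab, tree))["S1", "S2"], 4)
  expect_equal(as.matrix(beta_mntd(tab, tree, weighted = FALSE))["S1", "S2"],
               4)   # uniform abundances: weighting is degenerate here
  ident <- abundance_table(rbind(S1 = c(A = 3, B = 0, C = 0, D = 0),
                                 S2 = c(A = 7, B = 0, C = 0, D = 0)))
  expect_equal(as.matrix(beta_mntd(ident, tree))["S1", "S2"], 0)
})

test_that("betaMNTD agrees with an independent R reference and picante", {
  set.seed(40)
  tr <- simulate_tree(20, seed = 41)
  m <- matrix(rpois(5 * 20, 2), 5, 20,
              dimnames = list(paste0("S", 1:5), tr$tip.label))
  m[rowSums(m) == 0, 1] <- 1
  tab <- abundance_table(m)
  mine <- as.matrix(beta_mntd(tab, tr))
  ref <- bmntd_ref(m, ape::cophenetic.phylo(tr))
  expect_equal(mine, ref, tolerance = 1e-12)
  pic <- as.matrix(picante::comdistnt(m, ape::cophenetic.phylo(tr),
                                      abundance.weighted = TRUE))
  expect_equal(mine, pic[rownames(mine), colnames(mine)], tolerance = 1e-12)
  expect_true(isSymmetric(mine))
  expect_true(all(mine >= 0))
})

test_that("taxa missing from the tree are reported", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- rbind(S1 = c(A = 1, X = 2), S2 = c(A = 2, X = 1))
  colnames(m) <- c("A", "X")
  expect_error(beta_mntd(abundance_table(m), tree), "X")
})

test_that("Monte-Carlo betaNTI null matches exhaustive tip relabelling", {
  tree <- ape::read.tree(text = "((A:1,B:2):0.5,(C:0.7,D:1.4):1);")
  m <- rbind(S1 = c(A = 6, B = 3, C = 0, D = 0),
             S2 = c(A = 0, B = 2, C = 5, D = 1))
  tab <- abundance_table(m)
  exact <- bnti_null_exhaustive(m, tree)
  mc <- bnti(tab, tree, n_null = 8000, seed = 7)
  expect_equal(mc$null_mean, unname(exact["mean"]), tolerance = 0.02)
  expect_equal(mc$null_sd, unname(exact["sd"]), tolerance = 0.02)
})

test_that("a star phylogeny degenerates the null and flags NA", {
  star <- ape::stree(4, type = "star")
  star$edge.length <- rep(1, 4)
  star$tip.label <- LETTERS[1:4]
  m <- rbind(S1 = c(A = 3, B = 1, C = 0, D = 0),
             S2 = c(A = 0, B = 0, C = 2, D = 2))
  expect_warning(res <- bnti(abundance_table(m), star, n_null = 99, seed = 1),
                 "degenerate")
  expect_true(is.na(res$bnti))
})

test_that("Raup-Crick stays in [-1, 1] and pins identical samples near -1", {
  set.seed(42)
  m <- matrix(rpois(6 * 12, 3), 6, 12)
  m[rowSums(m) == 0, 1] <- 1
  rc <- raup_crick_bray(make_table(m), n_null = 199, seed = 2)
  expect_true(all(rc$rc_bray >= -1 & rc$rc_bray <= 1))
  dup <- make_table(rbind(m[1, ], m[1, ], m[2, ]))
  rc_dup <- raup_crick_bray(dup, n_null = 199, seed = 3)
  expect_lt(rc_dup$rc_bray[1], -0.9)     # BC_obs = 0: ties only
  expect_error(raup_crick_bray(make_table(matrix(c(0.5, 1, 2, 3), 2, 2)),
                               n_null = 99), "integer")
})

test_that("Raup-Crick converges to the exhaustive enumeration on a tiny table", {
  m <- rbind(S1 = c(3, 2, 0), S2 = c(0, 4, 2))
  colnames(m) <- c("a", "b", "c")
  exact <- rc_bray_exact(m)
  mc <- raup_crick_bray(abundance_table(m), n_null = 4999, seed = 11)
  expect_equal(mc$rc_bray, exact, tolerance = 0.05)
})

test_that("process classification reproduces the five published rules", {
  expect_equal(classify_assembly_process(1.0, 0.99), "dispersal_limitation")
  expect_equal(classify_assembly_process(-1.0, -0.99), "homogenizing_dispersal")
  expect_equal(classify_assembly_process(0.5, 0.2), "undominated")
  expect_equal(classify_assembly_process(-2.5, 0), "homogeneous_selection")
  expect_equal(classify_assembly_process(2.5, 0), "heterogeneous_selection")
  # boundary: |bnti| = 2 counts as selection; |rc| = 0.95 falls to undominated
  expect_equal(classify_assembly_process(2, 0), "heterogeneous_selection")
  expect_equal(classify_assembly_process(-2, 0), "homogeneous_selection")
  expect_equal(classify_assembly_process(0, 0.95), "undominated")
  expect_true(is.na(classify_assembly_process(NA, 0.5)))
  # the literal methods-text convention swaps the selection subtypes
  expect_equal(classify_assembly_process(-2.5, 0, "inverted"),
               "heterogeneous_selection")
  expect_equal(classify_assembly_process(2.5, 0, "inverted"),
               "homogeneous_selection")
})

test_that("process fractions normalise within groups and handle NA pairs", {
  pairs <- data.frame(
    sample_a = c("a1", "a1", "a2", "b1", "b1", "b2", "a1"),
    sample_b = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"),
    process = c("homogeneous_selection", "homogeneous_selection",
                "homogeneous_selection", "undominated",
                "dispersal_limitation", NA, "undominated"))
  groups <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  fr <- process_fractions(pairs, groups)
  a <- fr[fr$group == "A", ]
  expect_equal(a$fraction[a$process == "homogeneous_selection"], 1)
  expect_equal(sum(a$fraction), 1)
  b <- fr[fr$group == "B", ]
  expect_equal(sum(b$fraction), 1)
  expect_equal(unique(b$n_na), 1)
  expect_equal(unique(b$n_pairs), 2)      # cross-group pair a1-b1 excluded
  all_na <- data.frame(sample_a = "x1", sample_b = "x2",
                       process = NA_character_)
  expect_error(process_fractions(all_na, c(x1 = "X", x2 = "X")),
               "no classifiable")
})

test_that("opposed environments recover heterogeneous selection between groups", {
  tr <- simulate_tree(150, seed = 61)
  trt <- simulate_trait(tr, 1, seed = 62)
  sc <- sim_scenario("filtering", n_taxa = 150, n_samples = 8, depth = 6000,
                     niche_breadth = 0.5, env_optima = rep(c(-2, 2), each = 4),
                     seed = 63)
  asm <- assemble_communities(sc, tr, trt)
  b <- bnti(asm$table, tr, n_null = 199, seed = 64)
  ga <- rep(c("A", "B"), each = 4)[match(b$sample_a, sample_ids(asm$table))]
  gb <- rep(c("A", "B"), each = 4)[match(b$sample_b, sample_ids(asm$table))]
  between <- b$bnti[ga != gb]
  expect_gt(mean(between > 2), 0.7)
})

test_that("shared-environment filtering shifts betaNTI below the neutral regime", {
  tr <- simulate_tree(200, seed = 71)
  trt <- simulate_trait(tr, 1, seed = 72)
  scf <- sim_scenario("filtering", n_taxa = 200, n_samples = 8, depth = 8000,
                      niche_breadth = 0.5, env_optima = 0, seed = 73)
  scn <- sim_scenario("neutral", n_taxa = 200, n_samples = 8, depth = 8000,
                      seed = 74)
  bf <- bnti(assemble_communities(scf, tr, trt)$table, tr, n_null = 199,
             seed = 75)
  bn <- bnti(assemble_communities(scn, tr, trt)$table, tr, n_null = 199,
             seed = 76)
  expect_lt(mean(bf$bnti, na.rm = TRUE), mean(bn$bnti, na.rm = TRUE))
})

test_that("neutral assembly is classified as predominantly stochastic", {
  tr <- simulate_tree(200, seed = 81)
  trt <- simulate_trait(tr, 1, seed = 82)
  sc <- sim_scenario("neutral", n_taxa = 200, n_samples = 8, depth = 8000,
                     seed = 83)
  asm <- assemble_communities(sc, tr, trt)
  res <- assembly_analysis(asm$table, tr, n_null = 199, seed = 84)
  stoch <- c("dispersal_limitation", "homogenizing_dispersal", "undominated")
  fr <- res$fractions
  expect_gte(sum(fr$fraction[fr$process %in% stoch]), 0.6)
  expect_equal(sum(fr$fraction), 1)
})
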