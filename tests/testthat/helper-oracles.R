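# Independent oracles and fixture builders used across the suite.

# quick abundance table from a bare matrix
make_table <- function(m, groups = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("T%04d", seq_len(ncol(m)))
  abundance_table(m, groups = groups)
}

# pure-R reference betaMNTD, written directly from the definition (loops,
# no shared code with the Rcpp kernel)
bmntd_ref <- function(counts, dmat, weighted = TRUE) {
  ra <- sweep(counts, 1, rowSums(counts), "/")
  ns <- nrow(counts)
  out <- matrix(0, ns, ns, dimnames = list(rownames(counts), rownames(counts)))
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    if (a >= b) next
    pa <- colnames(counts)[counts[a, ] > 0]
    pb <- colnames(counts)[counts[b, ] > 0]
    half <- function(from, to, s) {
      v <- vapply(from, function(i) min(dmat[i, to]), numeric(1))
      w <- if (weighted) ra[s, from] else rep(1 / length(from), length(from))
      w <- w / sum(w)
      sum(w * v)
    }
    out[a, b] <- out[b, a] <- 0.5 * (half(pa, pb, a) + half(pb, pa, b))
  }
  out
}

# all permutations of 1..n (n small)
perms_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exhaustive betaNTI null (tip relabelling) for a 2-sample table on a small
# tree: mean and sd of betaMNTD over all tip permutations
bnti_null_exhaustive <- function(counts, tree, weighted = TRUE) {
  dmat <- ape::cophenetic.phylo(tree)
  tips <- tree$tip.label
  P <- perms_all(length(tips))
  vals <- apply(P, 1, function(p) {
    dp <- dmat[p, p]
    dimnames(dp) <- list(tips, tips)
    bmntd_ref(counts, dp, weighted)[1, 2]
  })
  # population sd: every permutation is an equally weighted outcome
  c(mean = mean(vals), sd = sqrt(mean((vals - mean(vals))^2)))
}

# --- exhaustive Raup-Crick oracle for tiny tables (<= 3 taxa) --------------

# probability of drawing `subset` (unordered) sequentially without
# replacement with weights w
subset_prob <- function(subset, w) {
  k <- length(subset)
  P <- perms_all(k)
  tot <- 0
  for (r in seq_len(nrow(P))) {
    ord <- subset[P[r, ]]
    rem <- sum(w)
    pr <- 1
    for (i in ord) {
      pr <- pr * w[i] / rem
      rem <- rem - w[i]
    }
    tot <- tot + pr
  }
  tot
}

# all compositions of n into k non-negative parts
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  do.call(rbind, lapply(0:n, function(i) {
    cbind(i, compositions(n - i, k - 1))
  }))
}

# full null distribution (value, prob) of one null sample's count vector
null_sample_dist <- function(richness, depth, occ_w, gamma_w) {
  n_taxa <- length(occ_w)
  subsets <- utils::combn(n_taxa, richness, simplify = FALSE)
  out <- list()
  for (sub in subsets) {
    ps <- subset_prob(sub, occ_w)
    extra <- depth - richness
    comps <- compositions(extra, richness)
    q <- gamma_w[sub] / sum(gamma_w[sub])
    for (r in seq_len(nrow(comps))) {
      x <- numeric(n_taxa)
      x[sub] <- 1 + comps[r, ]
      pc <- stats::dmultinom(comps[r, ], size = extra, prob = q)
      out[[length(out) + 1]] <- list(x = x, p = ps * pc)
    }
  }
  out
}

bray_curtis_vec <- function(x, y) {
  rx <- x / sum(x); ry <- y / sum(y)
  sum(abs(rx - ry)) / sum(rx + ry)
}

# exact rc_bray for a 2-sample table by enumerating the joint null
rc_bray_exact <- function(counts) {
  occ <- colSums(counts > 0)
  gam <- colSums(counts)
  bc_obs <- bray_curtis_vec(counts[1, ], counts[2, ])
  d1 <- null_sample_dist(sum(counts[1, ] > 0), sum(counts[1, ]), occ, gam)
  d2 <- null_sample_dist(sum(counts[2, ] > 0), sum(counts[2, ]), occ, gam)
  p_less <- 0; p_eq <- 0
  for (a in d1) for (b in d2) {
    bc <- bray_curtis_vec(a$x, b$x)
    pr <- a$p * b$p
    if (bc < bc_obs - 1e-12) p_less <- p_less + pr
    else if (abs(bc - bc_obs) <= 1e-12) p_eq <- p_eq + pr
  }
  unname(2 * (p_less + 0.5 * p_eq) - 1)
}

# closed-form test graphs
graph_complete <- function(n) igraph::make_full_graph(n)
graph_star <- function(n) igraph::make_star(n, mode = "undirected")
graph_path <- function(n) igraph::make_ring(n, circular = FALSE)
graph_cycle <- function(n) igraph::make_ring(n, circular = TRUE)
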