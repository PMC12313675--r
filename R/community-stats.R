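#' Alpha diversity per sample
#'
#' Richness (taxa with count > 0), bias-corrected Chao1
#' `S + F1(F1-1)/(2(F2+1))` (F1, F2 = singletons/doubletons; the correction
#' keeps F2 = 0 well-defined), Shannon entropy in nats, and Pielou evenness
#' `H / ln(richness)` (0 when richness <= 1).
#'
#' @param table an [abundance_table()]; Chao1 requires integer counts.
#' @param chao1_classic use the classic estimator `S + F1^2/(2 F2)` instead of
#'   the bias-corrected form (errors on F2 = 0 avoided by falling back to the
#'   corrected form with a warning).
#' @return data.frame: sample, richness, chao1, shannon, pielou.
#' @export
alpha_diversity <- function(table, chao1_classic = FALSE) {
  cts <- table$counts
  zero <- rownames(cts)[rowSums(cts) == 0]
  if (length(zero))
    stop("all-zero sample(s): ", paste(zero, collapse = ", "), call. = FALSE)
  if (any(cts != round(cts)))
    stop("Chao1 requires integer counts", call. = FALSE)
  res <- do.call(rbind, lapply(rownames(cts), function(s) {
    x <- cts[s, ]
    x <- x[x > 0]
    S <- length(x)
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    chao1 <- if (chao1_classic && f2 > 0) S + f1^2 / (2 * f2)
             else S + f1 * (f1 - 1) / (2 * (f2 + 1))
    p <- x / sum(x)
    shannon <- -sum(p * log(p))
    pielou <- if (S > 1) shannon / log(S) else 0
    data.frame(sample = s, richness = S, chao1 = chao1, shannon = shannon,
               pielou = pielou, row.names = NULL, stringsAsFactors = FALSE)
  }))
  res
}

#' Bray-Curtis dissimilarity matrix
#'
#' `sum |x - y| / sum (x + y)` over taxa, on relative abundances by default.
#'
#' @param table an [abundance_table()].
#' @param relative row-normalise before computing (default `TRUE`).
#' @return a `dist` object over samples, entries in `[0, 1]`.
#' @export
bray_curtis <- function(table, relative = TRUE) {
  m <- if (relative) rel_abund(table) else table$counts
  if (any(rowSums(m) == 0))
    stop("all-zero sample(s) make Bray-Curtis undefined", call. = FALSE)
  vegan::vegdist(m, method = "bray")
}

as_dist_matrix <- function(d, name) {
  if (inherits(d, "dist")) return(as.matrix(d))
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
    stop(sprintf("`%s` must be a symmetric distance matrix", name),
         call. = FALSE)
  d
}

check_dist_pair <- function(a, b) {
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!identical(rownames(a), rownames(b))) {
      if (!setequal(rownames(a), rownames(b)))
        stop("distance matrices have different sample sets", call. = FALSE)
      b <- b[rownames(a), rownames(a)]
    }
  }
  b
}

#' Mantel test
#'
#' Pearson correlation between the lower triangles of two distance matrices;
#' one-sided (greater) permutation p-value
#' `(1 + #\{r_perm >= r_obs\}) / (1 + n_perm)` under simultaneous row/column
#' permutation.
#'
#' @param dist_a,dist_b `dist` objects or symmetric matrices over the same
#'   samples.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = NULL) {
  a <- as_dist_matrix(dist_a, "dist_a")
  b <- check_dist_pair(a, as_dist_matrix(dist_b, "dist_b"))
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  if (sd(lower_tri(a)) == 0 || sd(lower_tri(b)) == 0)
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  fit <- with_seed(seed,
    vegan::mantel(as.dist(a), as.dist(b), method = "pearson",
                  permutations = n_perm))
  list(r = unname(fit$statistic), p = fit$signif, n_perm = n_perm)
}

#' Partial Mantel test
#'
#' Correlates the residuals of `dist_a` and `dist_b` after linear regression
#' of each lower triangle on that of `dist_c`; significance by simultaneous
#' row/column permutation of `dist_a` (one-sided, greater).  Degenerate cases
#' are defined explicitly: a constant `dist_c` reduces to the plain Mantel
#' test, and a residual vector with (near-)zero variance gives r = 0.
#'
#' @inheritParams mantel_test
#' @param dist_c the control distance matrix.
#' @return list with `r`, `p`, `n_perm`.
#' @export
partial_mantel <- function(dist_a, dist_b, dist_c, n_perm = 999, seed = NULL) {
  a <- as_dist_matrix(dist_a, "dist_a")
  b <- check_dist_pair(a, as_dist_matrix(dist_b, "dist_b"))
  cc <- check_dist_pair(a, as_dist_matrix(dist_c, "dist_c"))
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  va <- lower_tri(a); vb <- lower_tri(b); vc <- lower_tri(cc)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  if (sd(vc) == 0)
    return(mantel_test(a, b, n_perm = n_perm, seed = seed))
  res_b <- stats::residuals(stats::lm(vb ~ vc))
  partial_r <- function(va_perm) {
    res_a <- stats::residuals(stats::lm(va_perm ~ vc))
    if (sd(res_a) < 1e-12 || sd(res_b) < 1e-12) return(0)
    cor(res_a, res_b)
  }
  r_obs <- partial_r(va)
  n <- nrow(a)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    partial_r(lower_tri(a[idx, idx]))
  }, numeric(1)))
  list(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
       n_perm = n_perm)
}

#' One-way PERMANOVA (distance-based)
#'
#' Pseudo-F from the Gower-centred partition of a distance matrix by a single
#' grouping factor, with a permutation p-value (label permutation, ties
#' counted as extreme).
#'
#' @param dist a `dist` or symmetric distance matrix.
#' @param labels group labels, one per sample; >= 2 groups, each of size >= 2.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list with `pseudo_f`, `r2`, `p`.
#' @export
permanova <- function(dist, labels, n_perm = 999, seed = NULL) {
  d <- as_dist_matrix(dist, "dist")
  labels <- as.factor(as.character(labels))
  if (length(labels) != nrow(d))
    stop("labels must match the number of samples", call. = FALSE)
  if (nlevels(labels) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("every group needs at least 2 samples", call. = FALSE)
  df <- data.frame(grp = labels)
  fit <- with_seed(seed,
    vegan::adonis2(as.dist(d) ~ grp, data = df, permutations = n_perm))
  list(pseudo_f = fit$F[1], r2 = fit$R2[1], p = fit$`Pr(>F)`[1])
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment preserving input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the same order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Pearson correlation with a t-distribution p-value
#'
#' Two-sided p from `t = r sqrt((n-2)/(1-r^2))` with `n - 2` df, on
#' pairwise-complete observations.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs.
#' @return list with `rho`, `p`, `n` (complete pairs used).
#' @export
pearson_with_p <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 pairwise-complete observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mantel tests of a community distance against each environment variable
#'
#' For each numeric environment variable, builds a Euclidean distance on the
#' (optionally z-scored) variable and Mantel-tests it against the community
#' distance matrix; BH adjustment across the variable family.
#'
#' @param comm_dist community `dist` (e.g. [bray_curtis()]), labelled by
#'   sample.
#' @param env data.frame of numeric variables, row names = sample ids.
#' @param n_perm permutations per test.
#' @param seed optional integer seed.
#' @param scale_env z-score variables before the Euclidean distance.
#' @return data.frame: variable, r, p, p_adj.
#' @export
mantel_env_screen <- function(comm_dist, env, n_perm = 999, seed = NULL,
                              scale_env = TRUE) {
  dm <- as_dist_matrix(comm_dist, "comm_dist")
  ids <- rownames(dm)
  if (!all(ids %in% rownames(env)))
    stop("env table is missing sample(s): ",
         paste(setdiff(ids, rownames(env)), collapse = ", "), call. = FALSE)
  env <- env[ids, , drop = FALSE]
  env <- env[, vapply(env, is.numeric, logical(1)), drop = FALSE]
  if (!ncol(env)) stop("no numeric environment variables", call. = FALSE)
  out <- do.call(rbind, lapply(seq_along(env), function(j) {
    v <- env[[j]]
    if (sd(v, na.rm = TRUE) == 0 || sum(!is.na(v)) < 3)
      return(data.frame(variable = names(env)[j], r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    vv <- if (scale_env) as.numeric(scale(v)) else v
    dv <- as.matrix(stats::dist(vv))
    dimnames(dv) <- list(ids, ids)
    fit <- mantel_test(dm, dv, n_perm = n_perm,
                       seed = derive_seed(seed, j))
    data.frame(variable = names(env)[j], r = fit$r, p = fit$p,
               stringsAsFactors = FALSE)
  }))
  ok <- !is.na(out$p)
  out$p_adj <- NA_real_
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  out
}
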