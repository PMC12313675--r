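#' Keep the most abundant taxa
#'
#' Subsets an abundance table to the `n_top` taxa with the highest total
#' abundance across its samples (the paper-style top-700 bacteria / top-300
#' fungi pre-filter before network construction).  Ties at the cutoff are
#' broken towards the lexicographically smaller taxon id.
#'
#' @param table an [abundance_table()].
#' @param n_top number of taxa to keep (>= 2).
#' @return an [abundance_table()] restricted to the selected taxa; if the
#'   table has fewer taxa than `n_top`, all are kept with a warning.
#' @export
filter_top_asvs <- function(table, n_top) {
  if (n_top < 2) stop("n_top must be >= 2", call. = FALSE)
  totals <- colSums(table$counts)
  ord <- order(-totals, colnames(table$counts))
  if (n_top >= length(totals)) {
    if (n_top > length(totals))
      warning("table has only ", length(totals), " taxa; keeping all",
              call. = FALSE)
    return(table)
  }
  keep <- colnames(table$counts)[ord[seq_len(n_top)]]
  subset_table(table, taxa = keep)
}

new_cooc_network <- function(graph, edges, params = NULL) {
  structure(list(graph = graph, edges = edges,
                 nodes = if (igraph::vcount(graph)) igraph::V(graph)$name
                         else character(0),
                 params = params),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges (%d positive, %d negative)\n",
              igraph::vcount(x$graph), nrow(x$edges),
              sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Build a thresholded Pearson co-occurrence network
#'
#' Pairwise Pearson correlations of (by default log(1+x)-transformed) taxon
#' abundance vectors across samples; an undirected edge is kept iff
#' `|rho| > rho_min` and `p < p_max` (two-sided t-distribution p).  The sign
#' of each edge is stored; isolated nodes are dropped; zero-variance taxa are
#' skipped with a message.
#'
#' @param table an [abundance_table()], typically after [filter_top_asvs()].
#' @param rho_min correlation-magnitude threshold in `[0, 1)` (default 0.3).
#' @param p_max p-value threshold in `(0, 1]` (default 0.05).
#' @param transform `"log1p"` (default, natural log of count + 1),
#'   `"relative"`, or `"none"`.
#' @param positive_only keep only positive correlations (the literal reading
#'   of a "rho > rho_min" criterion); default `FALSE` keeps both signs.
#' @return a `cooc_network`: igraph graph (edge attributes rho, p, sign,
#'   weight = |rho|; node attribute degree), an edge data.frame and the
#'   provenance parameters.
#' @export
build_network <- function(table, rho_min = 0.3, p_max = 0.05,
                          transform = c("log1p", "relative", "none"),
                          positive_only = FALSE) {
  transform <- match.arg(transform)
  if (rho_min < 0 || rho_min >= 1) stop("rho_min must be in [0, 1)",
                                        call. = FALSE)
  if (p_max <= 0 || p_max > 1) stop("p_max must be in (0, 1]", call. = FALSE)
  n <- nrow(table$counts)
  if (n < 3L) stop("need at least 3 samples for correlation p-values",
                   call. = FALSE)
  m <- switch(transform,
              log1p = log1p(table$counts),
              relative = rel_abund(table),
              none = table$counts)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " zero-variance taxa skipped")
    m <- m[, sds > 0, drop = FALSE]
  }
  rho <- cor(m)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pmat <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  keep <- abs(rho) > rho_min & pmat < p_max
  if (positive_only) keep <- keep & rho > 0
  keep[!upper.tri(keep)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(source = colnames(m)[idx[, 1]],
                      target = colnames(m)[idx[, 2]],
                      rho = rho[idx], p = pmat[idx],
                      sign = ifelse(rho[idx] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  params <- list(rho_min = rho_min, p_max = p_max, transform = transform,
                 positive_only = positive_only, n_samples = n)
  if (nrow(edges) == 0L) {
    warning("no edge passes the thresholds; network is empty", call. = FALSE)
    return(new_cooc_network(igraph::make_empty_graph(0, directed = FALSE),
                            edges, params))
  }
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE)
  igraph::E(g)$rho <- edges$rho
  igraph::E(g)$p <- edges$p
  igraph::E(g)$sign <- edges$sign
  igraph::E(g)$weight <- abs(edges$rho)
  igraph::V(g)$degree <- igraph::degree(g)
  new_cooc_network(g, edges, params)
}

as_igraph <- function(net) {
  if (inherits(net, "cooc_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected a cooc_network or igraph object", call. = FALSE)
}

# maximum attainable sum of (max - c_i) for unit-norm eigenvector centrality,
# realised by the star graph; computed numerically per node count
star_eigen_max <- function(n) {
  if (n < 3) return(NA_real_)
  g <- igraph::make_star(n, mode = "undirected")
  ec <- abs(eigen(igraph::as_adjacency_matrix(g, sparse = FALSE),
                  symmetric = TRUE)$vectors[, 1])
  ec <- ec / sqrt(sum(ec^2))
  sum(max(ec) - ec)
}

#' Topological metric suite of a co-occurrence network
#'
#' Node/edge counts, connectance `2 NE / (n (n-1))`, average degree
#' `2 NE / n`, global clustering coefficient (3 x triangles / connected
#' triples), average local clustering coefficient (degree < 2 contributes 0),
#' average neighborhood connectivity (mean over nodes of mean neighbor
#' degree), Freeman degree centralization `sum(dmax - di) / ((n-1)(n-2))`, and
#' eigenvector centralization (unit-norm centralities, star-graph
#' normalization).  `CD` and `GCC` are `NA` for n < 3.
#'
#' @param net a `cooc_network` or igraph graph (undirected).
#' @return one-row data.frame: n_nodes, n_edges, connectance, avg_degree,
#'   gcc, acc, an, cd, ec.
#' @export
topology_metrics <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 1) stop("empty network", call. = FALSE)
  ne <- igraph::ecount(g)
  deg <- igraph::degree(g)
  connectance <- if (n > 1) 2 * ne / (n * (n - 1)) else NA_real_
  gcc <- if (n >= 3) {
    v <- igraph::transitivity(g, type = "global")
    if (is.nan(v)) 0 else v
  } else NA_real_
  acc <- if (n >= 1) {
    lc <- igraph::transitivity(g, type = "local", isolates = "zero")
    mean(lc)
  } else NA_real_
  an <- if (ne > 0) {
    knn <- suppressWarnings(igraph::knn(g, weights = NA)$knn)
    mean(knn[is.finite(knn)])
  } else 0
  cd <- if (n >= 3) sum(max(deg) - deg) / ((n - 1) * (n - 2)) else NA_real_
  ec <- if (n >= 3 && ne > 0) {
    # dense symmetric eigen: deterministic, fine at co-occurrence scales
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    cent <- abs(eigen(adj, symmetric = TRUE)$vectors[, 1])
    cent <- cent / sqrt(sum(cent^2))
    sum(max(cent) - cent) / star_eigen_max(n)
  } else NA_real_
  data.frame(n_nodes = n, n_edges = ne, connectance = connectance,
             avg_degree = if (n > 0) 2 * ne / n else NA_real_,
             gcc = gcc, acc = acc, an = an, cd = cd, ec = ec)
}

#' Louvain module partition
#'
#' Louvain community detection on absolute edge weights (deterministic given
#' `seed`), with modules relabelled 1, 2, ... by decreasing size.
#'
#' @param net a `cooc_network` or igraph graph with at least one edge.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed optional integer seed.
#' @param min_module_size module size threshold used to flag modules for
#'   downstream module-environment analysis (default 15 nodes).
#' @return list: `membership` (named integer vector node -> module),
#'   `modularity` (Q of the returned partition, weighted), `sizes`
#'   (module sizes, decreasing), `large_modules` (ids of modules with
#'   >= `min_module_size` nodes).
#' @export
louvain_modules <- function(net, resolution = 1, seed = NULL,
                            min_module_size = 15) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) stop("network has no edges", call. = FALSE)
  w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
  w <- abs(w)
  cl <- with_seed(seed,
    igraph::cluster_louvain(g, weights = w, resolution = resolution))
  memb <- igraph::membership(cl)
  ord <- order(-as.numeric(table(memb)), as.numeric(names(table(memb))))
  relabel <- stats::setNames(seq_along(ord), names(table(memb))[ord])
  memb <- stats::setNames(as.integer(relabel[as.character(memb)]),
                          igraph::V(g)$name)
  q <- igraph::modularity(g, memb, weights = w)
  sizes <- as.numeric(table(memb))
  list(membership = memb, modularity = q, sizes = sizes,
       large_modules = which(sizes >= min_module_size))
}

#' Composite network complexity
#'
#' Per topological property, min-max standardises across a *set* of networks:
#' `score = (X - Xmin) / (Xmax - Xmin)`, then averages the standardized scores
#' per network.  Properties constant across the set carry no contrast and are
#' dropped with a warning.
#'
#' @param metrics data.frame with one row per network (row names = network
#'   ids) containing the property columns.
#' @param properties property columns to use; defaults to the suite of node
#'   count, edge count, connectance, average degree, GCC, ACC, AN, CD, EC and
#'   positive cohesion (whichever are present).
#' @return data.frame of per-network standardized scores plus a `complexity`
#'   column (mean of scores, in `[0, 1]`).
#' @export
complexity_index <- function(metrics,
                             properties = c("n_nodes", "n_edges",
                                            "connectance", "avg_degree",
                                            "gcc", "acc", "an", "cd", "ec",
                                            "positive_cohesion")) {
  metrics <- as.data.frame(metrics)
  if (nrow(metrics) < 2L)
    stop("complexity is defined across >= 2 networks (min-max over the set)",
         call. = FALSE)
  properties <- intersect(properties, names(metrics))
  if (!length(properties)) stop("no usable property columns", call. = FALSE)
  scores <- lapply(properties, function(p) {
    x <- metrics[[p]]
    if (anyNA(x)) return(NULL)
    rng <- range(x)
    if (diff(rng) == 0) return(NULL)
    (x - rng[1]) / diff(rng)
  })
  names(scores) <- properties
  dropped <- properties[vapply(scores, is.null, logical(1))]
  if (length(dropped))
    warning("property(ies) without contrast dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  scores <- scores[!vapply(scores, is.null, logical(1))]
  if (!length(scores)) stop("no property varies across the set", call. = FALSE)
  out <- as.data.frame(scores)
  rownames(out) <- rownames(metrics)
  out$complexity <- rowMeans(out)
  out
}

#' Module-environment Pearson correlations
#'
#' Module abundance per sample = sum of member-taxon relative abundances;
#' Pearson r and p against each environment variable; BH adjustment across
#' the full module x variable family; significance stars at
#' P_adj < 0.05 / 0.01 / 0.001.  Only modules with at least `min_module_size`
#' nodes enter (the paper-style filter).
#'
#' @param modules named vector taxon id -> module id (as from
#'   [louvain_modules()]`$membership`).
#' @param table an [abundance_table()] containing the module members.
#' @param env data.frame of numeric variables, row names = sample ids
#'   covering the table's samples.
#' @param min_module_size minimum module size (default 15).
#' @return data.frame: module, variable, r, p, p_adj, stars.
#' @export
module_env_correlation <- function(modules, table, env, min_module_size = 15) {
  missing <- setdiff(names(modules), taxon_ids(table))
  if (length(missing))
    stop("module member(s) absent from the table: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  ids <- sample_ids(table)
  if (!all(ids %in% rownames(env)))
    stop("env table is missing sample(s): ",
         paste(setdiff(ids, rownames(env)), collapse = ", "), call. = FALSE)
  env <- env[ids, , drop = FALSE]
  env <- env[, vapply(env, is.numeric, logical(1)), drop = FALSE]
  if (!ncol(env)) stop("no numeric environment variables", call. = FALSE)
  sizes <- table(modules)
  use <- names(sizes)[sizes >= min_module_size]
  if (!length(use))
    stop("no module reaches min_module_size = ", min_module_size,
         call. = FALSE)
  ra <- rel_abund(table)
  out <- do.call(rbind, lapply(use, function(mod) {
    memb <- names(modules)[modules == mod]
    ab <- rowSums(ra[, memb, drop = FALSE])
    do.call(rbind, lapply(names(env), function(v) {
      fit <- tryCatch(pearson_with_p(ab, env[[v]]), error = function(e) NULL)
      data.frame(module = mod, variable = v,
                 r = if (is.null(fit)) NA_real_ else fit$rho,
                 p = if (is.null(fit)) NA_real_ else fit$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  ok <- !is.na(out$p)
  out$p_adj <- NA_real_
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  out$stars <- cut(out$p_adj, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out$stars <- as.character(out$stars)
  out
}
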