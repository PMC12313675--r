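#' Between-sample mean nearest taxon distance (betaMNTD)
#'
#' Abundance-weighted phylogenetic turnover between every pair of samples:
#' `0.5 * [ sum_i f_i min_j d(i,j) + sum_j f_j min_i d(i,j) ]`, where `f` are
#' within-sample relative abundances over present taxa, `d` is the cophenetic
#' distance, and the minima run over taxa present (count > 0) in the partner
#' sample (a shared taxon contributes distance 0).
#'
#' @param table an [abundance_table()]; every taxon must be a tree tip.
#' @param tree a rooted `phylo` with branch lengths.
#' @param weighted abundance-weight the means (default); `FALSE` gives the
#'   presence/absence version.
#' @return a `dist` of betaMNTD values over samples.
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  prep <- prep_phylo(table, tree)
  m <- bmntd_cpp(prep$relab, prep$dfull, prep$idx - 1L, weighted)
  dimnames(m) <- list(sample_ids(table), sample_ids(table))
  as.dist(m)
}

prep_phylo <- function(table, tree) {
  validate_tree(tree)
  taxa <- taxon_ids(table)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10),
         call. = FALSE)
  list(relab = rel_abund(table),
       dfull = ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label],
       idx = match(taxa, tree$tip.label),
       n_tips = length(tree$tip.label))
}

#' beta nearest taxon index (betaNTI)
#'
#' z-score of the observed betaMNTD against a taxa-labels null that shuffles
#' taxon identities across *all* tree tips and recomputes betaMNTD per
#' replicate: `betaNTI = (obs - mean_null) / sd_null` per sample pair.
#' `|betaNTI| >= 2` is conventionally read as deterministic selection.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip-shuffling replicates (>= 99; default 999).
#' @param seed optional integer seed.
#' @return data.frame with one row per unordered sample pair: sample_a,
#'   sample_b, beta_mntd, null_mean, null_sd, bnti.  Pairs whose null has zero
#'   spread (e.g. a star phylogeny) get `NA` with a warning.
#' @export
bnti <- function(table, tree, n_null = 999, seed = NULL, weighted = TRUE) {
  if (n_null < 99) stop("n_null must be >= 99", call. = FALSE)
  prep <- prep_phylo(table, tree)
  obs <- bmntd_cpp(prep$relab, prep$dfull, prep$idx - 1L, weighted)
  idx_null <- with_seed(seed, {
    t(vapply(seq_len(n_null),
             function(i) sample.int(prep$n_tips)[prep$idx],
             integer(ncol(prep$relab))))
  })
  nul <- bmntd_null_stats_cpp(prep$relab, prep$dfull, idx_null - 1L, weighted)
  pairs <- pair_grid(sample_ids(table))
  ia <- match(pairs$sample_a, sample_ids(table))
  ib <- match(pairs$sample_b, sample_ids(table))
  at <- function(m) m[cbind(ia, ib)]
  null_sd <- at(nul$sd)
  z <- ifelse(null_sd > 0, (at(obs) - at(nul$mean)) / null_sd, NA_real_)
  if (anyNA(z))
    warning(sum(is.na(z)), " pair(s) have a degenerate null (sd = 0); ",
            "betaNTI set to NA", call. = FALSE)
  cbind(pairs, data.frame(beta_mntd = at(obs), null_mean = at(nul$mean),
                          null_sd = null_sd, bnti = z))
}

#' Bray-Curtis-based Raup-Crick index (RC_bray)
#'
#' Probabilistic null for compositional turnover.  Each null replicate
#' rebuilds every sample with its observed richness and total count: member
#' taxa are drawn without replacement with probability proportional to
#' occupancy (fraction of samples occupied), one individual is seeded per
#' member, and the remaining individuals are assigned multinomially with
#' probability proportional to metacommunity relative abundance.  Per pair,
#' `rc = 2 * [ (#\{BC_null < BC_obs\} + 0.5 #\{BC_null = BC_obs\}) / n_null ] - 1`,
#' so values near +1/-1 flag turnover greater/less than the null expectation.
#'
#' @param table an [abundance_table()] of integer counts.
#' @param n_null number of null replicates (>= 99; default 999).
#' @param seed optional integer seed.
#' @return data.frame per unordered pair: sample_a, sample_b, bc_obs, rc_bray
#'   (in `[-1, 1]`).
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = NULL) {
  cts <- table$counts
  if (any(cts != round(cts)))
    stop("Raup-Crick null needs integer counts", call. = FALSE)
  if (n_null < 99) stop("n_null must be >= 99", call. = FALSE)
  occ <- colSums(cts > 0)
  gamma_w <- colSums(cts)
  pool <- which(occ > 0)
  rich <- rowSums(cts > 0)
  depth <- rowSums(cts)
  if (any(rich > length(pool)))
    stop("sample richness exceeds metacommunity richness", call. = FALSE)
  if (any(rich == 0))
    stop("all-zero sample(s): ", paste(rownames(cts)[rich == 0], collapse = ", "),
         call. = FALSE)
  ns <- nrow(cts)
  bc_obs <- as.matrix(bray_curtis(table, relative = TRUE))
  lt <- sum(upper.tri(bc_obs))
  less <- matrix(0, ns, ns); equal <- matrix(0, ns, ns)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      nullm <- matrix(0, ns, length(pool))
      for (s in seq_len(ns)) {
        members <- sample(seq_along(pool), rich[s], prob = occ[pool])
        x <- rep(1, rich[s])
        extra <- depth[s] - rich[s]
        if (extra > 0)
          x <- x + as.vector(rmultinom(1, extra, gamma_w[pool][members]))
        nullm[s, members] <- x
      }
      reln <- nullm / rowSums(nullm)
      bcn <- as.matrix(vegan::vegdist(reln, method = "bray"))
      less <- less + (bcn < bc_obs - 1e-12)
      equal <- equal + (abs(bcn - bc_obs) <= 1e-12)
    }
  })
  pairs <- pair_grid(sample_ids(table))
  ia <- match(pairs$sample_a, sample_ids(table))
  ib <- match(pairs$sample_b, sample_ids(table))
  at <- function(m) m[cbind(ia, ib)]
  rc <- 2 * ((at(less) + 0.5 * at(equal)) / n_null) - 1
  cbind(pairs, data.frame(bc_obs = at(bc_obs), rc_bray = rc))
}

#' Classify community assembly processes from betaNTI and RC_bray
#'
#' Five-process rules: `|betaNTI| >= 2` is selection — under the default
#' `stegen_standard` convention `betaNTI < -2` is homogeneous selection and
#' `betaNTI > +2` heterogeneous selection (`inverted` swaps the two
#' signs).  Otherwise `RC_bray > 0.95` is dispersal limitation,
#' `RC_bray < -0.95` homogenizing dispersal, and `|RC_bray| < 0.95`
#' undominated (drift); `|RC_bray|` exactly 0.95 falls to undominated.
#'
#' @param bnti numeric vector of betaNTI values (`NA` propagates).
#' @param rc_bray numeric vector of RC_bray values in `[-1, 1]`.
#' @param convention `"stegen_standard"` (default) or `"inverted"`.
#' @return character vector of process labels.
#' @export
classify_assembly_process <- function(bnti, rc_bray,
                                      convention = c("stegen_standard",
                                                     "inverted")) {
  convention <- match.arg(convention)
  stopifnot(length(bnti) == length(rc_bray))
  if (any(abs(rc_bray) > 1 + 1e-9, na.rm = TRUE))
    stop("RC_bray values must lie in [-1, 1]", call. = FALSE)
  neg_label <- if (convention == "stegen_standard") "homogeneous_selection"
               else "heterogeneous_selection"
  pos_label <- if (convention == "stegen_standard") "heterogeneous_selection"
               else "homogeneous_selection"
  out <- rep(NA_character_, length(bnti))
  sel_neg <- !is.na(bnti) & bnti <= -2
  sel_pos <- !is.na(bnti) & bnti >= 2
  sto <- !is.na(bnti) & abs(bnti) < 2
  out[sel_neg] <- neg_label
  out[sel_pos] <- pos_label
  out[sto & !is.na(rc_bray) & rc_bray > 0.95] <- "dispersal_limitation"
  out[sto & !is.na(rc_bray) & rc_bray < -0.95] <- "homogenizing_dispersal"
  out[sto & !is.na(rc_bray) & abs(rc_bray) <= 0.95] <- "undominated"
  out
}

assembly_processes <- c("heterogeneous_selection", "homogeneous_selection",
                        "dispersal_limitation", "homogenizing_dispersal",
                        "undominated")

#' Per-group fractions of assembly processes
#'
#' @param pairs data.frame with columns sample_a, sample_b, process (as from
#'   [assembly_analysis()]).
#' @param groups optional named character vector sample id -> group; when
#'   given, fractions are computed over within-group pairs per group,
#'   otherwise over all pairs (group `"all"`).
#' @return data.frame: group, process, fraction, n_pairs, n_na; fractions sum
#'   to 1 within each group (NA-labelled pairs excluded from the denominator).
#' @export
process_fractions <- function(pairs, groups = NULL) {
  if (is.null(groups)) {
    grp_of <- stats::setNames(rep("all", length(unique(c(pairs$sample_a, pairs$sample_b)))),
                              unique(c(pairs$sample_a, pairs$sample_b)))
  } else grp_of <- groups
  ga <- grp_of[pairs$sample_a]; gb <- grp_of[pairs$sample_b]
  keep <- !is.na(ga) & !is.na(gb) & ga == gb
  out <- do.call(rbind, lapply(unique(ga[keep]), function(g) {
    lab <- pairs$process[keep & ga == g]
    n_na <- sum(is.na(lab))
    lab <- lab[!is.na(lab)]
    if (!length(lab))
      stop("group '", g, "' has no classifiable pairs", call. = FALSE)
    data.frame(group = g, process = assembly_processes,
               fraction = as.numeric(table(factor(lab, assembly_processes))) /
                 length(lab),
               n_pairs = length(lab), n_na = n_na,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Full community-assembly analysis
#'
#' Runs [bnti()] and [raup_crick_bray()], classifies every sample pair, and
#' summarises per-group process fractions.
#'
#' @inheritParams bnti
#' @param convention passed to [classify_assembly_process()].
#' @param groups optional named character vector sample id -> group
#'   (defaults to the table's own groups).
#' @return list with `pairs` (per-pair data.frame incl. `process`) and
#'   `fractions` (per-group process fractions), plus the null settings used.
#' @export
assembly_analysis <- function(table, tree, n_null = 999, seed = NULL,
                              weighted = TRUE,
                              convention = "stegen_standard",
                              groups = NULL) {
  groups <- groups %||% table$groups
  b <- bnti(table, tree, n_null = n_null, seed = derive_seed(seed, 1),
            weighted = weighted)
  rc <- raup_crick_bray(table, n_null = n_null, seed = derive_seed(seed, 2))
  pairs <- merge(b, rc, by = c("sample_a", "sample_b"), sort = FALSE)
  pairs$process <- classify_assembly_process(pairs$bnti, pairs$rc_bray,
                                             convention = convention)
  list(pairs = pairs,
       fractions = process_fractions(pairs, groups = groups),
       n_null = n_null, seed = seed, convention = convention)
}
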