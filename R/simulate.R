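#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule (pure-birth) tree rescaled to unit crown depth, with tips labelled
#' `T0001`, `T0002`, ...
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed optional integer seed.
#' @return an ultrametric `phylo` with all root-to-tip distances equal to 1.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("T%04d", seq_len(n_taxa))
  tree
}

#' Simulate a Brownian niche trait on a tree
#'
#' Brownian motion from a root value of 0: along each branch the trait gains
#' an independent normal increment with variance `sigma2 * branch length`, so
#' related taxa end up with similar niche optima — the phylogenetic
#' conservation that lets betaNTI detect selection.
#'
#' @param tree a `phylo` with branch lengths.
#' @param sigma2 Brownian rate (> 0); on a unit-depth tree, tip trait
#'   standard deviation is `sqrt(sigma2)`.
#' @param seed optional integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_trait <- function(tree, sigma2 = 1, seed = NULL) {
  validate_tree(tree)
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop("sigma2 must be positive", call. = FALSE)
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "cladewise")  # preorder: parent edge first
  x <- numeric(ntip + tr$Nnode)
  edge <- tr$edge
  with_seed(seed, {
    steps <- rnorm(nrow(edge), 0, sqrt(sigma2 * tr$edge.length))
    for (i in seq_len(nrow(edge)))
      x[edge[i, 2]] <- x[edge[i, 1]] + steps[i]
  })
  stats::setNames(x[seq_len(ntip)], tr$tip.label)
}

#' Draw log-series random variates
#'
#' Kemp's O(1) generator for the logarithmic-series distribution with
#' parameter `p` in (0, 1); used for rank-abundance-skewed metacommunities.
#'
#' @param n number of draws.
#' @param p log-series parameter (often written x), in (0, 1).
#' @return integer-valued numeric vector of draws (>= 1).
#' @export
rlogseries <- function(n, p) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  h <- log1p(-p)
  vapply(seq_len(n), function(i) {
    v <- runif(1)
    if (v >= p) return(1)
    u <- runif(1)
    q <- -expm1(u * h)
    if (v <= q * q) floor(1 + log(v) / log(q))
    else if (v <= q) 2
    else 1
  }, numeric(1))
}

#' Log-series metacommunity relative abundances
#'
#' Draws one log-series abundance per taxon with the parameter implied by
#' Fisher's alpha and the taxon count (`J = alpha (e^(S/alpha) - 1)`,
#' `x = J/(J + alpha)`), then normalises.  Gives the realistic rank-abundance
#' skew that makes "top-N by abundance" filtering meaningful.
#'
#' @param n_taxa number of taxa.
#' @param fisher_alpha Fisher's alpha (default 20; smaller = more skew).
#' @param seed optional integer seed.
#' @return named numeric vector of relative abundances summing to 1.
#' @export
logseries_metacommunity <- function(n_taxa, fisher_alpha = 20, seed = NULL) {
  J <- fisher_alpha * expm1(n_taxa / fisher_alpha)
  x <- J / (J + fisher_alpha)
  ab <- with_seed(seed, rlogseries(n_taxa, x))
  stats::setNames(ab / sum(ab), sprintf("T%04d", seq_len(n_taxa)))
}

#' Simulation scenario description
#'
#' Bundles the parameters of a community-assembly simulation.  The regime
#' determines which parameters are read: `filtering` uses `niche_breadth`
#' (Gaussian niche width omega) and `env_optima` (per-sample trait optima);
#' `neutral` ignores both; `dispersal_limited` arranges samples on a chain
#' and uses `migration` (metacommunity mixing rate m).
#'
#' @param regime `"filtering"`, `"neutral"` or `"dispersal_limited"`.
#' @param n_taxa number of taxa (>= 8).
#' @param n_samples number of samples.
#' @param depth reads per sample (>= 100).
#' @param niche_breadth Gaussian niche breadth omega (> 0), trait units.
#' @param sigma2 Brownian trait rate.
#' @param env_optima per-sample niche optima (length `n_samples`, recycled);
#'   default 0 (shared environment).
#' @param migration metacommunity migration rate in `[0, 1]`
#'   (dispersal_limited only).
#' @param fisher_alpha Fisher's alpha of the log-series metacommunity.
#' @param seed integer seed recorded with the scenario.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(regime = c("filtering", "neutral",
                                    "dispersal_limited"),
                         n_taxa = 400, n_samples = 12, depth = 20000,
                         niche_breadth = 0.5, sigma2 = 1, env_optima = 0,
                         migration = 0.1, fisher_alpha = 20, seed = 1) {
  regime <- match.arg(regime)
  if (n_taxa < 8) stop("n_taxa must be >= 8", call. = FALSE)
  if (depth < 100) stop("depth must be >= 100", call. = FALSE)
  if (niche_breadth <= 0) stop("niche_breadth must be > 0", call. = FALSE)
  if (migration < 0 || migration > 1)
    stop("migration must be in [0, 1]", call. = FALSE)
  env_optima <- rep_len(env_optima, n_samples)
  structure(list(regime = regime, n_taxa = n_taxa, n_samples = n_samples,
                 depth = depth, niche_breadth = niche_breadth,
                 sigma2 = sigma2, env_optima = env_optima,
                 migration = migration, fisher_alpha = fisher_alpha,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# expected taxon sampling weights for one sample under a scenario
assembly_weights <- function(scenario, meta, traits, env_opt) {
  switch(scenario$regime,
         neutral = meta,
         filtering = {
           w <- meta * exp(-(traits - env_opt)^2 /
                             (2 * scenario$niche_breadth^2))
           w / sum(w)
         },
         stop("unknown regime", call. = FALSE))
}

#' Assemble communities under a controlled regime
#'
#' Draws one multinomial community per sample.  `filtering`: sampling weights
#' proportional to metacommunity abundance times a Gaussian niche factor
#' `exp(-(trait - env)^2 / (2 omega^2))`.  `neutral`: every sample draws from
#' the same log-series metacommunity.  `dispersal_limited`: samples sit on a
#' chain; each local pool is `(1 - m) x` the realised composition of its
#' neighbour plus `m x` the metacommunity.
#'
#' @param scenario a [sim_scenario()].
#' @param tree a tree from [simulate_tree()] with `n_taxa` tips (used for its
#'   tip set; communities and tree tips must match).
#' @param traits named trait vector from [simulate_trait()].
#' @return list: `table` ([abundance_table()], samples `S01`...),
#'   `metacommunity` (relative abundances), `scenario`.
#' @export
assemble_communities <- function(scenario, tree, traits) {
  stopifnot(inherits(scenario, "sim_scenario"))
  taxa <- tree$tip.label
  if (length(taxa) != scenario$n_taxa)
    stop("tree tip count does not match scenario n_taxa", call. = FALSE)
  if (!all(taxa %in% names(traits)))
    stop("traits must cover all tree tips", call. = FALSE)
  traits <- traits[taxa]
  seed <- scenario$seed
  meta <- logseries_metacommunity(scenario$n_taxa, scenario$fisher_alpha,
                                  seed = derive_seed(seed, 11))
  names(meta) <- taxa
  ns <- scenario$n_samples
  counts <- matrix(0L, ns, scenario$n_taxa,
                   dimnames = list(sprintf("S%02d", seq_len(ns)), taxa))
  with_seed(derive_seed(seed, 12), {
    if (scenario$regime == "dispersal_limited") {
      pool <- meta
      for (s in seq_len(ns)) {
        if (s > 1) {
          prev <- counts[s - 1, ] / sum(counts[s - 1, ])
          pool <- (1 - scenario$migration) * prev +
            scenario$migration * meta
        }
        counts[s, ] <- as.integer(rmultinom(1, scenario$depth, pool))
      }
    } else {
      for (s in seq_len(ns)) {
        w <- assembly_weights(scenario, meta, traits,
                              scenario$env_optima[s])
        counts[s, ] <- as.integer(rmultinom(1, scenario$depth, w))
      }
    }
  })
  list(table = abundance_table(counts), metacommunity = meta,
       scenario = scenario)
}

#' Simulate group-structured metal concentrations
#'
#' Concentration of metal `k` in a sample of group `g` is
#' `B_k * mult[g, k] * exp(N(0, sigma_log))` — a background value times a
#' group multiplier with lognormal noise.  With `mult = 1.5` and
#' `sigma_log = 0` the geo-accumulation index is exactly 0.
#'
#' @param groups character/factor of group labels, one per sample (sample ids
#'   taken from its names, else `S01`...).
#' @param multipliers numeric matrix groups x metals (dimnames required), all
#'   positive.
#' @param backgrounds named numeric vector of background values (> 0)
#'   covering the metals.
#' @param sigma_log lognormal noise sd on the log scale (default 0.2).
#' @param seed optional integer seed.
#' @return matrix samples x metals of concentrations (mg/kg).
#' @export
simulate_metals <- function(groups, multipliers, backgrounds,
                            sigma_log = 0.2, seed = NULL) {
  if (any(multipliers <= 0)) stop("multipliers must be positive",
                                  call. = FALSE)
  metals <- colnames(multipliers)
  if (is.null(metals) || is.null(rownames(multipliers)))
    stop("multipliers needs group row names and metal column names",
         call. = FALSE)
  if (any(backgrounds[metals] <= 0) || anyNA(backgrounds[metals]))
    stop("backgrounds must be positive for every metal", call. = FALSE)
  ids <- names(groups) %||% sprintf("S%02d", seq_along(groups))
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), rownames(multipliers))
  if (length(bad))
    stop("no multiplier row for group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  conc <- with_seed(seed, {
    noise <- matrix(exp(rnorm(length(groups) * length(metals), 0, sigma_log)),
                    length(groups), length(metals))
    multipliers[groups, , drop = FALSE] *
      matrix(backgrounds[metals], length(groups), length(metals),
             byrow = TRUE) * noise
  })
  dimnames(conc) <- list(ids, metals)
  conc
}

#' Simulate nutrient-style environment variables
#'
#' Soil variables (pH, SM, TOC, TN, NH4, NO3, TP, TS) generated as linear
#' functions of the per-sample selection gradient plus Gaussian noise, so
#' distance-based tests have recoverable environmental signal.
#'
#' @param gradient numeric per-sample selection gradient (e.g. the niche
#'   optima used by the filtering regime); names become sample ids.
#' @param signal slope applied to the z-scored gradient, in units of each
#'   variable's noise sd (default 2 = strong signal).
#' @param seed optional integer seed.
#' @return data.frame of variables, row names = sample ids.
#' @export
simulate_env <- function(gradient, signal = 2, seed = NULL) {
  ids <- names(gradient) %||% sprintf("S%02d", seq_along(gradient))
  g <- if (sd(gradient) > 0) as.numeric(scale(gradient)) else gradient * 0
  base <- c(pH = 6.5, SM = 20, TOC = 10, TN = 1.0, NH4 = 15, NO3 = 10,
            TP = 600, TS = 400)
  noise_sd <- c(pH = 0.3, SM = 3, TOC = 1.5, TN = 0.15, NH4 = 2.5, NO3 = 2,
                TP = 60, TS = 50)
  env <- with_seed(seed, {
    cols <- lapply(names(base), function(v) {
      base[[v]] + signal * noise_sd[[v]] * g +
        rnorm(length(g), 0, noise_sd[[v]])
    })
    as.data.frame(stats::setNames(cols, names(base)))
  })
  rownames(env) <- ids
  env
}

#' Default group multipliers echoing a high/low pollution contrast
#'
#' Multipliers for groups `H` (high pollution) and `L` (low pollution) chosen
#' so that expected single pollution indices reproduce the magnitude contrast
#' of a copper-mine vs rare-earth-mine tailings comparison (Cu strongly
#' enriched under H, Al higher under L, etc.).
#'
#' @param references reference table from [default_metal_references()].
#' @return matrix 2 x metals of multipliers.
#' @export
default_metal_multipliers <- function(references = default_metal_references()) {
  pi_h <- c(Fe = 1.56, Cu = 10.87, Zn = 0.34, Cd = 1.96, Pb = 0.06,
            Mn = 0.55, Al = 1.64)
  pi_l <- c(Fe = 1.12, Cu = 0.10, Zn = 0.58, Cd = 1.42, Pb = 0.52,
            Mn = 0.37, Al = 3.23)
  metals <- references$metal
  s <- stats::setNames(references$screening, references$metal)
  b <- stats::setNames(references$background, references$metal)
  rbind(H = pi_h[metals] * s[metals] / b[metals],
        L = pi_l[metals] * s[metals] / b[metals])
}

#' Simulate a full study-shaped dataset
#'
#' The desk-scale analogue of the study design: 2 pollution groups (H
#' filtering-assembled, L neutrally assembled by default) x 2 succession
#' stages x `n_rep` replicates, one shared phylogeny and metacommunity,
#' Brownian niche traits, group-structured metal concentrations and
#' gradient-linked nutrient variables.
#'
#' @param n_taxa,depth community size parameters (defaults 400 taxa, 20000
#'   reads).
#' @param n_rep replicates per group x stage cell (default 3 -> 12 samples).
#' @param niche_breadth,sigma2,fisher_alpha passed to the assembly scenario.
#' @param regimes named character vector giving the assembly regime of groups
#'   `H` and `L`.
#' @param sigma_log lognormal noise of metal concentrations.
#' @param seed integer seed (drives every stage).
#' @return list: `table` (with groups), `tree`, `traits`, `env` (nutrients +
#'   metals), `metals`, `backgrounds`, `screening`, `truth` (per-sample
#'   regime, stage, group).
#' @export
simulate_study <- function(n_taxa = 400, depth = 20000, n_rep = 3,
                           niche_breadth = 0.5, sigma2 = 1,
                           fisher_alpha = 20,
                           regimes = c(H = "filtering", L = "neutral"),
                           sigma_log = 0.2, seed = 1) {
  n_per_group <- 2 * n_rep
  tree <- simulate_tree(n_taxa, seed = derive_seed(seed, 1))
  traits <- simulate_trait(tree, sigma2 = sigma2, seed = derive_seed(seed, 2))
  groups_v <- c(rep("H", n_per_group), rep("L", n_per_group))
  stage_v <- rep(c(rep("T", n_rep), rep("B", n_rep)), 2)
  ids <- paste0(groups_v, stage_v, rep(seq_len(n_rep), 4))
  counts <- NULL
  for (gi in seq_along(unique(groups_v))) {
    g <- unique(groups_v)[gi]
    sc <- sim_scenario(regime = regimes[[g]], n_taxa = n_taxa,
                       n_samples = n_per_group, depth = depth,
                       niche_breadth = niche_breadth, sigma2 = sigma2,
                       env_optima = 0, fisher_alpha = fisher_alpha,
                       seed = derive_seed(seed, 20 + gi))
    asm <- assemble_communities(sc, tree, traits)
    counts <- rbind(counts, asm$table$counts)
  }
  rownames(counts) <- ids
  groups <- stats::setNames(groups_v, ids)
  table <- abundance_table(counts, groups = groups)
  refs <- default_metal_references()
  backgrounds <- stats::setNames(refs$background, refs$metal)
  screening <- stats::setNames(refs$screening, refs$metal)
  mult <- default_metal_multipliers(refs)
  metals <- simulate_metals(groups, mult, backgrounds,
                            sigma_log = sigma_log,
                            seed = derive_seed(seed, 3))
  gradient <- stats::setNames(ifelse(groups_v == "H", 1, -1), ids)
  env <- cbind(simulate_env(gradient, seed = derive_seed(seed, 4)),
               as.data.frame(metals))
  list(table = table, tree = tree, traits = traits, env = env,
       metals = metals, backgrounds = backgrounds, screening = screening,
       truth = data.frame(sample = ids, group = groups_v, stage = stage_v,
                          regime = regimes[groups_v],
                          row.names = NULL, stringsAsFactors = FALSE))
}
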