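#' Pipeline run configuration
#'
#' Holds input paths, thresholds, null-model replicate counts and the seed
#' for a full analysis run; every randomized stage derives its stream from
#' the one recorded seed.
#'
#' @param counts path to the sample-by-taxon table (TSV/CSV/BIOM-JSON).
#' @param tree optional Newick tree path (required for the assembly stage).
#' @param env optional environment CSV path.
#' @param backgrounds optional CSV path with columns metal, background and
#'   (optionally) screening, for the pollution stage.
#' @param groups optional named character vector sample id -> group, or the
#'   name of an env-table column holding group labels.
#' @param taxa_as_rows orientation of the counts file.
#' @param rho_min,p_max,transform network thresholds (see [build_network()]).
#' @param top_n optional top-N abundance filter before network construction.
#' @param n_null null-model replicates for betaNTI/RC-bray (>= 1 per spec'd
#'   stage minimums).
#' @param n_perm permutations for Mantel/PERMANOVA.
#' @param rarefy_depth optional rarefaction depth (default none).
#' @param bnti_convention passed to [classify_assembly_process()].
#' @param seed integer seed recorded with the run.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(counts, tree = NULL, env = NULL, backgrounds = NULL,
                       groups = NULL, taxa_as_rows = TRUE,
                       rho_min = 0.3, p_max = 0.05, transform = "log1p",
                       top_n = NULL, n_null = 999, n_perm = 999,
                       rarefy_depth = NULL,
                       bnti_convention = "stegen_standard",
                       seed = 1, out_dir = "results") {
  if (rho_min < 0 || rho_min >= 1) stop("rho_min must be in [0, 1)",
                                        call. = FALSE)
  if (p_max <= 0 || p_max > 1) stop("p_max must be in (0, 1]", call. = FALSE)
  if (n_null < 1 || n_perm < 1)
    stop("replicate counts must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(counts = counts, tree = tree, env = env,
                 backgrounds = backgrounds, groups = groups,
                 taxa_as_rows = taxa_as_rows, rho_min = rho_min,
                 p_max = p_max, transform = transform, top_n = top_n,
                 n_null = n_null, n_perm = n_perm,
                 rarefy_depth = rarefy_depth,
                 bnti_convention = bnti_convention,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr,
           error = function(e) stop("stage '", name, "' failed: ",
                                    conditionMessage(e), call. = FALSE))
}

#' Run the full succession analysis pipeline
#'
#' Chains pollution indices, alpha diversity, Bray-Curtis + Mantel screens,
#' per-group co-occurrence networks (metrics, modules, cohesion, complexity,
#' module-environment correlations) and null-model assembly partitioning,
#' writing one TSV per result plus a JSON metadata record of every threshold
#' used.  Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @return (invisibly) a named list of the result objects, with
#'   `$files` listing everything written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) file.path(config$out_dir, name)
  results <- list()

  table <- run_stage("read_counts", {
    tab <- read_abundance_table(config$counts,
                                taxa_as_rows = config$taxa_as_rows)
    if (!is.null(config$rarefy_depth))
      tab <- rarefy_table(tab, config$rarefy_depth,
                          seed = derive_seed(config$seed, 90))
    tab
  })
  env <- if (!is.null(config$env)) run_stage("read_env",
                                             read_env_table(config$env))
  groups <- config$groups
  if (is.character(groups) && length(groups) == 1L && !is.null(env) &&
      groups %in% colnames(env)) {
    groups <- stats::setNames(as.character(env[[groups]]), rownames(env))
    env <- env[, setdiff(colnames(env), config$groups), drop = FALSE]
  }
  if (!is.null(groups)) table$groups <- groups[sample_ids(table)]

  # -- pollution indices ----------------------------------------------------
  if (!is.null(config$backgrounds) && !is.null(env)) {
    results$pollution <- run_stage("pollution", {
      refs <- utils::read.table(config$backgrounds, sep = ",", header = TRUE,
                                stringsAsFactors = FALSE)
      metals <- intersect(refs$metal, colnames(env))
      conc <- as.matrix(env[, metals, drop = FALSE])
      idx <- pollution_indices(
        conc,
        backgrounds = stats::setNames(refs$background, refs$metal),
        screening = stats::setNames(
          if ("screening" %in% names(refs)) refs$screening
          else rep(NA_real_, nrow(refs)), refs$metal))
      files <- c(files, write_tsv(idx$per_metal, out("pollution_per_metal.tsv")),
                  write_tsv(idx$per_sample, out("pollution_per_sample.tsv")))
      if (!is.null(table$groups)) {
        g <- table$groups[idx$per_sample$sample]
        if (length(unique(g)) == 2L) {
          wide <- cbind(
            stats::reshape(idx$per_metal[, c("sample", "metal", "pi")],
                           idvar = "sample", timevar = "metal",
                           direction = "wide")[-1],
            nipi = idx$per_sample$nipi)
          cmp <- compare_groups(wide, g)
          files <- c(files, write_tsv(cmp, out("pollution_group_tests.tsv")))
          idx$group_tests <- cmp
        }
      }
      idx
    })
  }

  # -- diversity and community distance ------------------------------------
  results$alpha <- run_stage("alpha_diversity", {
    a <- alpha_diversity(table)
    files <- c(files, write_tsv(a, out("alpha_diversity.tsv")))
    a
  })
  bc <- run_stage("bray_curtis", bray_curtis(table))
  run_stage("write_bray_curtis", {
    m <- as.matrix(bc)
    files <- c(files, write_tsv(data.frame(sample = rownames(m), m,
                                            check.names = FALSE),
                                 out("bray_curtis.tsv")))
  })
  results$bray_curtis <- bc

  if (!is.null(env)) {
    results$mantel <- run_stage("mantel", {
      mt <- mantel_env_screen(bc, env, n_perm = config$n_perm,
                              seed = derive_seed(config$seed, 30))
      files <- c(files, write_tsv(mt, out("mantel.tsv")))
      mt
    })
    if (!is.null(table$groups) && length(unique(table$groups)) >= 2 &&
        all(table(table$groups) >= 2)) {
      results$permanova <- run_stage("permanova", {
        pm <- permanova(bc, table$groups[sample_ids(table)],
                        n_perm = config$n_perm,
                        seed = derive_seed(config$seed, 31))
        files <- c(files, write_tsv(
          data.frame(pseudo_f = pm$pseudo_f, r2 = pm$r2, p = pm$p),
          out("permanova.tsv")))
        pm
      })
    }
  }

  # -- per-group co-occurrence networks ------------------------------------
  results$networks <- run_stage("network", {
    grp_levels <- if (!is.null(table$groups)) unique(table$groups) else "all"
    nets <- list()
    metrics <- NULL
    for (g in grp_levels) {
      sub <- if (identical(g, "all")) table
             else subset_table(table,
                               samples = names(table$groups)[table$groups == g],
                               drop_empty_taxa = TRUE)
      if (!is.null(config$top_n)) sub <- filter_top_asvs(sub, config$top_n)
      net <- build_network(sub, rho_min = config$rho_min,
                           p_max = config$p_max,
                           transform = config$transform)
      coh <- cohesion(sub, seed = derive_seed(config$seed, 40))
      row <- topology_metrics(net)
      if (nrow(net$edges) > 0) {
        mod <- louvain_modules(net, seed = derive_seed(config$seed, 41))
        row$modularity <- mod$modularity
        row$n_modules <- length(mod$sizes)
        files <- c(files, write_tsv(
          data.frame(taxon = names(mod$membership),
                     module = as.integer(mod$membership)),
          out(sprintf("modules_%s.tsv", g))))
        if (!is.null(env) && length(mod$large_modules)) {
          me <- tryCatch(
            module_env_correlation(mod$membership, sub, env),
            error = function(e) NULL)
          if (!is.null(me))
            files <- c(files, write_tsv(me, out(sprintf("module_env_%s.tsv", g))))
        }
      } else {
        row$modularity <- NA_real_; row$n_modules <- 0L
      }
      row$positive_cohesion <- mean(coh$samples$positive_cohesion)
      row$negative_cohesion <- mean(coh$samples$negative_cohesion)
      rownames(row) <- g
      metrics <- rbind(metrics, row)
      write_network(net, out(sprintf("network_%s.graphml", g)), "graphml")
      write_network(net, out(sprintf("edges_%s.tsv", g)), "edge-tsv")
      files <- c(files, out(sprintf("network_%s.graphml", g)),
                  out(sprintf("edges_%s.tsv", g)))
      nets[[g]] <- net
    }
    files <- c(files, write_tsv(cbind(network = rownames(metrics), metrics),
                                 out("network_metrics.tsv")))
    if (nrow(metrics) >= 2) {
      cx <- complexity_index(metrics)
      files <- c(files, write_tsv(cbind(network = rownames(cx), cx),
                                   out("network_complexity.tsv")))
    }
    list(networks = nets, metrics = metrics)
  })

  # -- null-model assembly partitioning ------------------------------------
  if (!is.null(config$tree)) {
    results$assembly <- run_stage("assembly", {
      tree <- read_newick(config$tree)
      asm <- assembly_analysis(table, tree, n_null = config$n_null,
                               seed = derive_seed(config$seed, 50),
                               convention = config$bnti_convention)
      files <- c(files, write_tsv(asm$pairs, out("assembly_pairs.tsv")),
                  write_tsv(asm$fractions, out("assembly_fractions.tsv")))
      asm
    })
  }

  meta <- list(seed = config$seed, rho_min = config$rho_min,
               p_max = config$p_max, transform = config$transform,
               top_n = config$top_n, n_null = config$n_null,
               n_perm = config$n_perm, rarefy_depth = config$rarefy_depth,
               bnti_convention = config$bnti_convention)
  jsonlite::write_json(meta, out("run_metadata.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  files <- c(files, out("run_metadata.json"))
  results$files <- files
  invisible(results)
}
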