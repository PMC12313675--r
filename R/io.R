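#' Read a sample-by-taxon abundance table
#'
#' Reads TSV/CSV tables (first column holds ids) or BIOM-JSON (biom 1.0).  The
#' in-memory orientation is always samples x taxa; set `taxa_as_rows = FALSE`
#' if the file already has samples as rows.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"tsv"`, `"csv"`, `"biom-json"`; `"auto"`
#'   picks by file extension.
#' @param taxa_as_rows logical; `TRUE` (default, the common ASV-table layout)
#'   means file rows are taxa and columns are samples.
#' @param groups optional named character vector of sample groups, passed to
#'   [abundance_table()].
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 format = c("auto", "tsv", "csv", "biom-json"),
                                 taxa_as_rows = TRUE, groups = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", biom = "biom-json",
                     json = "biom-json",
                     stop("cannot guess format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for BIOM input", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa x samples
    return(abundance_table(t(m), groups = groups))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated ID(s) in first column: ", paste(dup, collapse = ", "),
         call. = FALSE)
  hdr <- names(df)[-1]
  dup_h <- unique(hdr[duplicated(hdr)])
  if (length(dup_h))
    stop("duplicated ID(s) in header: ", paste(dup_h, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  colnames(m) <- hdr
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path,
                           call. = FALSE)
  rownames(m) <- ids
  if (taxa_as_rows) m <- t(m)
  abundance_table(m, groups = groups)
}

#' Write an abundance table
#'
#' @inheritParams read_abundance_table
#' @param table an [abundance_table()].
#' @export
write_abundance_table <- function(table, path,
                                  format = c("auto", "tsv", "csv"),
                                  taxa_as_rows = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv"
  m <- table$counts
  if (taxa_as_rows) m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (taxa_as_rows) "taxon_id" else "sample_id"
  utils::write.table(df, path, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from Newick
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree; an error is raised if any branch length is
#'   missing (cophenetic distances are required downstream).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE),
                   warning = function(w) stop("Newick parse error in ", path,
                                              ": ", conditionMessage(w),
                                              call. = FALSE))
  if (is.null(tree)) stop("Newick parse error in ", path, call. = FALSE)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths; phylogenetic distances undefined",
         call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicated tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  tree
}

#' Read a sample-by-variable environment table
#'
#' CSV whose first column holds sample ids; all other columns are coerced to
#' numeric.  Cells that fail coercion are recorded as `NA` with a warning
#' naming the row and column, and are excluded pairwise downstream.
#'
#' @param path CSV file.
#' @return data.frame of numeric variables with sample ids as row names.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L)
    stop("environment table needs a sample-ID column plus >=1 variable",
         call. = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated sample ID(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  vars <- df[, -1, drop = FALSE]
  if (anyDuplicated(names(vars)))
    stop("duplicated variable name(s) in ", path, call. = FALSE)
  for (j in seq_along(vars)) {
    v <- vars[[j]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      filled <- !is.na(v) & v != "" & v != "NA"
      bad <- which(filled & is.na(coerced))
      if (length(bad) == sum(filled)) next  # label column: keep as character
      if (length(bad))
        warning(sprintf("non-numeric cell(s) in column '%s', row(s) %s set to NA",
                        names(vars)[j], paste(ids[bad], collapse = ", ")),
                call. = FALSE)
      vars[[j]] <- coerced
    }
  }
  rownames(vars) <- ids
  vars
}

#' Write an environment table
#'
#' @param env data.frame with sample ids as row names.
#' @param path output CSV path.
#' @export
write_env_table <- function(env, path) {
  df <- data.frame(sample_id = rownames(env), env, check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a co-occurrence network
#'
#' GraphML export (Gephi-loadable, with node `module` and `degree` attributes
#' when available) or a plain edge TSV with columns
#' source, target, rho, p, sign.
#'
#' @param net a [build_network()] result.
#' @param path output path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooc_network"))
  if (nrow(net$edges) == 0L) {
    warning("network is empty; writing header-only file", call. = FALSE)
    if (format == "edge-tsv") {
      utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      igraph::write_graph(igraph::make_empty_graph(0, directed = FALSE),
                          path, format = "graphml")
    }
    return(invisible(path))
  }
  if (format == "edge-tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(net$graph, path, format = "graphml")
  }
  invisible(path)
}

#' Import a co-occurrence network written by [write_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return a `cooc_network` (provenance fields are not recoverable from disk
#'   and are left `NULL`).
#' @export
read_network <- function(path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(source = ed$from, target = ed$to,
                        rho = ed$rho %||% ed$weight,
                        p = ed$p %||% NA_real_,
                        sign = ed$sign %||%
                          ifelse((ed$rho %||% ed$weight) >= 0,
                                 "positive", "negative"),
                        stringsAsFactors = FALSE)
  } else {
    edges <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target")], directed = FALSE)
    igraph::E(g)$rho <- edges$rho
    igraph::E(g)$p <- edges$p
    igraph::E(g)$sign <- edges$sign
    igraph::E(g)$weight <- abs(edges$rho)
    igraph::V(g)$degree <- igraph::degree(g)
  }
  new_cooc_network(g, edges, params = NULL)
}
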