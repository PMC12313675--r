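#' Sample-by-taxon abundance table
#'
#' The universal input container: a numeric matrix of non-negative counts (or
#' relative abundances) with samples as rows and taxa (typically ASVs) as
#' columns, plus an optional sample-to-group mapping.
#'
#' @param counts numeric matrix, samples x taxa, with unique row and column
#'   names.  All values must be non-negative; at least 2 samples and 2 taxa.
#' @param groups optional named character vector mapping sample id to group
#'   label (names must be a subset of the sample ids).
#' @return an object of class `abundance_table` with elements `counts` and
#'   `groups`.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("T", 1:4)))
#' abundance_table(m)
#' @export
abundance_table <- function(counts, groups = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts))
    stop("counts must be numeric", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and taxon column names",
         call. = FALSE)
  dup_s <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_s))
    stop("duplicated sample ID(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  dup_t <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_t))
    stop("duplicated taxon ID(s): ", paste(unique(dup_t), collapse = ", "),
         call. = FALSE)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least 2 samples and 2 taxa", call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (!is.null(groups)) {
    groups <- as.character(groups) |> stats::setNames(names(groups))
    if (is.null(names(groups)) || !all(names(groups) %in% rownames(counts)))
      stop("groups must be named by sample IDs present in the table",
           call. = FALSE)
  }
  structure(list(counts = counts, groups = groups), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total count %s; %s\n", format(sum(x$counts)),
              if (is.null(x$groups)) "no groups"
              else paste0("groups: ", paste(unique(x$groups), collapse = ", "))))
  invisible(x)
}

sample_ids <- function(table) rownames(table$counts)
taxon_ids  <- function(table) colnames(table$counts)

#' Relative abundances of an abundance table
#'
#' @param table an [abundance_table()].
#' @return matrix of row-normalised abundances (rows sum to 1).
#' @export
rel_abund <- function(table) {
  cts <- table$counts
  rs <- rowSums(cts)
  bad <- rownames(cts)[rs <= 0]
  if (length(bad))
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "),
         call. = FALSE)
  sweep(cts, 1, rs, "/")
}

#' Subset an abundance table
#'
#' @param table an [abundance_table()].
#' @param samples,taxa character vectors of ids to keep (default: all).
#' @param drop_empty_taxa drop taxa with zero total count after subsetting.
#' @return an [abundance_table()].
#' @export
subset_table <- function(table, samples = NULL, taxa = NULL,
                         drop_empty_taxa = FALSE) {
  cts <- table$counts
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(cts))
    if (length(missing))
      stop("unknown sample id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    cts <- cts[samples, , drop = FALSE]
  }
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, colnames(cts))
    if (length(missing))
      stop("unknown taxon id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    cts <- cts[, taxa, drop = FALSE]
  }
  if (drop_empty_taxa) cts <- cts[, colSums(cts) > 0, drop = FALSE]
  groups <- table$groups
  if (!is.null(groups)) groups <- groups[names(groups) %in% rownames(cts)]
  abundance_table(cts, groups = if (length(groups)) groups else NULL)
}

#' Rarefy an abundance table to even depth
#'
#' Optional subsampling without replacement to a common depth, for users who
#' prefer rarefied inputs; nothing in the pipeline rarefies by default.
#'
#' @param table an [abundance_table()] of integer counts.
#' @param depth target depth; every sample must have at least this many reads.
#' @param seed optional integer seed.
#' @return an [abundance_table()] whose rows all sum to `depth`.
#' @export
rarefy_table <- function(table, depth, seed = NULL) {
  cts <- table$counts
  if (any(cts != round(cts)))
    stop("rarefaction needs integer counts", call. = FALSE)
  if (any(rowSums(cts) < depth))
    stop("every sample must have total count >= depth", call. = FALSE)
  out <- with_seed(seed, vegan::rrarefy(cts, depth))
  abundance_table(out, groups = table$groups)
}
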