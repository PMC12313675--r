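#' Community cohesion
#'
#' Per-sample connectivity statistic built from null-corrected taxon-taxon
#' correlations.  Observed pairwise Pearson correlations of relative
#' abundances are corrected by subtracting a taxa-shuffle null expectation
#' (each taxon's abundances permuted independently across samples, `n_null`
#' replicates, pairwise mean correlation).  A taxon's positive (negative)
#' connectedness is the mean of its positive (negative) corrected
#' correlations with all partners, and a sample's positive (negative)
#' cohesion is the relative-abundance-weighted sum of connectedness over the
#' taxa it contains:
#' `cohesion_pos(s) = sum_j relabund[s, j] * connectedness_pos(j)`.
#' Positive cohesion is always >= 0 and negative cohesion <= 0 by
#' construction.
#'
#' @param table an [abundance_table()] with at least 3 samples.
#' @param n_null number of taxa-shuffle replicates (default 200).
#' @param seed optional integer seed.
#' @return list: `samples` (data.frame sample, positive_cohesion,
#'   negative_cohesion), `connectedness` (data.frame taxon, positive,
#'   negative), `n_null`.  Zero-variance taxa get `NA` connectedness and are
#'   excluded from the cohesion sums with a warning.
#' @export
cohesion <- function(table, n_null = 200, seed = NULL) {
  ra <- rel_abund(table)
  if (nrow(ra) < 3L) stop("cohesion needs at least 3 samples", call. = FALSE)
  sds <- apply(ra, 2, sd)
  flat <- sds == 0
  if (any(flat))
    warning(sum(flat), " zero-variance taxa excluded from cohesion",
            call. = FALSE)
  m <- ra[, !flat, drop = FALSE]
  nt <- ncol(m); ns <- nrow(m)
  obs <- cor(m)
  null_mean <- matrix(0, nt, nt)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      perm <- apply(m, 2, sample)
      null_mean <- null_mean + cor(perm)
    }
  })
  null_mean <- null_mean / n_null
  corrected <- obs - null_mean
  diag(corrected) <- 0
  conn_pos <- apply(corrected, 2, function(v) {
    pos <- v[v > 0]
    if (length(pos)) mean(pos) else 0
  })
  conn_neg <- apply(corrected, 2, function(v) {
    neg <- v[v < 0]
    if (length(neg)) mean(neg) else 0
  })
  coh_pos <- as.numeric(m %*% conn_pos)
  coh_neg <- as.numeric(m %*% conn_neg)
  connectedness <- data.frame(
    taxon = colnames(ra),
    positive = ifelse(flat, NA_real_,
                      conn_pos[match(colnames(ra), colnames(m))]),
    negative = ifelse(flat, NA_real_,
                      conn_neg[match(colnames(ra), colnames(m))]),
    row.names = NULL, stringsAsFactors = FALSE)
  list(samples = data.frame(sample = rownames(ra),
                            positive_cohesion = coh_pos,
                            negative_cohesion = coh_neg,
                            row.names = NULL, stringsAsFactors = FALSE),
       connectedness = connectedness, n_null = n_null)
}
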