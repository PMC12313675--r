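#' Geo-accumulation index
#'
#' `Igeo = log2(Cn / (1.5 * Bn))`, where `Cn` is the measured soil
#' concentration and `Bn` the geochemical background value; the factor 1.5
#' absorbs natural background fluctuation so that positive values flag
#' anthropogenic enrichment.
#'
#' @param c_n measured concentration(s), mg/kg, `>= 0`.
#' @param b_n geochemical background value(s), mg/kg, `> 0`.
#' @return numeric vector of Igeo values (log2 units); a zero concentration
#'   yields `-Inf` with a warning.
#' @examples
#' geo_accumulation_index(48, 20)   # log2(48/30) ~ 0.678
#' @export
geo_accumulation_index <- function(c_n, b_n) {
  if (anyNA(c_n) || anyNA(b_n) || any(c_n < 0))
    stop("concentrations must be non-negative and non-missing", call. = FALSE)
  if (any(b_n <= 0))
    stop("background values must be positive", call. = FALSE)
  if (any(c_n == 0))
    warning("zero concentration(s): Igeo is -Inf there", call. = FALSE)
  log2(c_n / (1.5 * b_n))
}

#' Single pollution index
#'
#' `PI = Ci / Si`: measured concentration over the environmental-quality
#' screening value (for Chinese agricultural soils, the GB 15618-2018 risk
#' screening values).
#'
#' @param c_i measured concentration(s), `>= 0`.
#' @param s_i screening value(s), `> 0`.
#' @return numeric vector of unitless PI values.
#' @export
single_pollution_index <- function(c_i, s_i) {
  if (anyNA(c_i) || any(c_i < 0))
    stop("concentrations must be non-negative and non-missing", call. = FALSE)
  if (anyNA(s_i) || any(s_i <= 0))
    stop("screening values must be positive", call. = FALSE)
  c_i / s_i
}

#' Nemerow integrated pollution index
#'
#' `NIPI = sqrt((PI_ave^2 + PI_max^2) / 2)` over the single pollution indices
#' of one sample; the max term makes the composite sensitive to the single
#' worst metal.
#'
#' @param pis numeric vector of single pollution indices for one sample
#'   (all `>= 0`, non-empty).
#' @return the NIPI value.
#' @examples
#' nemerow_index(c(1, 2, 3))  # sqrt(6.5)
#' @export
nemerow_index <- function(pis) {
  pis <- pis[!is.na(pis)]
  if (length(pis) == 0L) stop("empty PI list", call. = FALSE)
  if (any(pis < 0)) stop("PI values must be non-negative", call. = FALSE)
  sqrt((mean(pis)^2 + max(pis)^2) / 2)
}

#' Per-sample pollution indices for a metal concentration table
#'
#' Computes Igeo and PI per sample and metal, and the per-sample Nemerow
#' composite over all metals with a screening value.  Metals whose screening
#' value is `NA` still get Igeo but are excluded from PI/NIPI with a message.
#'
#' @param conc numeric matrix or data.frame, samples x metals (mg/kg), with
#'   sample row names and metal column names.
#' @param backgrounds named numeric vector of geochemical background values
#'   covering every metal column.
#' @param screening named numeric vector of screening values (may contain
#'   `NA` for metals without a published standard).
#' @return list with `per_metal` (long data.frame: sample, metal,
#'   concentration, igeo, pi) and `per_sample` (sample, pi_ave, pi_max, nipi).
#' @seealso [default_metal_references()]
#' @export
pollution_indices <- function(conc, backgrounds, screening) {
  conc <- as.matrix(conc)
  metals <- colnames(conc)
  if (is.null(metals) || is.null(rownames(conc)))
    stop("conc needs sample row names and metal column names", call. = FALSE)
  missing_b <- setdiff(metals, names(backgrounds))
  if (length(missing_b))
    stop("no background value for: ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  screening <- screening[intersect(names(screening), metals)]
  no_screen <- setdiff(metals, names(screening)[!is.na(screening)])
  if (length(no_screen))
    message("no screening value for ", paste(no_screen, collapse = ", "),
            "; excluded from PI/NIPI")
  per_metal <- do.call(rbind, lapply(metals, function(m) {
    s <- if (m %in% names(screening)) screening[[m]] else NA_real_
    data.frame(
      sample = rownames(conc), metal = m, concentration = conc[, m],
      igeo = geo_accumulation_index(conc[, m], backgrounds[[m]]),
      pi = if (is.na(s)) NA_real_ else single_pollution_index(conc[, m], s),
      row.names = NULL, stringsAsFactors = FALSE)
  }))
  per_sample <- do.call(rbind, lapply(rownames(conc), function(smp) {
    pis <- per_metal$pi[per_metal$sample == smp]
    pis <- pis[!is.na(pis)]
    data.frame(sample = smp, pi_ave = mean(pis), pi_max = max(pis),
               nipi = nemerow_index(pis), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  list(per_metal = per_metal, per_sample = per_sample)
}

#' Default metal background and screening references
#'
#' Geochemical backgrounds are Chinese soil background means; screening values
#' are the GB 15618-2018 agricultural risk screening values (6.5 < pH <= 7.5
#' class) where published.  GB 15618-2018 publishes no screening values for
#' Fe, Mn and Al; when `synthetic_screening = TRUE` (the default for the
#' simulator) placeholder screening values on the scale of the backgrounds are
#' supplied for them and flagged in the `synthetic` column — replace them with
#' site-appropriate standards for real data.
#'
#' @param synthetic_screening fill unpublished screening values (Fe, Mn, Al)
#'   with synthetic defaults instead of `NA`.
#' @return data.frame with columns metal, background, screening, synthetic.
#' @export
default_metal_references <- function(synthetic_screening = TRUE) {
  ref <- data.frame(
    metal      = c("Fe",    "Cu",  "Zn",  "Cd",    "Pb",  "Mn",  "Al"),
    background = c(29400,   22.6,  74.2,  0.097,   26.0,  583,   66300),
    screening  = c(NA,      100,   250,   0.3,     120,   NA,    NA),
    synthetic  = c(TRUE,    FALSE, FALSE, FALSE,   FALSE, TRUE,  TRUE),
    stringsAsFactors = FALSE)
  ref$synthetic[!is.na(ref$screening)] <- FALSE
  if (synthetic_screening) {
    fill <- c(Fe = 30000, Mn = 1500, Al = 70000)
    idx <- match(names(fill), ref$metal)
    ref$screening[idx] <- unname(fill)
    ref$synthetic[idx] <- TRUE
  }
  ref
}

#' Two-group comparison with BH adjustment
#'
#' Student's t-test (Welch by default) for each variable of a family, with
#' Benjamini-Hochberg adjustment across the family — the paper-style
#' comparison of pollution indices between tailings groups.
#'
#' @param values numeric matrix or data.frame, samples x variables.
#' @param groups factor/character of length `nrow(values)` with exactly two
#'   levels, each with at least 2 observations.
#' @param welch use the Welch (unequal-variance) t-test; `FALSE` gives the
#'   pooled-variance test.
#' @return data.frame: variable, statistic, p, p_adj.  When both groups are
#'   constant, p is 1 for equal means and 0 otherwise, by convention.
#' @export
compare_groups <- function(values, groups, welch = TRUE) {
  values <- as.data.frame(values)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  res <- do.call(rbind, lapply(names(values), function(v) {
    x <- values[[v]][groups == levels(groups)[1]]
    y <- values[[v]][groups == levels(groups)[2]]
    if (sd(x) == 0 && sd(y) == 0) {
      data.frame(variable = v, statistic = NA_real_,
                 p = if (mean(x) == mean(y)) 1 else 0,
                 stringsAsFactors = FALSE)
    } else {
      tt <- t.test(x, y, var.equal = !welch)
      data.frame(variable = v, statistic = unname(tt$statistic),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }
  }))
  res$p_adj <- bh_adjust(res$p)
  res
}
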