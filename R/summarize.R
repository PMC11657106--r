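#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the common scientific-software default); the
#' convention is configurable via `type` because published IQR endpoints
#' rarely state one.
#'
#' @param values non-empty numeric vector (NAs removed).
#' @param type quantile type passed to [stats::quantile()].
#' @return Named list `median`, `q1`, `q3`.
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5))  # 3 (2-4)
#' @export
median_iqr <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("median_iqr: empty input")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = type))
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Two-sample t-test for group comparison
#'
#' Independent Student's t-test (pooled variance) by default, matching the
#' study convention, with a Welch option; `significant` flags `p < alpha`
#' (default 0.05). The degenerate case of zero variance in both groups with
#' equal means returns `t = 0`, `p = 1` rather than an error.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @param var_equal pooled-variance Student's test (`TRUE`, default) or
#'   Welch's test (`FALSE`).
#' @param alpha significance threshold.
#' @return Named list `t`, `df`, `p`, `significant`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("compare_groups: each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  delta <- mean(a) - mean(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- if (se > 0)
      (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    else NA_real_
  }
  if (se == 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    t <- delta / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t = t, df = df, p = p, significant = p < alpha)
}

#' Percentage as printed
#'
#' `100 * numerator / denominator`, rounded half-away-from-zero to one
#' decimal place -- the convention used when reporting cohort proportions.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return Numeric percentage with one decimal.
#' @examples
#' percent(1021, 2147)  # 47.6
#' @export
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("percent: denominator must be > 0")
  x <- 100 * numerator / denominator
  sign(x) * floor(abs(x) * 10 + 0.5 + 1e-9) / 10
}

.cohort_samples <- function(cohort) {
  if (inherits(cohort, "hrd_cohort")) cohort$samples
  else as.data.frame(cohort)
}

#' Contingency table of two cohort axes
#'
#' Cross-tabulates two columns of the per-sample cohort table (e.g. `group`
#' by `hrd`) and reports counts plus within-row and within-column
#' percentages; marginals reconcile with the cohort size.
#'
#' @param cohort an `hrd_cohort` or its per-sample data.frame.
#' @param row_axis,col_axis column names.
#' @return List with `counts` (matrix), `row_pct`, `col_pct` (one-decimal
#'   percentages), `n`.
#' @export
crosstab <- function(cohort, row_axis, col_axis) {
  s <- .cohort_samples(cohort)
  for (ax in c(row_axis, col_axis))
    if (!ax %in% names(s)) stop("unknown axis: ", ax)
  counts <- table(s[[row_axis]], s[[col_axis]], dnn = c(row_axis, col_axis))
  counts <- unclass(counts)
  row_pct <- sweep(counts, 1, pmax(rowSums(counts), 1), "/") * 100
  col_pct <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 100
  one_dp <- function(m) {
    m[] <- sign(m) * floor(abs(m) * 10 + 0.5 + 1e-9) / 10
    m
  }
  list(counts = counts, row_pct = one_dp(row_pct),
       col_pct = one_dp(col_pct), n = sum(counts))
}

#' Subgroup GIS summaries
#'
#' One summary per level of a cohort axis: sample count, number with a
#' valid GIS, median and quartiles of GIS among valid samples, and the
#' proportion at or above the HRD cutoff. For `axis = "gene"` or
#' `"subtype"` the cohort's variant table is used (restricted to
#' gene-level-eligible samples, since gene-specific attribution is
#' otherwise impossible); other axes come from the per-sample table.
#' Levels with fewer than `min_n` samples are pooled into `"other"`;
#' output is ordered by descending n.
#'
#' @param cohort an `hrd_cohort`.
#' @param axis one of the per-sample columns (e.g. `group`, `study`,
#'   `setting`, `histology`, `race`, `location`, `hrd`) or `gene` /
#'   `subtype`.
#' @param min_n levels below this sample count are pooled into `"other"`
#'   (set to 0 to disable pooling).
#' @param cfg a [scoring_config()] supplying the HRD cutoff.
#' @return data.frame with columns `level`, `n`, `n_valid`, `median`, `q1`,
#'   `q3`, `prop_above_cutoff`.
#' @export
subgroup_report <- function(cohort, axis, min_n = 0,
                            cfg = scoring_config()) {
  if (axis %in% c("gene", "subtype")) {
    stopifnot(inherits(cohort, "hrd_cohort"))
    v <- cohort$variants[cohort$variants$gene_level_eligible, , drop = FALSE]
    s <- merge(v[, c("sample_id", axis)], .cohort_samples(cohort),
               by = "sample_id")
    s$.level <- s[[axis]]
  } else {
    s <- .cohort_samples(cohort)
    if (!axis %in% names(s)) stop("unknown axis: ", axis)
    s$.level <- s[[axis]]
  }
  if (nrow(s) == 0)
    return(data.frame(level = character(), n = integer(),
                      n_valid = integer(), median = numeric(),
                      q1 = numeric(), q3 = numeric(),
                      prop_above_cutoff = numeric()))
  cnt <- table(s$.level)
  small <- names(cnt)[cnt < min_n]
  if (length(small)) s$.level[s$.level %in% small] <- "other"
  out <- lapply(split(s, s$.level), function(ss) {
    g <- ss$gis[ss$valid]
    mi <- if (length(g)) median_iqr(g) else
      list(median = NA_real_, q1 = NA_real_, q3 = NA_real_)
    data.frame(level = ss$.level[1], n = nrow(ss), n_valid = length(g),
               median = mi$median, q1 = mi$q1, q3 = mi$q3,
               prop_above_cutoff = if (length(g))
                 mean(g >= cfg$hrd_cutoff) else NA_real_)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$n, out$level), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram bin table for GIS distributions
#'
#' Fixed-width bins over `[0, gis_cap]` (width 2 by default), suitable for
#' plotting the bimodal GIS distribution.
#'
#' @param gis_values numeric GIS values (NAs dropped).
#' @param width bin width.
#' @param cfg a [scoring_config()].
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
gis_histogram <- function(gis_values, width = 2, cfg = scoring_config()) {
  g <- gis_values[!is.na(gis_values)]
  breaks <- seq(0, cfg$gis_cap, by = width)
  if (breaks[length(breaks)] < cfg$gis_cap)
    breaks <- c(breaks, cfg$gis_cap)
  idx <- findInterval(g, breaks, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx > length(breaks) - 1] <- length(breaks) - 1
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = counts)
}
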