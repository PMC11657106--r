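#' Scoring configuration
#'
#' Length thresholds and score bounds for the three genomic-scar components
#' and the combined genomic instability score (GIS). Defaults follow the
#' established assay definitions: LOH regions must be longer than 15 Mb (but
#' shorter than the whole chromosome), telomeric allelic-imbalance regions
#' longer than 11 Mb, large-scale state transitions are breakpoints between
#' regions longer than 10 Mb after filtering out regions shorter than 3 Mb,
#' GIS is reported on a 0-100 scale, and GIS >= 42 defines HRD-positive.
#' All "longer/shorter than" comparisons are strict.
#'
#' @param loh_min_len minimum LOH run length in bp (exclusive bound).
#' @param tai_min_len minimum telomeric-imbalance run length in bp (exclusive).
#' @param lst_min_flank minimum flank length in bp on both sides of a counted
#'   breakpoint (exclusive).
#' @param lst_filter_len segments strictly shorter than this are filtered out
#'   before breakpoint counting.
#' @param gis_cap upper bound of the reported GIS scale.
#' @param hrd_cutoff GIS value at or above which a tumor is HRD-positive.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(loh_min_len = 15e6, tai_min_len = 11e6,
                           lst_min_flank = 10e6, lst_filter_len = 3e6,
                           gis_cap = 100, hrd_cutoff = 42) {
  cfg <- list(loh_min_len = loh_min_len, tai_min_len = tai_min_len,
              lst_min_flank = lst_min_flank, lst_filter_len = lst_filter_len,
              gis_cap = gis_cap, hrd_cutoff = hrd_cutoff)
  if (any(unlist(cfg[1:4]) <= 0)) stop("length thresholds must be positive")
  if (hrd_cutoff < 0 || hrd_cutoff > gis_cap)
    stop("hrd_cutoff must lie in [0, gis_cap]")
  structure(cfg, class = "scoring_config")
}

# maximal runs of a predicate over one chromosome's sorted segments;
# runs break where the predicate flips or where segments do not touch.
# Returns a data.frame of run start/end coordinates (predicate-true runs).
.pred_runs <- function(cs, pred) {
  n <- nrow(cs)
  if (n == 0 || !any(pred)) return(NULL)
  touching <- if (n > 1) cs$start[-1] == cs$end[-n] else logical(0)
  brk <- c(TRUE, pred[-1] != pred[-n] | !touching)
  first <- which(brk)
  last <- c(first[-1] - 1L, n)
  runs <- data.frame(start = cs$start[first], end = cs$end[last])
  runs <- runs[pred[first], , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' LOH score
#'
#' Counts loss-of-heterozygosity regions longer than 15 Mb (configurable)
#' but shorter than the whole chromosome. An LOH region is a maximal run of
#' touching segments with `minor_cn == 0` and `major_cn >= 1`; runs may
#' cross the centromere, and a run spanning an entire chromosome is
#' excluded whatever its length.
#'
#' @param profile a valid, tiling [segment_profile()].
#' @param genome a [genome_spec()].
#' @param cfg a [scoring_config()].
#' @return Integer count, or `NA_integer_` for an invalid profile.
#' @export
loh_score <- function(profile, genome, cfg = scoring_config()) {
  stopifnot(inherits(profile, "segment_profile"),
            inherits(genome, "genome_spec"))
  if (!profile$valid) return(NA_integer_)
  s <- .merge_equal(profile$segments)
  total <- 0L
  for (ch in unique(s$chrom)) {
    cs <- s[s$chrom == ch, , drop = FALSE]
    runs <- .pred_runs(cs, cs$minor_cn == 0 & cs$major_cn >= 1)
    if (is.null(runs) || nrow(runs) == 0) next
    len <- runs$end - runs$start
    chrom_len <- .chrom_row(genome, ch)$length
    whole <- runs$start == 0 & runs$end == chrom_len
    total <- total + sum(len > cfg$loh_min_len & !whole)
  }
  as.integer(total)
}

#' TAI score
#'
#' Counts regions of allelic imbalance (`major_cn != minor_cn`) that extend
#' to one of the subtelomeres (i.e. reach position 0 or the chromosome end),
#' do not cross or touch the centromere interval, and are longer than 11 Mb
#' (configurable). A run reaching both subtelomeres necessarily spans the
#' centromere and is excluded.
#'
#' @inheritParams loh_score
#' @return Integer count, or `NA_integer_` for an invalid profile.
#' @export
tai_score <- function(profile, genome, cfg = scoring_config()) {
  stopifnot(inherits(profile, "segment_profile"),
            inherits(genome, "genome_spec"))
  if (!profile$valid) return(NA_integer_)
  s <- .merge_equal(profile$segments)
  total <- 0L
  for (ch in unique(s$chrom)) {
    cs <- s[s$chrom == ch, , drop = FALSE]
    runs <- .pred_runs(cs, cs$major_cn != cs$minor_cn)
    if (is.null(runs) || nrow(runs) == 0) next
    row <- .chrom_row(genome, ch)
    len <- runs$end - runs$start
    telomeric <- runs$start == 0 | runs$end == row$length
    crosses_cen <- runs$start < row$cen_end & runs$end > row$cen_start
    total <- total + sum(telomeric & !crosses_cen & len > cfg$tai_min_len)
  }
  as.integer(total)
}

# one batch pass of the LST smoothing: drop all segments strictly shorter
# than filter_len, then merge every consecutive equal-state pair (absorbing
# the removed gap); repeated to fixpoint
.lst_filter <- function(cs, filter_len) {
  repeat {
    keep <- (cs$end - cs$start) >= filter_len
    cs2 <- cs[keep, , drop = FALSE]
    if (nrow(cs2) > 1) {
      new_run <- c(TRUE, !(cs2$major_cn[-1] == cs2$major_cn[-nrow(cs2)] &
                             cs2$minor_cn[-1] == cs2$minor_cn[-nrow(cs2)]))
      last <- c(which(new_run[-1]), nrow(cs2))
      merged <- cs2[new_run, , drop = FALSE]
      merged$end <- cs2$end[last]
      cs2 <- merged
    }
    rownames(cs2) <- NULL
    if (nrow(cs2) == nrow(cs) && (nrow(cs) == 0 ||
                                    all(cs2$start == cs$start & cs2$end == cs$end)))
      return(cs2)
    cs <- cs2
  }
}

#' LST score
#'
#' Counts large-scale state transitions: breakpoints between copy-number
#' regions longer than 10 Mb after filtering out regions shorter than 3 Mb
#' (both configurable). Computed per chromosome arm, so a junction spanning
#' the centromere is never counted. Filtering is iterative: all segments
#' strictly shorter than `lst_filter_len` are removed, newly adjacent
#' equal-state neighbours are re-merged (absorbing the removed span), and
#' the pass repeats until stable. A junction between two remaining
#' neighbours counts when their states differ and both are strictly longer
#' than `lst_min_flank`.
#'
#' @inheritParams loh_score
#' @return Integer count, or `NA_integer_` for an invalid profile.
#' @export
lst_score <- function(profile, genome, cfg = scoring_config()) {
  stopifnot(inherits(profile, "segment_profile"),
            inherits(genome, "genome_spec"))
  if (!profile$valid) return(NA_integer_)
  arms <- split_by_arm(normalize_profile(profile), genome)
  total <- 0L
  for (cs in arms) {
    cs <- .lst_filter(cs, cfg$lst_filter_len)
    n <- nrow(cs)
    if (n < 2) next
    len <- cs$end - cs$start
    differ <- cs$major_cn[-1] != cs$major_cn[-n] |
      cs$minor_cn[-1] != cs$minor_cn[-n]
    total <- total + sum(differ & len[-1] > cfg$lst_min_flank &
                           len[-n] > cfg$lst_min_flank)
  }
  as.integer(total)
}

#' Combined genomic instability score
#'
#' Sums the LOH, TAI and LST components and caps the total at `gis_cap`
#' (default 100) to honour the assay's reported 0-100 scale; the raw sum is
#' retained in `gis_raw` so the cap is auditable. For an invalid
#' (assay-failure) profile all scores are `NA` and `valid` is `FALSE`.
#'
#' @inheritParams loh_score
#' @return An object of class `scar_scores`: list with `sample_id`, `loh`,
#'   `tai`, `lst`, `gis`, `gis_raw`, `valid`.
#' @examples
#' g <- toy_genome()
#' p <- segment_profile("s1", data.frame(
#'   chrom = "A", start = c(0, 20e6), end = c(20e6, 200e6),
#'   major_cn = c(1, 1), minor_cn = c(0, 1)), genome = g)
#' gis(p, g)
#' @export
gis <- function(profile, genome, cfg = scoring_config()) {
  stopifnot(inherits(profile, "segment_profile"))
  if (!profile$valid) {
    return(structure(list(sample_id = profile$sample_id,
                          loh = NA_integer_, tai = NA_integer_,
                          lst = NA_integer_, gis = NA_real_,
                          gis_raw = NA_real_, valid = FALSE),
                     class = "scar_scores"))
  }
  loh <- loh_score(profile, genome, cfg)
  tai <- tai_score(profile, genome, cfg)
  lst <- lst_score(profile, genome, cfg)
  raw <- loh + tai + lst
  structure(list(sample_id = profile$sample_id, loh = loh, tai = tai,
                 lst = lst, gis = min(raw, cfg$gis_cap), gis_raw = raw,
                 valid = TRUE),
            class = "scar_scores")
}

#' @export
print.scar_scores <- function(x, ...) {
  if (!x$valid) {
    cat("<scar_scores> ", x$sample_id, ": invalid (assay failure)\n", sep = "")
  } else {
    cat(sprintf("<scar_scores> %s: LOH %d + TAI %d + LST %d -> GIS %g%s\n",
                x$sample_id, x$loh, x$tai, x$lst, x$gis,
                if (x$gis_raw > x$gis) sprintf(" (raw %g, capped)", x$gis_raw)
                else ""))
  }
  invisible(x)
}

#' HRD status classification
#'
#' A tumor is HRD-positive if it carries a tumor BRCA1/BRCA2 mutation
#' (tBRCAm) or its GIS meets the cutoff (>= 42 by default, boundary
#' inclusive); HRD-negative if non-tBRCAm with a valid GIS below the cutoff;
#' and HRD-unknown if non-tBRCAm and the GIS could not be determined
#' (assay failure). Every (scores, tbrcam) pair lands in exactly one state.
#'
#' @param scores a `scar_scores` object from [gis()].
#' @param tbrcam logical: does the tumor carry a deleterious/suspected
#'   deleterious BRCA1 or BRCA2 mutation?
#' @param cfg a [scoring_config()].
#' @return `"positive"`, `"negative"` or `"unknown"`.
#' @export
classify_hrd <- function(scores, tbrcam, cfg = scoring_config()) {
  stopifnot(inherits(scores, "scar_scores"), is.logical(tbrcam))
  if (tbrcam) return("positive")
  if (!scores$valid) return("unknown")
  if (scores$gis >= cfg$hrd_cutoff) "positive" else "negative"
}
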