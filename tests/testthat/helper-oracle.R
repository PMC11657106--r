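# independent brute-force enumerators for the three scar scores: every
# candidate run / junction is tested explicitly against the verbatim rules,
# with no code shared with the package implementation

# all maximal predicate-true runs over one chromosome's sorted segments,
# by exhaustive (i, j) enumeration
oracle_runs <- function(cs, pred) {
  n <- nrow(cs)
  runs <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (!all(pred[i:j])) next
    if (j > i && !all(cs$start[(i + 1):j] == cs$end[i:(j - 1)])) next
    ext_left <- i > 1 && pred[i - 1] && cs$end[i - 1] == cs$start[i]
    ext_right <- j < n && pred[j + 1] && cs$start[j + 1] == cs$end[j]
    if (ext_left || ext_right) next
    runs[[length(runs) + 1L]] <- c(start = cs$start[i], end = cs$end[j])
  }
  runs
}

oracle_loh <- function(profile, genome, cfg) {
  if (!profile$valid) return(NA_integer_)
  total <- 0L
  for (ch in unique(profile$segments$chrom)) {
    cs <- profile$segments[profile$segments$chrom == ch, , drop = FALSE]
    chrom_len <- genome$length[genome$name == ch]
    runs <- oracle_runs(cs, cs$minor_cn == 0 & cs$major_cn >= 1)
    for (r in runs) {
      is_whole <- r["start"] == 0 && r["end"] == chrom_len
      if (r["end"] - r["start"] > cfg$loh_min_len && !is_whole)
        total <- total + 1L
    }
  }
  total
}

oracle_tai <- function(profile, genome, cfg) {
  if (!profile$valid) return(NA_integer_)
  total <- 0L
  for (ch in unique(profile$segments$chrom)) {
    cs <- profile$segments[profile$segments$chrom == ch, , drop = FALSE]
    g <- genome[genome$name == ch, ]
    runs <- oracle_runs(cs, cs$major_cn != cs$minor_cn)
    for (r in runs) {
      touches_telomere <- r["start"] == 0 || r["end"] == g$length
      overlaps_cen <- r["start"] < g$cen_end && r["end"] > g$cen_start
      if (touches_telomere && !overlaps_cen &&
          r["end"] - r["start"] > cfg$tai_min_len)
        total <- total + 1L
    }
  }
  total
}

# batch smoothing, written as one-at-a-time scans: first merge equal
# neighbours to a fixpoint (the rules are about regions -- maximal
# equal-state runs -- not raw segments), then drop every region shorter
# than the filter, and repeat the whole pass until nothing changes
oracle_lst_arm <- function(cs, cfg) {
  merge_fixpoint <- function(cs) {
    repeat {
      merged <- FALSE
      for (i in seq_len(max(0, nrow(cs) - 1))) {
        if (cs$major_cn[i] == cs$major_cn[i + 1] &&
            cs$minor_cn[i] == cs$minor_cn[i + 1]) {
          cs$end[i] <- cs$end[i + 1]
          cs <- cs[-(i + 1), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (!merged) return(cs)
    }
  }
  repeat {
    before <- cs
    cs <- merge_fixpoint(cs)
    cs <- cs[cs$end - cs$start >= cfg$lst_filter_len, , drop = FALSE]
    if (nrow(cs) == nrow(before) &&
        all(cs$start == before$start & cs$end == before$end))
      break
  }
  cnt <- 0L
  for (i in seq_len(max(0, nrow(cs) - 1))) {
    state_differs <- cs$major_cn[i] != cs$major_cn[i + 1] ||
      cs$minor_cn[i] != cs$minor_cn[i + 1]
    if (state_differs &&
        cs$end[i] - cs$start[i] > cfg$lst_min_flank &&
        cs$end[i + 1] - cs$start[i + 1] > cfg$lst_min_flank)
      cnt <- cnt + 1L
  }
  cnt
}

oracle_lst <- function(profile, genome, cfg) {
  if (!profile$valid) return(NA_integer_)
  total <- 0L
  s <- profile$segments
  for (ch in unique(s$chrom)) {
    g <- genome[genome$name == ch, ]
    for (bounds in list(c(0, g$cen_start), c(g$cen_end, g$length))) {
      cs <- s[s$chrom == ch & s$end > bounds[1] & s$start < bounds[2], ,
              drop = FALSE]
      if (nrow(cs) == 0) next
      cs$start <- pmax(cs$start, bounds[1])
      cs$end <- pmin(cs$end, bounds[2])
      total <- total + oracle_lst_arm(cs, cfg)
    }
  }
  total
}
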