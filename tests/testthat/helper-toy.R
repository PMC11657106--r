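# shared builders for the 3-chromosome toy genome (A: 200 Mb cen 90-100,
# B: 150 Mb cen 60-70, C: 100 Mb cen 45-50)

toy <- toy_genome()
default_cfg <- scoring_config()

# quick profile: seg() rows are c(chrom, start_mb, end_mb, major, minor)
seg <- function(chrom, start_mb, end_mb, major, minor) {
  data.frame(chrom = chrom, start = start_mb * 1e6, end = end_mb * 1e6,
             major_cn = major, minor_cn = minor)
}

mk_profile <- function(..., sample_id = "s", genome = toy) {
  segment_profile(sample_id, do.call(rbind, list(...)), genome = genome)
}

# fully diploid profile over every toy chromosome
flat_profile <- function(sample_id = "s", genome = toy) {
  segs <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i)
    data.frame(chrom = genome$name[i], start = 0, end = genome$length[i],
               major_cn = 1, minor_cn = 1)))
  segment_profile(sample_id, segs, genome = genome)
}

# random tiling of the toy genome with <= max_segs segments in total;
# states drawn from a small unphased palette
random_profile <- function(max_segs = 12, sample_id = "r", genome = toy) {
  states <- matrix(c(1, 1, 1, 0, 2, 1, 2, 2, 2, 0, 3, 1, 0, 0, 3, 0),
                   ncol = 2, byrow = TRUE)
  n_chrom <- nrow(genome)
  ks <- rep(1L, n_chrom)
  extra <- max_segs - n_chrom
  if (extra > 0) {
    add <- sample.int(n_chrom, sample.int(extra + 1, 1) - 1L, replace = TRUE)
    for (a in add) ks[a] <- ks[a] + 1L
  }
  segs <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    len <- genome$length[i]
    k <- ks[i]
    brk <- sort(sample.int(len - 1, k - 1))
    bounds <- c(0, brk, len)
    st <- states[sample.int(nrow(states), k, replace = TRUE), , drop = FALSE]
    data.frame(chrom = genome$name[i], start = bounds[-(k + 1)],
               end = bounds[-1], major_cn = st[, 1], minor_cn = st[, 2])
  }))
  segment_profile(sample_id, segs, genome = genome)
}

# split random segments at random interior points (equal-state refinement)
refine_profile <- function(profile, n_splits = 3) {
  s <- profile$segments
  for (i in seq_len(n_splits)) {
    j <- sample.int(nrow(s), 1)
    if (s$end[j] - s$start[j] < 2) next
    cut <- s$start[j] + sample.int(s$end[j] - s$start[j] - 1, 1)
    top <- s[j, ]; bot <- s[j, ]
    top$end <- cut; bot$start <- cut
    s <- rbind(s[seq_len(j - 1), ], top, bot,
               s[setdiff(seq_len(nrow(s)), seq_len(j)), ])
  }
  segment_profile(profile$sample_id, s)
}
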