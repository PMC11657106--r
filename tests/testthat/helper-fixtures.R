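# synthetic "machine twin" cohorts encoding the printed marginals of the
# published pooled analysis (2147 tumors across six trials); no patient
# data -- every record is constructed from the printed counts alone

# single-chromosome fixture genome: large enough that a block-alternation
# profile exceeds the HRD cutoff
fixture_genome <- function() {
  genome_spec(data.frame(name = "F1", length = 600e6,
                         cen_start = 295e6, cen_end = 305e6))
}

# high-GIS prototype: alternating 1/1|2/2 blocks of 12 Mb on both arms
# (every junction is an LST); GIS ~ 48 >= 42
fixture_profile_high <- function(sample_id, genome = fixture_genome()) {
  mk_arm <- function(a, b) {
    starts <- seq(a, b - 12e6, by = 12e6)
    ends <- c(starts[-1], b)
    cn <- rep(c(1, 2), length.out = length(starts))
    data.frame(chrom = "F1", start = starts, end = ends,
               major_cn = cn, minor_cn = cn)
  }
  segs <- rbind(mk_arm(0, 295e6),
                data.frame(chrom = "F1", start = 295e6, end = 305e6,
                           major_cn = 1, minor_cn = 1),
                mk_arm(305e6, 600e6))
  segment_profile(sample_id, segs, genome = genome)
}

# low-GIS prototype: fully diploid, GIS 0
fixture_profile_low <- function(sample_id, genome = fixture_genome()) {
  segment_profile(sample_id, data.frame(
    chrom = "F1", start = 0, end = 600e6, major_cn = 1, minor_cn = 1),
    genome = genome)
}

fixture_profile_invalid <- function(sample_id) {
  segment_profile(sample_id, NULL, valid = FALSE)
}

# cohort twin of the GIS/biomarker bookkeeping: group sizes, valid-GIS
# counts and above-cutoff counts per group, split into the four studies
# with non-BRCA groups (1788 samples) vs the BRCA-only studies (359)
fixture_cohort_records <- function() {
  genome <- fixture_genome()
  hi <- fixture_profile_high("proto_hi", genome)$segments
  lo <- fixture_profile_low("proto_lo", genome)$segments
  spec <- rbind(
    # group, gene, study bucket, n_high, n_low, n_invalid
    data.frame(group = "tBRCAm", gene = "BRCA1", study = "four",
               hi = 528, lo = 29, inv = 105),
    data.frame(group = "tBRCAm", gene = "BRCA1", study = "brca_only",
               hi = 282, lo = 24, inv = 53),
    data.frame(group = "non-BRCA-HRRm", gene = "RAD51C", study = "four",
               hi = 55, lo = 52, inv = 14),
    data.frame(group = "non-HRRm", gene = "TP53", study = "four",
               hi = 264, lo = 604, inv = 137))
  records <- list()
  k <- 0
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    kinds <- rep(c("hi", "lo", "inv"), times = c(row$hi, row$lo, row$inv))
    for (kind in kinds) {
      k <- k + 1
      sid <- sprintf("F%04d", k)
      prof <- switch(kind,
        hi = structure(list(sample_id = sid, segments = hi, valid = TRUE),
                       class = "segment_profile"),
        lo = structure(list(sample_id = sid, segments = lo, valid = TRUE),
                       class = "segment_profile"),
        inv = fixture_profile_invalid(sid))
      v <- variant_calls(sid, row$gene)
      records[[k]] <- tumor_record(sid, prof, v, study = row$study)
    }
  }
  records
}

# zygosity twin of the BRCA biallelic-loss table: 838 evaluable BRCAm
# tumors -- germline 672 (658 biallelic), somatic 108 (101), origin
# undetermined 58 (56)
fixture_zygosity_inputs <- function() {
  genome <- fixture_genome()
  locus <- gene_locus("BRCA1", "F1", 150e6, 150.1e6)
  biallelic_segs <- rbind(
    seg("F1", 0, 145, 1, 1), seg("F1", 145, 155, 1, 0),
    seg("F1", 155, 600, 1, 1))
  het_segs <- seg("F1", 0, 600, 1, 1)
  mk <- function(n_bi, n_het, germ, offset) {
    lapply(seq_len(n_bi + n_het), function(j) {
      sid <- sprintf("Z%04d", offset + j)
      segs <- if (j <= n_bi) biallelic_segs else het_segs
      list(profile = segment_profile(sid, segs, genome = genome),
           variants = variant_calls(sid, "BRCA1", germline_test = germ))
    })
  }
  c(mk(658, 14, "positive", 0),
    mk(101, 7, "negative", 1000),
    mk(56, 2, "not-done", 2000))
}

fixture_locus_brca1 <- function() gene_locus("BRCA1", "F1", 150e6, 150.1e6)
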