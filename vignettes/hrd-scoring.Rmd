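---
title: "Genomic scar scores and HRD classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic scar scores and HRD classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscar)
```

## The model

A tumor's allele-specific copy-number landscape is a tiling of each
chromosome by segments with unphased states `(major_cn, minor_cn)`,
`minor_cn <= major_cn`. Three scar statistics are computed on this
landscape; their sum, capped to a 0–100 scale, is the genomic instability
score (GIS), and `GIS >= 42` or a tumor BRCA1/BRCA2 mutation defines
HRD-positivity. The package's scope starts downstream of segmentation:
it never touches reads, BAFs or logR — the assay that produces the
segments, and its variant interpretation, are configuration and input,
not code.

### The three rules, as implemented

- **LOH**: a region is a maximal run of touching segments with
  `minor_cn = 0` and `major_cn >= 1`. Runs longer than `loh_min_len`
  (15 Mb) count unless they span an entire chromosome. Runs may cross
  the centromere: of the three definitions only LOH lacks an arm clause,
  and we preserve that asymmetry deliberately.
- **TAI**: a maximal allelic-imbalance run (`major_cn != minor_cn`)
  counts when it touches position 0 or the chromosome end, does not
  overlap the centromere interval, and is longer than `tai_min_len`
  (11 Mb). A run touching both telomeres necessarily spans the
  centromere and is thereby excluded. Imbalance is ploidy-free
  (`major != minor`), since no ploidy adjustment is specified anywhere;
  the comparison is configurable only in the sense that the thresholds
  are.
- **LST**: computed per chromosome arm, so no breakpoint spanning a
  centromere is ever counted. Regions strictly shorter than
  `lst_filter_len` (3 Mb) are removed and newly adjacent equal-state
  neighbours re-merged (absorbing the removed span), repeating to a
  fixpoint; then a junction between adjacent remaining regions counts
  when their states differ and both are strictly longer than
  `lst_min_flank` (10 Mb).

Three interpretive decisions deserve flagging:

1. **Strictness.** All "longer/shorter than" comparisons are strict.
   A region of exactly 15 Mb does not count toward LOH; a region of
   exactly 3 Mb survives the LST filter. The rule text says "longer
   than" and "shorter than", and we take it literally; users who prefer
   inclusive bounds can shift a threshold by one base pair.
2. **Batch filtering.** The LST smoothing is iterative, and the order of
   operations within an iteration matters: removing short regions one at
   a time can splice a removed region's span into a merged neighbour
   that a batch pass would have deleted outright. We define one pass as
   *remove every* sub-threshold region, *then* merge all equal-state
   neighbours, repeated until stable. The test suite's independent
   oracle implements the same semantics through a different control
   structure (one-at-a-time scans to fixpoints), so agreement between
   them checks the arithmetic, not the convention.
3. **The cap.** The raw component sum is unbounded, yet the score is
   defined on 0–100. Whether the commercial assay normalizes, caps or
   simply never observes sums above 100 is undisclosed; we cap at
   `gis_cap` and retain the raw sum in `gis_raw` so the cap is always
   auditable.

Scoring is representation independent: splitting any segment into
equal-state pieces, or merging such pieces (`normalize_profile()`),
never changes any score. This is a tested invariant, not an assumption.

### HRD triage

`classify_hrd()` implements the three-way partition exactly: positive if
tBRCAm or (valid and `GIS >= cutoff`); negative if non-tBRCAm, valid and
below the cutoff; unknown if non-tBRCAm and the assay failed. Assay
failure is modelled as a profile-level flag (`valid = FALSE`) — e.g. a
low-purity sample — under which all scores are undefined (`NA`), never
zero: silently scoring a failed assay as 0 would fabricate HRD-negative
calls, which is precisely what the failure flag exists to prevent.

## Zygosity

Biallelic loss of a mutated gene is called from the segments overlapping
its locus: biallelic if every overlapping segment has `minor_cn = 0`
(the minor allele is verifiably absent — the segment-level equivalent of
a zero minor-allele frequency), or the gene carries a homozygous
deleterious variant, or two or more distinct deleterious variants;
heterozygous if the locus is wholly in a non-LOH state; unknown if an
LOH/non-LOH boundary falls strictly inside the gene or the assay failed.
"The region encompassing the gene" is operationalized as the overlap
set of the locus interval — no flanking window, since none is specified.
`apply_manual_review()` reproduces the documented correction: a
deleterious variant co-occurring with locus LOH evidence upgrades an
unknown or heterozygous call to biallelic (basis `manual-correction`);
the upgrade requires an overlapping `minor_cn = 0` segment and is
idempotent. Only that documented correction is implemented; any other
manual curation the source assay applied is unknowable from the outside.

## Biomarker classification

Groups follow the precedence **tBRCAm > non-BRCA HRRm > non-HRRm** over
deleterious/suspected-deleterious variants only. The 13-gene HRR panel
(ATM, BARD1, BRIP1, CDK12, CHEK1, CHEK2, FANCL, PALB2, PPP2R2A, RAD51B,
RAD51C, RAD51D, RAD54L) ships as JSON configuration, not code — panels
differ between assays. Somatic origin is a positive tumor finding with a
negative germline test; no germline test means undetermined. Tumors with
co-occurring BRCA1 and BRCA2, or with two distinct panel genes, keep
their group but are flagged ineligible for individual-gene analyses.
CCNE1 amplification is an input annotation (subtype `amplification`),
not derived from segment copy number: no amplification threshold is
specified by the source assay, and inventing one would silently change
group compositions.

## The synthetic cohort generator

Real segment landscapes cannot be sampled with known scores, so the
generator is **plan-then-construct**: event counts are drawn first from
per-group count distributions, then `construct_profile()` lays out
segments that realize them exactly. The layout engine gives each event
type its own chromosome arm over a diploid (1/1) background:

- LOH runs are interior 16 Mb `1/0` tracts separated by 5 Mb balanced
  guards; guards are sized to survive the 3 Mb LST filter yet stay at or
  below the 10 Mb flank bound, so no planted LOH edge ever counts as an
  LST, and the leading guard keeps the run off the telomere so it never
  counts as TAI.
- TAI tracts are `2/1` (imbalanced but not LOH) filling an arm from its
  telomere up to a guard short of the centromere.
- LST junctions are alternating balanced `1/1`/`2/2` blocks of at least
  11 Mb tiling an arm end to end; balanced states contribute neither
  LOH nor TAI.
- Planted biallelic loss is a ~4 Mb `1/0` tract over the gene locus —
  above the LST filter, far below the LOH length bound, and clear of
  telomeres — on an arm reserved for the sample's mutated gene.

Per-sample seeds jitter segment lengths and nothing that affects counts;
identical seeds reproduce byte-identical output files. Draws that exceed
the genome's arm capacity (possible for TAI, which is limited to one
tract per arm) are decremented until they fit, and the *recorded* plan is
the truncated truth, so recovery tests remain exact. Infeasible explicit
plans raise an error naming the shortfall rather than silently scoring
less than planted.

Defaults: event counts are negative binomial (counts in tumors are
over-dispersed; the family is configurable, and unidentifiable from the
published medians/IQRs in any case). The `"paper"` preset transcribes the
published cohort structure — prevalences 47.6% / 5.6% / 46.8%, assay
failure 15.5% / 11.6% / 13.6%, biallelic rates 97.3% / 92% / 50%, and
GIS centres 62 / 42 / 32 with IQR-matched dispersions (component size
16 / 1.4 / 0.54). The per-component mean is calibrated numerically so the
median of the three-component sum hits the published group median; the
even split of each centre across LOH/TAI/LST is explicitly arbitrary —
component-level contributions are not published. The preset is
calibration for eyeballing realistic cohorts, not ground truth about any
patient.

What the generator does **not** emulate: mutational processes (scars are
placed geometrically, not generated biologically), whole-genome
duplication, intra-tumor heterogeneity or purity effects (failure is a
coin flip, not a purity model), BRCA1/RAD51C promoter methylation,
co-occurring mutations within a sample (one mutated gene per sample),
and any correlation between scar counts and mutation status beyond the
group means. A green recovery test therefore establishes that the
*pipeline* is correct and internally consistent — not that real tumors
look like the preset.

## Summary statistics

Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7) — the published IQR endpoints are integers and
consistent with several conventions, so the choice is configurable.
Group comparison is the independent Student's *t*-test (pooled variance)
with `p < 0.05` significance, plus a Welch option since tilde-reported
p-values cannot disambiguate the variant used; the degenerate
zero-variance-equal-means case returns `t = 0, p = 1` by definition
rather than erroring. Percentages are rounded half away from zero to one
decimal, matching printed cohort proportions (e.g. 1021/2147 prints as
47.6). No multiple-testing correction is applied, matching the source
convention. Subgroup reports order levels by descending n and pool
levels below a configurable minimum into `"other"`; gene- and
subtype-level reports use only gene-level-eligible samples, since
gene-specific attribution is undefined for excluded double-hit tumors.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere; lengths are exact
  base-pair differences and Mb thresholds exact constants (15 Mb =
  15,000,000), since no rounding rule exists to follow.
- Profiles may omit chromosomes; omitted chromosomes contribute zero to
  every score (the conservative reading — the alternative would invent
  scars from missing data).
- Copy-number states are unordered pairs with `minor <= major`, so a
  "phase-only" junction (2/1 vs 1/2) cannot be represented: the assay
  output being modelled is unphased.
- An empty variant list with a failed assay still classifies
  (non-HRRm, HRD-unknown); `assign_origin()` on a non-BRCA record is a
  contract error, not a silent `NA`.
- `percent()` requires a positive denominator; `median_iqr()` rejects
  empty input.

## Known limitations

The genome build behind the source assay is unpublished; the shipped
22-autosome spec is hg19-like configuration and every function takes an
arbitrary `genome_spec`. The GIS cap is this package's explicit stand-in
for an undisclosed normalization. Zygosity manual review implements only
the documented correction rule. Survival/efficacy analyses, methylation,
whole-genome duplication handling and the wet-lab assay itself are out
of scope by design.
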