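#' Gene locus
#'
#' A gene's genomic interval, used to test whether the chromosomal region
#' encompassing the gene is in LOH.
#'
#' @param gene gene symbol.
#' @param chrom chromosome label.
#' @param start,end 0-based half-open interval in bp, `start < end`.
#' @return An object of class `gene_locus`.
#' @export
gene_locus <- function(gene, chrom, start, end) {
  if (!(start < end) || start < 0) stop("gene_locus: need 0 <= start < end")
  structure(list(gene = as.character(gene), chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end)),
            class = "gene_locus")
}

#' Read gene loci from JSON
#'
#' Expects an array of objects with fields `gene`, `chrom`, `start`, `end`.
#'
#' @param path path to a JSON file.
#' @return Named list of [gene_locus()] objects keyed by gene symbol.
#' @export
read_loci <- function(path) {
  tab <- as.data.frame(jsonlite::fromJSON(path))
  loci <- lapply(seq_len(nrow(tab)), function(i)
    gene_locus(tab$gene[i], tab$chrom[i], tab$start[i], tab$end[i]))
  names(loci) <- tab$gene
  loci
}

#' Default gene loci
#'
#' Gene intervals for BRCA1/BRCA2, the 13-gene homologous-recombination
#' repair panel and frequently assessed non-HRR genes, positioned on the
#' default 22-autosome genome (`inst/extdata/loci_default.json`).
#'
#' @return Named list of [gene_locus()] objects.
#' @export
default_loci <- function() {
  read_loci(system.file("extdata", "loci_default.json",
                        package = "hrdscar", mustWork = TRUE))
}

.deleterious <- function(variants) {
  variants[variants$classification %in%
             c("deleterious", "suspected-deleterious"), , drop = FALSE]
}

.new_zygosity_call <- function(sample_id, gene, status, basis) {
  stopifnot(status %in% c("biallelic", "heterozygous", "unknown"),
            basis %in% c("region-LOH", "homozygous-variant", "multi-variant",
                         "manual-correction", "boundary", "assay-failure"))
  if (status == "unknown" && !basis %in% c("boundary", "assay-failure"))
    stop("unknown status requires basis boundary or assay-failure")
  structure(list(sample_id = sample_id, gene = gene, status = status,
                 basis = basis),
            class = "zygosity_call")
}

#' @export
print.zygosity_call <- function(x, ...) {
  cat(sprintf("<zygosity_call> %s %s: %s (%s)\n",
              x$sample_id, x$gene, x$status, x$basis))
  invisible(x)
}

#' Call gene-level zygosity (biallelic loss)
#'
#' Determines whether both copies of a mutated gene are lost. The call is
#' `biallelic` when (a) every segment overlapping the locus has
#' `minor_cn == 0` (region LOH: no wild-type allele remains over a
#' deleterious variant), (b) the gene carries a homozygous deleterious
#' variant, or (c) it carries two or more distinct deleterious variants.
#' It is `heterozygous` when the locus lies wholly in a non-LOH state with
#' a single deleterious variant (one functional copy remains), and
#' `unknown` when an LOH/non-LOH boundary falls strictly inside the gene
#' (and neither (b) nor (c) applies) or when the copy-number assay failed.
#'
#' @param profile a [segment_profile()].
#' @param locus a [gene_locus()].
#' @param variants data.frame of this sample's variant calls (columns
#'   `gene`, `classification`, `homozygous`); only
#'   deleterious/suspected-deleterious rows for the locus gene are used.
#' @return A `zygosity_call`.
#' @export
call_zygosity <- function(profile, locus, variants = NULL) {
  stopifnot(inherits(profile, "segment_profile"),
            inherits(locus, "gene_locus"))
  v <- .gene_variants(variants, locus$gene)
  # variant-based biallelic evidence holds even without copy-number data
  if (nrow(v) > 0 && any(v$homozygous))
    return(.new_zygosity_call(profile$sample_id, locus$gene,
                              "biallelic", "homozygous-variant"))
  if (nrow(v) >= 2)
    return(.new_zygosity_call(profile$sample_id, locus$gene,
                              "biallelic", "multi-variant"))
  if (!profile$valid)
    return(.new_zygosity_call(profile$sample_id, locus$gene,
                              "unknown", "assay-failure"))
  ov <- .locus_overlap(profile, locus)
  if (nrow(ov) == 0)
    stop("locus ", locus$gene, " on chromosome ", locus$chrom,
         " absent from profile ", profile$sample_id)
  loh <- ov$minor_cn == 0
  if (all(loh))
    return(.new_zygosity_call(profile$sample_id, locus$gene,
                              "biallelic", "region-LOH"))
  if (any(loh))  # mixed: an LOH/non-LOH boundary lies inside the gene
    return(.new_zygosity_call(profile$sample_id, locus$gene,
                              "unknown", "boundary"))
  .new_zygosity_call(profile$sample_id, locus$gene,
                     "heterozygous", "region-LOH")
}

.gene_variants <- function(variants, gene) {
  if (is.null(variants) || nrow(variants) == 0)
    return(data.frame(gene = character(), classification = character(),
                      homozygous = logical()))
  v <- .deleterious(variants[variants$gene == gene, , drop = FALSE])
  if (!"homozygous" %in% names(v)) v$homozygous <- FALSE
  v$homozygous <- as.logical(v$homozygous) & !is.na(v$homozygous)
  unique(v)
}

.locus_overlap <- function(profile, locus) {
  s <- profile$segments
  s[s$chrom == locus$chrom & s$end > locus$start & s$start < locus$end, ,
    drop = FALSE]
}

#' Manual-review correction of a zygosity call
#'
#' Mirrors the assay's manual review of initial LOH calls: a sample with a
#' deleterious (or suspected deleterious) variant whose locus shows LOH
#' evidence (any overlapping segment with `minor_cn == 0`, i.e. the minor
#' allele is verified absent) is upgraded to biallelic even if the initial
#' region call was `unknown` (boundary) or `heterozygous`. The upgrade
#' records basis `manual-correction`. Idempotent; calls with no LOH overlap
#' or no deleterious variant are returned unchanged.
#'
#' @param call a `zygosity_call` from [call_zygosity()].
#' @param variants data.frame of the sample's variant calls.
#' @param profile the sample's [segment_profile()].
#' @param locus the [gene_locus()] the call refers to.
#' @return A `zygosity_call`.
#' @export
apply_manual_review <- function(call, variants, profile, locus) {
  stopifnot(inherits(call, "zygosity_call"), inherits(locus, "gene_locus"),
            call$gene == locus$gene)
  if (call$status == "biallelic") return(call)
  v <- .gene_variants(variants, locus$gene)
  if (nrow(v) == 0) return(call)
  if (!profile$valid) return(call)
  ov <- .locus_overlap(profile, locus)
  # minor-allele state must be verified zero before any biallelic upgrade
  if (nrow(ov) > 0 && any(ov$minor_cn == 0))
    return(.new_zygosity_call(call$sample_id, call$gene,
                              "biallelic", "manual-correction"))
  call
}
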