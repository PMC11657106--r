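#' The default non-BRCA homologous-recombination-repair gene panel
#'
#' The 13 genes whose loss-of-function mutations define the non-BRCA HRRm
#' biomarker group. Shipped as configuration
#' (`inst/extdata/hrr_panel.json`): panels differ across assays, so the
#' panel is never hard-coded into classification logic.
#'
#' @return Character vector of gene symbols.
#' @export
default_hrr_panel <- function() {
  unlist(jsonlite::fromJSON(system.file("extdata", "hrr_panel.json",
                                        package = "hrdscar",
                                        mustWork = TRUE)))
}

.variant_cols <- c("sample_id", "gene", "classification", "subtype",
                   "homozygous", "germline_test")

#' Construct a variant-call table
#'
#' One row per reported mutation. `classification` is one of
#' `deleterious`, `suspected-deleterious`, `other` (only the first two enter
#' biomarker grouping); `subtype` one of `missense`, `splice`,
#' `loss/rearrangement`, `nonsense`, `frameshift/indel`, `amplification`;
#' `germline_test` one of `positive`, `negative`, `not-done`.
#'
#' @param sample_id,gene,classification,subtype,homozygous,germline_test
#'   vectors, recycled to common length.
#' @return data.frame with the canonical variant columns.
#' @export
variant_calls <- function(sample_id, gene, classification = "deleterious",
                          subtype = "frameshift/indel", homozygous = FALSE,
                          germline_test = "not-done") {
  if (length(sample_id) == 0)
    return(data.frame(sample_id = character(), gene = character(),
                      classification = character(), subtype = character(),
                      homozygous = logical(), germline_test = character(),
                      stringsAsFactors = FALSE))
  v <- data.frame(sample_id = sample_id, gene = gene,
                  classification = classification, subtype = subtype,
                  homozygous = homozygous, germline_test = germline_test,
                  stringsAsFactors = FALSE)
  .check_variants(v)
  v
}

.check_variants <- function(v) {
  miss <- setdiff(.variant_cols, names(v))
  if (length(miss))
    stop("variant table missing columns: ", paste(miss, collapse = ", "))
  bad <- !v$classification %in% c("deleterious", "suspected-deleterious",
                                  "other")
  if (any(bad)) stop("bad variant classification: ",
                     v$classification[which(bad)[1]])
  bad <- !v$germline_test %in% c("positive", "negative", "not-done")
  if (any(bad)) stop("bad germline_test value: ",
                     v$germline_test[which(bad)[1]])
  invisible(TRUE)
}

#' Read / write variant-call TSV
#'
#' Tab-separated, one row per mutation, columns `sample_id`, `gene`,
#' `classification`, `subtype`, `homozygous` (TRUE/FALSE),
#' `germline_test`.
#'
#' @param path file path.
#' @return `read_variants`: validated data.frame.
#' @export
read_variants <- function(path) {
  v <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  v$homozygous <- as.logical(v$homozygous)
  .check_variants(v)
  v[, .variant_cols]
}

#' @rdname read_variants
#' @param variants variant data.frame.
#' @export
write_variants <- function(variants, path) {
  .check_variants(variants)
  utils::write.table(variants[, .variant_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tumor record
#'
#' Bundles one sample's variant calls, copy-number profile and clinical
#' annotation axes used by subgroup reports.
#'
#' @param sample_id sample label.
#' @param profile a [segment_profile()].
#' @param variants variant data.frame for this sample (may be empty).
#' @param study,setting,histology,race,location free-text subgroup labels;
#'   `setting` is conventionally `newly-diagnosed` or `PSROC`.
#' @return An object of class `tumor_record`.
#' @export
tumor_record <- function(sample_id, profile, variants = NULL,
                         study = "study1", setting = "newly-diagnosed",
                         histology = "serous", race = "unknown",
                         location = "ovary") {
  if (is.null(variants))
    variants <- variant_calls(character(), character())
  .check_variants(variants)
  if (nrow(variants) > 0 && !all(variants$sample_id == sample_id))
    stop("variant rows do not belong to sample ", sample_id)
  stopifnot(inherits(profile, "segment_profile"))
  structure(list(sample_id = as.character(sample_id), profile = profile,
                 variants = variants, study = study, setting = setting,
                 histology = histology, race = race, location = location),
            class = "tumor_record")
}

.brca_genes <- c("BRCA1", "BRCA2")

#' Assign the biomarker group of a tumor
#'
#' Groups use the precedence tBRCAm > non-BRCA HRRm > non-HRRm, so a tumor
#' with a deleterious BRCA1/BRCA2 mutation is tBRCAm regardless of
#' co-occurring alterations, and a tumor with any panel HRR mutation (but
#' no BRCAm) is non-BRCA HRRm regardless of co-occurring non-HRR
#' alterations. Only deleterious / suspected-deleterious variants are
#' considered. Tumors with co-occurring BRCA1 and BRCA2 alterations, or
#' with multiple distinct non-BRCA HRR genes altered, are flagged
#' ineligible for individual-gene analyses (`gene_level_eligible = FALSE`)
#' because gene-specific HRD and zygosity cannot be attributed. HRD status
#' is delegated to [classify_hrd()].
#'
#' @param record a [tumor_record()].
#' @param hrr_panel character vector of non-BRCA HRR genes.
#' @param genome a [genome_spec()] (needed to score the profile).
#' @param cfg a [scoring_config()].
#' @return An object of class `biomarker_assignment`: list with
#'   `sample_id`, `group`, `brca_genes`, `brca_origin`,
#'   `gene_level_eligible`, `hrd`, `scores`.
#' @export
assign_group <- function(record, hrr_panel = default_hrr_panel(),
                         genome, cfg = scoring_config()) {
  stopifnot(inherits(record, "tumor_record"))
  v <- .deleterious(record$variants)
  genes <- unique(v$gene)
  brca <- intersect(genes, .brca_genes)
  hrr <- intersect(genes, hrr_panel)
  group <- if (length(brca)) "tBRCAm"
  else if (length(hrr)) "non-BRCA-HRRm"
  else "non-HRRm"
  eligible <- !(length(brca) == 2 || length(hrr) >= 2)
  origin <- if (group == "tBRCAm") assign_origin(record) else "n/a"
  scores <- gis(record$profile, genome, cfg)
  structure(list(sample_id = record$sample_id, group = group,
                 brca_genes = brca, brca_origin = origin,
                 gene_level_eligible = eligible,
                 hrd = classify_hrd(scores, group == "tBRCAm", cfg),
                 scores = scores),
            class = "biomarker_assignment")
}

#' Germline versus somatic origin of a tumor BRCA mutation
#'
#' Somatic BRCAm is a positive tumor BRCAm with a negative germline test;
#' a positive germline test means germline origin; samples without a
#' germline test result are of undetermined origin. Calling this on a
#' record without a deleterious BRCA1/BRCA2 variant is a contract error.
#'
#' @param record a [tumor_record()] carrying a tumor BRCA mutation.
#' @return `"germline"`, `"somatic"` or `"undetermined"`.
#' @export
assign_origin <- function(record) {
  stopifnot(inherits(record, "tumor_record"))
  v <- .deleterious(record$variants)
  bv <- v[v$gene %in% .brca_genes, , drop = FALSE]
  if (nrow(bv) == 0)
    stop("assign_origin: record ", record$sample_id, " carries no tBRCAm")
  if (any(bv$germline_test == "positive")) return("germline")
  if (any(bv$germline_test == "negative")) return("somatic")
  "undetermined"
}

#' Build a cohort table
#'
#' Runs scoring, HRD and biomarker classification, and gene-level zygosity
#' (with manual review) over a list of tumor records. Deterministic given
#' its inputs.
#'
#' @param records list of [tumor_record()] objects with unique sample ids.
#' @param genome a [genome_spec()].
#' @param cfg a [scoring_config()].
#' @param hrr_panel character vector of non-BRCA HRR genes.
#' @param loci named list of [gene_locus()] objects; zygosity is called for
#'   each deleterious-mutated gene with a configured locus.
#' @return An object of class `hrd_cohort`: list with
#'   \describe{
#'     \item{samples}{data.frame, one row per sample: subgroup labels,
#'       `group`, `brca_genes`, `brca_origin`, `gene_level_eligible`,
#'       `loh`, `tai`, `lst`, `gis`, `valid`, `hrd`.}
#'     \item{zygosity}{data.frame, one row per (sample, mutated gene) with
#'       a configured locus: `status`, `basis`.}
#'     \item{variants}{data.frame, one row per deleterious variant:
#'       `sample_id`, `gene`, `subtype`, `group`, `gene_level_eligible`.}
#'   }
#' @export
build_cohort <- function(records, genome, cfg = scoring_config(),
                         hrr_panel = default_hrr_panel(),
                         loci = list()) {
  ids <- vapply(records, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(records)
  samples <- data.frame(
    sample_id = character(n), study = character(n), setting = character(n),
    histology = character(n), race = character(n), location = character(n),
    group = character(n), brca_genes = character(n),
    brca_origin = character(n), gene_level_eligible = logical(n),
    loh = integer(n), tai = integer(n), lst = integer(n), gis = numeric(n),
    valid = logical(n), hrd = character(n), stringsAsFactors = FALSE)
  zyg <- list()
  varrows <- list()
  for (i in seq_len(n)) {
    r <- records[[i]]
    a <- assign_group(r, hrr_panel, genome, cfg)
    sc <- a$scores
    samples[i, c("sample_id", "study", "setting", "histology", "race",
                 "location")] <-
      c(r$sample_id, r$study, r$setting, r$histology, r$race, r$location)
    samples$group[i] <- a$group
    samples$brca_genes[i] <- paste(a$brca_genes, collapse = ",")
    samples$brca_origin[i] <- a$brca_origin
    samples$gene_level_eligible[i] <- a$gene_level_eligible
    samples$loh[i] <- sc$loh; samples$tai[i] <- sc$tai
    samples$lst[i] <- sc$lst; samples$gis[i] <- sc$gis
    samples$valid[i] <- sc$valid; samples$hrd[i] <- a$hrd
    v <- .deleterious(r$variants)
    for (g in unique(v$gene)) {
      varrows[[length(varrows) + 1L]] <- data.frame(
        sample_id = r$sample_id, gene = g,
        subtype = v$subtype[v$gene == g][1], group = a$group,
        gene_level_eligible = a$gene_level_eligible,
        stringsAsFactors = FALSE)
      if (!is.null(loci[[g]])) {
        zc <- call_zygosity(r$profile, loci[[g]], v)
        zc <- apply_manual_review(zc, v, r$profile, loci[[g]])
        zyg[[length(zyg) + 1L]] <- data.frame(
          sample_id = r$sample_id, gene = g, status = zc$status,
          basis = zc$basis, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    samples = samples,
    zygosity = if (length(zyg)) do.call(rbind, zyg) else
      data.frame(sample_id = character(), gene = character(),
                 status = character(), basis = character()),
    variants = if (length(varrows)) do.call(rbind, varrows) else
      data.frame(sample_id = character(), gene = character(),
                 subtype = character(), group = character(),
                 gene_level_eligible = logical())),
    class = "hrd_cohort")
}

#' @export
print.hrd_cohort <- function(x, ...) {
  tab <- table(x$samples$group)
  cat("<hrd_cohort> ", nrow(x$samples), " samples (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Write the per-sample cohort table to TSV
#'
#' @param cohort an `hrd_cohort` from [build_cohort()].
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "hrd_cohort"))
  utils::write.table(cohort$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
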