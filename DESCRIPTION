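Package: hrdscar
Title: Genomic Scar Scoring and HRD Classification for Tumor Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes allele-specific copy-number scar scores for tumor
    samples: loss of heterozygosity (LOH), telomeric allelic imbalance (TAI)
    and large-scale state transitions (LST), combines them into a genomic
    instability score (GIS, 0-100) and classifies homologous recombination
    deficiency (HRD) status with the established GIS >= 42 cutoff. Also
    provides gene-level zygosity (biallelic-loss) calling, biomarker cohort
    stratification (tumor BRCA-mutated, non-BRCA HRR-mutated, non-HRR-mutated;
    germline versus somatic origin), a synthetic-cohort generator with planted
    ground truth, and cohort summary statistics (median/IQR, Student's t-test,
    contingency tables, subgroup reports).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
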