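#' Genome specification
#'
#' A genome specification defines the coordinate system all scoring operates
#' on: per chromosome, its length and the centromere interval that separates
#' the p and q arms. Coordinates are 0-based, half-open throughout the
#' package, so the p arm is `[0, cen_start)` and the q arm is
#' `[cen_end, length)`.
#'
#' @param chromosomes data.frame with columns `name` (unique labels),
#'   `length`, `cen_start`, `cen_end` (base pairs; the centromere must lie
#'   strictly inside the chromosome: `0 < cen_start < cen_end < length`).
#' @return An object of class `genome_spec` (a validated data.frame).
#' @examples
#' genome_spec(data.frame(name = "chr1", length = 200e6,
#'                        cen_start = 90e6, cen_end = 100e6))
#' @export
genome_spec <- function(chromosomes) {
  stopifnot(is.data.frame(chromosomes))
  req <- c("name", "length", "cen_start", "cen_end")
  miss <- setdiff(req, names(chromosomes))
  if (length(miss))
    stop("genome spec missing columns: ", paste(miss, collapse = ", "))
  g <- chromosomes[, req]
  g$name <- as.character(g$name)
  for (cn in c("length", "cen_start", "cen_end")) g[[cn]] <- as.numeric(g[[cn]])
  if (anyDuplicated(g$name))
    stop("duplicate chromosome names in genome spec")
  bad <- !(g$cen_start > 0 & g$cen_start < g$cen_end & g$cen_end < g$length)
  if (any(bad))
    stop("centromere not strictly inside chromosome: ",
         paste(g$name[bad], collapse = ", "))
  if (any(g$length != round(g$length) | g$length <= 0))
    stop("chromosome lengths must be positive integers")
  class(g) <- c("genome_spec", "data.frame")
  g
}

#' Read a genome specification from JSON
#'
#' The expected layout is an array of objects, one per chromosome, each with
#' fields `name`, `length`, `cen_start`, `cen_end` (base pairs, 0-based
#' half-open).
#'
#' @param path path to a JSON file.
#' @return A [genome_spec()].
#' @export
read_genome <- function(path) {
  g <- jsonlite::fromJSON(path)
  genome_spec(as.data.frame(g))
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", nrow(x), " chromosomes, ",
      format(sum(x$length), big.mark = ","), " bp\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Built-in genome specifications
#'
#' `toy_genome()` is a 3-chromosome genome used in examples and tests;
#' `default_genome()` is a 22-autosome spec with hg19-like chromosome lengths
#' and centromere intervals, shipped as configuration
#' (`inst/extdata/genome_default.json`), not code, so scoring never
#' hard-codes a build.
#'
#' @return A [genome_spec()].
#' @export
toy_genome <- function() {
  genome_spec(data.frame(
    name      = c("A", "B", "C"),
    length    = c(200e6, 150e6, 100e6),
    cen_start = c(90e6, 60e6, 45e6),
    cen_end   = c(100e6, 70e6, 50e6)
  ))
}

#' @rdname toy_genome
#' @export
default_genome <- function() {
  read_genome(system.file("extdata", "genome_default.json",
                          package = "hrdscar", mustWork = TRUE))
}

# internal: chromosome row lookup with error on unknown name
.chrom_row <- function(genome, chrom) {
  i <- match(chrom, genome$name)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  genome[i, ]
}

#' Chromosome arm table
#'
#' Expands a genome spec into one row per arm with its half-open interval.
#'
#' @param genome a [genome_spec()].
#' @return data.frame with columns `chrom`, `arm` ("p"/"q"), `start`, `end`,
#'   `len`.
#' @export
genome_arms <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  rbind(
    data.frame(chrom = genome$name, arm = "p",
               start = 0, end = genome$cen_start,
               len = genome$cen_start),
    data.frame(chrom = genome$name, arm = "q",
               start = genome$cen_end, end = genome$length,
               len = genome$length - genome$cen_end)
  )
}
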