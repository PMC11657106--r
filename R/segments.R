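#' Allele-specific copy-number segment profiles
#'
#' A `segment_profile` holds one tumor's allele-specific copy-number
#' landscape as disjoint segments per chromosome. Each segment carries an
#' unphased copy-number state `(major_cn, minor_cn)` with
#' `minor_cn <= major_cn`. A segment is in LOH when `minor_cn == 0` and
#' `major_cn >= 1`, and in allelic imbalance when `major_cn != minor_cn`.
#' `valid = FALSE` models assay failure (e.g. low tumor purity): such a
#' profile carries no usable segments and all scores are undefined.
#'
#' @param sample_id sample label.
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `major_cn`, `minor_cn`.
#' @param valid logical flag; `FALSE` models assay failure.
#' @param genome optional [genome_spec()]; when supplied, coordinates are
#'   checked against chromosome bounds and, for valid profiles, complete
#'   tiling of each represented chromosome is enforced.
#' @return An object of class `segment_profile`.
#' @export
segment_profile <- function(sample_id, segments, valid = TRUE, genome = NULL) {
  if (!valid) {
    p <- structure(list(sample_id = as.character(sample_id),
                        segments = .empty_segments(), valid = FALSE),
                   class = "segment_profile")
    return(p)
  }
  stopifnot(is.data.frame(segments))
  req <- c("chrom", "start", "end", "major_cn", "minor_cn")
  miss <- setdiff(req, names(segments))
  if (length(miss))
    stop("segment table missing columns: ", paste(miss, collapse = ", "))
  s <- segments[, req]
  s$chrom <- as.character(s$chrom)
  for (cn in req[-1]) s[[cn]] <- as.numeric(s[[cn]])
  s <- s[order(match(s$chrom, unique(s$chrom)), s$start), , drop = FALSE]
  rownames(s) <- NULL
  .check_segments(s, genome)
  structure(list(sample_id = as.character(sample_id), segments = s,
                 valid = TRUE),
            class = "segment_profile")
}

.empty_segments <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             major_cn = numeric(), minor_cn = numeric())
}

# invariant checks shared by the constructor and read_seg
.check_segments <- function(s, genome = NULL, line = NULL) {
  where <- function(i) {
    if (is.null(line)) sprintf("segment %d", i)
    else sprintf("line %d", line[i])
  }
  for (i in seq_len(nrow(s))) {
    if (s$start[i] < 0 || s$start[i] >= s$end[i])
      stop(sprintf("%s: bad interval [%s, %s)", where(i),
                   format(s$start[i], scientific = FALSE),
                   format(s$end[i], scientific = FALSE)))
    if (s$major_cn[i] < 0 || s$minor_cn[i] < 0 ||
        s$major_cn[i] != round(s$major_cn[i]) ||
        s$minor_cn[i] != round(s$minor_cn[i]))
      stop(sprintf("%s: copy numbers must be non-negative integers", where(i)))
    if (s$minor_cn[i] > s$major_cn[i])
      stop(sprintf("%s: minor_cn > major_cn", where(i)))
  }
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    cs <- s[idx, ]
    if (!is.null(genome)) {
      row <- .chrom_row(genome, ch)
      if (any(cs$end > row$length))
        stop(sprintf("%s: segment end beyond chromosome %s length",
                     where(idx[which(cs$end > row$length)[1]]), ch))
    }
    if (nrow(cs) > 1) {
      for (k in 2:nrow(cs)) {
        if (cs$start[k] < cs$end[k - 1])
          stop(sprintf("%s: overlaps previous segment on %s",
                       where(idx[k]), ch))
        if (!is.null(genome) && cs$start[k] > cs$end[k - 1])
          stop(sprintf("%s: gap before segment on %s (tiling required)",
                       where(idx[k]), ch))
      }
    }
    if (!is.null(genome)) {
      row <- .chrom_row(genome, ch)
      if (cs$start[1] != 0 || cs$end[nrow(cs)] != row$length)
        stop(sprintf("chromosome %s not fully tiled ([%s, %s) covered, length %s)",
                     ch, format(cs$start[1], scientific = FALSE),
                     format(cs$end[nrow(cs)], scientific = FALSE),
                     format(row$length, scientific = FALSE)))
    }
  }
  invisible(TRUE)
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("<segment_profile> ", x$sample_id,
      if (!x$valid) " [assay failure]" else "",
      ": ", nrow(x$segments), " segments on ",
      length(unique(x$segments$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}

#' Read allele-specific segments from a SEG-like TSV
#'
#' The file must be tab-separated with header columns `sample`, `chrom`,
#' `start`, `end`, `major_cn`, `minor_cn`; coordinates are 0-based half-open.
#' A sample whose rows carry `NA` copy numbers is read as an assay failure
#' (`valid = FALSE`, no segments). Structural problems (overlap, gap, minor
#' above major, unknown chromosome, malformed field) raise an error naming
#' the offending line.
#'
#' @param path path to the TSV file.
#' @param genome a [genome_spec()] used to validate coordinates and tiling.
#' @return Named list of [segment_profile()] objects, one per sample.
#' @seealso [write_seg()]
#' @export
read_seg <- function(path, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample", "chrom", "start", "end", "major_cn", "minor_cn")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("SEG file missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) return(structure(list(), names = character()))
  tab$.line <- seq_len(nrow(tab)) + 1L  # header is line 1
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- is.na(v) & !(is.na(tab[[col]]) | tab[[col]] %in% c("NA", ""))
    if (any(bad))
      stop(sprintf("line %d: malformed numeric field '%s': %s",
                   tab$.line[which(bad)[1]], col, tab[[col]][which(bad)[1]]))
    v
  }
  tab$start <- num("start"); tab$end <- num("end")
  tab$major_cn <- num("major_cn"); tab$minor_cn <- num("minor_cn")
  # assay-failure rows (NA copy numbers) carry a placeholder chromosome
  unknown <- !(tab$chrom %in% genome$name) &
    !(is.na(tab$major_cn) & is.na(tab$minor_cn))
  if (any(unknown))
    stop(sprintf("line %d: unknown chromosome: %s",
                 tab$.line[which(unknown)[1]], tab$chrom[which(unknown)[1]]))
  out <- list()
  for (sid in unique(tab$sample)) {
    rows <- tab[tab$sample == sid, , drop = FALSE]
    if (all(is.na(rows$major_cn) & is.na(rows$minor_cn))) {
      out[[sid]] <- segment_profile(sid, .empty_segments(), valid = FALSE)
      next
    }
    if (any(is.na(rows$major_cn) | is.na(rows$minor_cn)))
      stop(sprintf("line %d: NA copy number in an otherwise valid sample",
                   rows$.line[which(is.na(rows$major_cn) |
                                      is.na(rows$minor_cn))[1]]))
    s <- rows[, c("chrom", "start", "end", "major_cn", "minor_cn")]
    s <- s[order(match(s$chrom, genome$name), s$start), , drop = FALSE]
    rownames(s) <- NULL
    .check_segments(s, genome,
                    line = rows$.line[order(match(rows$chrom, genome$name),
                                            rows$start)])
    out[[sid]] <- structure(list(sample_id = sid, segments = s, valid = TRUE),
                            class = "segment_profile")
  }
  out
}

#' Write segment profiles to a SEG-like TSV
#'
#' Inverse of [read_seg()]: writes the canonical tab-separated layout
#' (columns `sample`, `chrom`, `start`, `end`, `major_cn`, `minor_cn`;
#' 0-based half-open coordinates). An invalid (assay-failure) profile is
#' written as a single row with `NA` copy numbers spanning nothing.
#'
#' @param profiles a [segment_profile()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("sample\tchrom\tstart\tend\tmajor_cn\tminor_cn", con)
  for (p in profiles) {
    if (!p$valid) {
      writeLines(sprintf("%s\t.\t0\t1\tNA\tNA", p$sample_id), con)
      next
    }
    s <- p$segments
    writeLines(sprintf("%s\t%s\t%s\t%s\t%d\t%d",
                       p$sample_id, s$chrom,
                       format(s$start, scientific = FALSE, trim = TRUE),
                       format(s$end, scientific = FALSE, trim = TRUE),
                       as.integer(s$major_cn), as.integer(s$minor_cn)), con)
  }
  invisible(path)
}

#' Merge adjacent equal-state segments
#'
#' Canonicalizes a profile by merging touching neighbours that share the
#' same `(major_cn, minor_cn)` state. Scoring is representation-independent,
#' so `normalize_profile` never changes any score; it exists so that
#' profiles from different segmenters compare equal. Idempotent.
#'
#' @param profile a [segment_profile()].
#' @return A [segment_profile()] tiling the same intervals.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "segment_profile"))
  if (!profile$valid || nrow(profile$segments) == 0) return(profile)
  profile$segments <- .merge_equal(profile$segments)
  profile
}

# merge touching runs of equal (major, minor) state, per chromosome;
# segments separated by a gap are never merged
.merge_equal <- function(s) {
  if (nrow(s) < 2) return(s)
  new_run <- c(TRUE, !(s$chrom[-1] == s$chrom[-nrow(s)] &
                         s$start[-1] == s$end[-nrow(s)] &
                         s$major_cn[-1] == s$major_cn[-nrow(s)] &
                         s$minor_cn[-1] == s$minor_cn[-nrow(s)]))
  last <- c(which(new_run[-1]), nrow(s))
  out <- s[new_run, , drop = FALSE]
  out$end <- s$end[last]
  rownames(out) <- NULL
  out
}

#' Split a profile by chromosome arm
#'
#' Clips segments at the centromere: the p arm is `[0, cen_start)`, the q
#' arm `[cen_end, length)`; segments wholly inside the centromere are
#' dropped and no emitted segment ever crosses a centromere boundary. Arm
#' geometry underlies the TAI ("do not cross the centromere") and LST
#' (per-arm breakpoints) rules.
#'
#' @param profile a valid [segment_profile()].
#' @param genome a [genome_spec()].
#' @return Named list (names `"<chrom>_p"`, `"<chrom>_q"`) of segment
#'   data.frames; arms with no overlapping segments are omitted.
#' @export
split_by_arm <- function(profile, genome) {
  stopifnot(inherits(profile, "segment_profile"),
            inherits(genome, "genome_spec"))
  if (!profile$valid) stop("cannot split an invalid (assay-failure) profile")
  arms <- genome_arms(genome)
  s <- profile$segments
  out <- list()
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    cs <- s[s$chrom == a$chrom & s$end > a$start & s$start < a$end, ,
            drop = FALSE]
    if (nrow(cs) == 0) next
    cs$start <- pmax(cs$start, a$start)
    cs$end <- pmin(cs$end, a$end)
    rownames(cs) <- NULL
    out[[paste0(a$chrom, "_", a$arm)]] <- cs
  }
  out
}
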