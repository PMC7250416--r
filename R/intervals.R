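#' Read a BED file into a GRanges object
#'
#' Parses BED3/BED6 lines into a [GenomicRanges::GRanges]. BED coordinates
#' are 0-based half-open on disk; the returned object follows the
#' Bioconductor 1-based closed convention, so a line `chr1  10  20` becomes
#' a range with `start = 11`, `end = 20`. [write_bed()] inverts the
#' conversion, making the round trip lossless.
#'
#' @param path Path to a tab-separated BED file (3 or more columns).
#' @return A `GRanges` with `name` and `score` metadata columns when the
#'   file provides them.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20\tx", tf)
#' read_bed(tf)
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 3L)
  if (length(bad) > 0L) {
    stop("BED parse error at line ", bad[1L], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad) > 0L) {
    stop("BED parse error at line ", bad[1L], ": non-integer coordinates")
  }
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad) > 0L) {
    stop("BED parse error at line ", bad[1L],
         ": requires 0 <= start < end, got [", start0[bad[1L]], ", ",
         end0[bad[1L]], ")")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
  )
  if (all(ncols >= 4L)) {
    gr$name <- vapply(fields, `[[`, character(1), 4L)
  }
  if (all(ncols >= 5L)) {
    gr$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, character(1), 5L)))
  }
  if (all(ncols >= 6L)) {
    st <- vapply(fields, `[[`, character(1), 6L)
    st[!st %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- st
  }
  gr
}

#' Write a GRanges object as BED
#'
#' Emits BED3, BED4, BED5 or BED6 depending on which of `name`, `score`,
#' and strand are informative. Coordinates are converted back to the
#' 0-based half-open BED convention.
#'
#' @param gr A `GRanges`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  has_name <- !is.null(gr$name)
  has_score <- !is.null(gr$score)
  has_strand <- any(as.character(GenomicRanges::strand(gr)) != "*")
  if (has_name || has_score || has_strand) {
    df$name <- if (has_name) gr$name else "."
  }
  if (has_score || has_strand) {
    df$score <- if (has_score) gr$score else 0
  }
  if (has_strand) {
    st <- as.character(GenomicRanges::strand(gr))
    st[st == "*"] <- "."
    df$strand <- st
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an activity-colored BED9 track
#'
#' Writes one BED9 line per range with the `itemRgb` field shaded
#' proportionally to the range's activity score: the minimum score maps to
#' the `low` color, the maximum to `high`, with linear interpolation in
#' between. Monotone scores therefore map to monotone color intensity.
#' Used to visualize reporter-assay enhancer activity in a genome browser.
#'
#' @param gr A `GRanges` of scored elements.
#' @param scores Numeric activity scores, one per range; all finite.
#' @param path Output file path.
#' @param low,high Colors anchoring the ramp (any R color specification).
#' @return Invisibly, `path`.
#' @export
write_bed9_rgb <- function(gr, scores, path, low = "green", high = "red") {
  stopifnot(length(scores) == length(gr), all(is.finite(scores)))
  rng <- range(scores)
  frac <- if (rng[2] > rng[1]) (scores - rng[1]) / (rng[2] - rng[1]) else
    rep(0, length(scores))
  ramp <- grDevices::colorRamp(c(low, high))
  rgb <- ramp(frac)
  item_rgb <- apply(round(rgb), 1L, paste, collapse = ",")
  nm <- if (!is.null(gr$name)) gr$name else
    paste0("elem", seq_along(gr))
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm,
    score = round(1000 * frac),
    strand = st,
    thickStart = GenomicRanges::start(gr) - 1L,
    thickEnd = GenomicRanges::end(gr),
    itemRgb = item_rgb,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a scored GRanges
#'
#' @param path Path to a 4-column bedGraph file.
#' @return A `GRanges` with a numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  gr <- read_bed(path)
  if (length(gr) > 0L) {
    names(S4Vectors::mcols(gr))[names(S4Vectors::mcols(gr)) == "name"] <-
      "score"
    gr$score <- as.numeric(gr$score)
  }
  gr
}

#' Write a scored GRanges as bedGraph
#'
#' Ranges whose score is missing (`NA`) are dropped, matching the sparse
#' bedGraph representation where absent intervals mean "no data".
#'
#' @param gr A `GRanges` with a numeric `score` column.
#' @param path Output file path.
#' @param digits Number of significant digits retained on disk.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(gr, path, digits = 10) {
  stopifnot(!is.null(gr$score))
  gr <- gr[!is.na(gr$score)]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = signif(gr$score, digits),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' In-silico restriction digestion of a nucleotide sequence
#'
#' Scans `sequence` for every occurrence of the enzyme recognition `site`
#' (e.g. `"GATC"` for DpnII, `"GTAC"` for Csp6I) and places a cut at the
#' first base of each occurrence — a simplification of the enzyme's
#' overhang chemistry that is adequate for fragment mapping, where fragment
#' boundaries rather than sticky ends matter. The resulting fragments tile
#' the sequence without gaps; a sequence lacking the site yields a single
#' fragment covering it entirely.
#'
#' @param sequence A nucleotide string over `{A,C,G,T}` or a
#'   [Biostrings::DNAString].
#' @param site Recognition sequence, e.g. `"GATC"`.
#' @param chrom Chromosome name attached to the fragments.
#' @return A `GRanges` of contiguous fragments with a `fragment_id`
#'   metadata column and the enzyme site stored in
#'   `S4Vectors::metadata(.)$enzyme`.
#' @examples
#' frags <- digest("AAAAAAAAGATCAAAAAAAA", "GATC", "chrTest")
#' GenomicRanges::width(frags) # 8 and 12
#' @export
digest <- function(sequence, site, chrom = "chr") {
  stopifnot(nchar(site) >= 1L)
  seq <- Biostrings::DNAString(as.character(sequence))
  len <- length(seq)
  stopifnot(len > 0L)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(site), seq)
  cuts0 <- BiocGenerics::start(hits) - 1L  # 0-based cut offsets
  bounds0 <- sort(unique(c(0L, cuts0, len)))
  starts0 <- bounds0[-length(bounds0)]
  ends0 <- bounds0[-1L]
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts0 + 1L, end = ends0)
  )
  gr$fragment_id <- seq_along(gr)
  S4Vectors::metadata(gr)$enzyme <- site
  S4Vectors::metadata(gr)$chrom_length <- len
  gr
}

#' Length-weighted mean coverage of a signal track within a window
#'
#' Computes the mean of the track's per-base values over `window`. Bases not
#' covered by any track interval contribute a value of 0, matching the
#' sparse bedGraph convention where absent intervals mean zero signal.
#'
#' @param track A `GRanges` with a numeric `score` column; intervals must
#'   not overlap one another.
#' @param window A single `GRanges` range on the track's chromosome.
#' @return The length-weighted mean signal, a single number.
#' @export
mean_coverage_in_window <- function(track, window) {
  stopifnot(length(window) == 1L, !is.null(track$score))
  w <- GenomicRanges::width(window)
  if (w <= 0L) stop("zero-length window")
  track <- track[as.character(GenomicRanges::seqnames(track)) ==
                   as.character(GenomicRanges::seqnames(window))]
  if (length(track) == 0L) return(0)
  ov <- IRanges::pintersect(
    IRanges::findOverlapPairs(track, window, ignore.strand = TRUE))
  if (length(ov) == 0L) return(0)
  hit <- GenomicRanges::findOverlaps(track, window, ignore.strand = TRUE)
  vals <- track$score[S4Vectors::queryHits(hit)]
  sum(as.numeric(GenomicRanges::width(ov)) * vals) / w
}

#' Count peak sets overlapping a target interval
#'
#' Counts how many of the supplied named peak sets contain at least one
#' interval sharing at least one base with `target` (half-open overlap:
#' abutting intervals do not count). Used to ask how many transcription
#' factors bind a candidate enhancer.
#'
#' @param target A single `GRanges` range.
#' @param peak_sets A named list of `GRanges` peak sets.
#' @return Integer count of overlapping sets; the names of the overlapping
#'   sets are attached as the `"sets"` attribute.
#' @export
overlap_count <- function(target, peak_sets) {
  stopifnot(length(target) == 1L, is.list(peak_sets))
  hit <- vapply(peak_sets, function(ps) {
    length(ps) > 0L &&
      GenomicRanges::countOverlaps(target, ps, ignore.strand = TRUE) > 0L
  }, logical(1))
  n <- sum(hit)
  attr(n, "sets") <- names(peak_sets)[hit]
  n
}
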