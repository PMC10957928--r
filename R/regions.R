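#' Genomic regions as tibbles
#'
#' All interval arithmetic in this package works on plain tibbles with columns
#' `chrom` (character), `start` and `end` (integer base pairs). Coordinates are
#' 0-based half-open, the BED convention: a region covers bases
#' `start, start+1, ..., end-1`. An optional `name` column is carried along
#' where present; any further columns are preserved by filtering operations and
#' dropped by fragment-producing ones.
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @param genome Optional genome table (`chrom`, `length`) used to check that
#'   regions stay within chromosome bounds.
#' @return A tibble sorted by (`chrom`, `start`, `end`) with validated
#'   coordinates.
#' @examples
#' as_regions(data.frame(chrom = "chr1", start = 0, end = 100))
#' @export
as_regions <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("region table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      class = "ecre_input_error"
    )
  }
  out <- tibble::as_tibble(x)
  out$chrom <- as.character(out$chrom)
  out$start <- as.integer(round(out$start))
  out$end <- as.integer(round(out$end))
  if (any(out$start < 0)) {
    rlang::abort("negative start coordinate", class = "ecre_input_error")
  }
  if (any(out$start >= out$end)) {
    rlang::abort("empty or inverted region (start >= end)", class = "ecre_input_error")
  }
  if (!is.null(genome)) {
    len <- stats::setNames(genome$length, genome$chrom)
    bad <- is.na(len[out$chrom]) | out$end > len[out$chrom]
    if (any(bad)) {
      rlang::abort(
        paste0("region beyond chromosome bounds: ", format_region_id(out[which(bad)[1], ])),
        class = "ecre_input_error"
      )
    }
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

# validation without re-sorting, for row-order-preserving operations
# (feature matrices must keep rows aligned with labels and row names)
validate_regions <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("region table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      class = "ecre_input_error"
    )
  }
  out <- tibble::as_tibble(x)
  out$chrom <- as.character(out$chrom)
  out$start <- as.integer(round(out$start))
  out$end <- as.integer(round(out$end))
  if (any(out$start < 0) || any(out$start >= out$end)) {
    rlang::abort("invalid region coordinates", class = "ecre_input_error")
  }
  out
}

#' Parse and format table-style region identifiers
#'
#' Region id strings of the form `"chr11-55022942-55023482"` are treated as
#' 1-based inclusive display coordinates, the dialect used in printed candidate
#' tables; internally they become 0-based half-open
#' (`start = display_start - 1`). `format_region_id()` is the exact inverse, so
#' `format_region_id(parse_region_id(x))` reproduces `x`.
#'
#' @param ids Character vector of `<chrom>-<start>-<end>` strings.
#' @return `parse_region_id()`: a region tibble with a `name` column holding
#'   the original strings. `format_region_id()`: a character vector.
#' @examples
#' parse_region_id("chr11-55022942-55023482")
#' @export
parse_region_id <- function(ids) {
  ids <- as.character(ids)
  m <- stringr::str_match(ids, "^([^-]+)-([0-9]+)-([0-9]+)$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("malformed region id: '", ids[bad[1]], "'"),
      class = "ecre_parse_error"
    )
  }
  start <- as.integer(m[, 3]) - 1L
  end <- as.integer(m[, 4])
  # display coordinates must satisfy start < end; equal coordinates are
  # treated as a degenerate (empty) interval in this dialect
  if (any(start + 1L >= end)) {
    i <- which(start + 1L >= end)[1]
    rlang::abort(
      paste0("empty interval in region id: '", ids[i], "'"),
      class = "ecre_parse_error"
    )
  }
  tibble::tibble(chrom = m[, 2], start = start, end = end, name = ids)
}

#' @rdname parse_region_id
#' @param regions A region tibble.
#' @export
format_region_id <- function(regions) {
  sprintf("%s-%d-%d", regions$chrom, regions$start + 1L, regions$end)
}

# internal bridges to GenomicRanges (1-based closed)
regions_to_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

gr_to_regions <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Pairwise region overlap test
#'
#' Two regions overlap when they share at least one base under half-open
#' semantics: equal `chrom` and `max(start) < min(end)`. Bookended regions
#' (`end == start`) do not overlap. Vectors recycle as usual.
#'
#' @param a,b Region tibbles of equal (or length-1) row count.
#' @return Logical vector.
#' @export
region_overlaps <- function(a, b) {
  a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end)
}

#' Intersect two region sets
#'
#' Returns the base-level intersection of the two sets as merged fragments:
#' every returned base is covered by at least one region in `a` and one in
#' `b`, and bookended or overlapping fragments are merged.
#'
#' @param a,b Region tibbles.
#' @return A region tibble of intersection fragments (no extra columns).
#' @export
region_intersect <- function(a, b) {
  a <- as_regions(a)
  b <- as_regions(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::intersect(regions_to_gr(a), regions_to_gr(b), ignore.strand = TRUE)
  as_regions(gr_to_regions(gr))
}

#' Drop regions overlapping an exclusion set
#'
#' Whole-region filtering, not trimming: any region of `a` sharing at least one
#' base with any region of `excl` is removed; all other rows are returned
#' unchanged (extra columns preserved).
#'
#' @param a Region tibble to filter.
#' @param excl Exclusion region tibble (e.g. a blacklist), possibly empty.
#' @return The retained rows of `a`.
#' @export
filter_excluded <- function(a, excl) {
  a <- as_regions(a)
  if (is.null(excl) || nrow(excl) == 0 || nrow(a) == 0) {
    return(a)
  }
  excl <- as_regions(excl)
  hits <- GenomicRanges::countOverlaps(regions_to_gr(a), regions_to_gr(excl))
  a[hits == 0L, , drop = FALSE]
}

#' Consensus peaks across two replicates
#'
#' A consensus region is chromatin called open in both biological replicates.
#' The default `"fragment"` mode returns the base-level intersection segments
#' (merged when bookended); `"rep1"` mode instead keeps the full replicate-1
#' peaks that overlap at least one replicate-2 peak.
#'
#' @param rep1,rep2 Region tibbles of peaks from the two replicates.
#' @param mode `"fragment"` (default) or `"rep1"`.
#' @return A region tibble; every returned region overlaps at least one peak
#'   in each replicate.
#' @export
consensus_peaks <- function(rep1, rep2, mode = c("fragment", "rep1")) {
  mode <- match.arg(mode)
  if (mode == "fragment") {
    region_intersect(rep1, rep2)
  } else {
    rep1 <- as_regions(rep1)
    if (nrow(rep1) == 0 || nrow(as_regions(rep2)) == 0) {
      return(rep1[0, , drop = FALSE])
    }
    hits <- GenomicRanges::countOverlaps(regions_to_gr(rep1), regions_to_gr(as_regions(rep2)))
    rep1[hits > 0L, , drop = FALSE]
  }
}
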