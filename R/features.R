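#' Binary track-overlap features
#'
#' One column per peak track; entry (i, j) is 1 when region i shares at least
#' one base with any peak of track j, else 0.
#'
#' @param regions Region tibble (rows of the feature matrix).
#' @param peak_tracks Named list of region tibbles.
#' @return Numeric matrix, `nrow(regions)` x `length(peak_tracks)`, with the
#'   track names as column names and region ids as row names.
#' @export
binary_overlap_features <- function(regions, peak_tracks) {
  check_track_names(names(peak_tracks), length(peak_tracks))
  regions <- validate_regions(regions) # row order preserved
  gr <- regions_to_gr(regions)
  X <- matrix(0, nrow(regions), length(peak_tracks),
    dimnames = list(format_region_id(regions), names(peak_tracks))
  )
  for (j in seq_along(peak_tracks)) {
    trk <- peak_tracks[[j]]
    if (is.null(trk) || nrow(trk) == 0) next
    hits <- GenomicRanges::countOverlaps(gr, regions_to_gr(as_regions(trk)))
    X[, j] <- as.numeric(hits > 0)
  }
  X
}

#' Coverage-sum features
#'
#' One column per coverage track; entry (i, j) is the base-pair-weighted sum
#' of track j over region i: for every coverage interval, its value times the
#' number of bases it shares with the region. This sum is invariant to how the
#' same signal is segmented into intervals.
#'
#' @param regions Region tibble.
#' @param coverage_tracks Named list of coverage tibbles
#'   (`chrom`, `start`, `end`, `value`, values >= 0).
#' @return Numeric matrix with non-negative entries.
#' @export
coverage_sum_features <- function(regions, coverage_tracks) {
  check_track_names(names(coverage_tracks), length(coverage_tracks))
  regions <- validate_regions(regions) # row order preserved
  gr <- regions_to_gr(regions)
  X <- matrix(0, nrow(regions), length(coverage_tracks),
    dimnames = list(format_region_id(regions), names(coverage_tracks))
  )
  for (j in seq_along(coverage_tracks)) {
    trk <- coverage_tracks[[j]]
    if (is.null(trk) || nrow(trk) == 0) next
    if (any(trk$value < 0)) {
      rlang::abort(paste0("negative coverage value in track '", names(coverage_tracks)[j], "'"),
        class = "ecre_input_error"
      )
    }
    tgr <- regions_to_gr(trk)
    hits <- GenomicRanges::findOverlaps(gr, tgr)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(regions$end[qh], trk$end[sh]) - pmax(regions$start[qh], trk$start[sh])
    contrib <- trk$value[sh] * ov
    sums <- tapply(contrib, qh, sum)
    X[as.integer(names(sums)), j] <- as.numeric(sums)
  }
  X
}

check_track_names <- function(nm, n) {
  if (n == 0) {
    return(invisible(TRUE))
  }
  if (is.null(nm) || any(!nzchar(nm))) {
    rlang::abort("tracks must be named", class = "ecre_input_error")
  }
  if (anyDuplicated(nm)) {
    rlang::abort("duplicate track names", class = "ecre_input_error")
  }
  invisible(TRUE)
}

#' Bundle peak and coverage tracks into a feature library
#'
#' @param peak_tracks Named list of region tibbles (binary-feature sources).
#' @param coverage_tracks Named list of coverage tibbles (sum-feature
#'   sources).
#' @return A `track_library` object.
#' @export
track_library <- function(peak_tracks = list(), coverage_tracks = list()) {
  all_names <- c(names(peak_tracks), names(coverage_tracks))
  check_track_names(all_names, length(all_names))
  structure(
    list(peak_tracks = peak_tracks, coverage_tracks = coverage_tracks),
    class = "track_library"
  )
}

#' @export
print.track_library <- function(x, ...) {
  cat(
    "<track_library>", length(x$peak_tracks), "peak track(s),",
    length(x$coverage_tracks), "coverage track(s)\n"
  )
  invisible(x)
}

#' Assemble the labeled feature matrix
#'
#' Rows are the positive regions followed by the negative regions; columns are
#' the binary overlap block followed by the coverage-sum block; labels are 1
#' for positives and 0 for negatives. With the study-scale inputs (695
#' positives, 695 matched negatives, 81 peak + 2 coverage tracks) this is the
#' 1390 x 83 design matrix.
#'
#' @param pos,neg Region tibbles of positive and negative examples.
#' @param tracks A [track_library()].
#' @return A `feature_matrix` object: list with `X` (numeric matrix), `y`
#'   (0/1 labels, `NULL` for query-only matrices) and `regions`.
#' @export
assemble_features <- function(pos, neg = NULL, tracks) {
  stopifnot(inherits(tracks, "track_library"))
  p <- length(tracks$peak_tracks) + length(tracks$coverage_tracks)
  if (p == 0) {
    rlang::abort("track library is empty: no features to assemble",
      class = "ecre_input_error"
    )
  }
  pos <- as_regions(pos)
  regions <- pos
  y <- rep(1, nrow(pos))
  if (!is.null(neg)) {
    neg <- as_regions(neg)
    regions <- dplyr::bind_rows(
      pos[, c("chrom", "start", "end")],
      neg[, c("chrom", "start", "end")]
    )
    y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  } else {
    regions <- pos[, c("chrom", "start", "end")]
    y <- NULL
  }
  blocks <- list()
  if (length(tracks$peak_tracks) > 0) {
    blocks$bin <- binary_overlap_features(regions, tracks$peak_tracks)
  }
  if (length(tracks$coverage_tracks) > 0) {
    blocks$cov <- coverage_sum_features(regions, tracks$coverage_tracks)
  }
  X <- do.call(cbind, unname(blocks))
  rownames(X) <- format_region_id(regions)
  structure(list(X = X, y = y, regions = regions), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(
    "<feature_matrix>", nrow(x$X), "regions x", ncol(x$X), "features;",
    if (is.null(x$y)) "unlabeled" else paste0(sum(x$y == 1), " pos / ", sum(x$y == 0), " neg"),
    "\n"
  )
  invisible(x)
}
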