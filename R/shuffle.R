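#' Length-matched genome shuffling of template regions
#'
#' Draws, for each template region, a random placement somewhere in the genome
#' with exactly the template's length, rejecting placements that overlap the
#' exclusion set or run past a chromosome end. This is how matched negative
#' (non-enhancer) regions are produced: same length distribution as the
#' positives, guaranteed not to touch the positives or the blacklist.
#'
#' The chromosome is chosen with probability proportional to its length, then
#' the start uniformly over admissible positions `[0, length - L]`; placements
#' may land on any chromosome. Rejection sampling runs against `excl` with up
#' to `max_attempts` rounds per template. Randomness comes from R's global
#' RNG, so results are reproducible after `set.seed()`.
#'
#' @param templates Region tibble whose length multiset is to be matched.
#' @param genome Genome table with columns `chrom`, `length`.
#' @param excl Region tibble the placements must not overlap (typically the
#'   templates themselves plus a blacklist); may be `NULL` or empty.
#' @param max_attempts Rejection-sampling budget per template (default 1000).
#' @return A region tibble with `nrow(templates)` rows (in template order)
#'   whose sorted lengths equal the templates' sorted lengths and which
#'   overlap nothing in `excl`.
#' @examples
#' genome <- tibble::tibble(chrom = "chr1", length = 10000L)
#' pos <- tibble::tibble(chrom = "chr1", start = 100L, end = 400L)
#' set.seed(1)
#' shuffle_match(pos, genome, excl = pos)
#' @export
shuffle_match <- function(templates, genome, excl = NULL, max_attempts = 1000L) {
  templates <- as_regions(templates)
  lens <- templates$end - templates$start
  draw_placements(lens, genome, excl, max_attempts, self_avoid = FALSE)
}

# Vectorized rejection sampler. When self_avoid is TRUE the accepted regions
# must also be pairwise non-overlapping (used to plant enhancers).
draw_placements <- function(lens, genome, excl, max_attempts, self_avoid) {
  n <- length(lens)
  empty <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  if (n == 0) {
    return(empty)
  }
  if (any(lens > max(genome$length))) {
    rlang::abort(
      paste0("no chromosome can hold a region of length ", max(lens)),
      class = "ecre_placement_error"
    )
  }
  chrom_prob <- genome$length / sum(genome$length)
  chrom_len <- genome$length
  excl_gr <- if (!is.null(excl) && nrow(excl) > 0) {
    ex <- as_regions(excl)
    GenomicRanges::GRanges(
      factor(ex$chrom, levels = union(genome$chrom, ex$chrom)),
      IRanges::IRanges(start = ex$start + 1L, end = ex$end)
    )
  } else {
    NULL
  }

  out_ci <- integer(n)
  out_s <- integer(n)
  remaining <- seq_len(n)
  accepted_gr <- NULL
  for (round in seq_len(max_attempts)) {
    k <- length(remaining)
    ci <- sample.int(nrow(genome), k, replace = TRUE, prob = chrom_prob)
    L <- lens[remaining]
    fits <- chrom_len[ci] >= L
    s <- integer(k)
    s[fits] <- as.integer(floor(stats::runif(sum(fits)) * (chrom_len[ci[fits]] - L[fits] + 1)))
    ok <- fits
    if (any(ok)) {
      cand_gr <- GenomicRanges::GRanges(
        factor(genome$chrom[ci], levels = genome$chrom),
        IRanges::IRanges(start = s + 1L, width = L)
      )
      if (!is.null(excl_gr)) {
        ok <- ok & GenomicRanges::countOverlaps(cand_gr, excl_gr) == 0L
      }
      if (self_avoid) {
        if (!is.null(accepted_gr)) {
          ok <- ok & GenomicRanges::countOverlaps(cand_gr, accepted_gr) == 0L
        }
        # within-round self conflicts: accept greedily in index order
        hits <- GenomicRanges::findOverlaps(cand_gr, cand_gr)
        qh <- S4Vectors::queryHits(hits)
        sh <- S4Vectors::subjectHits(hits)
        drop <- unique(qh[ok[qh] & ok[sh] & sh < qh])
        ok[drop] <- FALSE
      }
    }
    acc <- remaining[ok]
    out_ci[acc] <- ci[ok]
    out_s[acc] <- s[ok]
    if (self_avoid && any(ok)) {
      new_gr <- GenomicRanges::GRanges(
        factor(genome$chrom[ci[ok]], levels = genome$chrom),
        IRanges::IRanges(start = s[ok] + 1L, width = L[ok])
      )
      accepted_gr <- if (is.null(accepted_gr)) new_gr else c(accepted_gr, new_gr)
    }
    remaining <- remaining[!ok]
    if (length(remaining) == 0) break
  }
  if (length(remaining) > 0) {
    rlang::abort(
      paste0(
        "failed to place a region of length ", lens[remaining[1]],
        " after ", max_attempts, " attempts"
      ),
      class = "ecre_placement_error"
    )
  }
  tibble::tibble(
    chrom = genome$chrom[out_ci],
    start = out_s,
    end = as.integer(out_s + lens)
  )
}
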