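#' Two-caller consensus of differentially accessible regions
#'
#' Keeps the rows of the primary caller's table (coordinates preserved) that
#' overlap at least one region of the confirming caller's table with the same
#' direction of change. This is the cross-caller consensus rule: a region
#' counts as differentially accessible only when both callers agree on it,
#' sign included.
#'
#' @param primary,confirming Signed-region tibbles with columns `chrom`,
#'   `start`, `end`, `direction` (`up`/`down`) and typically `logFC`, `p`,
#'   `FDR`.
#' @return The retained rows of `primary`, unchanged.
#' @export
consensus_dars <- function(primary, confirming) {
  primary <- validate_signed_regions(tibble::as_tibble(primary))
  confirming <- validate_signed_regions(tibble::as_tibble(confirming))
  if (nrow(primary) == 0 || nrow(confirming) == 0) {
    return(primary[0, , drop = FALSE])
  }
  keep <- rep(FALSE, nrow(primary))
  for (dir in c("up", "down")) {
    pi <- which(primary$direction == dir)
    ci <- which(confirming$direction == dir)
    if (length(pi) == 0 || length(ci) == 0) next
    hits <- GenomicRanges::countOverlaps(
      regions_to_gr(primary[pi, , drop = FALSE]),
      regions_to_gr(confirming[ci, , drop = FALSE])
    )
    keep[pi] <- hits > 0
  }
  primary[keep, , drop = FALSE]
}

#' Filter differential regions by direction of change
#'
#' @param dars Signed-region tibble.
#' @param direction `"up"` (opened) or `"down"` (closed).
#' @return The rows with the requested direction.
#' @export
select_opened <- function(dars, direction = "up") {
  if (!direction %in% c("up", "down")) {
    rlang::abort(paste0("unknown direction '", direction, "' (use 'up' or 'down')"),
      class = "ecre_input_error"
    )
  }
  dars[dars$direction == direction, , drop = FALSE]
}

#' Two-method consensus of differentially expressed genes
#'
#' A gene is a consensus DEG when it is declared significant by both methods
#' and the two log2 fold-changes have the same sign. The reported `log2FC` is
#' the first (primary) method's value.
#'
#' @param a,b Per-method DEG tibbles with columns `gene`, `log2FC`,
#'   `significant`.
#' @return A tibble `gene`, `log2FC` of consensus genes, sorted by symbol.
#' @export
consensus_degs <- function(a, b) {
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  joined <- dplyr::inner_join(
    dplyr::filter(a, .data$significant),
    dplyr::filter(b, .data$significant),
    by = "gene", suffix = c("_a", "_b")
  )
  joined <- dplyr::filter(joined, sign(.data$log2FC_a) == sign(.data$log2FC_b))
  dplyr::arrange(
    tibble::tibble(gene = joined$gene, log2FC = joined$log2FC_a),
    .data$gene
  )
}

#' Map opened differential regions to marker genes
#'
#' Annotates each opened region with its nearest gene TSS and keeps the
#' regions whose nearest gene belongs to the marker list; the result is one
#' candidate regulatory element per retained region, with the gene's
#' expression log2 fold-change joined from the consensus DEG table (`NA`,
#' rendered as "not expressed", when the gene has no expression call).
#' Regions sharing a nearest gene are all retained.
#'
#' @param opened_dars Signed-region tibble (typically the `up` rows of the
#'   DAR consensus).
#' @param genes Gene annotation tibble (see [annotate_nearest_tss()]).
#' @param markers Character vector of marker gene symbols.
#' @param deg Consensus DEG tibble (`gene`, `log2FC`); may be `NULL`.
#' @return A candidate tibble sorted by coordinate, with columns `region_id`,
#'   coordinates, DAR statistics, `location`, `distance_to_tss`, `gene`,
#'   `gene_log2FC`.
#' @export
map_to_markers <- function(opened_dars, genes, markers, deg = NULL) {
  opened_dars <- tibble::as_tibble(opened_dars)
  markers <- stringr::str_trim(as.character(markers))
  empty <- tibble::tibble(
    region_id = character(), chrom = character(), start = integer(),
    end = integer(), logFC_atac = numeric(), p_value = numeric(),
    fdr = numeric(), location = character(), distance_to_tss = integer(),
    gene = character(), gene_log2FC = numeric()
  )
  if (nrow(opened_dars) == 0 || length(markers) == 0) {
    return(empty)
  }
  ann <- annotate_nearest_tss(opened_dars[, c("chrom", "start", "end")], genes)
  keep <- !is.na(ann$gene) & stringr::str_trim(ann$gene) %in% markers
  if (!any(keep)) {
    return(empty)
  }
  d <- opened_dars[keep, , drop = FALSE]
  out <- tibble::tibble(
    region_id = format_region_id(d),
    chrom = d$chrom, start = d$start, end = d$end,
    logFC_atac = if ("logFC" %in% names(d)) d$logFC else NA_real_,
    p_value = if ("p" %in% names(d)) d$p else NA_real_,
    fdr = if ("FDR" %in% names(d)) d$FDR else NA_real_,
    location = ann$location[keep],
    distance_to_tss = ann$distance_to_tss[keep],
    gene = ann$gene[keep]
  )
  if (!is.null(deg) && nrow(deg) > 0) {
    out <- dplyr::left_join(out, deg[, c("gene", "log2FC")], by = "gene")
    out <- dplyr::rename(out, gene_log2FC = "log2FC")
  } else {
    out$gene_log2FC <- NA_real_
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Attach ensemble prediction scores to candidates
#'
#' Joins mean ensemble scores by region id and sorts candidates by score,
#' descending, with coordinate order breaking ties. Every candidate must have
#' a score.
#'
#' @param candidates Candidate tibble from [map_to_markers()].
#' @param scores An `ensemble_score` object, or a tibble with `region_id` and
#'   `mean_score` columns.
#' @return The candidates with a `prediction_score` column, sorted.
#' @export
attach_scores <- function(candidates, scores) {
  if (inherits(scores, "ensemble_score")) scores <- scores$scores
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) == 0) {
    candidates$prediction_score <- numeric(0)
    return(candidates)
  }
  lut <- stats::setNames(scores$mean_score, scores$region_id)
  sc <- lut[candidates$region_id]
  if (anyNA(sc)) {
    rlang::abort(
      paste0(
        "no score for region ",
        candidates$region_id[which(is.na(sc))[1]]
      ),
      class = "ecre_input_error"
    )
  }
  candidates$prediction_score <- unname(sc)
  dplyr::arrange(
    candidates, dplyr::desc(.data$prediction_score),
    .data$chrom, .data$start, .data$end
  )
}

#' Summarize a scored candidate table at a decision threshold
#'
#' Counts candidates, candidates scoring strictly above the threshold, and
#' above-threshold candidates with a literature reference; percentages are
#' rounded to the nearest integer (so 15 of 57 reports 26%).
#'
#' @param candidates Scored candidate tibble (must carry `prediction_score`;
#'   `literature_ref` is optional).
#' @param tau Decision threshold (strict `>`), default 0.5.
#' @return A one-row tibble: `n_total`, `n_above`, `n_above_with_ref`,
#'   `pct_above`, `pct_ref_of_above`.
#' @export
summarize_candidates <- function(candidates, tau = 0.5) {
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) == 0) {
    return(tibble::tibble(
      n_total = 0L, n_above = 0L, n_above_with_ref = 0L,
      pct_above = 0L, pct_ref_of_above = 0L
    ))
  }
  if (!"prediction_score" %in% names(candidates) ||
    anyNA(candidates$prediction_score)) {
    rlang::abort("candidates lack attached prediction scores",
      class = "ecre_input_error"
    )
  }
  above <- classify(candidates$prediction_score, tau)
  has_ref <- if ("literature_ref" %in% names(candidates)) {
    !is.na(candidates$literature_ref) & nzchar(candidates$literature_ref)
  } else {
    rep(FALSE, nrow(candidates))
  }
  n_total <- nrow(candidates)
  n_above <- sum(above)
  n_ref <- sum(above & has_ref)
  pct <- function(num, den) if (den == 0) 0L else as.integer(floor(100 * num / den + 0.5))
  tibble::tibble(
    n_total = n_total, n_above = n_above, n_above_with_ref = n_ref,
    pct_above = pct(n_above, n_total),
    pct_ref_of_above = pct(n_ref, n_above)
  )
}

#' Motif-family co-presence across regions
#'
#' Given per-region motif hits, counts the regions containing at least one
#' hit from each of two motif families and reports the count, the fraction of
#' all regions, and the rounded percentage.
#'
#' @param hits Long tibble with columns `region_id` and `motif` (family
#'   labels); one row per hit.
#' @param famA,famB The two motif-family labels.
#' @return A one-row tibble: `n_regions`, `n_copresent`, `fraction`,
#'   `percent`.
#' @export
motif_copresence <- function(hits, famA, famB) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) {
    rlang::abort("motif hit table is empty", class = "ecre_input_error")
  }
  per_region <- dplyr::summarise(
    dplyr::group_by(hits, .data$region_id),
    both = famA %in% .data$motif && famB %in% .data$motif,
    .groups = "drop"
  )
  n <- nrow(per_region)
  cnt <- sum(per_region$both)
  tibble::tibble(
    n_regions = n,
    n_copresent = cnt,
    fraction = cnt / n,
    percent = as.integer(floor(100 * cnt / n + 0.5))
  )
}
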