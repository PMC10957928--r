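#' Read and write the plain-text genomic formats the pipeline exchanges
#'
#' All files are tab-separated. BED and bedGraph coordinates are 0-based
#' half-open; `chrom.sizes` is the two-column `(chrom, length)` table used to
#' bound shuffling; gene annotation is a headered TSV with `symbol`, `chrom`,
#' `strand`, `tss` and optional comma-separated `exon_starts`/`exon_ends`.
#'
#' @param path File path.
#' @return A tibble (readers) or `invisible(path)` (writers).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, comment = "#"
  )
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  out <- tibble::tibble(
    chrom = x[[1]],
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]])
  )
  if (ncol(x) >= 4) out$name <- x[[4]]
  as_regions(out)
}

#' @rdname pipeline_io
#' @param regions Region tibble to write (BED3, plus a name column if present).
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(regions))
  readr::write_tsv(regions[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "length"),
    col_types = readr::cols(readr::col_character(), readr::col_integer()),
    progress = FALSE
  )
  if (anyDuplicated(x$chrom) || any(x$length <= 0)) {
    rlang::abort("invalid chrom.sizes: duplicate chromosome or non-positive length",
      class = "ecre_input_error"
    )
  }
  x
}

#' @rdname pipeline_io
#' @param genome Genome tibble (`chrom`, `length`).
#' @export
write_chrom_sizes <- function(genome, path) {
  readr::write_tsv(genome[, c("chrom", "length")], path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = readr::cols(
      readr::col_character(), readr::col_integer(),
      readr::col_integer(), readr::col_double()
    ),
    progress = FALSE, comment = "#"
  )
  tibble::as_tibble(x)
}

#' @rdname pipeline_io
#' @param track Coverage tibble (`chrom`, `start`, `end`, `value`).
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gene_annotation <- function(path) {
  # exon columns are comma-separated coordinate lists: force character so
  # they are never parsed as grouped numbers
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      tss = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  need <- c("symbol", "chrom", "strand", "tss")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    rlang::abort(paste0("gene annotation lacks column(s): ", paste(miss, collapse = ", ")),
      class = "ecre_input_error"
    )
  }
  tibble::as_tibble(x)
}

#' @rdname pipeline_io
#' @param genes Gene annotation tibble.
#' @export
write_gene_annotation <- function(genes, path) {
  readr::write_tsv(genes, path, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_marker_list <- function(path) {
  x <- readLines(path)
  x <- stringr::str_trim(x)
  unique(x[nzchar(x)])
}

#' @rdname pipeline_io
#' @param markers Character vector of gene symbols.
#' @export
write_marker_list <- function(markers, path) {
  writeLines(markers, path)
  invisible(path)
}

#' Read and write Table-2-style candidate reports
#'
#' The candidate report carries one row per candidate regulatory element:
#' coordinates (as a 1-based display id), differential-accessibility
#' statistics, location, distance and nearest gene, the gene's expression
#' log2 fold-change (the string `"not expressed"` marks genes without an
#' expression call and is read back as `NA`), the ensemble prediction score
#' and an optional literature reference tag.
#'
#' @param path File path to a tab-separated candidate table.
#' @return A tibble with coordinates expanded to `chrom`/`start`/`end` and a
#'   numeric `gene_log2FC` column.
#' @export
read_candidate_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE)
  out <- parse_region_id(x$region_id)
  out$region_id <- x$region_id
  out$name <- NULL
  num <- function(v) suppressWarnings(as.numeric(v))
  for (col in intersect(c("logFC_atac", "p_value", "fdr"), names(x))) {
    out[[col]] <- num(x[[col]])
  }
  for (col in intersect(c("location", "gene"), names(x))) {
    out[[col]] <- x[[col]]
  }
  if ("distance_to_tss" %in% names(x)) out$distance_to_tss <- as.integer(x$distance_to_tss)
  if ("gene_log2FC" %in% names(x)) {
    v <- x$gene_log2FC
    v[v %in% c("not expressed", "NA", "")] <- NA
    out$gene_log2FC <- num(v)
  }
  if ("prediction_score" %in% names(x)) out$prediction_score <- num(x$prediction_score)
  if ("literature_ref" %in% names(x)) {
    v <- x$literature_ref
    v[v %in% c("NA", "")] <- NA
    out$literature_ref <- v
  }
  out
}

#' @rdname read_candidate_table
#' @param candidates Candidate tibble as produced by [map_to_markers()] /
#'   [attach_scores()].
#' @export
write_candidate_table <- function(candidates, path) {
  x <- candidates
  x$region_id <- if ("region_id" %in% names(x)) x$region_id else format_region_id(x)
  keep <- intersect(
    c(
      "region_id", "logFC_atac", "p_value", "fdr", "location",
      "distance_to_tss", "gene", "gene_log2FC", "prediction_score",
      "literature_ref"
    ),
    names(x)
  )
  x <- x[, keep]
  if ("gene_log2FC" %in% names(x)) {
    x$gene_log2FC <- ifelse(is.na(x$gene_log2FC), "not expressed",
      format(x$gene_log2FC, trim = TRUE, scientific = FALSE)
    )
  }
  readr::write_tsv(x, path, progress = FALSE, na = "NA")
  invisible(path)
}

#' Read a differential-region table
#'
#' Expected columns: `chrom`, `start`, `end`, `logFC`, `p`, `FDR`,
#' `direction` (`up`/`down`). Direction must be consistent with the sign of
#' `logFC`.
#'
#' @param path File path.
#' @return A signed-region tibble.
#' @export
read_differential_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("chrom", "start", "end", "logFC", "p", "FDR", "direction")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    rlang::abort(paste0("differential table lacks column(s): ", paste(miss, collapse = ", ")),
      class = "ecre_input_error"
    )
  }
  validate_signed_regions(tibble::as_tibble(x))
}

validate_signed_regions <- function(x) {
  if (!all(x$direction %in% c("up", "down"))) {
    rlang::abort("direction must be 'up' or 'down'", class = "ecre_input_error")
  }
  lfc <- x[["logFC"]]
  if (!is.null(lfc)) {
    bad <- (x$direction == "up" & lfc < 0) | (x$direction == "down" & lfc > 0)
    if (any(bad)) {
      rlang::abort("direction inconsistent with sign of logFC", class = "ecre_input_error")
    }
  }
  for (col in c("p", "FDR")) {
    v <- x[[col]]
    if (!is.null(v) && any(v < 0 | v > 1)) {
      rlang::abort("p and FDR must lie in [0, 1]", class = "ecre_input_error")
    }
  }
  x
}

#' Read a per-method differential-expression table
#'
#' Expected columns: `gene`, `log2FC`, `significant` (logical).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_deg_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  miss <- setdiff(c("gene", "log2FC", "significant"), names(x))
  if (length(miss) > 0) {
    rlang::abort(paste0("DEG table lacks column(s): ", paste(miss, collapse = ", ")),
      class = "ecre_input_error"
    )
  }
  x$significant <- as.logical(x$significant)
  tibble::as_tibble(x)
}
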