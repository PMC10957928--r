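#' Annotate regions with their nearest gene TSS
#'
#' For each region, finds the gene whose transcription start site (TSS) is
#' closest and reports a signed, strand-aware distance plus a genomic location
#' category. Distances are measured from the TSS to the nearest region
#' boundary and are 0 only when the region spans the TSS itself; negative
#' distances mean the region lies upstream of the TSS on the gene's strand.
#'
#' Location categories follow the convention of standard peak annotators with
#' the promoter window set to TSS +/- 1000 bp:
#' * `Promoter` - the region overlaps `[tss - 1000, tss + 1000]`. A promoter
#'   region can still have a nonzero distance when it does not span the TSS.
#' * `exon i of n` / `intron i of n` - if the gene carries exon structure and
#'   the region midpoint falls inside the gene body; indices count in
#'   transcription order (exon 1 is 5'-most).
#' * `Distal Intergenic` - everything else.
#'
#' Ties on absolute distance break to the lexicographically smallest gene
#' symbol, so output is deterministic. Genes on other chromosomes are
#' infinitely far; a region on a chromosome without genes gets an `NA` row
#' with a warning.
#'
#' @param regions Region tibble.
#' @param genes Gene table with columns `symbol`, `chrom`, `strand` (`+`/`-`),
#'   `tss` (0-based base position) and optional `exon_starts`/`exon_ends`
#'   (comma-separated 0-based half-open coordinates).
#' @return A tibble with one row per input region: `gene`,
#'   `distance_to_tss`, `location`.
#' @export
annotate_nearest_tss <- function(regions, genes) {
  regions <- as_regions(regions)
  if (is.null(genes) || nrow(genes) == 0) {
    rlang::abort("gene table is empty", class = "ecre_input_error")
  }
  genes <- dplyr::arrange(tibble::as_tibble(genes), .data$symbol)
  genes$strand <- as.character(genes$strand)
  genes$chrom <- as.character(genes$chrom)

  out <- tibble::tibble(
    gene = rep(NA_character_, nrow(regions)),
    distance_to_tss = rep(NA_integer_, nrow(regions)),
    location = rep(NA_character_, nrow(regions))
  )
  if (nrow(regions) == 0) {
    return(out)
  }

  for (cr in unique(regions$chrom)) {
    ri <- which(regions$chrom == cr)
    gsub_ <- genes[genes$chrom == cr, , drop = FALSE]
    if (nrow(gsub_) == 0) {
      warning("no gene on chromosome ", cr, "; regions left unannotated")
      next
    }
    s <- regions$start[ri]
    e <- regions$end[ri]
    n <- length(ri)
    m <- nrow(gsub_)
    tssM <- matrix(gsub_$tss, n, m, byrow = TRUE)
    sM <- matrix(s, n, m)
    eM <- matrix(e, n, m)
    # raw genomic distance: 0 if the region contains the TSS, else signed gap
    # from the TSS to the nearest covered base
    d_raw <- ifelse(
      sM <= tssM & tssM < eM, 0L,
      ifelse(tssM < sM, sM - tssM, (eM - 1L) - tssM)
    )
    strandM <- matrix(gsub_$strand, n, m, byrow = TRUE)
    d_signed <- ifelse(strandM == "+", d_raw, -d_raw)
    best <- max.col(-abs(d_signed), ties.method = "first")
    idx <- cbind(seq_len(n), best)
    out$gene[ri] <- gsub_$symbol[best]
    out$distance_to_tss[ri] <- as.integer(d_signed[idx])
    out$location[ri] <- vapply(seq_len(n), function(k) {
      locate_region(s[k], e[k], gsub_[best[k], ])
    }, character(1))
  }
  out
}

# location category for one region against its nearest gene
locate_region <- function(s, e, gene) {
  tss <- gene$tss
  if (s <= tss + 1000L && e > tss - 1000L) {
    return("Promoter")
  }
  ex_s <- parse_coord_list(gene[["exon_starts"]])
  ex_e <- parse_coord_list(gene[["exon_ends"]])
  if (length(ex_s) == 0) {
    return("Distal Intergenic")
  }
  mid <- (s + e) %/% 2L
  body_s <- min(ex_s)
  body_e <- max(ex_e)
  if (mid < body_s || mid >= body_e) {
    return("Distal Intergenic")
  }
  o <- order(ex_s)
  ex_s <- ex_s[o]
  ex_e <- ex_e[o]
  n_ex <- length(ex_s)
  in_ex <- which(ex_s <= mid & mid < ex_e)
  if (length(in_ex) >= 1) {
    g <- in_ex[1]
    i <- if (gene$strand == "+") g else n_ex - g + 1L
    return(sprintf("exon %d of %d", i, n_ex))
  }
  g <- max(which(ex_e <= mid), 1L) # genomic intron after exon g
  i <- if (gene$strand == "+") g else n_ex - g
  sprintf("intron %d of %d", i, n_ex - 1L)
}

parse_coord_list <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(x)) {
    return(integer())
  }
  as.integer(strsplit(as.character(x), ",", fixed = TRUE)[[1]])
}
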