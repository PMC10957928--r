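#' Configuration for the synthetic-data generator
#'
#' The generator emulates every input of the screening pipeline on a toy
#' genome with known ground truth: planted enhancers standing in for the 695
#' validated positives, a library of peak tracks enriched over the enhancers
#' at a stated rate, coverage tracks with a stated gain over enhancers,
#' two differential-accessibility tables with a planted consensus, and a gene
#' annotation in which every enhancer's nearest gene is known.
#'
#' Defaults mirror the study conditions where those are stated: 695 planted
#' enhancers, 81 peak tracks (40 informative + 41 pure-noise) plus 2 coverage
#' tracks, a promoter-scale enhancer length range, and 252 marker genes
#' (fraction 0.252 of 1000 genes). The toy genome is 5 x 10 Mb.
#'
#' @param seed Integer master seed; every generator derives an independent
#'   substream from it, so adding a generator never perturbs the others.
#' @param n_chrom,chrom_length Number and length (bp) of toy chromosomes.
#' @param n_pos Number of planted enhancers.
#' @param length_range Enhancer length bounds (bp), drawn uniformly.
#' @param n_informative,n_noise Counts of informative and noise peak tracks.
#' @param p_fg Probability an informative track carries a peak over each
#'   planted enhancer.
#' @param p_bg Background peak probability per 1 kb window (all tracks).
#' @param n_coverage Number of coverage (bedGraph) tracks.
#' @param coverage_gain Mean coverage multiplier over enhancers.
#' @param n_genes Number of genes in the annotation.
#' @param marker_fraction Fraction of genes flagged as cluster markers.
#' @param n_dar Rows in the primary differential-accessibility table.
#' @param flip_fraction,orphan_fraction Fractions of primary differential
#'   regions whose confirming-table counterpart has flipped sign, or is
#'   absent, respectively; the remainder form the planted consensus.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 5L,
                       chrom_length = 1e7,
                       n_pos = 695L,
                       length_range = c(200L, 2000L),
                       n_informative = 40L,
                       n_noise = 41L,
                       p_fg = 0.9,
                       p_bg = 0.05,
                       n_coverage = 2L,
                       coverage_gain = 5,
                       n_genes = 1000L,
                       marker_fraction = 0.252,
                       n_dar = 100L,
                       flip_fraction = 0.2,
                       orphan_fraction = 0.2) {
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length = as.integer(chrom_length), n_pos = as.integer(n_pos),
    length_range = as.integer(length_range),
    n_informative = as.integer(n_informative), n_noise = as.integer(n_noise),
    p_fg = p_fg, p_bg = p_bg, n_coverage = as.integer(n_coverage),
    coverage_gain = coverage_gain, n_genes = as.integer(n_genes),
    marker_fraction = marker_fraction, n_dar = as.integer(n_dar),
    flip_fraction = flip_fraction, orphan_fraction = orphan_fraction
  )
  stopifnot(
    cfg$n_chrom >= 0, cfg$n_pos >= 0, cfg$length_range[1] >= 1,
    cfg$length_range[1] <= cfg$length_range[2],
    cfg$p_bg <= cfg$p_fg, cfg$p_fg <= 1, cfg$p_bg >= 0,
    cfg$coverage_gain >= 1, cfg$flip_fraction + cfg$orphan_fraction <= 1
  )
  structure(cfg, class = "sim_config")
}

#' Derive a reproducible substream seed from a master seed and a label
#'
#' Stable string hash combined with the master seed, kept below 2^31 so it is
#' a valid R integer seed. Used so each generator draws from its own stream.
#'
#' @param seed Integer master seed.
#' @param name Stream label.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((as.numeric(seed) %% 2147483647 + h * 2654435) %% 2147483647)
}

with_substream <- function(cfg, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(cfg$seed, name))
  code()
}

#' Build the toy genome
#'
#' @param cfg A [sim_config()].
#' @return A genome tibble (`chrom`, `length`).
#' @export
make_genome <- function(cfg) {
  if (cfg$n_chrom < 1) {
    rlang::abort("n_chrom must be >= 1", class = "ecre_input_error")
  }
  tibble::tibble(
    chrom = paste0("chr", seq_len(cfg$n_chrom)),
    length = rep(cfg$chrom_length, cfg$n_chrom)
  )
}

#' Plant non-overlapping enhancer regions
#'
#' Lengths are drawn uniformly within `cfg$length_range`; placements are
#' rejection-sampled against the already-placed enhancers so the set is
#' pairwise non-overlapping. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param genome Genome tibble from [make_genome()].
#' @return A region tibble of `cfg$n_pos` enhancers with a `name` column.
#' @export
simulate_enhancers <- function(cfg, genome) {
  if (cfg$n_pos == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(),
      end = integer(), name = character()
    ))
  }
  with_substream(cfg, "enhancers", function() {
    lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]), cfg$n_pos, replace = TRUE)
    # place with an 11 kb tail pad so enhancers are mutually separated by
    # more than 11 kb: this makes each enhancer's paired gene (placed within
    # 5 kb) provably its nearest gene in the synthetic annotation
    pad <- 11001L
    placed <- draw_placements(lens + pad, genome,
      excl = NULL,
      max_attempts = 1000L, self_avoid = TRUE
    )
    placed$end <- placed$start + lens
    placed <- as_regions(placed, genome)
    placed$name <- sprintf("enh_%04d", seq_len(nrow(placed)))
    placed
  })
}

#' Simulate the epigenetic peak-track library
#'
#' Informative tracks carry a peak overlapping each planted enhancer with
#' probability `p_fg` (centered on the enhancer with +/- 200 bp jitter) on top
#' of homogeneous background peaks dropped per 1 kb window at rate `p_bg`;
#' noise tracks carry background only, so their enhancer-overlap rate is the
#' chance rate.
#'
#' @param cfg A [sim_config()].
#' @param genome Genome tibble.
#' @param enhancers Planted enhancers from [simulate_enhancers()].
#' @return A list with `tracks` (named list of region tibbles) and `truth`
#'   (tibble: `track`, `informative`, `p_fg`, `p_bg`).
#' @export
simulate_tracks <- function(cfg, genome, enhancers) {
  with_substream(cfg, "tracks", function() {
    n_tracks <- cfg$n_informative + cfg$n_noise
    names_all <- c(
      sprintf("informative_%02d", seq_len(cfg$n_informative)),
      sprintf("noise_%02d", seq_len(cfg$n_noise))
    )
    informative <- rep(c(TRUE, FALSE), c(cfg$n_informative, cfg$n_noise))
    tracks <- vector("list", n_tracks)
    names(tracks) <- names_all
    for (t in seq_len(n_tracks)) {
      bg <- background_peaks(cfg, genome)
      if (informative[t] && nrow(enhancers) > 0) {
        hit <- stats::runif(nrow(enhancers)) < cfg$p_fg
        fg <- planted_peaks(enhancers[hit, , drop = FALSE], genome)
        peaks <- dplyr::bind_rows(bg, fg)
      } else {
        peaks <- bg
      }
      tracks[[t]] <- if (nrow(peaks) > 0) as_regions(peaks) else peaks
    }
    truth <- tibble::tibble(
      track = names_all,
      informative = informative,
      p_fg = ifelse(informative, cfg$p_fg, cfg$p_bg),
      p_bg = cfg$p_bg
    )
    list(tracks = tracks, truth = truth)
  })
}

background_peaks <- function(cfg, genome) {
  out <- list()
  for (ci in seq_len(nrow(genome))) {
    n_win <- genome$length[ci] %/% 1000L
    win <- which(stats::runif(n_win) < cfg$p_bg)
    if (length(win) == 0) next
    w <- sample(200:800, length(win), replace = TRUE)
    s <- (win - 1L) * 1000L + vapply(
      pmax(1L, 1000L - w + 1L), function(u) sample.int(u, 1L) - 1L, integer(1)
    )
    out[[length(out) + 1]] <- tibble::tibble(
      chrom = genome$chrom[ci],
      start = as.integer(s),
      end = as.integer(pmin(s + w, genome$length[ci]))
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  dplyr::bind_rows(out)
}

planted_peaks <- function(enh, genome) {
  if (nrow(enh) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  mid <- (enh$start + enh$end) %/% 2L +
    as.integer(round(stats::runif(nrow(enh), -200, 200)))
  w <- sample(300:800, nrow(enh), replace = TRUE)
  len <- stats::setNames(genome$length, genome$chrom)
  s <- pmax(0L, mid - w %/% 2L)
  e <- pmin(as.integer(len[enh$chrom]), s + w)
  tibble::tibble(chrom = enh$chrom, start = as.integer(s), end = as.integer(e))
}

#' Simulate a coverage track with a stated gain over enhancers
#'
#' Piecewise-constant values on 1 kb bins with gamma-distributed background of
#' mean 1; every bin overlapping an enhancer is multiplied by
#' `cfg$coverage_gain`, so the mean per-base value over enhancers is about
#' `coverage_gain` times the background mean.
#'
#' @param cfg A [sim_config()].
#' @param genome Genome tibble.
#' @param enhancers Planted enhancers.
#' @param name Substream label (default `"coverage"`), so multiple tracks can
#'   be drawn independently.
#' @return A coverage tibble (`chrom`, `start`, `end`, `value`).
#' @export
simulate_coverage <- function(cfg, genome, enhancers, name = "coverage") {
  with_substream(cfg, name, function() {
    out <- list()
    enh_gr <- if (nrow(enhancers) > 0) regions_to_gr(enhancers) else NULL
    for (ci in seq_len(nrow(genome))) {
      n_win <- as.integer(ceiling(genome$length[ci] / 1000))
      s <- (seq_len(n_win) - 1L) * 1000L
      e <- pmin(s + 1000L, genome$length[ci])
      v <- stats::rgamma(n_win, shape = 20, rate = 20)
      bins <- tibble::tibble(chrom = genome$chrom[ci], start = s, end = e, value = v)
      if (!is.null(enh_gr)) {
        hit <- GenomicRanges::countOverlaps(
          regions_to_gr(bins[, c("chrom", "start", "end")]), enh_gr
        ) > 0
        bins$value[hit] <- bins$value[hit] * cfg$coverage_gain
      }
      out[[ci]] <- bins
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate two differential-accessibility tables with planted consensus
#'
#' The primary table stands in for one caller's regions; the confirming table
#' for the second caller. A known subset of primary rows overlaps a confirming
#' row of the same sign (the planted consensus), a disjoint subset overlaps a
#' confirming row of flipped sign, and the rest overlap nothing.
#'
#' @param cfg A [sim_config()].
#' @param genome Genome tibble.
#' @return A list: `primary`, `confirming` (signed-region tibbles with
#'   `region_id`, `direction`, `logFC`, `p`, `FDR`) and `truth_ids` (the
#'   `region_id`s of the planted consensus).
#' @export
simulate_dar_tables <- function(cfg, genome) {
  with_substream(cfg, "dar_tables", function() {
    n <- cfg$n_dar
    widths <- sample(300:1500, n, replace = TRUE)
    # place primary regions with a 400 bp tail pad so confirming rows shifted
    # by up to 150 bp can only ever overlap their own primary region
    primary <- draw_placements(widths + 400L, genome,
      excl = NULL,
      max_attempts = 1000L, self_avoid = TRUE
    )
    primary$end <- primary$start + widths
    primary$region_id <- format_region_id(primary)
    primary$direction <- sample(c("up", "down"), n, replace = TRUE)
    primary$logFC <- ifelse(primary$direction == "up", 1, -1) *
      abs(stats::rnorm(n, mean = 2, sd = 0.7))
    primary$p <- stats::runif(n, 1e-8, 0.005)
    primary$FDR <- pmin(1, primary$p * 2)

    n_flip <- round(cfg$flip_fraction * n)
    n_orph <- round(cfg$orphan_fraction * n)
    n_same <- n - n_flip - n_orph
    role <- sample(rep(c("same", "flip", "orphan"), c(n_same, n_flip, n_orph)))

    keep <- role != "orphan"
    shift <- as.integer(round(stats::runif(sum(keep), -150, 150)))
    conf <- primary[keep, c("chrom", "start", "end")]
    conf$start <- pmax(0L, conf$start + shift)
    conf$end <- conf$end + shift
    conf$direction <- ifelse(role[keep] == "same",
      primary$direction[keep],
      ifelse(primary$direction[keep] == "up", "down", "up")
    )
    conf$logFC <- ifelse(conf$direction == "up", 1, -1) *
      abs(stats::rnorm(sum(keep), mean = 2, sd = 0.7))
    conf$p <- stats::runif(sum(keep), 1e-8, 0.005)
    conf$FDR <- pmin(1, conf$p * 2)
    conf$region_id <- format_region_id(conf)

    list(
      primary = primary,
      confirming = conf,
      truth_ids = primary$region_id[role == "same"]
    )
  })
}

#' Simulate a gene annotation, marker list and expression table
#'
#' Each planted enhancer gets one paired gene whose TSS is placed 1-5 kb from
#' the enhancer edge; filler genes are kept at least 10 kb away from every
#' enhancer, so the paired gene is provably each enhancer's nearest. A
#' `marker_fraction` of all genes (always including the paired genes first) is
#' flagged as cluster markers; expression log2 fold-changes follow a
#' two-component model with markers shifted up.
#'
#' @param cfg A [sim_config()].
#' @param genome Genome tibble.
#' @param enhancers Planted enhancers.
#' @return A list: `genes` (annotation tibble), `markers` (character vector),
#'   `degs` (tibble `gene`, `log2FC`, `significant`), and `truth_nearest`
#'   (tibble `name`, `gene` pairing each enhancer with its nearest gene).
#' @export
simulate_annotation <- function(cfg, genome, enhancers) {
  if (cfg$n_genes < 1) {
    rlang::abort("n_genes must be >= 1", class = "ecre_input_error")
  }
  with_substream(cfg, "annotation", function() {
    n_enh <- nrow(enhancers)
    n_pair <- min(n_enh, cfg$n_genes)
    genes <- list()
    if (n_pair > 0) {
      off <- sample(1000:5000, n_pair, replace = TRUE)
      side <- sample(c(-1L, 1L), n_pair, replace = TRUE)
      tss <- ifelse(side > 0,
        enhancers$end[seq_len(n_pair)] - 1L + off,
        enhancers$start[seq_len(n_pair)] - off
      )
      len <- stats::setNames(genome$length, genome$chrom)
      tss <- pmin(pmax(tss, 0L), as.integer(len[enhancers$chrom[seq_len(n_pair)]]) - 1L)
      genes[[1]] <- tibble::tibble(
        symbol = sprintf("Gene%04d", seq_len(n_pair)),
        chrom = enhancers$chrom[seq_len(n_pair)],
        strand = sample(c("+", "-"), n_pair, replace = TRUE),
        tss = as.integer(tss)
      )
    }
    n_fill <- cfg$n_genes - n_pair
    if (n_fill > 0) {
      enh_pad <- if (n_enh > 0) {
        tibble::tibble(
          chrom = enhancers$chrom,
          start = pmax(0L, enhancers$start - 10000L),
          end = enhancers$end + 10000L
        )
      } else {
        NULL
      }
      spots <- shuffle_match(
        tibble::tibble(
          chrom = genome$chrom[1], start = 0L,
          end = rep(2L, n_fill)
        ),
        genome,
        excl = enh_pad
      )
      genes[[length(genes) + 1]] <- tibble::tibble(
        symbol = sprintf("Gene%04d", n_pair + seq_len(n_fill)),
        chrom = spots$chrom,
        strand = sample(c("+", "-"), n_fill, replace = TRUE),
        tss = spots$start
      )
    }
    genes <- dplyr::bind_rows(genes)
    # simple exon structure: 3-6 non-overlapping exons within 30 kb of the TSS
    n_ex <- sample(3:6, nrow(genes), replace = TRUE)
    ex <- purrr::map2(genes$tss, n_ex, function(t, k) {
      starts <- t + c(0L, sort(sample(seq(2000L, 30000L, by = 500L), k - 1L)))
      widths <- sample(100:400, k, replace = TRUE)
      list(starts = starts, ends = starts + widths)
    })
    genes$exon_starts <- vapply(ex, function(z) paste(z$starts, collapse = ","), character(1))
    genes$exon_ends <- vapply(ex, function(z) paste(z$ends, collapse = ","), character(1))

    n_mark <- round(cfg$marker_fraction * cfg$n_genes)
    filler_pool <- if (n_pair > 0) genes$symbol[-seq_len(n_pair)] else genes$symbol
    markers <- if (n_mark == 0) {
      character()
    } else if (n_mark <= n_pair) {
      genes$symbol[seq_len(n_mark)]
    } else {
      c(genes$symbol[seq_len(n_pair)], sample(filler_pool, n_mark - n_pair))
    }
    is_marker <- genes$symbol %in% markers
    log2fc <- ifelse(is_marker,
      stats::rnorm(nrow(genes), mean = 3, sd = 1),
      stats::rnorm(nrow(genes), mean = 0, sd = 1)
    )
    degs <- tibble::tibble(
      gene = genes$symbol,
      log2FC = log2fc,
      significant = is_marker | abs(log2fc) > 2
    )
    truth_nearest <- if (n_pair > 0) {
      tibble::tibble(
        name = enhancers$name[seq_len(n_pair)],
        gene = genes$symbol[seq_len(n_pair)]
      )
    } else {
      tibble::tibble(name = character(), gene = character())
    }
    list(genes = genes, markers = markers, degs = degs, truth_nearest = truth_nearest)
  })
}
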