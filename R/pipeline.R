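#' Pipeline commands: simulate, train/score, discover
#'
#' File-tree orchestration over the package's functions. Each command reads
#' its inputs from disk, writes its outputs under `out_dir`, and finishes by
#' writing a `manifest.json` recording the seed/configuration and an MD5
#' checksum of every emitted file, so reruns with equal inputs can be checked
#' for byte-identical output.
#'
#' @name pipeline
NULL

write_manifest <- function(out_dir, command, config, files) {
  files <- sort(files)
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    command = command,
    config = config,
    files = as.list(stats::setNames(unname(sums), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest
}

#' @rdname pipeline
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_simulation <- function(cfg = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
  genome <- make_genome(cfg)
  enh <- simulate_enhancers(cfg, genome)
  if (nrow(enh) == 0) {
    warning("simulation produced zero enhancers (n_pos = 0)")
  }
  trk <- simulate_tracks(cfg, genome, enh)
  ann <- simulate_annotation(cfg, genome, enh)
  dar <- simulate_dar_tables(cfg, genome)

  files <- character()
  emit <- function(writer, obj, rel) {
    writer(obj, file.path(out_dir, rel))
    files <<- c(files, rel)
  }
  emit(write_chrom_sizes, genome, "genome.chrom.sizes")
  emit(write_bed, enh, "enhancers.bed")
  for (nm in names(trk$tracks)) {
    emit(write_bed, trk$tracks[[nm]], file.path("tracks", paste0(nm, ".bed")))
  }
  for (i in seq_len(cfg$n_coverage)) {
    cov <- simulate_coverage(cfg, genome, enh, name = paste0("coverage_", i))
    emit(write_bedgraph, cov, sprintf("coverage_%d.bedGraph", i))
  }
  emit(
    function(x, p) readr::write_tsv(x, p, progress = FALSE),
    dar$primary[, c(
      "region_id", "chrom", "start", "end", "direction",
      "logFC", "p", "FDR"
    )], "dar_primary.tsv"
  )
  emit(
    function(x, p) readr::write_tsv(x, p, progress = FALSE),
    dar$confirming[, c(
      "region_id", "chrom", "start", "end", "direction",
      "logFC", "p", "FDR"
    )], "dar_confirming.tsv"
  )
  emit(write_gene_annotation, ann$genes, "genes.tsv")
  emit(write_marker_list, ann$markers, "markers.txt")
  # two per-method expression tables with identical consensus by construction
  deg_b <- ann$degs
  jitter <- with_substream(cfg, "deg_methods", function() {
    stats::runif(nrow(deg_b), 0.8, 1.2)
  })
  deg_b$log2FC <- deg_b$log2FC * jitter
  emit(
    function(x, p) readr::write_tsv(x, p, progress = FALSE),
    ann$degs, "degs_method_a.tsv"
  )
  emit(
    function(x, p) readr::write_tsv(x, p, progress = FALSE),
    deg_b, "degs_method_b.tsv"
  )
  truth <- list(
    track_truth = trk$truth,
    dar_truth_ids = dar$truth_ids,
    truth_nearest = ann$truth_nearest
  )
  emit(
    function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA),
    truth, "truth.json"
  )
  invisible(write_manifest(out_dir, "simulate", unclass(cfg), files))
}

read_track_dir <- function(track_dir) {
  beds <- sort(list.files(track_dir, pattern = "\\.bed$", full.names = TRUE))
  tracks <- purrr::map(beds, read_bed)
  names(tracks) <- sub("\\.bed$", "", basename(beds))
  tracks
}

#' @rdname pipeline
#' @param positives_bed,chrom_sizes,track_dir,coverage_bedgraphs,blacklist_bed,queries_bed
#'   Input paths: positive enhancers (BED), genome sizes, directory of peak
#'   track BED files, character vector of coverage bedGraph paths, optional
#'   blacklist BED and optional query BED to score.
#' @param config A [train_config()].
#' @return The manifest, invisibly; `scores.tsv` and one model JSON per
#'   repeat are written under `out_dir`.
#' @export
run_train_score <- function(positives_bed, chrom_sizes, track_dir,
                            coverage_bedgraphs = character(),
                            blacklist_bed = NULL, queries_bed = NULL,
                            config = train_config(), out_dir) {
  for (p in c(
    positives_bed, chrom_sizes, track_dir, coverage_bedgraphs,
    blacklist_bed, queries_bed
  )) {
    if (!file.exists(p)) {
      rlang::abort(paste0("input not found: ", p), class = "ecre_input_error")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pos <- read_bed(positives_bed)
  genome <- read_chrom_sizes(chrom_sizes)
  peak_tracks <- read_track_dir(track_dir)
  cov_tracks <- purrr::map(coverage_bedgraphs, read_bedgraph)
  names(cov_tracks) <- sub("\\.bedGraph$", "", basename(coverage_bedgraphs))
  tracks <- track_library(peak_tracks, cov_tracks)
  excl <- if (!is.null(blacklist_bed)) read_bed(blacklist_bed) else NULL
  queries <- if (!is.null(queries_bed)) read_bed(queries_bed) else NULL

  ens <- ensemble_predict(pos, tracks, genome,
    excl = excl, queries = queries,
    config = config
  )
  files <- character()
  if (!is.null(ens$scores)) {
    readr::write_tsv(
      dplyr::arrange(ens$scores, dplyr::desc(.data$mean_score), .data$region_id),
      file.path(out_dir, "scores.tsv"),
      progress = FALSE
    )
    files <- c(files, "scores.tsv")
  }
  for (r in seq_along(ens$fits)) {
    rel <- sprintf("model_repeat%02d.json", r)
    write_lasso_fit(ens$fits[[r]], file.path(out_dir, rel))
    files <- c(files, rel)
  }
  run_info <- list(
    seed = config$seed,
    lambda_per_repeat = ens$lambdas,
    accuracy_per_repeat = ens$accuracies,
    mean_accuracy = mean(ens$accuracies)
  )
  jsonlite::write_json(run_info, file.path(out_dir, "run_info.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  files <- c(files, "run_info.json")
  invisible(write_manifest(out_dir, "train-score", unclass(config), files))
}

#' @rdname pipeline
#' @param dar_primary,dar_confirming,genes_tsv,markers_txt,deg_method_a,deg_method_b,scores_tsv
#'   Input paths for the discovery stage. Alternatively supply
#'   `candidates_file`, an already scored Table-style candidate report, to
#'   summarize it directly.
#' @param candidates_file Optional pre-built candidate table (passthrough
#'   mode).
#' @param threshold Decision threshold for the summary.
#' @return The manifest, invisibly; writes `candidates.tsv` and
#'   `summary.json`.
#' @export
run_discovery <- function(dar_primary = NULL, dar_confirming = NULL,
                          genes_tsv = NULL, markers_txt = NULL,
                          deg_method_a = NULL, deg_method_b = NULL,
                          scores_tsv = NULL, candidates_file = NULL,
                          threshold = 0.5, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(candidates_file)) {
    candidates <- read_candidate_table(candidates_file)
  } else {
    for (p in c(dar_primary, dar_confirming, genes_tsv, markers_txt)) {
      if (!file.exists(p)) {
        rlang::abort(paste0("input not found: ", p), class = "ecre_input_error")
      }
    }
    dars <- consensus_dars(
      read_differential_table(dar_primary),
      read_differential_table(dar_confirming)
    )
    opened <- select_opened(dars, "up")
    deg <- if (!is.null(deg_method_a) && !is.null(deg_method_b)) {
      consensus_degs(read_deg_table(deg_method_a), read_deg_table(deg_method_b))
    } else {
      NULL
    }
    candidates <- map_to_markers(
      opened, read_gene_annotation(genes_tsv),
      read_marker_list(markers_txt), deg
    )
    if (!is.null(scores_tsv)) {
      scores <- readr::read_tsv(scores_tsv, col_types = readr::cols(), progress = FALSE)
      candidates <- attach_scores(candidates, scores)
    }
  }
  write_candidate_table(candidates, file.path(out_dir, "candidates.tsv"))
  files <- "candidates.tsv"
  if ("prediction_score" %in% names(candidates) && nrow(candidates) > 0) {
    summary <- summarize_candidates(candidates, tau = threshold)
    jsonlite::write_json(as.list(summary), file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    files <- c(files, "summary.json")
  }
  invisible(write_manifest(
    out_dir, "discover",
    list(threshold = threshold), files
  ))
}
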