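signed <- function(chrom, start, end, direction) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    direction = direction,
    logFC = ifelse(direction == "up", 1, -1) * stats::runif(length(start), 0.5, 4),
    p = stats::runif(length(start), 0, 0.01),
    FDR = stats::runif(length(start), 0, 0.02)
  )
}

random_signed <- function(n, len = 5000L) {
  r <- random_regions(n, len = len, min_w = 20L, max_w = 300L)
  signed(r$chrom, r$start, r$end, sample(c("up", "down"), n, replace = TRUE))
}

test_that("two-caller DAR consensus keeps exactly the same-sign overlapping rows", {
  set.seed(420)
  prim <- random_signed(10)
  expect_equal(nrow(consensus_dars(prim, prim[0, ])), 0)

  # planted design via the simulator
  cfg <- sim_config(
    seed = 61, n_chrom = 2, chrom_length = 2e6, n_pos = 10,
    n_genes = 10, n_dar = 100, flip_fraction = 0.2, orphan_fraction = 0.2
  )
  g <- make_genome(cfg)
  dar <- simulate_dar_tables(cfg, g)
  cons <- consensus_dars(dar$primary, dar$confirming)
  expect_setequal(cons$region_id, dar$truth_ids)
  expect_equal(length(dar$truth_ids), 60)

  # random instances against an O(n * m) oracle, and structural properties
  ok <- ok_idem <- TRUE
  for (i in 1:300) {
    prim <- random_signed(sample(2:10, 1))
    conf <- random_signed(sample(1:8, 1))
    got <- consensus_dars(prim, conf)
    keep <- vapply(seq_len(nrow(prim)), function(r) {
      any(vapply(seq_len(nrow(conf)), function(k) {
        prim$direction[r] == conf$direction[k] &&
          max(prim$start[r], conf$start[k]) < min(prim$end[r], conf$end[k])
      }, logical(1)))
    }, logical(1))
    ok <- ok && df_equal(got, prim[keep, ])
    # idempotence under re-confirmation
    ok_idem <- ok_idem && df_equal(consensus_dars(got, conf), got)
  }
  expect_true(ok)
  expect_true(ok_idem)
})

test_that("direction selection partitions the table and rejects unknown labels", {
  set.seed(421)
  d <- random_signed(40)
  up <- select_opened(d, "up")
  down <- select_opened(d, "down")
  expect_equal(nrow(up) + nrow(down), nrow(d))
  expect_true(all(up$direction == "up"))
  expect_identical(as.data.frame(up), as.data.frame(d[d$direction == "up", ]))
  all_down <- signed("chr1", c(0, 100), c(50, 160), c("down", "down"))
  expect_equal(nrow(select_opened(all_down, "up")), 0)
  expect_error(select_opened(d, "sideways"), class = "ecre_input_error")
})

test_that("DEG consensus requires significance in both methods and concordant sign", {
  a <- tibble::tibble(gene = c("A", "B", "C"), log2FC = c(2, -1, 3), significant = TRUE)
  b <- tibble::tibble(gene = c("D", "E"), log2FC = c(1, 1), significant = TRUE)
  expect_equal(nrow(consensus_degs(a, b)), 0) # disjoint
  same <- consensus_degs(a, a)
  expect_setequal(same$gene, c("A", "B", "C"))

  set.seed(422)
  pool <- sprintf("G%02d", 1:20)
  ok <- TRUE
  for (i in 1:300) {
    a <- tibble::tibble(
      gene = sample(pool, 12), log2FC = stats::rnorm(12),
      significant = sample(c(TRUE, FALSE), 12, replace = TRUE)
    )
    b <- tibble::tibble(
      gene = sample(pool, 12), log2FC = stats::rnorm(12),
      significant = sample(c(TRUE, FALSE), 12, replace = TRUE)
    )
    got <- consensus_degs(a, b)
    want <- sort(intersect(
      a$gene[a$significant],
      b$gene[b$significant]
    ))
    want <- want[vapply(want, function(gn) {
      sign(a$log2FC[a$gene == gn]) == sign(b$log2FC[b$gene == gn])
    }, logical(1))]
    ok <- ok && identical(got$gene, want) &&
      identical(got$log2FC, a$log2FC[match(want, a$gene)])
  }
  expect_true(ok)
})

test_that("marker mapping keeps exactly the marker-adjacent regions", {
  genes <- tibble::tibble(
    symbol = c("Ma", "Mb", "Nc"), chrom = "chr1", strand = "+",
    tss = c(10000L, 50000L, 90000L)
  )
  dars <- signed("chr1", c(8000, 48000, 88000), c(8600, 48500, 88700), rep("up", 3))
  deg <- tibble::tibble(gene = c("Ma"), log2FC = 2.5)
  out <- map_to_markers(dars, genes, markers = c("Ma", "Mb"), deg = deg)
  expect_equal(nrow(out), 2) # the region near Nc is dropped
  expect_setequal(out$gene, c("Ma", "Mb"))
  expect_equal(out$gene_log2FC[out$gene == "Ma"], 2.5)
  expect_true(is.na(out$gene_log2FC[out$gene == "Mb"])) # "not expressed"
  # distance/location fields agree with direct annotation
  ann <- annotate_nearest_tss(out[, c("chrom", "start", "end")], genes)
  expect_identical(out$location, ann$location)
  expect_identical(out$distance_to_tss, ann$distance_to_tss)

  expect_equal(nrow(map_to_markers(dars, genes, markers = character(), deg = deg)), 0)
})

test_that("score attachment sorts descending and fails on missing regions", {
  set.seed(423)
  cand <- map_to_markers(
    signed("chr1", c(100, 900, 5000), c(400, 1400, 5800), rep("up", 3)),
    tibble::tibble(
      symbol = c("M1", "M2", "M3"), chrom = "chr1", strand = "+",
      tss = c(500L, 1500L, 6000L)
    ),
    markers = c("M1", "M2", "M3")
  )
  scores <- tibble::tibble(
    region_id = cand$region_id,
    mean_score = c(0.2, 0.9, 0.6)
  )
  out <- attach_scores(cand, scores)
  expect_equal(out$prediction_score, sort(out$prediction_score, decreasing = TRUE))
  expect_equal(
    out$prediction_score,
    scores$mean_score[match(out$region_id, scores$region_id)]
  )
  expect_error(attach_scores(cand, scores[-1, ]), class = "ecre_input_error")
  empty <- attach_scores(cand[0, ], scores)
  expect_equal(nrow(empty), 0)
})

test_that("candidate summaries count strict threshold passes and referenced hits", {
  expect_equal(summarize_candidates(tibble::tibble())$n_total, 0L)

  set.seed(424)
  ok <- TRUE
  for (i in 1:200) {
    n <- sample(1:60, 1)
    cand <- tibble::tibble(
      region_id = sprintf("chr1-%d-%d", 1:n, 1:n + 10),
      prediction_score = stats::runif(n),
      literature_ref = ifelse(stats::runif(n) < 0.3, "ref", NA)
    )
    s <- summarize_candidates(cand, tau = 0.4)
    ok <- ok && s$n_total == n &&
      s$n_above == sum(cand$prediction_score > 0.4) &&
      s$n_above_with_ref == sum(cand$prediction_score > 0.4 & !is.na(cand$literature_ref)) &&
      s$n_above_with_ref <= s$n_above && s$n_above <= s$n_total
  }
  expect_true(ok)

  unscored <- tibble::tibble(region_id = "chr1-1-10")
  expect_error(summarize_candidates(unscored), class = "ecre_input_error")
})

test_that("percentage rounding matches the published convention", {
  # 15 of 57 -> 26%, 57 of 101 -> 56%
  cand <- tibble::tibble(
    prediction_score = c(rep(0.9, 57), rep(0.1, 44)),
    literature_ref = c(rep("x", 15), rep(NA, 86))
  )
  s <- summarize_candidates(cand, 0.5)
  expect_equal(s$pct_above, 56L)
  expect_equal(s$pct_ref_of_above, 26L)
})

test_that("motif co-presence counts regions holding both families", {
  none <- tibble::tibble(region_id = c("r1", "r2"), motif = c("GATA", "ETS"))
  expect_equal(motif_copresence(none, "GATA", "ETS")$n_copresent, 0)
  expect_error(motif_copresence(none[0, ], "GATA", "ETS"), class = "ecre_input_error")

  # 56 co-hit regions out of 101 reproduce the printed 55%
  hits <- dplyr::bind_rows(
    tibble::tibble(
      region_id = rep(sprintf("co%03d", 1:56), each = 2),
      motif = rep(c("GATA", "ETS"), 56)
    ),
    tibble::tibble(region_id = sprintf("single%03d", 1:45), motif = "GATA")
  )
  got <- motif_copresence(hits, "GATA", "ETS")
  expect_equal(got$n_regions, 101L)
  expect_equal(got$n_copresent, 56L)
  expect_equal(got$percent, 55L)

  set.seed(425)
  fams <- c("GATA", "ETS", "FOS", "SOX")
  ok <- TRUE
  for (i in 1:300) {
    n <- sample(3:20, 1)
    hits <- tibble::tibble(
      region_id = sample(sprintf("r%02d", 1:10), n, replace = TRUE),
      motif = sample(fams, n, replace = TRUE)
    )
    got <- motif_copresence(hits, "GATA", "ETS")
    by_region <- split(hits$motif, hits$region_id)
    want <- sum(vapply(by_region, function(m) "GATA" %in% m && "ETS" %in% m, logical(1)))
    ok <- ok && got$n_copresent == want && got$n_regions == length(by_region)
  }
  expect_true(ok)
})

test_that("the published candidate fixtures reproduce the headline counts", {
  t2 <- read_candidate_table(system.file("extdata", "table2_candidates.tsv", package = "ecrescreen"))
  expect_equal(nrow(t2), 101)
  s <- summarize_candidates(t2, 0.5)
  expect_equal(s$n_total, 101L)
  expect_equal(s$n_above, 57L)
  expect_equal(s$n_above_with_ref, 15L)
  expect_equal(s$pct_ref_of_above, 26L)
  # re-sorting by score leaves the table invariant (it is printed sorted)
  expect_equal(order(t2$prediction_score, decreasing = TRUE), seq_len(101))
  # several regions may map to the same gene and are all retained
  expect_gt(max(table(t2$gene)), 1)

  t3 <- read_candidate_table(system.file("extdata", "table3_candidates.tsv", package = "ecrescreen"))
  expect_equal(nrow(t3), 6)
  expect_equal(sum(classify(t3$prediction_score, 0.5)), 4)
})
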