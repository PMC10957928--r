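# Brute-force per-base oracles and tiny random-instance builders used across
# the suite. Everything here is deliberately naive (O(n * m) scans, logical
# base masks) and independent of the interval code paths it checks.

random_regions <- function(n, chrom = "chr1", len = 2000L, min_w = 1L, max_w = 200L) {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(len - wi + 1L, 1L) - 1L, integer(1))
  tibble::tibble(chrom = chrom, start = as.integer(s), end = as.integer(s + w))
}

# logical mask over the bases of one chromosome
base_mask <- function(regions, chrom = "chr1", len = 2000L) {
  m <- logical(len)
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    m[(r$start[i] + 1L):r$end[i]] <- TRUE
  }
  m
}

# maximal TRUE runs of a mask, back to half-open regions
mask_to_regions <- function(m, chrom = "chr1") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(
    chrom = chrom,
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep])
  )
}

# scalar signed TSS distance, same convention as the package but written
# independently: 0 if the region spans the TSS, else gap from TSS to the
# nearest covered base, upstream negative on the gene's strand
oracle_tss_distance <- function(s, e, tss, strand) {
  d <- if (s <= tss && tss < e) {
    0L
  } else if (tss < s) {
    s - tss
  } else {
    (e - 1L) - tss
  }
  if (strand == "+") d else -d
}

oracle_nearest_gene <- function(s, e, genes) {
  d <- vapply(seq_len(nrow(genes)), function(i) {
    oracle_tss_distance(s, e, genes$tss[i], genes$strand[i])
  }, integer(1))
  o <- order(abs(d), genes$symbol)
  list(gene = genes$symbol[o[1]], distance = d[o[1]])
}

# rank-based (Mann-Whitney) AUROC
rank_auc <- function(label, score) {
  r <- rank(score)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

toy_genome <- function(n_chrom = 1L, len = 10000L) {
  tibble::tibble(chrom = paste0("chr", seq_len(n_chrom)), length = len)
}

# fast frame equality ignoring row names (subsetting keeps original row names)
df_equal <- function(a, b) {
  a <- as.data.frame(a)
  b <- as.data.frame(b)
  rownames(a) <- NULL
  rownames(b) <- NULL
  identical(a, b)
}
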