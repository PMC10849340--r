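make_maps <- function(n_genes = 4, n_samples = 2, seed = 1, ...) {
  generate_barcode_maps(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("s%d", seq_len(n_samples)),
                        seed = seed, ...)
}

test_that("demultiplexing matches exactly and conserves every read", {
  maps <- make_maps(seed = 2)
  lay <- barcode_layout()
  good <- paste0(maps$sample_indexes$index[1], maps$gene_barcodes$barcode[1],
                 "AAAA")
  # single substitution in the barcode field
  bad_bc <- good
  substr(bad_bc, lay$barcode_start, lay$barcode_start) <-
    setdiff(c("A", "C", "G", "T"),
            substr(good, lay$barcode_start, lay$barcode_start))[1]
  bad_idx <- paste0("NNNNNN", maps$gene_barcodes$barcode[2], "AAAA")
  short <- substr(good, 1, 10)

  dm <- demultiplex_counts(c(good, bad_bc, bad_idx, short),
                           maps$gene_barcodes, maps$sample_indexes)
  expect_equal(sum(dm$counts$count), 1)
  expect_equal(dm$counts$count[dm$counts$gene_id == "g01" &
                                 dm$counts$sample_id == "s1"], 1L)
  st <- dm$discard_stats
  expect_equal(st$n[st$reason == "total"], 4)
  expect_equal(st$n[st$reason == "counted"], 1)
  expect_equal(st$n[st$reason == "bad_barcode"], 1)
  expect_equal(st$n[st$reason == "bad_index"], 1)
  expect_equal(st$n[st$reason == "too_short"], 1)
  # conservation: counted + discarded = total
  discarded <- sum(st$n[!st$reason %in% c("counted", "total")])
  expect_equal(st$n[st$reason == "counted"] + discarded,
               st$n[st$reason == "total"])
})

test_that("demultiplexing a generated FASTQ file recovers the truth exactly", {
  maps <- make_maps(n_genes = 6, n_samples = 3, seed = 5)
  tc <- tidyr::expand_grid(gene_id = sprintf("g%02d", 1:6),
                           sample_id = sprintf("s%d", 1:3))
  set.seed(6)
  tc$count <- rpois(nrow(tc), 15)
  sim <- generate_barcode_reads(tc, maps$gene_barcodes, maps$sample_indexes,
                                error_rate = 0.01, seed = 7)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)

  dm <- demultiplex_counts(fq, maps$gene_barcodes, maps$sample_indexes)
  st <- dm$discard_stats
  discarded <- sum(st$n[!st$reason %in% c("counted", "total")])
  expect_equal(discarded, sum(sim$truth$field_error))
  expect_equal(st$n[st$reason == "counted"] + discarded, nrow(sim$reads))

  clean_truth <- dplyr::count(sim$truth[!sim$truth$field_error, ],
                              gene_id, sample_id, name = "n_true")
  merged <- dplyr::left_join(dm$counts, clean_truth,
                             by = c("gene_id", "sample_id"))
  merged$n_true[is.na(merged$n_true)] <- 0L
  expect_equal(merged$count, merged$n_true)
})

test_that("the exact test reproduces hand-enumerated and symmetric cases", {
  res <- exact_count_test(10, 0, 1e6, 1e6)
  expect_equal(res$p_value, 2 / 1024, tolerance = 1e-12)

  even <- exact_count_test(6, 6, 500, 500)
  expect_equal(even$p_value, 1)
  expect_equal(even$log2fc, 0)

  a <- exact_count_test(13, 4, 1000, 2000)
  b <- exact_count_test(4, 13, 2000, 1000)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)

  zero <- exact_count_test(0, 0, 100, 300)
  expect_equal(zero$p_value, 1)
  expect_equal(zero$log2fc, 0)

  expect_error(exact_count_test(-1, 0, 1, 1), class = "rhozero_validation_error")
  expect_error(exact_count_test(1, 0, 0, 1), class = "rhozero_validation_error")
})

test_that("the exact test agrees with enumeration and edgeR for all n <= 50", {
  pairs <- expand.grid(a = 0:50, b = 0:50)
  pairs <- pairs[pairs$a + pairs$b <= 50 & pairs$a + pairs$b > 0, ]

  # loop-based enumeration oracle, equal and unequal sizes
  for (sizes in list(c(1e4, 1e4), c(2e4, 1e4))) {
    ours <- exact_count_test(pairs$a, pairs$b, sizes[1], sizes[2])$p_value
    orc <- mapply(exact_test_oracle, pairs$a, pairs$b, sizes[1], sizes[2])
    expect_equal(ours, orc, tolerance = 1e-12)
  }

  skip_if_not_installed("edgeR")
  ours <- exact_count_test(pairs$a, pairs$b, 1e4, 1e4)$p_value
  theirs <- edgeR::binomTest(pairs$a, pairs$b, n1 = 1e4, n2 = 1e4)
  expect_equal(ours, theirs, tolerance = 1e-9)

  # unequal sizes: edgeR resolves exact probability ties by outcome index
  # rather than the minimum-likelihood rule; compare away from ties
  ours2 <- exact_count_test(pairs$a, pairs$b, 2e4, 1e4)$p_value
  theirs2 <- edgeR::binomTest(pairs$a, pairs$b, n1 = 2e4, n2 = 1e4)
  tied <- mapply(function(a, b) {
    n <- a + b
    probs <- dbinom(0:n, n, 2 / 3)
    pobs <- probs[a + 1]
    sum(abs(probs / pobs - 1) < 1e-7) > 1
  }, pairs$a, pairs$b)
  expect_gt(sum(!tied), 1000)
  expect_equal(ours2[!tied], theirs2[!tied], tolerance = 1e-9)
})

test_that("exact-test p-values are invariant to scaling both library sizes", {
  set.seed(3)
  a <- rpois(20, 30); b <- rpois(20, 30)
  p1 <- exact_count_test(a, b, 1e4, 2e4)$p_value
  p2 <- exact_count_test(a, b, 5e4, 1e5)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the rank metric implements sign times -log10 p", {
  expect_equal(rank_metric(0.01, 1), 2)
  expect_equal(rank_metric(0.001, -2), -3)
  expect_equal(rank_metric(1, 1), 0)
  expect_equal(rank_metric(1, -1), 0)
  expect_equal(rank_metric(0.01, 0), 0)
  grid <- expand.grid(p = c(1e-8, 1e-4, 0.05, 0.5, 1), s = c(-1, 1))
  expect_equal(rank_metric(grid$p, grid$s), grid$s * -log10(grid$p))
  expect_warning(capped <- rank_metric(0, 1),
                 class = "rhozero_pfloor_warning")
  expect_equal(capped, 300)
  expect_error(rank_metric(1.2, 1), class = "rhozero_validation_error")
})

test_that("BH adjustment equals the step-up oracle and is order-invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(12)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 0)), class = "rhozero_validation_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "rhozero_validation_error")
})

test_that("contrasts on identical pooled counts are entirely null", {
  genes <- sprintf("g%02d", 1:10)
  counts <- tidyr::expand_grid(gene_id = genes,
                               condition = c("control", "etbr"),
                               replicate = 1:2)
  counts$sample_id <- paste0(counts$condition, "_r", counts$replicate)
  counts$count <- rep(50L, nrow(counts))
  res <- run_contrast(counts, c("etbr", "control"))
  expect_true(all(res$p_value == 1))
  expect_true(all(res$rank_metric == 0))
  expect_true(all(!res$significant))
})

test_that("contrast output is invariant to replicate relabeling", {
  counts <- generate_screen_counts(n_genes = 100, seed = 9)
  res0 <- run_contrast(counts, c("etbr", "control"))
  shuffled <- dplyr::mutate(
    counts,
    replicate = dplyr::if_else(condition == "etbr", 4L - replicate, replicate),
    sample_id = paste0(condition, "_r", replicate)
  )
  res1 <- run_contrast(shuffled, c("etbr", "control"))
  expect_equal(res1$p_value, res0$p_value)
  expect_equal(res1$log2fc, res0$log2fc)
})

test_that("spiked genes dominate the rank-metric ordering", {
  genes <- sprintf("g%04d", 1:200)
  spikes <- tibble::tibble(
    gene_id = genes[1:6],
    condition = "etbr",
    log2fc = c(2, 2, 2, -2, -2, -2)
  )
  counts <- generate_screen_counts(n_genes = 200, n_reps = 3,
                                   library_size = 1e5, spikes = spikes,
                                   dispersion = 0.05, seed = 14)
  res <- run_contrast(counts, c("etbr", "control"))
  top <- select_hits(res, "top", k = 6)
  bottom <- select_hits(res, "bottom", k = 6)
  ranked <- res[order(-abs(res$rank_metric)), ]
  expect_true(all(spikes$gene_id %in% ranked$gene_id[1:12]))
  expect_true(all(res$rank_metric[match(genes[1:3], res$gene_id)] > 0))
  expect_true(all(res$rank_metric[match(genes[4:6], res$gene_id)] < 0))
  expect_true(all(genes[1:3] %in% top$gene_id))
  expect_true(all(genes[4:6] %in% bottom$gene_id))
})

test_that("hit selection is deterministic, bounded and disjoint", {
  counts <- generate_screen_counts(n_genes = 50, seed = 16)
  res <- run_contrast(counts, c("etbr", "control"))
  one <- select_hits(res, "top", k = 1)
  expect_equal(one$rank_metric, max(res$rank_metric))
  top <- select_hits(res, "top", k = 10)
  bottom <- select_hits(res, "bottom", k = 5)
  expect_equal(nrow(top), 10)
  expect_equal(nrow(bottom), 5)
  expect_length(intersect(top$gene_id, bottom$gene_id), 0)
  expect_warning(big <- select_hits(res, "top", k = 500))
  expect_equal(nrow(big), 50)
  expect_error(select_hits(res, "top"), class = "rhozero_validation_error")
  expect_s3_class(plot_rank_metric(res), "ggplot")
})

test_that("null screens yield empty or near-empty FDR hit sets", {
  fp <- vapply(1:10, function(s) {
    counts <- generate_screen_counts(n_genes = 200, library_size = 5e4,
                                     dispersion = 0, seed = 100 + s)
    res <- run_contrast(counts, c("etbr", "control"))
    nrow(select_hits(res, "fdr", fdr = 0.05))
  }, numeric(1))
  expect_lt(mean(fp) / 200, 0.05)
})
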