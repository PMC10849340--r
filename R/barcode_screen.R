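#' Demultiplex barcode reads into a count table by exact matching
#'
#' A read is counted for (sample, gene) only when its index field exactly
#' equals a mapped sample index and its barcode field exactly equals a
#' mapped gene barcode; all other reads are discarded with a reason
#' (bad index, bad barcode, both, or read too short for the layout).
#' Counted plus discarded always equals the total number of reads.
#'
#' @param reads A FASTQ file path, a character vector of read sequences, or
#'   a tibble with a `sequence` column (e.g. from
#'   [generate_barcode_reads()]).
#' @param gene_barcodes Tibble `gene_id`, `barcode`.
#' @param sample_indexes Tibble `sample_id`, `index`, optionally with
#'   `condition` and `replicate` columns that are carried onto the counts.
#' @param layout A [barcode_layout()].
#' @return A `demux_result` list: `counts` (long tibble `gene_id`,
#'   `sample_id`, `count`, plus annotations, complete over the gene x
#'   sample grid) and `discard_stats` (tibble `reason`, `n`, including
#'   `counted` and `total`).
#' @examples
#' maps <- generate_barcode_maps(c("gA", "gB"), c("s1", "s2"), seed = 1)
#' tc <- tidyr::expand_grid(gene_id = c("gA", "gB"), sample_id = c("s1", "s2"))
#' tc$count <- c(5, 3, 2, 7)
#' sim <- generate_barcode_reads(tc, maps$gene_barcodes, maps$sample_indexes,
#'                               seed = 2)
#' demultiplex_counts(sim$reads, maps$gene_barcodes, maps$sample_indexes)
#' @export
demultiplex_counts <- function(reads, gene_barcodes, sample_indexes,
                               layout = barcode_layout()) {
  check_maps(gene_barcodes, sample_indexes, layout)
  seqs <- read_sequences(reads)
  n_total <- length(seqs)

  min_len <- max(layout$index_start + layout$index_length,
                 layout$barcode_start + layout$barcode_length) - 1
  too_short <- nchar(seqs) < min_len
  idx_field <- substr(seqs, layout$index_start,
                      layout$index_start + layout$index_length - 1)
  bc_field <- substr(seqs, layout$barcode_start,
                     layout$barcode_start + layout$barcode_length - 1)
  samp <- sample_indexes$sample_id[match(idx_field, sample_indexes$index)]
  gene <- gene_barcodes$gene_id[match(bc_field, gene_barcodes$barcode)]
  samp[too_short] <- NA
  gene[too_short] <- NA

  ok <- !is.na(samp) & !is.na(gene)
  reason <- dplyr::case_when(
    too_short ~ "too_short",
    is.na(samp) & is.na(gene) ~ "bad_index_and_barcode",
    is.na(samp) ~ "bad_index",
    is.na(gene) ~ "bad_barcode",
    TRUE ~ NA_character_
  )

  counts <- tibble(gene_id = gene[ok], sample_id = samp[ok])
  counts <- dplyr::count(counts, .data$gene_id, .data$sample_id, name = "count")
  counts <- tidyr::complete(
    counts,
    gene_id = gene_barcodes$gene_id,
    sample_id = sample_indexes$sample_id,
    fill = list(count = 0L)
  )
  ann_cols <- intersect(c("condition", "replicate"), names(sample_indexes))
  if (length(ann_cols) > 0) {
    counts <- dplyr::left_join(
      counts, sample_indexes[, c("sample_id", ann_cols)], by = "sample_id"
    )
  }
  discard_stats <- dplyr::bind_rows(
    dplyr::count(tibble(reason = reason[!ok]), .data$reason, name = "n"),
    tibble(reason = c("counted", "total"), n = c(sum(ok), n_total))
  )
  structure(list(counts = counts, discard_stats = discard_stats),
            class = "demux_result")
}

read_sequences <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    return(as.character(Biostrings::readDNAStringSet(reads, format = "fastq")))
  }
  if (is.character(reads)) return(reads)
  if (is.data.frame(reads)) {
    check_columns(reads, "sequence", "reads")
    return(reads$sequence)
  }
  stop_validation("`reads` must be a FASTQ path, character vector, or tibble with `sequence`.")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("<demux_result>\n")
  print(x$discard_stats)
  invisible(x)
}

#' Write reads to a FASTQ file
#'
#' Standard 4-line records with constant Phred+33 quality ("I", Q40).
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_columns(reads, c("read_id", "sequence"), "reads")
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(
      dna, Biostrings::PhredQuality(qual)
    ),
    path
  )
  invisible(path)
}

#' Conditional binomial exact test for a pair of counts
#'
#' Conditions on the total \eqn{n = a + b}: under the null of equal
#' relative abundance, \eqn{a \sim Binomial(n, s_a / (s_a + s_b))} where
#' \eqn{s_a, s_b} are the library sizes. The two-sided p-value sums the
#' probabilities of all outcomes whose point probability does not exceed
#' that of the observed outcome (minimum-likelihood rule), capped at 1.
#' The log2 fold change uses a half-count pseudocount on each side:
#' \eqn{\log_2\{((a + 0.5)/s_a) / ((b + 0.5)/s_b)\}}.
#'
#' `n = 0` returns `p = 1`, `log2fc = 0` by convention. Vectorised over
#' counts (sizes recycled).
#'
#' @param count_a,count_b Non-negative integer counts.
#' @param size_a,size_b Library sizes (> 0).
#' @return A tibble with columns `p_value` and `log2fc`.
#' @examples
#' exact_count_test(10, 0, 1e6, 1e6) # p = 2/2^10
#' @export
exact_count_test <- function(count_a, count_b, size_a, size_b) {
  if (any(count_a < 0) || any(count_b < 0)) {
    stop_validation("counts must be non-negative.")
  }
  if (any(size_a <= 0) || any(size_b <= 0)) {
    stop_validation("library sizes must be positive.")
  }
  m <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, m); count_b <- rep_len(count_b, m)
  size_a <- rep_len(size_a, m); size_b <- rep_len(size_b, m)

  p <- vapply(seq_len(m), function(i) {
    n <- count_a[i] + count_b[i]
    if (n == 0) return(1)
    p0 <- size_a[i] / (size_a[i] + size_b[i])
    probs <- dbinom(0:n, n, p0)
    pobs <- probs[count_a[i] + 1]
    # guard against underflow to exactly zero at extreme counts
    max(min(1, sum(probs[probs <= pobs * (1 + 1e-7)])), .Machine$double.xmin)
  }, numeric(1))
  log2fc <- log2(((count_a + 0.5) / size_a) / ((count_b + 0.5) / size_b))
  log2fc[count_a + count_b == 0] <- 0
  tibble(p_value = p, log2fc = log2fc)
}

#' Signed rank metric for screen ordering
#'
#' The rank metric is the sign of the relative enrichment (+1 enriched,
#' -1 depleted) multiplied by the negative base-10 logarithm of the raw
#' p-value. A p-value of 1, or a zero fold change, gives 0. P-values below
#' `p_floor` are capped (with a warning) so the metric stays finite.
#'
#' @param p_raw Raw p-values in `(0, 1]` (zeros are floored).
#' @param log2fc Log2 fold changes (sign gives the direction).
#' @param p_floor Smallest usable p-value (default 1e-300).
#' @return Numeric vector of signed rank metrics.
#' @examples
#' rank_metric(c(0.01, 0.001, 1), c(1, -2, 3)) # +2, -3, 0
#' @export
rank_metric <- function(p_raw, log2fc, p_floor = 1e-300) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop_validation("`p_raw` must lie in [0, 1].")
  }
  if (any(p_raw < p_floor, na.rm = TRUE)) {
    rlang::warn("p-values below the floor were capped for the rank metric.",
                class = "rhozero_pfloor_warning")
    p_raw <- pmax(p_raw, p_floor)
  }
  sign(log2fc) * (-log10(p_raw))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone, capped at 1), returned in
#' input order.
#'
#' @param p P-values in `(0, 1]`.
#' @return Adjusted p-values, elementwise >= the raw values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop_validation("p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Run an enrichment contrast on a screen count table
#'
#' Replicate samples are rescaled to the common median library size
#' (rounded) and pooled within each condition; the conditional binomial
#' exact test is applied per gene to the pooled counts, the signed rank
#' metric is computed, and BH adjustment is applied across genes.
#' Enrichment is measured for `contrast[1]` relative to `contrast[2]`.
#'
#' @param counts Long count table (`gene_id`, `sample_id`, `condition`,
#'   `count`), e.g. from [generate_screen_counts()] or
#'   [demultiplex_counts()].
#' @param contrast Length-2 character vector: (condition of interest,
#'   reference condition).
#' @param fdr FDR level for the `significant` flag (default 0.05).
#' @return An `enrichment_result` tibble with one row per gene: pooled
#'   counts, `log2fc`, `p_value`, `p_adj`, `rank_metric`, `significant`,
#'   and `low_evidence` (gene absent from both pooled conditions).
#' @examples
#' spikes <- tibble::tibble(gene_id = "g0001", condition = "etbr", log2fc = 2)
#' counts <- generate_screen_counts(100, spikes = spikes, seed = 1)
#' res <- run_contrast(counts, c("etbr", "control"))
#' head(dplyr::arrange(res, dplyr::desc(rank_metric)))
#' @export
run_contrast <- function(counts, contrast, fdr = 0.05) {
  check_columns(counts, c("gene_id", "sample_id", "condition", "count"),
                "counts")
  if (length(contrast) != 2) {
    stop_validation("`contrast` must name two conditions.")
  }
  if (!all(contrast %in% counts$condition)) {
    stop_validation("both contrast conditions must be present in `counts`.")
  }
  sub <- dplyr::filter(counts, .data$condition %in% contrast)
  libs <- dplyr::summarise(dplyr::group_by(sub, .data$sample_id),
                           lib = sum(.data$count), .groups = "drop")
  if (any(libs$lib == 0)) {
    stop_validation("every sample must have a positive library size.")
  }
  med <- median(libs$lib)
  sub <- dplyr::left_join(sub, libs, by = "sample_id")
  sub$scaled <- round(sub$count * med / sub$lib)

  pooled <- dplyr::summarise(
    dplyr::group_by(sub, .data$gene_id, .data$condition),
    scaled = sum(.data$scaled), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(pooled, names_from = "condition",
                             values_from = "scaled",
                             values_fill = 0L)
  a <- wide[[contrast[1]]]
  b <- wide[[contrast[2]]]
  size_a <- sum(a)
  size_b <- sum(b)

  test <- exact_count_test(a, b, size_a, size_b)
  res <- tibble(
    gene_id = wide$gene_id,
    count_a = a, count_b = b,
    log2fc = test$log2fc,
    p_value = test$p_value,
    p_adj = bh_adjust(test$p_value),
    rank_metric = rank_metric(test$p_value, test$log2fc),
    low_evidence = (a + b) == 0
  )
  res$significant <- res$p_adj < fdr
  attr(res, "contrast") <- contrast
  attr(res, "pooled_sizes") <- c(size_a, size_b)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Select hits from an enrichment result
#'
#' Genes are ordered deterministically by rank metric (descending), ties
#' broken lexicographically by gene id.
#'
#' @param results An `enrichment_result` tibble from [run_contrast()].
#' @param mode `"top"` (the `k` most adaptive, i.e. largest rank metric),
#'   `"bottom"` (the `k` least adaptive), or `"fdr"` (all genes with
#'   `p_adj < fdr`).
#' @param k Number of genes for `"top"`/`"bottom"`; truncated with a
#'   warning when larger than the table.
#' @param fdr FDR level for `"fdr"` mode.
#' @return The selected rows, ordered, with a `direction` column
#'   ("enriched"/"depleted"/"none").
#' @export
select_hits <- function(results, mode = c("top", "bottom", "fdr"),
                        k = NULL, fdr = 0.05) {
  mode <- match.arg(mode)
  check_columns(results, c("gene_id", "rank_metric", "p_adj"), "results")
  if (nrow(results) == 0) {
    stop_validation("`results` is empty.")
  }
  ord <- results[order(-results$rank_metric, results$gene_id), ]
  ord$direction <- dplyr::case_when(
    ord$rank_metric > 0 ~ "enriched",
    ord$rank_metric < 0 ~ "depleted",
    TRUE ~ "none"
  )
  if (mode == "fdr") {
    return(ord[ord$p_adj < fdr, ])
  }
  if (is.null(k) || k < 1) {
    stop_validation("`k` (>= 1) is required for top/bottom selection.")
  }
  if (k > nrow(ord)) {
    rlang::warn(sprintf("k = %d exceeds table size %d; truncated.",
                        k, nrow(ord)))
    k <- nrow(ord)
  }
  if (mode == "top") head(ord, k) else tail(ord, k)[seq(k, 1), ]
}
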