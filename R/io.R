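# Readers and writers for the pipeline's plain-text interchange formats.
# All tables are UTF-8 with a mandatory header row, "." decimal separator
# and NA for missing values; column orders below are stable API.

#' Read a plate-reader CSV into long format
#'
#' Expected layout: a `time_min` column followed by one OD600 column per
#' well.
#'
#' @param path CSV file path.
#' @return A long tibble with columns `curve_id`, `time_min`, `od600`.
#' @export
read_plate_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, "time_min", "plate csv")
  tidyr::pivot_longer(df, -"time_min", names_to = "curve_id",
                      values_to = "od600")[, c("curve_id", "time_min", "od600")]
}

#' Write a long plate table back to wide CSV
#'
#' @param plate Long tibble (`curve_id`, `time_min`, `od600`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  check_columns(plate, c("curve_id", "time_min", "od600"), "plate")
  wide <- tidyr::pivot_wider(plate, names_from = "curve_id",
                             values_from = "od600")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read a colony-area CSV
#'
#' Columns: `plate_id` or `strain`, `colony_id`, `area_mm2`, and optional
#' `respiring` (logical or TRUE/FALSE/NA strings).
#'
#' @param path CSV file path.
#' @return A tibble with a logical `respiring` column (NA = unknown).
#' @export
read_colony_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("plate_id" %in% names(df) && !"strain" %in% names(df)) {
    df$strain <- df$plate_id
  }
  check_columns(df, c("colony_id", "area_mm2"), "colony csv")
  if ("respiring" %in% names(df) && !is.logical(df$respiring)) {
    df$respiring <- as.logical(df$respiring)
  }
  as_tibble(df)
}

#' Read a petite time-series TSV
#'
#' Columns: `replicate` (or `replicate_id`), `genotype`, `time_h`,
#' `n_total`, `n_petite`.
#'
#' @param path TSV file path.
#' @return A tibble with the standard column names.
#' @export
read_petite_series_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if ("replicate" %in% names(df) && !"replicate_id" %in% names(df)) {
    df <- dplyr::rename(df, replicate_id = "replicate")
  }
  check_columns(df, c("replicate_id", "time_h", "n_total", "n_petite"),
                "petite series tsv")
  as_tibble(df)
}

#' Read gene-barcode and sample-index maps
#'
#' @param path TSV path; gene map needs columns `gene_id`, `barcode`;
#'   index map needs `sample_id`, `index` (plus optional `condition`,
#'   `replicate`).
#' @return A tibble.
#' @export
read_barcode_map_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("gene_id", "barcode"), "gene barcode tsv")
  as_tibble(df)
}

#' @rdname read_barcode_map_tsv
#' @export
read_sample_index_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("sample_id", "index"), "sample index tsv")
  as_tibble(df)
}

#' Read / write a gene x sample count matrix TSV
#'
#' On disk the matrix is wide (first column `gene_id`, one column per
#' sample); in memory it is the long tidy form used throughout.
#'
#' @param path TSV path.
#' @param sample_info Optional tibble (`sample_id`, `condition`,
#'   `replicate`) joined onto the long table after reading.
#' @return `read_counts_tsv`: a long tibble (`gene_id`, `sample_id`,
#'   `count`, plus annotations). `write_counts_tsv`: `path`, invisibly.
#' @export
read_counts_tsv <- function(path, sample_info = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, "gene_id", "counts tsv")
  long <- tidyr::pivot_longer(df, -"gene_id", names_to = "sample_id",
                              values_to = "count")
  if (!is.null(sample_info)) {
    check_columns(sample_info, "sample_id", "sample_info")
    long <- dplyr::left_join(long, sample_info, by = "sample_id")
  }
  long
}

#' @rdname read_counts_tsv
#' @param counts Long count tibble (`gene_id`, `sample_id`, `count`).
#' @export
write_counts_tsv <- function(counts, path) {
  check_columns(counts, c("gene_id", "sample_id", "count"), "counts")
  wide <- tidyr::pivot_wider(counts[, c("gene_id", "sample_id", "count")],
                             names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Validate pipeline input files
#'
#' Schema-checks every provided input (column names, value ranges) and, for
#' FASTQ, record well-formedness (4-line records, matching sequence and
#' quality lengths, header sigils). Issues are collected into one report
#' rather than thrown one at a time.
#'
#' @param paths Named list of file paths; recognised names: `plate_csv`,
#'   `colony_csv`, `petite_series_tsv`, `gene_barcodes_tsv`,
#'   `sample_indexes_tsv`, `counts_tsv`, `fastq`.
#' @return A tibble of issues (`input`, `issue`); zero rows when all inputs
#'   pass.
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(input, issue) {
    issues[[length(issues) + 1]] <<- tibble(input = input, issue = issue)
  }
  try_read <- function(input, fn, checks) {
    path <- paths[[input]]
    if (!file.exists(path)) {
      note(input, "file does not exist")
      return(invisible(NULL))
    }
    obj <- tryCatch(fn(path), error = function(e) {
      note(input, paste("failed to parse:", conditionMessage(e)))
      NULL
    })
    if (!is.null(obj)) checks(obj)
  }

  if (!is.null(paths$plate_csv)) {
    try_read("plate_csv", read_plate_csv, function(df) {
      if (any(!is.finite(df$od600))) note("plate_csv", "non-finite OD600 values")
      if (any(df$time_min < 0)) note("plate_csv", "negative times")
    })
  }
  if (!is.null(paths$colony_csv)) {
    try_read("colony_csv", read_colony_csv, function(df) {
      bad <- !is.finite(df$area_mm2) | df$area_mm2 <= 0
      if (any(bad)) {
        note("colony_csv", sprintf("%d colony area(s) out of range (must be > 0)",
                                   sum(bad)))
      }
    })
  }
  if (!is.null(paths$petite_series_tsv)) {
    try_read("petite_series_tsv", read_petite_series_tsv, function(df) {
      if (any(df$n_total <= 0)) note("petite_series_tsv", "n_total must be > 0")
      if (any(df$n_petite < 0 | df$n_petite > df$n_total)) {
        note("petite_series_tsv", "n_petite outside [0, n_total]")
      }
      if (any(df$time_h < 0)) note("petite_series_tsv", "negative times")
    })
  }
  if (!is.null(paths$gene_barcodes_tsv)) {
    try_read("gene_barcodes_tsv", read_barcode_map_tsv, function(df) {
      if (anyDuplicated(df$barcode)) note("gene_barcodes_tsv", "duplicate barcodes")
      if (any(grepl("[^ACGT]", df$barcode))) {
        note("gene_barcodes_tsv", "barcodes contain non-ACGT characters")
      }
    })
  }
  if (!is.null(paths$sample_indexes_tsv)) {
    try_read("sample_indexes_tsv", read_sample_index_tsv, function(df) {
      if (anyDuplicated(df$index)) note("sample_indexes_tsv", "duplicate indexes")
      if (any(grepl("[^ACGT]", df$index))) {
        note("sample_indexes_tsv", "indexes contain non-ACGT characters")
      }
    })
  }
  if (!is.null(paths$counts_tsv)) {
    try_read("counts_tsv", read_counts_tsv, function(df) {
      if (any(df$count < 0, na.rm = TRUE)) note("counts_tsv", "negative counts")
      if (anyNA(df$count)) note("counts_tsv", "missing counts")
    })
  }
  if (!is.null(paths$fastq)) {
    path <- paths$fastq
    if (!file.exists(path)) {
      note("fastq", "file does not exist")
    } else {
      lines <- readLines(path, warn = FALSE)
      if (length(lines) %% 4 != 0) {
        note("fastq", "truncated record: line count not a multiple of 4")
      } else if (length(lines) > 0) {
        heads <- lines[seq(1, length(lines), by = 4)]
        plus <- lines[seq(3, length(lines), by = 4)]
        seqs <- lines[seq(2, length(lines), by = 4)]
        quals <- lines[seq(4, length(lines), by = 4)]
        if (any(substr(heads, 1, 1) != "@")) note("fastq", "header line not starting with @")
        if (any(substr(plus, 1, 1) != "+")) note("fastq", "separator line not starting with +")
        if (any(nchar(seqs) != nchar(quals))) {
          note("fastq", "sequence and quality lengths differ")
        }
      }
    }
  }
  if (length(issues) == 0) {
    tibble(input = character(0), issue = character(0))
  } else {
    dplyr::bind_rows(issues)
  }
}
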