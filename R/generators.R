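#' Simulate a time-resolved petite plating series
#'
#' Emulates the time-resolved mtDNA loss assay: an aerobically conditioned
#' culture (starting mutant fraction `baseline_fraction`) grows in glucose
#' medium while losing mtDNA; at each sampling time an aliquot is plated and
#' colonies are scored. The number of colonies per plate is Poisson around
#' the configured density and the number of petites is binomial with the
#' model's mutant fraction at plating.
#'
#' Defaults follow the assay design: 8 replicates, sampling every 3 hours
#' for 9 hours, roughly 150 colonies per plate.
#'
#' @inheritParams solve_closed_form
#' @param sampling_times Plating times, hours since relaxation of selection.
#' @param colonies_per_plate Expected colonies per plate (Poisson mean);
#'   plates that draw zero colonies are redrawn so every record has
#'   `n_total > 0`.
#' @param n_replicates Independent biological replicates.
#' @param baseline_fraction Mutant fraction at time zero, in `[0, 1)`;
#'   overrides the initial abundances in `params`.
#' @param genotype Label carried through to the output.
#' @param seed Optional integer seed (fixed seed, identical table).
#' @return A tibble with columns `replicate_id`, `genotype`, `time_h`,
#'   `n_total`, `n_petite`, and the generating fraction `true_f`.
#' @examples
#' p <- two_state_params(0.4, 0.4, 0.15)
#' generate_petite_time_series(p, seed = 1)
#' @export
generate_petite_time_series <- function(params,
                                        sampling_times = c(0, 3, 6, 9),
                                        colonies_per_plate = 150,
                                        n_replicates = 8,
                                        baseline_fraction = 0,
                                        genotype = "synthetic",
                                        seed = NULL) {
  params <- as_two_state_params(params)
  check_times(sampling_times)
  check_finite_scalar(colonies_per_plate, "colonies_per_plate", lower = 1)
  check_finite_scalar(n_replicates, "n_replicates", lower = 1)
  check_finite_scalar(baseline_fraction, "baseline_fraction", lower = 0)
  if (baseline_fraction >= 1) {
    stop_validation("`baseline_fraction` must be in [0, 1).")
  }
  p <- two_state_params(params$g_wt, params$g_mut, params$r,
                        p_wt0 = 1 - baseline_fraction,
                        p_mut0 = baseline_fraction)
  f_t <- mutant_fraction_at(p, sampling_times)
  with_seed_or_current(seed, {
    grid <- tidyr::expand_grid(
      replicate_id = paste0("rep", seq_len(n_replicates)),
      time_h = sampling_times
    )
    grid$true_f <- rep(f_t, times = n_replicates)
    n_total <- rpois(nrow(grid), colonies_per_plate)
    while (any(n_total == 0L)) {
      n_total[n_total == 0L] <- rpois(sum(n_total == 0L), colonies_per_plate)
    }
    grid$n_total <- n_total
    grid$n_petite <- rbinom(nrow(grid), size = n_total, prob = grid$true_f)
    grid$genotype <- genotype
    grid[, c("replicate_id", "genotype", "time_h", "n_total", "n_petite", "true_f")]
  })
}

#' Simulate a plate-reader OD600 growth curve
#'
#' Lag, then exponential growth, then saturation, plus additive Gaussian
#' read noise. The exponential phase is exactly
#' `initial_od * exp(rate * t)` until the curve reaches
#' `transition_frac * capacity_od`; beyond that point the signal relaxes
#' exponentially toward `capacity_od` with matched value and slope
#' (continuously differentiable), emulating the bend of a culture running
#' out of fermentable carbon. With `noise_sd = 0` and `lag_h = 0` the
#' sub-transition part of the series is exactly exponential, so log-linear
#' fitting recovers `rate` to machine precision there.
#'
#' @param rate Exponential growth constant, per hour (natural log).
#' @param lag_h Lag before growth starts, hours.
#' @param initial_od Cell density signal at inoculation (OD600 units).
#' @param capacity_od Carrying capacity (OD600); `Inf` for pure exponential.
#' @param transition_frac Fraction of capacity at which exponential growth
#'   hands over to saturation (default 0.5).
#' @param noise_sd SD of additive Gaussian read noise (OD units).
#' @param interval_min Sampling interval in minutes (plate readers commonly
#'   read every 20 minutes).
#' @param duration_h Total duration, hours.
#' @param curve_id Identifier carried through to the output.
#' @param seed Optional integer seed.
#' @return A tibble with columns `curve_id`, `time_min`, `od600`.
#' @examples
#' generate_growth_curve(rate = 0.35, seed = 1)
#' @export
generate_growth_curve <- function(rate, lag_h = 0, initial_od = 0.05,
                                  capacity_od = 1.2, transition_frac = 0.5,
                                  noise_sd = 0.002,
                                  interval_min = 20, duration_h = 12,
                                  curve_id = "sim", seed = NULL) {
  check_finite_scalar(rate, "rate", lower = 0)
  check_finite_scalar(lag_h, "lag_h", lower = 0)
  check_finite_scalar(initial_od, "initial_od", lower = 1e-12)
  if (!(is.numeric(capacity_od) && length(capacity_od) == 1L &&
        (is.infinite(capacity_od) || capacity_od > initial_od))) {
    stop_validation("`capacity_od` must exceed `initial_od` (or be Inf).")
  }
  check_finite_scalar(transition_frac, "transition_frac", lower = 0, upper = 1)
  check_finite_scalar(noise_sd, "noise_sd", lower = 0)
  time_min <- seq(0, duration_h * 60, by = interval_min)
  t_eff <- pmax(time_min / 60 - lag_h, 0)
  od_trans <- transition_frac * capacity_od
  if (is.infinite(capacity_od) || rate == 0 || initial_od >= od_trans) {
    od <- pmin(initial_od * exp(rate * t_eff),
               if (is.infinite(capacity_od)) Inf else capacity_od)
  } else {
    t_star <- log(od_trans / initial_od) / rate
    # saturating branch: value and slope matched at t_star
    k_sat <- rate * transition_frac / (1 - transition_frac)
    od <- ifelse(
      t_eff <= t_star,
      initial_od * exp(rate * t_eff),
      capacity_od - (capacity_od - od_trans) * exp(-k_sat * (t_eff - t_star))
    )
  }
  noise <- if (noise_sd > 0) {
    with_seed_or_current(seed, rnorm(length(od), 0, noise_sd))
  } else {
    0
  }
  tibble(curve_id = curve_id, time_min = time_min, od600 = od + noise)
}

#' Simulate a bimodal colony-area table
#'
#' Draws petite (small) and respiring-size (large) colony areas from
#' log-normal components, labels each colony with its respiration phenotype,
#' and optionally flips a fraction of labels to emulate patching errors and
#' cells that lost mtDNA after plating.
#'
#' @param n Number of colonies.
#' @param petite_fraction Probability a colony is petite (small component).
#' @param meanlog_small,sdlog_small,meanlog_large,sdlog_large Log-normal
#'   parameters of the small and large area components (areas in mm^2).
#'   Defaults put petites near 0.5 mm^2 and respiring colonies near 3 mm^2,
#'   either side of the conventional 1.5 mm^2 petite cutoff.
#' @param label_noise Fraction of respiration labels flipped, in `[0, 0.5)`.
#' @param strain Strain label.
#' @param seed Optional integer seed.
#' @return A tibble with columns `strain`, `colony_id`, `area_mm2`,
#'   `respiring` (observed, possibly noisy, label) and `true_petite`.
#' @examples
#' generate_colony_areas(100, petite_fraction = 0.3, seed = 1)
#' @export
generate_colony_areas <- function(n, petite_fraction = 0.3,
                                  meanlog_small = log(0.5), sdlog_small = 0.25,
                                  meanlog_large = log(3), sdlog_large = 0.25,
                                  label_noise = 0, strain = "synthetic",
                                  seed = NULL) {
  check_finite_scalar(n, "n", lower = 1)
  check_finite_scalar(petite_fraction, "petite_fraction", lower = 0, upper = 1)
  check_finite_scalar(label_noise, "label_noise", lower = 0)
  if (label_noise >= 0.5) {
    stop_validation("`label_noise` must be in [0, 0.5).")
  }
  with_seed_or_current(seed, {
    petite <- runif(n) < petite_fraction
    area <- numeric(n)
    area[petite] <- rlnorm(sum(petite), meanlog_small, sdlog_small)
    area[!petite] <- rlnorm(sum(!petite), meanlog_large, sdlog_large)
    respiring <- !petite
    if (label_noise > 0) {
      flip <- runif(n) < label_noise
      respiring[flip] <- !respiring[flip]
    }
    tibble(
      strain = strain,
      colony_id = paste0(strain, "_c", seq_len(n)),
      area_mm2 = area,
      respiring = respiring,
      true_petite = petite
    )
  })
}

#' Read layout of a barcode amplicon
#'
#' Describes where the in-line sample index and the gene barcode sit within
#' each read. Defaults: a 6 nt index at the start of the read, a 20 nt gene
#' barcode immediately after, and random filler bases out to 30 nt. The
#' geometry is configurable because primer schemes differ between libraries.
#'
#' @param index_start,index_length 1-based start and length of the index
#'   field.
#' @param barcode_start,barcode_length 1-based start and length of the gene
#'   barcode field.
#' @param read_length Total read length; must cover both fields.
#' @return A `barcode_layout` list.
#' @export
barcode_layout <- function(index_start = 1, index_length = 6,
                           barcode_start = 7, barcode_length = 20,
                           read_length = 30) {
  for (v in c("index_start", "index_length", "barcode_start",
              "barcode_length", "read_length")) {
    check_finite_scalar(get(v), v, lower = 1)
  }
  if (index_start + index_length - 1 > read_length ||
      barcode_start + barcode_length - 1 > read_length) {
    stop_validation("fields must fit within `read_length`.")
  }
  structure(
    list(index_start = index_start, index_length = index_length,
         barcode_start = barcode_start, barcode_length = barcode_length,
         read_length = read_length),
    class = "barcode_layout"
  )
}

#' Random barcode and index maps
#'
#' Convenience generator of unique random DNA sequences for gene barcodes
#' and sample indexes.
#'
#' @param gene_ids,sample_ids Identifiers to map.
#' @param layout A [barcode_layout()] giving the sequence lengths.
#' @param conditions Optional condition label per sample (recycled).
#' @param replicates Optional replicate id per sample (recycled).
#' @param seed Optional integer seed.
#' @return A list with tibbles `gene_barcodes` (`gene_id`, `barcode`) and
#'   `sample_indexes` (`sample_id`, `index`, plus `condition`/`replicate`
#'   if given).
#' @export
generate_barcode_maps <- function(gene_ids, sample_ids,
                                  layout = barcode_layout(),
                                  conditions = NULL, replicates = NULL,
                                  seed = NULL) {
  with_seed_or_current(seed, {
    bc <- random_unique_seqs(length(gene_ids), layout$barcode_length)
    idx <- random_unique_seqs(length(sample_ids), layout$index_length)
    gene_barcodes <- tibble(gene_id = gene_ids, barcode = bc)
    sample_indexes <- tibble(sample_id = sample_ids, index = idx)
    if (!is.null(conditions)) {
      sample_indexes$condition <- rep_len(conditions, length(sample_ids))
    }
    if (!is.null(replicates)) {
      sample_indexes$replicate <- rep_len(replicates, length(sample_ids))
    }
    list(gene_barcodes = gene_barcodes, sample_indexes = sample_indexes)
  })
}

random_unique_seqs <- function(n, len, max_tries = 100) {
  out <- character(0)
  tries <- 0
  while (length(out) < n && tries < max_tries) {
    need <- n - length(out)
    new <- vapply(seq_len(need), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, new))
    tries <- tries + 1
  }
  if (length(out) < n) {
    stop_validation("could not generate enough unique sequences; increase length.")
  }
  out[seq_len(n)]
}

#' Simulate barcode amplicon reads with a truth table
#'
#' Builds one read per counted molecule (sample index, then gene barcode,
#' then random filler per the layout), injects independent per-base
#' substitution errors at `error_rate`, and records for every read whether
#' any error landed inside the index or barcode fields - the quantity that
#' determines whether exact-match demultiplexing must discard it.
#'
#' @param true_counts Tibble with columns `gene_id`, `sample_id`, `count`:
#'   intended number of reads per (gene, sample).
#' @param gene_barcodes Tibble `gene_id`, `barcode` (unique DNA sequences).
#' @param sample_indexes Tibble `sample_id`, `index` (unique DNA sequences).
#' @param layout A [barcode_layout()].
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A list with `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (tibble `read_id`, `sample_id`, `gene_id`, `field_error`).
#' @export
generate_barcode_reads <- function(true_counts, gene_barcodes, sample_indexes,
                                   layout = barcode_layout(),
                                   error_rate = 0, seed = NULL) {
  check_columns(true_counts, c("gene_id", "sample_id", "count"), "true_counts")
  check_maps(gene_barcodes, sample_indexes, layout)
  check_finite_scalar(error_rate, "error_rate", lower = 0, upper = 1)

  tc <- dplyr::filter(true_counts, .data$count > 0)
  tc <- dplyr::left_join(tc, gene_barcodes, by = "gene_id")
  tc <- dplyr::left_join(tc, sample_indexes[, c("sample_id", "index")],
                         by = "sample_id")
  if (anyNA(tc$barcode) || anyNA(tc$index)) {
    stop_validation("`true_counts` refers to genes or samples missing from the maps.")
  }

  n_reads <- sum(tc$count)
  gene <- rep(tc$gene_id, tc$count)
  samp <- rep(tc$sample_id, tc$count)
  bc <- rep(tc$barcode, tc$count)
  idx <- rep(tc$index, tc$count)

  with_seed_or_current(seed, {
    # assemble reads as a base matrix: filler everywhere, then fields
    L <- layout$read_length
    mat <- matrix(sample(c("A", "C", "G", "T"), n_reads * L, replace = TRUE),
                  nrow = n_reads, ncol = L)
    icols <- layout$index_start:(layout$index_start + layout$index_length - 1)
    bcols <- layout$barcode_start:(layout$barcode_start + layout$barcode_length - 1)
    mat[, icols] <- do.call(rbind, strsplit(idx, ""))
    mat[, bcols] <- do.call(rbind, strsplit(bc, ""))

    field_error <- logical(n_reads)
    if (error_rate > 0 && n_reads > 0) {
      err <- matrix(runif(n_reads * L) < error_rate, nrow = n_reads)
      if (any(err)) {
        pos <- which(err)
        # substitution to one of the three other bases
        shift <- sample.int(3, length(pos), replace = TRUE)
        bases <- c("A", "C", "G", "T")
        cur <- match(mat[pos], bases)
        mat[pos] <- bases[((cur - 1 + shift) %% 4) + 1]
      }
      field_error <- rowSums(err[, c(icols, bcols), drop = FALSE]) > 0
    }

    reads <- tibble(
      read_id = sprintf("read%06d", seq_len(n_reads)),
      sequence = apply(mat, 1, paste, collapse = "")
    )
    truth <- tibble(
      read_id = reads$read_id, sample_id = samp, gene_id = gene,
      field_error = field_error
    )
    list(reads = reads, truth = truth)
  })
}

check_maps <- function(gene_barcodes, sample_indexes, layout) {
  check_columns(gene_barcodes, c("gene_id", "barcode"), "gene_barcodes")
  check_columns(sample_indexes, c("sample_id", "index"), "sample_indexes")
  for (nm in c("barcode", "index")) {
    seqs <- if (nm == "barcode") gene_barcodes$barcode else sample_indexes$index
    if (anyDuplicated(seqs)) {
      stop_validation(sprintf("duplicate %s sequences in map.", nm))
    }
    if (any(grepl("[^ACGT]", seqs))) {
      stop_validation(sprintf("%s sequences must be over {A,C,G,T}.", nm))
    }
    len <- if (nm == "barcode") layout$barcode_length else layout$index_length
    if (any(nchar(seqs) != len)) {
      stop_validation(sprintf("%s sequences must all have length %d.", nm, len))
    }
  }
  invisible(TRUE)
}

#' Simulate a multi-condition barcode count table
#'
#' Gene-wise counts are drawn around condition-specific expected proportions
#' (equal across genes at baseline; spiked genes have their proportion
#' multiplied by `2^log2fc` in the named condition, then proportions are
#' renormalised). Counts are gamma-mixed Poisson, i.e. negative binomial
#' with `dispersion` as the NB dispersion (variance `mu + dispersion mu^2`);
#' `dispersion = 0` gives Poisson sampling.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per condition (screens commonly use 3).
#' @param library_size Expected reads per sample.
#' @param conditions Condition labels, first is the baseline.
#' @param spikes Optional tibble with columns `gene_id`, `condition`,
#'   `log2fc` giving per-condition proportion shifts.
#' @param dispersion NB dispersion (>= 0).
#' @param seed Optional integer seed.
#' @return A long count table: tibble with `gene_id`, `sample_id`,
#'   `condition`, `replicate`, `count`.
#' @examples
#' spikes <- tibble::tibble(gene_id = "g0001", condition = "etbr", log2fc = 2)
#' counts <- generate_screen_counts(100, spikes = spikes, seed = 1)
#' @export
generate_screen_counts <- function(n_genes = 1000, n_reps = 3,
                                   library_size = 2e5,
                                   conditions = c("control", "etbr"),
                                   spikes = NULL, dispersion = 0.05,
                                   seed = NULL) {
  check_finite_scalar(n_genes, "n_genes", lower = 1)
  check_finite_scalar(n_reps, "n_reps", lower = 1)
  check_finite_scalar(library_size, "library_size", lower = 1)
  check_finite_scalar(dispersion, "dispersion", lower = 0)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (!is.null(spikes)) {
    check_columns(spikes, c("gene_id", "condition", "log2fc"), "spikes")
    if (!all(spikes$gene_id %in% gene_ids)) {
      stop_validation("spiked gene_ids must be among the generated genes.")
    }
    if (!all(spikes$condition %in% conditions)) {
      stop_validation("spiked conditions must be among `conditions`.")
    }
  }
  with_seed_or_current(seed, {
    purrr::map_dfr(conditions, function(cond) {
      prop <- rep(1, n_genes)
      if (!is.null(spikes)) {
        sp <- spikes[spikes$condition == cond, ]
        if (nrow(sp) > 0) {
          prop[match(sp$gene_id, gene_ids)] <- 2^sp$log2fc
        }
      }
      prop <- prop / sum(prop)
      mu <- library_size * prop
      purrr::map_dfr(seq_len(n_reps), function(rep_i) {
        count <- if (dispersion > 0) {
          rnbinom(n_genes, mu = mu, size = 1 / dispersion)
        } else {
          rpois(n_genes, mu)
        }
        tibble(
          gene_id = gene_ids,
          sample_id = paste0(cond, "_r", rep_i),
          condition = cond, replicate = rep_i, count = count
        )
      })
    })
  })
}
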