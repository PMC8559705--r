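# CpG methylation: binned per-read profiling from per-CpG modified-base
# posteriors, all-or-none 45S copy classification, IGS methylation,
# adjacency/switch statistics, and copy-number / active-copy analysis.

#' Read a per-CpG methylation-call TSV
#'
#' Canonical input: one row per CpG call with columns `read_id`,
#' `position` (0-based read offset) and `posterior` (probability the CpG
#' is methylated).
#'
#' @param path Path to the TSV (with header).
#' @return Tibble with the three columns, typed.
#' @export
read_methylation_calls <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "position", "posterior")
  if (!all(need %in% names(d))) {
    abort("methylation TSV must have columns read_id, position, posterior.")
  }
  tibble(
    read_id = as.character(d$read_id),
    position = as.integer(d$position),
    posterior = as.numeric(d$posterior)
  )
}

#' Write methylation calls to TSV
#'
#' @param calls Tibble with `read_id`, `position`, `posterior`.
#' @param path Output path.
#' @export
write_methylation_calls <- function(calls, path) {
  write.table(calls, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(calls)
}

check_posteriors <- function(calls) {
  bad <- is.na(calls$posterior) | calls$posterior < 0 | calls$posterior > 1
  if (any(bad)) {
    warn(sprintf(
      "dropping %d methylation call(s) with posterior outside [0,1].",
      sum(bad)
    ))
    calls <- calls[!bad, , drop = FALSE]
  }
  calls
}

#' Bin per-CpG methylation posteriors along a read
#'
#' Two per-bin metrics are computed: `avg_freq`, the mean posterior
#' ("average" metric), and `thresh_freq`, the fraction of CpGs whose
#' posterior is at least `threshold` ("threshold" metric). Bins without a
#' CpG carry no value and are excluded.
#'
#' @param calls Tibble of calls for one read (`position`, `posterior`).
#' @param read_length Read length in bases.
#' @param bin Bin width (default 200).
#' @param threshold Posterior threshold for the threshold metric
#'   (default 0.8).
#' @return Tibble: `bin_start`, `n_cpg`, `avg_freq`, `thresh_freq`.
#' @export
bin_methylation <- function(calls, read_length, bin = 200L,
                            threshold = 0.8) {
  calls <- check_posteriors(calls)
  if (any(calls$position < 0L | calls$position >= read_length)) {
    abort("call positions must lie within the read.")
  }
  if (nrow(calls) == 0L) {
    return(tibble(
      bin_start = integer(0), n_cpg = integer(0),
      avg_freq = numeric(0), thresh_freq = numeric(0)
    ))
  }
  calls |>
    dplyr::mutate(bin_start = as.integer(.data$position %/% bin * bin)) |>
    dplyr::group_by(.data$bin_start) |>
    dplyr::summarise(
      n_cpg = dplyr::n(),
      avg_freq = mean(.data$posterior),
      thresh_freq = mean(.data$posterior >= threshold),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin_start)
}

#' Per-copy 45S methylation status
#'
#' For each complete copy segment, the mean posterior over the CpG calls
#' inside the copy's coding (45S) sub-interval, classified
#' methylated/unmethylated against the `border` (strictly greater is
#' methylated). With `metric = "threshold"` the fraction of CpGs at
#' posterior >= `threshold` is used instead of the mean.
#'
#' @param segments Copy segments of one read ([segment_copies()]).
#' @param calls Methylation calls of the same read.
#' @param border Classification border (default 0.1, strict).
#' @param metric `"average"` (default) or `"threshold"`.
#' @param threshold Posterior threshold for the threshold metric.
#' @return Tibble: `read_id`, `copy_index`, `n_cpg`, `mean_45s`, `class`
#'   (`"methylated"`/`"unmethylated"`, `NA` when no CpG call falls in the
#'   coding sub-interval).
#' @export
copy_methylation <- function(segments, calls, border = 0.1,
                             metric = c("average", "threshold"),
                             threshold = 0.8) {
  metric <- match.arg(metric)
  calls <- check_posteriors(calls)
  seg <- segments[segments$complete, , drop = FALSE]
  one <- function(i) {
    in_cr <- calls$position >= seg$coding_read_start[i] &
      calls$position < seg$coding_read_end[i]
    p <- calls$posterior[in_cr]
    m <- if (length(p) == 0L) {
      NA_real_
    } else if (metric == "average") {
      mean(p)
    } else {
      mean(p >= threshold)
    }
    tibble(
      read_id = seg$read_id[i], copy_index = seg$copy_index[i],
      n_cpg = length(p), mean_45s = m,
      class = if (is.na(m)) {
        NA_character_
      } else if (m > border) "methylated" else "unmethylated"
    )
  }
  if (nrow(seg) == 0L) {
    return(tibble(
      read_id = character(0), copy_index = integer(0), n_cpg = integer(0),
      mean_45s = numeric(0), class = character(0)
    ))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(seg)), one))
}

#' Per-copy IGS methylation (Butterfly/Long region excluded)
#'
#' Mean posterior over CpG calls inside the copy's intergenic spacer in
#' read space, excluding the Butterfly/Long sub-interval (microsatellites
#' with few CpGs and variable length).
#'
#' @inheritParams copy_methylation
#' @return Tibble: `read_id`, `copy_index`, `n_cpg_igs`,
#'   `igs_methylation` (`NA` when no eligible CpG).
#' @export
igs_methylation <- function(segments, calls) {
  calls <- check_posteriors(calls)
  seg <- segments[segments$complete, , drop = FALSE]
  one <- function(i) {
    in_seg <- calls$position >= seg$read_start[i] &
      calls$position < seg$read_end[i]
    in_coding <- calls$position >= seg$coding_read_start[i] &
      calls$position < seg$coding_read_end[i]
    in_bl <- !is.na(seg$bl_read_start[i]) &
      calls$position >= seg$bl_read_start[i] &
      calls$position < seg$bl_read_end[i]
    p <- calls$posterior[in_seg & !in_coding & !in_bl]
    tibble(
      read_id = seg$read_id[i], copy_index = seg$copy_index[i],
      n_cpg_igs = length(p),
      igs_methylation = if (length(p) == 0L) NA_real_ else mean(p)
    )
  }
  if (nrow(seg) == 0L) {
    return(tibble(
      read_id = character(0), copy_index = integer(0),
      n_cpg_igs = integer(0), igs_methylation = numeric(0)
    ))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(seg)), one))
}

#' Per-copy methylation status (45S + flanking IGS)
#'
#' Convenience join of [copy_methylation()] and [igs_methylation()] for
#' one read. The IGS reported for a copy is the spacer downstream of its
#' 45S gene (the copy's own segment when the unit origin coincides with
#' the 45S start).
#'
#' @inheritParams copy_methylation
#' @return Tibble with the columns of both per-copy tables.
#' @export
copy_methyl_status <- function(segments, calls, border = 0.1,
                               metric = "average", threshold = 0.8) {
  dplyr::left_join(
    copy_methylation(segments, calls,
      border = border, metric = metric,
      threshold = threshold
    ),
    igs_methylation(segments, calls),
    by = c("read_id", "copy_index")
  )
}

#' Correlation of 45S and flanking IGS methylation (strong stratum)
#'
#' Pearson correlation between per-copy 45S methylation and flanking IGS
#' methylation, restricted to strongly methylated copies
#' (`mean_45s > strong_cutoff`, strict).
#'
#' @param statuses Tibble with `mean_45s` and `igs_methylation` columns
#'   (e.g. pooled [copy_methyl_status()] rows).
#' @param strong_cutoff Stratum cutoff (default 0.3, strict).
#' @param min_n Minimum stratum size (default 10).
#' @return One-row tibble: `n`, `r`, `p_value`, `note`.
#' @export
correlate_45s_igs <- function(statuses, strong_cutoff = 0.3, min_n = 10L) {
  st <- statuses[
    !is.na(statuses$mean_45s) & !is.na(statuses$igs_methylation) &
      statuses$mean_45s > strong_cutoff, ,
    drop = FALSE
  ]
  if (nrow(st) < min_n) {
    return(tibble(
      n = nrow(st), r = NA_real_, p_value = NA_real_,
      note = "undetermined: stratum too small"
    ))
  }
  if (stats::var(st$igs_methylation) == 0 || stats::var(st$mean_45s) == 0) {
    return(tibble(
      n = nrow(st), r = NA_real_, p_value = NA_real_,
      note = "undetermined: zero variance"
    ))
  }
  ct <- cor.test(st$mean_45s, st$igs_methylation, method = "pearson")
  tibble(
    n = nrow(st), r = unname(ct$estimate), p_value = ct$p.value,
    note = ""
  )
}

#' Methylation adjacency: contiguous copies vs randomised pairs
#'
#' Absolute differences of 45S methylation between adjacent copies within
#' reads, a seeded random-pair control drawn from the pooled copies, and
#' the one-sided rank test that adjacent differences are smaller.
#'
#' @param statuses Pooled per-copy statuses (with `read_id`, `copy_index`,
#'   `mean_45s`).
#' @param n_random Number of control pairs (default: number of adjacent
#'   pairs, at least 100).
#' @param seed Integer seed for the control draw.
#' @return List with elements `adjacent` (tibble `read_id`, `abs_diff`),
#'   `control` (tibble `abs_diff`) and `test` (one-row tibble from
#'   [compare_adjacent_vs_random()]).
#' @export
methylation_adjacency <- function(statuses, n_random = NULL, seed = 1L) {
  adj <- statuses |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$copy_index, .by_group = TRUE) |>
    dplyr::mutate(
      adjacent = dplyr::lead(.data$copy_index) == .data$copy_index + 1L,
      abs_diff = abs(dplyr::lead(.data$mean_45s) - .data$mean_45s)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$adjacent, !is.na(.data$abs_diff)) |>
    dplyr::select("read_id", "abs_diff")
  if (nrow(adj) == 0L) {
    inform("no reads with >= 2 informative copies; adjacency undefined.")
    return(list(
      adjacent = adj, control = tibble(abs_diff = numeric(0)),
      test = NULL
    ))
  }
  pool <- statuses$mean_45s[!is.na(statuses$mean_45s)]
  n_random <- n_random %||% max(nrow(adj), 100L)
  control <- withr::with_seed(seed, {
    i <- sample.int(length(pool), n_random, replace = TRUE)
    j <- sample.int(length(pool) - 1L, n_random, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    tibble(abs_diff = abs(pool[i] - pool[j]))
  })
  list(
    adjacent = adj, control = control,
    test = compare_adjacent_vs_random(adj$abs_diff, control$abs_diff)
  )
}

#' Methylation switch rate between adjacent copies
#'
#' Fraction of adjacent classified copy pairs (within reads) whose
#' methylation classes differ, and the implied mean run length (1/rate).
#'
#' @param statuses Pooled per-copy statuses (with `read_id`, `copy_index`,
#'   `class`).
#' @return One-row tibble: `n_pairs`, `n_switches`, `switch_rate`,
#'   `mean_run_length`. Rates are `NA` with zero pairs.
#' @export
methylation_switch_rate <- function(statuses) {
  pairs <- statuses |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$copy_index, .by_group = TRUE) |>
    dplyr::mutate(
      adjacent = dplyr::lead(.data$copy_index) == .data$copy_index + 1L,
      switch = dplyr::lead(.data$class) != .data$class
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$adjacent, !is.na(.data$switch))
  n <- nrow(pairs)
  k <- sum(pairs$switch)
  tibble(
    n_pairs = n, n_switches = k,
    switch_rate = if (n > 0L) k / n else NA_real_,
    mean_run_length = if (n > 0L && k > 0L) n / k else NA_real_
  )
}

#' Estimate rDNA copy number per cell from the sequencing depth ratio
#'
#' `copies_per_cell = (rdna_bases / total_bases) * genome_size /
#' unit_length`. The ratio is base-weighted (total rDNA bases over total
#' sequenced bases).
#'
#' @param rdna_bases Total bases in rDNA reads.
#' @param total_bases Total sequenced bases (> 0).
#' @param genome_size Genome size in bases (default 6.27e9, diploid
#'   human).
#' @param unit_length Repeat-unit length in bases.
#' @return One-row tibble: `rdna_bases`, `total_bases`, `fraction`,
#'   `genome_size`, `unit_length`, `copies_per_cell`.
#' @export
estimate_copy_number <- function(rdna_bases, total_bases,
                                 genome_size = 6.27e9, unit_length) {
  if (unit_length <= 0) abort("`unit_length` must be positive.")
  if (total_bases <= 0) abort("`total_bases` must be positive.")
  if (rdna_bases > total_bases) {
    abort("`rdna_bases` cannot exceed `total_bases`.")
  }
  frac <- rdna_bases / total_bases
  tibble(
    rdna_bases = rdna_bases, total_bases = total_bases, fraction = frac,
    genome_size = genome_size, unit_length = unit_length,
    copies_per_cell = frac * genome_size / unit_length
  )
}

#' Active-copy analysis across samples
#'
#' Tests whether the number of unmethylated (active) copies is constant
#' across samples: Pearson correlation between copy number `N` and the
#' unmethylated proportion `p` (expected negative under a constant active
#' count), Pearson correlation between `N` and the active count `N * p`
#' (expected near zero), and the least-squares fit of `p = A / N`
#' returning the constant `A`.
#'
#' @param samples Tibble with columns `copies_per_cell` and
#'   `unmethylated_proportion` (one row per sample; a `sample_id` column
#'   is carried through if present).
#' @param reference_constant Reference value of `A` to overlay in plots
#'   (default 230).
#' @return Object of class `rdna_active_fit` with [tidy()], [glance()],
#'   [autoplot()] and print methods.
#' @export
active_copy_analysis <- function(samples, reference_constant = 230) {
  n <- nrow(samples)
  if (n < 5L) abort("need >= 5 samples.")
  N <- samples$copies_per_cell
  p <- samples$unmethylated_proportion
  if (stats::var(N) == 0) {
    return(structure(
      list(
        A = NA_real_, r_proportion = NA_real_, p_proportion = NA_real_,
        r_count = NA_real_, p_count = NA_real_, n = n, data = samples,
        reference_constant = reference_constant,
        note = "undetermined: no variance in copy number"
      ),
      class = "rdna_active_fit"
    ))
  }
  # least squares for p = A/N has the closed form below
  A <- sum(p / N) / sum(1 / N^2)
  ct1 <- cor.test(N, p)
  ct2 <- cor.test(N, N * p)
  structure(
    list(
      A = A,
      r_proportion = unname(ct1$estimate), p_proportion = ct1$p.value,
      r_count = unname(ct2$estimate), p_count = ct2$p.value,
      n = n, data = samples, reference_constant = reference_constant,
      note = ""
    ),
    class = "rdna_active_fit"
  )
}

#' @export
print.rdna_active_fit <- function(x, ...) {
  cat("<rdna_active_fit>\n")
  if (nzchar(x$note)) {
    cat(" ", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "  %d samples; fitted constant active copies A = %.1f\n", x$n, x$A
  ))
  cat(sprintf(
    "  r(N, unmethylated proportion) = %+.3f (p = %.3g)\n",
    x$r_proportion, x$p_proportion
  ))
  cat(sprintf(
    "  r(N, unmethylated count)      = %+.3f (p = %.3g)\n",
    x$r_count, x$p_count
  ))
  invisible(x)
}

#' @method tidy rdna_active_fit
#' @export
tidy.rdna_active_fit <- function(x, ...) {
  tibble(
    term = c("A", "r_proportion", "r_count"),
    estimate = c(x$A, x$r_proportion, x$r_count),
    p.value = c(NA, x$p_proportion, x$p_count)
  )
}

#' @method glance rdna_active_fit
#' @export
glance.rdna_active_fit <- function(x, ...) {
  tibble(
    n = x$n, A = x$A, r_proportion = x$r_proportion,
    p_proportion = x$p_proportion, r_count = x$r_count,
    p_count = x$p_count, note = x$note
  )
}

#' Per-sample correlation of R-repeat copy number and 45S methylation
#'
#' Spearman correlation per sample between the R-repeat copy-count proxy
#' and the 45S methylation level of the same copies, with
#' Benjamini-Hochberg false-discovery-rate correction across samples.
#'
#' @param data Tibble with columns `sample_id`, `r_units` (numeric
#'   R-repeat copy measure per copy) and `mean_45s`.
#' @param min_pairs Minimum paired copies per sample (default 10); smaller
#'   or zero-variance samples are skipped.
#' @param fdr Significance level on the adjusted p-values (default 0.05).
#' @return Tibble: `sample_id`, `n`, `rho`, `p_value`, `q_value`,
#'   `significant`, `skipped`.
#' @export
correlate_r_repeat_methylation <- function(data, min_pairs = 10L,
                                           fdr = 0.05) {
  one <- function(d, sid) {
    d <- d[!is.na(d$r_units) & !is.na(d$mean_45s), , drop = FALSE]
    if (nrow(d) < min_pairs || stats::var(d$r_units) == 0 ||
      stats::var(d$mean_45s) == 0) {
      return(tibble(
        sample_id = sid, n = nrow(d), rho = NA_real_,
        p_value = NA_real_, skipped = TRUE
      ))
    }
    ct <- suppressWarnings(
      cor.test(d$r_units, d$mean_45s, method = "spearman", exact = FALSE)
    )
    tibble(
      sample_id = sid, n = nrow(d), rho = unname(ct$estimate),
      p_value = ct$p.value, skipped = FALSE
    )
  }
  out <- dplyr::bind_rows(lapply(
    split(data, data$sample_id),
    function(d) one(d, d$sample_id[1])
  ))
  out$q_value <- NA_real_
  ok <- !out$skipped
  out$q_value[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < fdr
  out[, c(
    "sample_id", "n", "rho", "p_value", "q_value", "significant",
    "skipped"
  )]
}
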