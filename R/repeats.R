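# Repeat genotyping: per-copy R and Butterfly/Long repeat length deltas by
# anchor mapping, sample-level IGS typing, and the adjacent-vs-random copy
# similarity statistic (the gene-conversion signature).

#' Estimate per-copy R and Butterfly/Long repeat lengths
#'
#' Three fixed-length anchor sections taken from the reference (defaults:
#' 500 nt at unit positions 10000, 20000, 30000) are mapped onto the read.
#' Within each copy segment the leftmost hit per anchor is used (multiple
#' hits flag `multi_hit`). The R-repeat length delta is the read distance
#' between anchors 1 and 2 minus their reference distance; the
#' Butterfly/Long delta uses anchors 2 and 3. Deltas are `NA` when an
#' anchor is not located inside the segment.
#'
#' @param read The read (sequence string or list with `read_id`,
#'   `sequence`).
#' @param segments Copy segments from [segment_copies()].
#' @param ref The `rdna_reference`.
#' @param aligner Alignment backend (default [aligner_builtin()]).
#' @param r_unit_size,bl_unit_size Satellite unit sizes used for the
#'   derived copy-count columns (defaults 680 and 4500 bases).
#' @return Tibble: `read_id`, `copy_index`, `complete`, `delta_r`,
#'   `delta_bl`, `r_unit_delta` (rounded `delta_r / r_unit_size`),
#'   `multi_hit`.
#' @export
estimate_repeat_lengths <- function(read, segments, ref,
                                    aligner = aligner_builtin(),
                                    r_unit_size = 680,
                                    bl_unit_size = 4500) {
  seq <- read_sequence(read)
  rid <- read_id_of(read, default = segments$read_id[1] %||% "read")
  a <- ref$anchor_positions
  if (length(a) < 3L) abort("reference must define three anchors.")
  anchors <- setNames(
    substring(
      ref$unit_sequence, a + 1L,
      a + ref$anchor_length
    ),
    paste0("anchor", seq_along(a))
  )
  hits <- align_query(aligner, anchors, seq,
    circular = FALSE,
    all_hits = TRUE
  )

  if (nrow(segments) == 0L) {
    return(tibble(
      read_id = character(0), copy_index = integer(0),
      complete = logical(0), delta_r = numeric(0), delta_bl = numeric(0),
      r_unit_delta = numeric(0), multi_hit = logical(0)
    ))
  }

  one_segment <- function(i) {
    lo <- segments$read_start[i]
    hi <- segments$read_end[i]
    pos <- numeric(3)
    multi <- FALSE
    for (j in 1:3) {
      h <- hits[hits$query == paste0("anchor", j) &
        hits$strand == segments$strand[i] &
        hits$ref_pos >= lo & hits$ref_pos < hi, , drop = FALSE]
      if (nrow(h) == 0L) {
        pos[j] <- NA_real_
      } else {
        if (nrow(h) > 1L) multi <- TRUE
        pos[j] <- min(h$ref_pos) # leftmost hit in the segment
      }
    }
    d12 <- abs(pos[2] - pos[1])
    d23 <- abs(pos[3] - pos[2])
    tibble(
      read_id = rid,
      copy_index = segments$copy_index[i],
      complete = segments$complete[i],
      delta_r = d12 - (a[2] - a[1]),
      delta_bl = d23 - (a[3] - a[2]),
      multi_hit = multi
    )
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(segments)), one_segment))
  out$r_unit_delta <- round(out$delta_r / r_unit_size)
  out[, c(
    "read_id", "copy_index", "complete", "delta_r", "delta_bl",
    "r_unit_delta", "multi_hit"
  )]
}

#' Classify a sample's IGS length type
#'
#' The short/long IGS typing of a sample is the proportion of copies whose
#' Butterfly/Long repeat is more than `short_delta` bases shorter than the
#' reference (strict); samples above `type_cutoff` are type `"short"`.
#'
#' @param estimates Tibble from [estimate_repeat_lengths()] (or any tibble
#'   with a `delta_bl` column), or a numeric vector of `delta_bl` values.
#' @param short_delta Shortness threshold in bases (default 2000,
#'   exclusive: a delta of exactly -2000 is not short).
#' @param type_cutoff Proportion above which the sample is type short
#'   (default 0.2).
#' @param min_copies Minimum informative copies (default 20); below it the
#'   type is `"undetermined"`.
#' @return One-row tibble: `n_informative`, `short_proportion`, `type`.
#' @export
classify_igs_type <- function(estimates, short_delta = 2000,
                              type_cutoff = 0.2, min_copies = 20L) {
  db <- if (is.numeric(estimates)) estimates else estimates$delta_bl
  db <- db[!is.na(db)]
  n <- length(db)
  if (n < min_copies) {
    return(tibble(
      n_informative = n, short_proportion = NA_real_,
      type = "undetermined"
    ))
  }
  p <- mean(db < -short_delta)
  tibble(
    n_informative = n, short_proportion = p,
    type = if (p > type_cutoff) "short" else "long"
  )
}

#' Absolute repeat-length differences between adjacent copies
#'
#' For every pair of adjacent copies within a read (consecutive copy
#' indices, both informative) the absolute difference of their length
#' deltas, separately for the R and Butterfly/Long repeats.
#'
#' @param estimates Tibble from [estimate_repeat_lengths()] pooled over
#'   reads.
#' @return Tibble: `read_id`, `metric` (`"delta_r"`/`"delta_bl"`),
#'   `abs_diff`.
#' @export
adjacent_pair_differences <- function(estimates) {
  long <- tidyr::pivot_longer(
    estimates[, c("read_id", "copy_index", "delta_r", "delta_bl")],
    c("delta_r", "delta_bl"),
    names_to = "metric", values_to = "delta"
  )
  long |>
    dplyr::group_by(.data$read_id, .data$metric) |>
    dplyr::arrange(.data$copy_index, .by_group = TRUE) |>
    dplyr::mutate(
      adjacent = dplyr::lead(.data$copy_index) == .data$copy_index + 1L,
      abs_diff = abs(dplyr::lead(.data$delta) - .data$delta)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$adjacent, !is.na(.data$abs_diff)) |>
    dplyr::select("read_id", "metric", "abs_diff")
}

#' Randomised control: differences between randomly paired copies
#'
#' Draws `n_pairs` pairs of distinct copies uniformly from the sample pool
#' regardless of read of origin, per metric; the null distribution the
#' adjacent-pair differences are compared against.
#'
#' @param estimates Tibble from [estimate_repeat_lengths()] pooled over
#'   reads.
#' @param n_pairs Number of control pairs per metric.
#' @param seed Integer seed; the draw is reproducible.
#' @return Tibble: `metric`, `abs_diff`.
#' @export
randomized_pair_differences <- function(estimates, n_pairs, seed) {
  draw <- function(values, metric) {
    values <- values[!is.na(values)]
    if (length(values) < 2L) {
      abort(sprintf("pool for %s has fewer than 2 copies.", metric))
    }
    i <- sample.int(length(values), n_pairs, replace = TRUE)
    j <- sample.int(length(values) - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j) # distinct partner, uniform
    tibble(metric = metric, abs_diff = abs(values[i] - values[j]))
  }
  withr::with_seed(
    seed,
    dplyr::bind_rows(
      draw(estimates$delta_r, "delta_r"),
      draw(estimates$delta_bl, "delta_bl")
    )
  )
}

#' One-sided rank test: are adjacent copies more similar than random
#' pairs?
#'
#' Mann-Whitney (Wilcoxon rank-sum) test that the adjacent-pair
#' differences are stochastically smaller than the randomised control
#' differences. No multiple-testing correction is applied here (one
#' comparison per repeat per sample).
#'
#' @param adjacent Numeric vector of adjacent-pair absolute differences.
#' @param control Numeric vector of control absolute differences.
#' @return One-row tibble: `n_adjacent`, `n_control`, `statistic`,
#'   `p_value`, `all_tied`.
#' @export
compare_adjacent_vs_random <- function(adjacent, control) {
  if (length(adjacent) == 0L || length(control) == 0L) {
    abort("both `adjacent` and `control` must be non-empty.")
  }
  if (stats::var(c(adjacent, control)) == 0) {
    return(tibble(
      n_adjacent = length(adjacent), n_control = length(control),
      statistic = NA_real_, p_value = 1, all_tied = TRUE
    ))
  }
  wt <- suppressWarnings(
    wilcox.test(adjacent, control, alternative = "less", exact = FALSE)
  )
  tibble(
    n_adjacent = length(adjacent), n_control = length(control),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    all_tied = FALSE
  )
}
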