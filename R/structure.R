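# Per-read structure: segmentation into rDNA copies, large structural
# gap detection with satellite-region suppression, inversion detection
# and palindromic-artifact triage.

# Unwrapped unit coordinates for the mapped dominant-strand sections of a
# read. The first mapped section anchors the coordinate; each subsequent
# section advances by its expected displacement plus its (wrapped)
# deviation, so the coordinate is robust to structural jumps < L/2.
# Returns tibble(read_offset, length, ref_pos, u).
unwrapped_positions <- function(map, ref) {
  L <- ref$unit_length
  s <- map$splits[
    !is.na(map$splits$ref_pos) &
      map$splits$strand == map$dominant_strand, ,
    drop = FALSE
  ]
  if (nrow(s) == 0L) {
    return(tibble(
      read_offset = integer(0), length = integer(0),
      ref_pos = integer(0), u = numeric(0)
    ))
  }
  sign <- if (map$dominant_strand == "+") 1 else -1
  # v is the unit coordinate at the section's read_offset: the alignment
  # start for forward sections, the alignment end for reverse sections
  v <- if (sign > 0) s$ref_pos else s$ref_pos + s$length
  step <- sign * diff(s$read_offset) +
    wrap_to_half(diff(v) - sign * diff(s$read_offset), L)
  tibble(
    read_offset = s$read_offset, length = s$length, ref_pos = s$ref_pos,
    u = cumsum(c(v[1], step))
  )
}

#' Segment a read into rDNA copies
#'
#' Copy boundaries are placed where consecutive mapped sections straddle
#' the reference origin (the unit start) in the dominant direction; the
#' boundary read offset is interpolated linearly between the two flanking
#' sections. One segment is produced per interval between crossings;
#' leading/trailing partial segments are flagged incomplete. For complete
#' segments the coding (45S) and Butterfly/Long sub-intervals are also
#' interpolated into read space.
#'
#' @param map An `rdna_read_map` with dominant-strand fraction >= 0.9;
#'   inverted reads are rejected (run [detect_inversion()] first).
#' @param ref The `rdna_reference`.
#' @param min_dominant Minimum dominant-strand fraction (default 0.9).
#' @return Tibble with columns `read_id`, `copy_index`, `read_start`,
#'   `read_end`, `complete`, `strand`, `coding_read_start`,
#'   `coding_read_end`, `bl_read_start`, `bl_read_end` (read-space
#'   coordinates; `NA` for incomplete segments).
#' @export
segment_copies <- function(map, ref, min_dominant = 0.9) {
  if (!is.na(map$dominant_fraction) && map$dominant_fraction < min_dominant) {
    abort(sprintf(
      "read %s looks inverted (dominant fraction %.2f < %.2f); run inversion analysis first.",
      map$read_id, map$dominant_fraction, min_dominant
    ))
  }
  L <- ref$unit_length
  up <- unwrapped_positions(map, ref)
  empty <- tibble(
    read_id = character(0), copy_index = integer(0),
    read_start = numeric(0), read_end = numeric(0), complete = logical(0),
    strand = character(0), coding_read_start = numeric(0),
    coding_read_end = numeric(0), bl_read_start = numeric(0),
    bl_read_end = numeric(0)
  )
  if (nrow(up) < 2L) {
    return(empty)
  }

  # extrapolate the unwrapped coordinate to both read edges, so a read
  # that starts or ends exactly at the unit origin owns that boundary
  sgn <- if (map$dominant_strand == "+") 1 else -1
  n_up <- nrow(up)
  u0 <- up$u[1] - sgn * up$read_offset[1]
  uend <- up$u[n_up] + sgn * (map$read_length - up$read_offset[n_up])
  ux <- c(u0, up$u, uend)
  ox <- c(0, up$read_offset, map$read_length)

  # read offset at a given unwrapped coordinate, by linear interpolation
  # along the section map (u is monotone up to small jitter)
  ord <- order(ux)
  ux <- ux[ord]
  ox <- ox[ord]
  keep <- !duplicated(ux)
  offset_at_u <- function(u) {
    approx(ux[keep], ox[keep], xout = u, rule = 2)$y
  }

  # origin crossings: unwrapped multiples of L inside the read span,
  # with a small tolerance so boundaries at the read edges are kept
  eps <- 25
  lo <- min(u0, uend)
  hi <- max(u0, uend)
  ks <- seq.int(ceiling((lo - eps) / L), floor((hi + eps) / L))
  ks <- ks[ks * L >= lo - eps & ks * L <= hi + eps]
  if (length(ks) == 0L) {
    return(empty)
  }
  b_off <- pmin(pmax(offset_at_u(ks * L), 0), map$read_length)
  if (map$dominant_strand == "-") {
    ks <- rev(ks)
    b_off <- rev(b_off)
  }

  starts <- c(0, b_off)
  ends <- c(b_off, map$read_length)
  complete <- c(FALSE, rep(TRUE, length(b_off) - 1L), FALSE)
  # unit multiple owned by each complete segment (forward: [kL,(k+1)L);
  # reverse: ((k-1)L, kL] descending)
  seg_k <- if (map$dominant_strand == "+") {
    c(NA, ks[-length(ks)], NA)
  } else {
    c(NA, ks[-length(ks)] - 1L, NA)
  }

  sub_iv <- function(iv, k) {
    if (is.na(k)) {
      return(c(NA_real_, NA_real_))
    }
    u <- k * L + iv
    sort(offset_at_u(u))
  }
  coding <- t(vapply(seg_k, sub_iv, numeric(2), iv = ref$coding_interval))
  bl <- t(vapply(seg_k, sub_iv, numeric(2),
    iv = ref$butterfly_long_interval
  ))

  out <- tibble(
    read_id = map$read_id,
    copy_index = seq_along(starts),
    read_start = starts,
    read_end = ends,
    complete = complete,
    strand = map$dominant_strand,
    coding_read_start = coding[, 1],
    coding_read_end = coding[, 2],
    bl_read_start = bl[, 1],
    bl_read_end = bl[, 2]
  )
  out <- out[out$read_end - out$read_start >= 1, , drop = FALSE]
  out$copy_index <- seq_len(nrow(out))
  out
}

#' Detect large structural gaps in a read map
#'
#' Consecutive mapped same-strand section pairs whose circular deviation
#' from the expected displacement strictly exceeds `threshold` are emitted
#' as gap events. Events whose flanking sections both lie inside the
#' R-repeat interval or both inside the Butterfly/Long interval are marked
#' `suppressed` (natural satellite-length variation) and are excluded from
#' noncanonical counting downstream. Positive deviation means reference
#' sequence missing from the read (deletion); negative means extra read
#' sequence (duplication/insertion).
#'
#' Single-section excursions that immediately revert (the next pair
#' cancels the deviation within `blip_tolerance`) are mapping
#' ambiguities in repeated sequence, not structure, and are dropped when
#' `drop_blips` is `TRUE`.
#'
#' @param map An `rdna_read_map`.
#' @param ref The `rdna_reference`.
#' @param threshold Structural threshold in bases (default 500, strict
#'   inequality).
#' @param drop_blips Drop immediately-reverting single-section excursions.
#' @param blip_tolerance Net deviation under which an excursion pair is
#'   considered reverted (default 100 bases).
#' @return Tibble of gap events: `read_id`, `offset_a`, `offset_b`,
#'   `ref_a`, `ref_b`, `strand`, `deviation`, `class`
#'   (`"deletion"`/`"duplication"`), `suppressed`.
#' @export
detect_structural_gaps <- function(map, ref, threshold = 500,
                                   drop_blips = TRUE,
                                   blip_tolerance = 100) {
  pd <- pair_deviations(map, ref)
  pd$read_id <- rep(map$read_id, nrow(pd))
  ev <- abs(pd$deviation) > threshold
  if (drop_blips && any(ev)) {
    i <- which(ev)
    revert <- rep(FALSE, nrow(pd))
    for (j in i) {
      if (j < nrow(pd) &&
        pd$offset_a[j + 1L] == pd$offset_b[j] &&
        abs(pd$deviation[j] + pd$deviation[j + 1L]) <= blip_tolerance &&
        abs(pd$deviation[j + 1L]) > threshold) {
        revert[j] <- TRUE
        revert[j + 1L] <- TRUE
      }
    }
    ev <- ev & !revert
  }
  out <- pd[ev, , drop = FALSE]
  if (nrow(out) == 0L) {
    return(tibble(
      read_id = character(0), offset_a = integer(0), offset_b = integer(0),
      ref_a = integer(0), ref_b = integer(0), strand = character(0),
      deviation = numeric(0), class = character(0), suppressed = logical(0)
    ))
  }
  len <- map$split_length
  L <- ref$unit_length
  # a flanking section lies "within" a satellite region when its
  # alignment span overlaps the region
  olap <- function(pos, iv) {
    (iv[2] - iv[1]) > 0 & pos < iv[2] & (pos + len) > iv[1]
  }
  both_in <- function(iv) olap(out$ref_a, iv) & olap(out$ref_b, iv)
  # additionally, an event whose implied reference span (the skipped
  # stretch for deletions, the re-traversed stretch for duplications)
  # falls inside a satellite region expanded by one section is satellite
  # length variation, wherever the aligner realised the jump
  ev_start <- ifelse(out$deviation > 0,
    (out$ref_a + len) %% L, out$ref_b %% L
  )
  ev_width <- abs(out$deviation)
  span_in <- function(iv) {
    if (iv[2] - iv[1] <= 0) {
      return(rep(FALSE, nrow(out)))
    }
    lo <- iv[1] - len
    hi <- iv[2] + len
    (ev_start >= lo & ev_start + ev_width <= hi) |
      (ev_start - L >= lo & ev_start - L + ev_width <= hi)
  }
  suppressed <- both_in(ref$r_repeat_interval) |
    both_in(ref$butterfly_long_interval) |
    span_in(ref$r_repeat_interval) |
    span_in(ref$butterfly_long_interval)
  tibble(
    read_id = out$read_id,
    offset_a = out$offset_a, offset_b = out$offset_b,
    ref_a = out$ref_a, ref_b = out$ref_b, strand = out$strand,
    deviation = out$deviation,
    class = ifelse(out$deviation > 0, "deletion", "duplication"),
    suppressed = suppressed
  )
}

#' Detect an inversion (palindromic read)
#'
#' A read is labelled inverted iff the mapped sections on the non-dominant
#' strand strictly exceed `min_opposite_fraction` of all mapped sections.
#' For inverted reads the inversion point is located with
#' [locate_inversion_point()].
#'
#' @param map An `rdna_read_map`.
#' @param min_opposite_fraction Strict threshold (default 0.10).
#' @return `NULL` when not inverted, otherwise a one-row tibble:
#'   `read_id`, `read_length`, `opposite_fraction`, `n_transitions`,
#'   `complex`, `inversion_offset`, `relative_position`, `breakpoint_ref`,
#'   `orientation`.
#' @export
detect_inversion <- function(map, min_opposite_fraction = 0.10) {
  s <- map$splits[!is.na(map$splits$ref_pos), , drop = FALSE]
  if (nrow(s) == 0L) {
    return(NULL)
  }
  n_opp <- sum(s$strand != map$dominant_strand)
  frac <- n_opp / nrow(s)
  if (!(frac > min_opposite_fraction)) {
    return(NULL)
  }
  pt <- locate_inversion_point(map)
  tibble(
    read_id = map$read_id,
    read_length = map$read_length,
    opposite_fraction = frac,
    n_transitions = pt$n_transitions,
    complex = pt$n_transitions > 1L,
    inversion_offset = pt$inversion_offset,
    relative_position = pt$relative_position,
    breakpoint_ref = pt$breakpoint_ref,
    orientation = pt$orientation
  )
}

#' Locate the strand-switch point of an inverted read
#'
#' For a read with a single strand transition among its mapped sections,
#' the inversion offset is the midpoint between the end of the last
#' section of the first strand run and the start of the first section of
#' the second run. Reads with more than one transition are flagged complex
#' and carry no single point.
#'
#' @param map An `rdna_read_map`.
#' @return A list: `inversion_offset`, `relative_position`
#'   (`offset / read_length`), `n_transitions`, `breakpoint_ref`
#'   (unit-space coordinate of the switch, from the flanking sections) and
#'   `orientation` (e.g. `"+-"`).
#' @export
locate_inversion_point <- function(map) {
  s <- map$splits[!is.na(map$splits$ref_pos), , drop = FALSE]
  r <- rle(s$strand)
  n_trans <- length(r$lengths) - 1L
  if (n_trans < 1L) {
    abort(sprintf(
      "read %s has no strand transition; not an inverted read.",
      map$read_id
    ))
  }
  if (n_trans > 1L) {
    return(list(
      inversion_offset = NA_real_, relative_position = NA_real_,
      n_transitions = n_trans, breakpoint_ref = NA_real_,
      orientation = paste(r$values, collapse = "")
    ))
  }
  i_last <- r$lengths[1L]
  a <- s[i_last, ]
  b <- s[i_last + 1L, ]
  off <- ((a$read_offset + a$length) + b$read_offset) / 2
  # for a strand reflection both flanks extrapolate to the same unit
  # coordinate at the junction; solving for that read offset refines the
  # midpoint estimate to indel-level precision (split alignments only)
  if (!is.null(map$ref_unit_length) && !is.na(map$ref_unit_length)) {
    L <- map$ref_unit_length
    dp <- wrap_to_half(b$ref_pos - a$ref_pos, L)
    refined <- if (a$strand == "+") {
      (dp + a$read_offset + b$read_offset + b$length) / 2
    } else {
      (-dp + a$read_offset + a$length + b$read_offset) / 2
    }
    if (!is.na(refined) && refined >= a$read_offset &&
      refined <= b$read_offset + b$length) {
      off <- refined
    }
  }
  bp <- if (a$strand == "+") a$ref_pos + a$length else a$ref_pos
  list(
    inversion_offset = off,
    relative_position = off / map$read_length,
    n_transitions = 1L,
    breakpoint_ref = as.numeric(bp),
    orientation = paste0(a$strand, b$strand)
  )
}

#' Detect a quality-score drop after an inversion point
#'
#' Per-base Phred scores are binned; the flag is `TRUE` iff within
#' `window` bases after the inversion point there are at least `span`
#' consecutive bins whose mean falls at least `drop` Phred units below the
#' mean of the `span` bins preceding the inversion point. Returns `NA`
#' (undetermined) when the inversion lies within `window` of the read end
#' or too few bins precede it.
#'
#' @param qualities Integer/numeric vector of per-base Phred scores.
#' @param inversion_offset Read offset of the inversion point (0-based).
#' @param bin Bin width in bases (default 200).
#' @param drop Minimum drop in Phred units (default 5).
#' @param span Bins the drop must be sustained for, and bins used for the
#'   pre-inversion baseline (default 3).
#' @param window Search window after the inversion point in bases
#'   (default 2000).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
detect_quality_drop <- function(qualities, inversion_offset, bin = 200L,
                                drop = 5, span = 3L, window = 2000L) {
  n <- length(qualities)
  if (is.na(inversion_offset) || inversion_offset + window > n) {
    return(NA)
  }
  bins <- floor((seq_len(n) - 1L) / bin)
  means <- tapply(qualities, bins, mean)
  ib <- floor(inversion_offset / bin)
  before_idx <- (ib - span):(ib - 1L)
  if (any(before_idx < 0L)) {
    return(NA)
  }
  before <- mean(means[as.character(before_idx)])
  after_idx <- (ib + 1L):(ib + ceiling(window / bin))
  after <- means[as.character(after_idx)]
  after <- after[!is.na(after)]
  if (length(after) < span) {
    return(NA)
  }
  low <- as.vector(after <= before - drop)
  r <- rle(low)
  any(r$values & r$lengths >= span)
}

#' Classify a palindromic read
#'
#' Template-switch artifacts have their inversion point at or after the
#' read centre; an inversion point in the first half without a quality
#' drop is a candidate real palindrome; one in the first half with a
#' quality drop is dubious.
#'
#' @param relative_position Relative inversion position(s) in `[0, 1]`.
#' @param quality_drop Logical flag(s) from [detect_quality_drop()];
#'   `NA` is treated as no observed drop.
#' @return Character vector: `"artifact_consistent"`, `"candidate_real"`
#'   or `"dubious"`.
#' @export
classify_palindrome <- function(relative_position, quality_drop = NA) {
  quality_drop <- rep_len(quality_drop, length(relative_position))
  ifelse(relative_position >= 0.5, "artifact_consistent",
    ifelse(!is.na(quality_drop) & quality_drop, "dubious", "candidate_real")
  )
}

#' Cluster inversion breakpoints across a sample
#'
#' Single-linkage clustering of unit-space breakpoints within `tolerance`
#' bases (circular) and matching flank orientation. Groups of size >= 2
#' are recurrent -- independent reads showing the same inversion pattern
#' support a real palindrome rather than a per-read artifact.
#'
#' @param calls Tibble of inversion calls (from [detect_inversion()]),
#'   with columns `read_id`, `breakpoint_ref`, `orientation`.
#' @param ref The `rdna_reference`.
#' @param tolerance Breakpoint clustering tolerance in bases (default
#'   500).
#' @return `calls` with added columns `group`, `group_size`, `recurrent`.
#' @export
cluster_inversion_breakpoints <- function(calls, ref, tolerance = 500) {
  if (nrow(calls) == 0L) {
    return(dplyr::mutate(calls,
      group = integer(0), group_size = integer(0), recurrent = logical(0)
    ))
  }
  L <- ref$unit_length
  calls$group <- NA_integer_
  g <- 0L
  for (orient in unique(calls$orientation)) {
    idx <- which(calls$orientation == orient & !is.na(calls$breakpoint_ref))
    if (length(idx) == 0L) next
    ord <- idx[order(calls$breakpoint_ref[idx])]
    bp <- calls$breakpoint_ref[ord]
    new_cluster <- c(TRUE, diff(bp) > tolerance)
    cl <- cumsum(new_cluster)
    # circular wrap: merge the first and last cluster when their extreme
    # breakpoints are within tolerance around the origin
    if (max(cl) > 1L && (bp[1] + L - bp[length(bp)]) <= tolerance) {
      cl[cl == max(cl)] <- 1L
    }
    calls$group[ord] <- g + cl
    g <- g + max(cl)
  }
  sizes <- table(calls$group)
  calls$group_size <- as.integer(sizes[as.character(calls$group)])
  calls$recurrent <- !is.na(calls$group_size) & calls$group_size >= 2L
  calls
}

#' Summarise noncanonical structure over a sample
#'
#' @param gap_events Tibble of gap events across all reads (rows of
#'   [detect_structural_gaps()] output).
#' @param n_copies Total rDNA copies counted in the sample.
#' @param n_reads Total reads analysed.
#' @param inversion_calls Optional tibble of classified inversion calls
#'   (with a `classification` column).
#' @return One-row tibble of counts and rates; rates are `NA` when
#'   `n_copies` is zero.
#' @export
summarize_noncanonical <- function(gap_events, n_copies, n_reads,
                                   inversion_calls = NULL) {
  if (nrow(gap_events) > 0L && "suppressed" %in% names(gap_events)) {
    unsup <- gap_events[!gap_events$suppressed, , drop = FALSE]
    n_events <- nrow(unsup)
    n_reads_ev <- length(unique(unsup$read_id))
  } else {
    n_events <- 0L
    n_reads_ev <- 0L
  }
  n_cand <- if (!is.null(inversion_calls) && nrow(inversion_calls) > 0L) {
    sum(inversion_calls$classification == "candidate_real", na.rm = TRUE)
  } else {
    0L
  }
  rate <- function(x) if (n_copies > 0L) x / n_copies else NA_real_
  tibble(
    n_reads = n_reads,
    n_copies = n_copies,
    n_noncanonical_events = n_events,
    n_reads_with_events = n_reads_ev,
    noncanonical_rate_per_copy = rate(n_events),
    noncanonical_rate_per_read = if (n_reads > 0L) {
      n_reads_ev / n_reads
    } else {
      NA_real_
    },
    n_palindromic = if (is.null(inversion_calls)) 0L else nrow(inversion_calls),
    n_candidate_real = n_cand,
    candidate_real_rate_per_copy = rate(n_cand)
  )
}
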