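# Read screening: select reads that represent genuine rDNA array
# fragments, in whole-genome (WGS) mode and Cas9-enrichment mode.

#' Screen one whole-genome read for rDNA array content
#'
#' A read passes when (a) it passed platform quality filtering (if a QC
#' record is supplied), (b) it carries a continuous run of mapped sections
#' spanning at least `min_rdna` bases reaching one read end or the other,
#' and (c) at least `min_coding_fraction` of its sections map to the
#' coding (45S) region -- the guard against microsatellite decoy reads.
#' "Continuous" tolerates isolated mapping dropouts: a run may contain up
#' to `max_internal_unmapped` consecutive unmapped sections.
#'
#' @param map An `rdna_read_map`.
#' @param ref The `rdna_reference`.
#' @param qc Optional one-row QC record (from
#'   [read_sequencing_summary()]) with column `passes_filtering`; when
#'   `NULL` the QC rule is skipped with a note.
#' @param min_rdna Minimum continuous rDNA span in bases (default 40000).
#' @param min_coding_fraction Minimum fraction of sections mapping to the
#'   coding region (default 0.10, inclusive).
#' @param max_internal_unmapped Mapping dropouts tolerated inside a run.
#' @param end_slack Sections of slack allowed between a qualifying run and
#'   the read terminus it anchors to.
#' @return One-row tibble: `read_id`, `pass`, `reasons` (list column of
#'   failed rule identifiers; empty iff `pass`).
#' @export
screen_wgs_read <- function(map, ref, qc = NULL, min_rdna = 40000,
                            min_coding_fraction = 0.10,
                            max_internal_unmapped = 2L, end_slack = 2L) {
  reasons <- character(0)

  if (!is.null(qc)) {
    ok <- isTRUE(as.logical(qc$passes_filtering[1]))
    if (!ok) reasons <- c(reasons, "qc_filter")
  } else {
    inform(sprintf(
      "read %s: no sequencing-summary record; QC rule skipped.",
      map$read_id
    ))
  }

  runs <- mapped_runs(map, max_internal_unmapped)
  span_ok <- FALSE
  if (nrow(runs) > 0L) {
    slack <- end_slack * map$split_length
    at_end <- runs$start_offset <= slack |
      runs$end_offset >= map$read_length - slack
    span_ok <- any(at_end & runs$span >= min_rdna)
  }
  if (!span_ok) {
    reasons <- c(
      reasons,
      if (max(c(0, runs$span)) < min_rdna) "min_length" else "continuity"
    )
  }

  s <- map$splits
  mid <- ifelse(is.na(s$ref_pos), NA_real_,
    (s$ref_pos + s$length / 2) %% ref$unit_length
  )
  in_coding <- !is.na(mid) & mid >= ref$coding_interval[1] &
    mid < ref$coding_interval[2]
  if (nrow(s) == 0L || sum(in_coding) / nrow(s) < min_coding_fraction) {
    reasons <- c(reasons, "coding_fraction")
  }

  tibble(
    read_id = map$read_id, pass = length(reasons) == 0L,
    reasons = list(reasons)
  )
}

# Maximal runs of mapped sections tolerating short internal unmapped
# stretches. Returns tibble(start_offset, end_offset, span).
mapped_runs <- function(map, max_internal_unmapped = 2L) {
  s <- map$splits
  mapped <- !is.na(s$ref_pos)
  if (!any(mapped)) {
    return(tibble(
      start_offset = integer(0), end_offset = integer(0),
      span = integer(0)
    ))
  }
  idx <- which(mapped)
  brk <- c(TRUE, diff(idx) > max_internal_unmapped + 1L)
  grp <- cumsum(brk)
  first <- tapply(idx, grp, min)
  last <- tapply(idx, grp, max)
  tibble(
    start_offset = s$read_offset[first],
    end_offset = s$read_offset[last] + s$length[last],
    span = s$read_offset[last] + s$length[last] - s$read_offset[first]
  )
}

#' Screen one Cas9-enrichment read
#'
#' Passes iff both read termini map within `end_tolerance` bases of a
#' configured Cas9 cut site (strand-aware: each terminus position is
#' extrapolated to unit space from the nearest mapped section).
#'
#' @param map An `rdna_read_map`.
#' @param ref The `rdna_reference`.
#' @param cut_sites Unit-space cut-site coordinates (see
#'   [locate_guide_sites()]).
#' @param end_tolerance Tolerance in bases (default 50).
#' @return One-row tibble as in [screen_wgs_read()].
#' @export
screen_cas9_read <- function(map, ref, cut_sites, end_tolerance = 50) {
  if (length(cut_sites) == 0L) abort("`cut_sites` must be non-empty.")
  reasons <- character(0)
  term <- terminus_positions(map, ref)
  if (anyNA(term)) {
    reasons <- "cas9_ends"
  } else {
    near <- vapply(term, function(p) {
      min(abs(wrap_to_half(cut_sites - p, ref$unit_length)))
    }, numeric(1))
    if (any(near > end_tolerance)) reasons <- "cas9_ends"
  }
  tibble(
    read_id = map$read_id, pass = length(reasons) == 0L,
    reasons = list(reasons)
  )
}

# Extrapolate both read termini into unit space from the first/last mapped
# section (strand-aware). Returns c(start_pos, end_pos) or NAs.
terminus_positions <- function(map, ref) {
  L <- ref$unit_length
  s <- map$splits[!is.na(map$splits$ref_pos), , drop = FALSE]
  if (nrow(s) == 0L) {
    return(c(NA_real_, NA_real_))
  }
  f <- s[1L, ]
  l <- s[nrow(s), ]
  start_pos <- if (f$strand == "+") {
    (f$ref_pos - f$read_offset) %% L
  } else {
    (f$ref_pos + f$length + f$read_offset) %% L
  }
  end_pos <- if (l$strand == "+") {
    (l$ref_pos + (map$read_length - l$read_offset)) %% L
  } else {
    (l$ref_pos - (map$read_length - l$read_offset - l$length)) %% L
  }
  c(start_pos, end_pos)
}

#' Locate guide-RNA target sites in the reference unit
#'
#' Exact matching of each guide sequence (and its reverse complement)
#' against the unit; the match start is used as the cut-site coordinate.
#'
#' @param ref An `rdna_reference`.
#' @param guides Character vector of guide target sequences.
#' @return Integer vector of unit-space cut-site positions (sorted,
#'   unique). Guides without an exact match are dropped with a warning.
#' @export
locate_guide_sites <- function(ref, guides) {
  subj <- Biostrings::DNAString(ref$unit_sequence)
  pos <- integer(0)
  miss <- character(0)
  for (g in guides) {
    hit <- Biostrings::matchPattern(Biostrings::DNAString(g), subj)
    hit_rc <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(g)), subj
    )
    p <- c(Biostrings::start(hit) - 1L, Biostrings::start(hit_rc) - 1L)
    if (length(p) == 0L) miss <- c(miss, g) else pos <- c(pos, p)
  }
  if (length(miss) > 0L) {
    warn(sprintf(
      "no exact match in reference for %d guide(s): %s",
      length(miss), paste(substr(miss, 1, 12), collapse = ", ")
    ))
  }
  sort(unique(pos))
}

#' Read a platform sequencing-summary TSV
#'
#' Only the `read_id` and `passes_filtering` columns are consumed.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `read_id` and `passes_filtering` (logical).
#' @export
read_sequencing_summary <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("read_id", "passes_filtering") %in% names(d))) {
    abort("sequencing summary must have columns read_id, passes_filtering.")
  }
  tibble(
    read_id = as.character(d$read_id),
    passes_filtering = as.logical(d$passes_filtering)
  )
}
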