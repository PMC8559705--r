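# Split-and-map: decompose a long read into fixed-length sections, map
# each section independently to the repeat-unit reference, and assemble
# the per-read alignment map (the dot-plot substrate all structural
# analysis runs on).

#' Split a read into fixed-length sections
#'
#' @param read A read: either a character scalar (the sequence) or a list
#'   with elements `read_id` and `sequence`.
#' @param split_length Section length in bases (default 300).
#' @param min_tail A terminal partial section is kept iff at least this
#'   long (default 150).
#' @return A tibble with columns `read_offset` (0-based start of the
#'   section in the read), `length` and `sequence`.
#' @export
split_read <- function(read, split_length = 300L, min_tail = 150L) {
  seq <- read_sequence(read)
  if (split_length <= 0L) abort("`split_length` must be positive.")
  n <- nchar(seq)
  if (n < 1L) abort("read length must be >= 1.")
  offsets <- seq.int(0L, n - 1L, by = split_length)
  lens <- pmin(split_length, n - offsets)
  keep <- lens == split_length | lens >= min_tail
  offsets <- offsets[keep]
  lens <- lens[keep]
  if (length(offsets) == 0L) {
    return(tibble(
      read_offset = integer(0), length = integer(0), sequence = character(0)
    ))
  }
  tibble(
    read_offset = as.integer(offsets),
    length = as.integer(lens),
    sequence = substring(seq, offsets + 1L, offsets + lens)
  )
}

read_sequence <- function(read) {
  if (is.character(read) && length(read) == 1L) {
    return(read)
  }
  if (is.list(read) && !is.null(read$sequence)) {
    return(read$sequence)
  }
  abort("`read` must be a sequence string or a list with $sequence.")
}

read_id_of <- function(read, default = "read") {
  if (is.list(read) && !is.null(read$read_id)) {
    return(as.character(read$read_id))
  }
  default
}

#' Map the sections of one read against the unit reference
#'
#' Each section is aligned independently; only the primary (best-scoring)
#' hit is kept, ties broken towards the forward strand then the lowest
#' reference position. A section with no hit is recorded as unmapped.
#'
#' @param read A read (character sequence or list with `read_id`,
#'   `sequence`).
#' @param ref An [reference_model()] object.
#' @param aligner Alignment backend (default [aligner_builtin()]).
#' @param split_length,min_tail Passed to [split_read()].
#' @return An object of class `rdna_read_map`: a list with `read_id`,
#'   `read_length`, `split_length`, `splits` (tibble: `read_offset`,
#'   `length`, `ref_pos`, `strand`, `score`; `NA` when unmapped),
#'   `unmapped_count`, `dominant_strand` and `dominant_fraction`.
#' @export
map_splits <- function(read, ref, aligner = aligner_builtin(),
                       split_length = 300L, min_tail = 150L) {
  stopifnot(inherits(ref, "rdna_reference"))
  rid <- read_id_of(read)
  seq <- read_sequence(read)
  sections <- split_read(seq, split_length, min_tail)
  queries <- setNames(sections$sequence, as.character(sections$read_offset))
  hits <- tryCatch(
    align_query(aligner, queries, ref$unit_sequence, circular = TRUE),
    error = function(e) {
      abort(sprintf("aligner backend failed for read '%s': %s", rid,
        conditionMessage(e)))
    }
  )
  m <- match(as.character(sections$read_offset), hits$query)
  splits <- tibble(
    read_offset = sections$read_offset,
    length = sections$length,
    ref_pos = as.integer(hits$ref_pos[m]),
    strand = as.character(hits$strand[m]),
    score = as.numeric(hits$score[m])
  )
  new_read_map(rid, nchar(seq), split_length, splits,
    ref_unit_length = ref$unit_length
  )
}

new_read_map <- function(read_id, read_length, split_length, splits,
                         ref_unit_length = NA_integer_) {
  mapped <- !is.na(splits$ref_pos)
  n_fwd <- sum(splits$strand[mapped] == "+")
  n_rev <- sum(mapped) - n_fwd
  dominant <- if (n_fwd >= n_rev) "+" else "-"
  structure(
    list(
      read_id = read_id,
      read_length = as.integer(read_length),
      split_length = as.integer(split_length),
      ref_unit_length = as.integer(ref_unit_length),
      splits = splits,
      unmapped_count = sum(!mapped),
      dominant_strand = dominant,
      dominant_fraction = if (any(mapped)) {
        max(n_fwd, n_rev) / sum(mapped)
      } else {
        NA_real_
      }
    ),
    class = "rdna_read_map"
  )
}

#' @export
print.rdna_read_map <- function(x, ...) {
  cat(sprintf(
    "<rdna_read_map> %s: %d bases, %d sections (%d unmapped), dominant %s (%.2f)\n",
    x$read_id, x$read_length, nrow(x$splits), x$unmapped_count,
    x$dominant_strand, x$dominant_fraction
  ))
  invisible(x)
}

#' Tidy the per-section alignments of a read map
#'
#' @param x An `rdna_read_map`.
#' @param ... Unused.
#' @return The `splits` tibble with a `read_id` column prepended.
#' @method tidy rdna_read_map
#' @export
tidy.rdna_read_map <- function(x, ...) {
  dplyr::bind_cols(tibble(read_id = x$read_id), x$splits)
}

# Deviations between consecutive mapped same-strand sections.
#
# For each consecutive pair of mapped sections on the same strand, the
# expected reference displacement is the read-offset difference signed by
# strand; the deviation is the circular difference between observed and
# expected displacement, wrapped into (-L/2, L/2].
pair_deviations <- function(map, ref) {
  L <- ref$unit_length
  s <- map$splits[!is.na(map$splits$ref_pos), , drop = FALSE]
  if (nrow(s) < 2L) {
    return(tibble(
      offset_a = integer(0), offset_b = integer(0),
      len_a = integer(0), ref_a = integer(0), ref_b = integer(0),
      strand = character(0), expected = numeric(0), deviation = numeric(0)
    ))
  }
  a <- s[-nrow(s), ]
  b <- s[-1L, ]
  same <- a$strand == b$strand
  sign <- ifelse(a$strand == "+", 1, -1)
  expected <- sign * (b$read_offset - a$read_offset)
  deviation <- wrap_to_half(b$ref_pos - a$ref_pos - expected, L)
  tibble(
    offset_a = a$read_offset, offset_b = b$read_offset,
    len_a = a$length, ref_a = a$ref_pos, ref_b = b$ref_pos,
    strand = a$strand, expected = expected, deviation = deviation
  )[same, , drop = FALSE]
}

#' Count reference gaps in a read map
#'
#' For each consecutive pair of mapped same-strand sections, the expected
#' reference displacement equals the read-offset difference (signed by
#' strand, circular in unit space). A pair whose absolute deviation from
#' that expectation strictly exceeds `tolerance` counts as one gap. Used
#' to rank candidate repeat-unit references (fewest gaps wins).
#'
#' @param map An `rdna_read_map`.
#' @param ref The `rdna_reference` the map was built against.
#' @param tolerance Deviation tolerance in bases (default 100; the gap
#'   boundary is exclusive, i.e. a deviation of exactly 100 is no gap).
#' @return Integer gap count.
#' @export
count_reference_gaps <- function(map, ref, tolerance = 100) {
  pd <- pair_deviations(map, ref)
  sum(abs(pd$deviation) > tolerance)
}
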