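# Reference model: one rDNA repeat unit plus landmark annotation.
#
# All coordinates in this package are 0-based, half-open, in "unit space"
# (positions within the repeat unit). Tandem arrays wrap at the unit
# boundary, so displacement arithmetic is circular (see circular_delta()).

#' Construct a repeat-unit reference model
#'
#' A reference model bundles the single repeat-unit sequence with its
#' landmark annotation: the coding (45S rDNA) interval, the R-repeat
#' interval and the Butterfly/Long-repeat interval of the intergenic
#' spacer (IGS), plus the anchor coordinates used for repeat-length
#' genotyping. All intervals are 0-based half-open in unit space.
#'
#' @param unit_sequence Single nucleotide string (the repeat unit).
#' @param coding_interval Integer vector `c(start, end)` of the 45S rDNA.
#' @param r_repeat_interval Integer vector `c(start, end)` of the R repeat
#'   block. A zero-width interval (`start == end`) marks "no R repeat".
#' @param butterfly_long_interval Integer vector `c(start, end)` of the
#'   Butterfly/Long repeat block; zero-width allowed.
#' @param anchor_positions Unit-space start positions of the repeat-length
#'   anchors (default 10000, 20000, 30000).
#' @param anchor_length Anchor section length in bases (default 500).
#' @param name Reference name.
#' @param sim Optional simulator bookkeeping (see
#'   [make_synthetic_reference()]); `NULL` for real references.
#'
#' @return An object of class `rdna_reference`.
#' @export
reference_model <- function(unit_sequence,
                            coding_interval,
                            r_repeat_interval,
                            butterfly_long_interval,
                            anchor_positions = c(10000L, 20000L, 30000L),
                            anchor_length = 500L,
                            name = "rdna_unit",
                            sim = NULL) {
  unit_sequence <- toupper(as.character(unit_sequence))
  if (length(unit_sequence) != 1L || nchar(unit_sequence) < 1L) {
    abort("`unit_sequence` must be a single non-empty nucleotide string.")
  }
  L <- nchar(unit_sequence)

  check_interval <- function(iv, what, allow_empty = FALSE) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || anyNA(iv)) {
      abort(sprintf("Interval '%s' must be c(start, end).", what))
    }
    lo_ok <- if (allow_empty) iv[1] <= iv[2] else iv[1] < iv[2]
    if (!(iv[1] >= 0L && lo_ok && iv[2] <= L)) {
      abort(sprintf(
        "Interval '%s' [%d,%d) does not fit in the %d-base unit.",
        what, iv[1], iv[2], L
      ))
    }
    iv
  }
  coding_interval <- check_interval(coding_interval, "coding")
  r_repeat_interval <- check_interval(r_repeat_interval, "r_repeat",
    allow_empty = TRUE
  )
  butterfly_long_interval <- check_interval(butterfly_long_interval,
    "butterfly_long",
    allow_empty = TRUE
  )

  overlaps <- function(a, b) {
    (a[2] - a[1]) > 0 && (b[2] - b[1]) > 0 && a[1] < b[2] && b[1] < a[2]
  }
  ivs <- list(
    coding = coding_interval,
    r_repeat = r_repeat_interval,
    butterfly_long = butterfly_long_interval
  )
  for (i in 1:2) {
    for (j in (i + 1):3) {
      if (overlaps(ivs[[i]], ivs[[j]])) {
        abort(sprintf(
          "Intervals '%s' and '%s' overlap.",
          names(ivs)[i], names(ivs)[j]
        ))
      }
    }
  }

  anchor_positions <- as.integer(anchor_positions)
  anchor_length <- as.integer(anchor_length)
  if (anchor_length < 1L) abort("`anchor_length` must be positive.")
  bad <- anchor_positions < 0L | (anchor_positions + anchor_length) > L
  if (any(bad)) {
    abort(sprintf(
      "Anchor(s) at %s with length %d exceed the %d-base unit.",
      paste(anchor_positions[bad], collapse = ", "), anchor_length, L
    ))
  }

  structure(
    list(
      unit_sequence = unit_sequence,
      unit_length = L,
      coding_interval = coding_interval,
      r_repeat_interval = r_repeat_interval,
      butterfly_long_interval = butterfly_long_interval,
      anchor_positions = anchor_positions,
      anchor_length = anchor_length,
      name = as.character(name),
      sim = sim
    ),
    class = "rdna_reference"
  )
}

#' @export
print.rdna_reference <- function(x, ...) {
  cat(sprintf("<rdna_reference> %s (%d bases)\n", x$name, x$unit_length))
  cat(sprintf(
    "  coding (45S):    [%d, %d)\n", x$coding_interval[1],
    x$coding_interval[2]
  ))
  cat(sprintf(
    "  R repeat:        [%d, %d)\n", x$r_repeat_interval[1],
    x$r_repeat_interval[2]
  ))
  cat(sprintf(
    "  Butterfly/Long:  [%d, %d)\n", x$butterfly_long_interval[1],
    x$butterfly_long_interval[2]
  ))
  cat(sprintf(
    "  anchors: %s (+%d)\n",
    paste(x$anchor_positions, collapse = ", "), x$anchor_length
  ))
  invisible(x)
}

#' Load a repeat-unit reference from FASTA and BED
#'
#' The FASTA must contain exactly one record (the repeat unit). The BED
#' must contain the three named landmark intervals `coding`, `r_repeat`
#' and `butterfly_long`, each exactly once. BED records are converted to
#' 0-based half-open unit-space intervals.
#'
#' @param fasta_path Path to a single-record FASTA.
#' @param bed_path Path to the landmark BED (3+1 columns).
#' @inheritParams reference_model
#' @return An `rdna_reference`.
#' @export
load_reference <- function(fasta_path, bed_path,
                           anchor_positions = c(10000L, 20000L, 30000L),
                           anchor_length = 500L,
                           name = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    abort(sprintf(
      "Reference FASTA must contain exactly one record, found %d.",
      length(seqs)
    ))
  }
  bed <- rtracklayer::import(bed_path, format = "BED")
  nm <- bed$name
  need <- c("coding", "r_repeat", "butterfly_long")
  for (w in need) {
    if (sum(nm == w) != 1L) {
      abort(sprintf(
        "Landmark BED must name interval '%s' exactly once (found %d).",
        w, sum(nm == w)
      ))
    }
  }
  iv <- function(w) {
    i <- which(nm == w)
    c(GenomicRanges::start(bed)[i] - 1L, GenomicRanges::end(bed)[i])
  }
  reference_model(
    unit_sequence = as.character(seqs[[1]]),
    coding_interval = iv("coding"),
    r_repeat_interval = iv("r_repeat"),
    butterfly_long_interval = iv("butterfly_long"),
    anchor_positions = anchor_positions,
    anchor_length = anchor_length,
    name = name %||% names(seqs)[1]
  )
}

#' Write a reference model to FASTA and BED
#'
#' Inverse of [load_reference()]; used mainly to serialise synthetic
#' references.
#'
#' @param ref An `rdna_reference`.
#' @param fasta_path,bed_path Output paths.
#' @return Invisibly, `ref`.
#' @export
write_reference <- function(ref, fasta_path, bed_path) {
  stopifnot(inherits(ref, "rdna_reference"))
  seq <- Biostrings::DNAStringSet(ref$unit_sequence)
  names(seq) <- ref$name
  Biostrings::writeXStringSet(seq, fasta_path)
  ivs <- rbind(
    c(ref$coding_interval, NA),
    c(ref$r_repeat_interval, NA),
    c(ref$butterfly_long_interval, NA)
  )
  # hand-assembled BED3+1 line layout, written through write.table
  bed <- data.frame(
    chrom = ref$name,
    start = as.integer(ivs[, 1]),
    end = as.integer(ivs[, 2]),
    name = c("coding", "r_repeat", "butterfly_long")
  )
  write.table(bed, bed_path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(ref)
}

#' Signed circular displacement between two unit-space positions
#'
#' Returns the signed displacement from `a` to `b` with the minimal
#' absolute value among `(b - a) mod L` and that minus `L`. The tie at
#' exactly `L/2` resolves to `+L/2`. Needed because positions wrap at the
#' unit boundary in a tandem array.
#'
#' @param a,b Unit-space positions in `[0, unit_length)`. Vectorised.
#' @param unit_length Unit length in bases (positive).
#' @return Signed displacement(s) in bases, in `(-L/2, L/2]`.
#' @export
#' @examples
#' circular_delta(100, 400, 1000) # +300
#' circular_delta(900, 100, 1000) # +200 (wraps)
#' circular_delta(0, 500, 1000) # +500 (tie resolves positive)
circular_delta <- function(a, b, unit_length) {
  if (length(unit_length) != 1L || !is.finite(unit_length) ||
    unit_length <= 0) {
    abort("`unit_length` must be a single positive number.")
  }
  if (any(a < 0 | a >= unit_length | b < 0 | b >= unit_length,
    na.rm = TRUE
  )) {
    abort("positions must lie in [0, unit_length).")
  }
  wrap_to_half(b - a, unit_length)
}

# Wrap any displacement into (-L/2, L/2]; vectorised, no domain check.
wrap_to_half <- function(x, L) {
  r <- x %% L
  ifelse(r > L / 2, r - L, r)
}
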