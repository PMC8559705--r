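# Pipeline orchestration: screen -> split-map -> structure -> repeats ->
# methylation -> per-sample summary. analyze_sample() is the in-memory
# core; run_pipeline() is the file-based wrapper driven by a YAML config.

#' Analyse one sample of reads end to end
#'
#' Runs the full analysis for a set of reads: split-and-map, screening
#' (WGS or Cas9 mode), inversion detection and palindrome triage,
#' copy segmentation, structural-gap detection, repeat genotyping and --
#' when methylation calls are supplied -- per-copy methylation status and
#' the derived sample statistics.
#'
#' @param reads Named list of reads (`read_id`, `sequence`, `qualities`).
#' @param ref An `rdna_reference`.
#' @param calls Optional methylation-call tibble (`read_id`, `position`,
#'   `posterior`).
#' @param mode `"wgs"` or `"cas9"`.
#' @param qc Optional sequencing-summary tibble
#'   ([read_sequencing_summary()]).
#' @param cut_sites Cas9 cut sites (cas9 mode).
#' @param aligner Alignment backend.
#' @param split_length,min_tail Split parameters.
#' @param min_rdna,min_coding_fraction WGS screen thresholds.
#' @param structural_threshold Gap threshold in bases.
#' @param min_opposite_fraction Inversion threshold.
#' @param methyl_border 45S methylation classification border.
#' @param genome_size,total_bases Copy-number inputs; `total_bases`
#'   defaults to the sample's own base count (only meaningful when
#'   background reads are included).
#' @param seed Seed for the randomised controls.
#' @return List: `summary` (one-row tibble), `screen`, `maps`,
#'   `inversions`, `segments`, `gap_events`, `estimates`, `statuses`,
#'   `igs_type`, `adjacency`, `switch`, `copy_number`.
#' @export
analyze_sample <- function(reads, ref, calls = NULL,
                           mode = c("wgs", "cas9"),
                           qc = NULL, cut_sites = NULL,
                           aligner = aligner_builtin(),
                           split_length = 300L, min_tail = 150L,
                           min_rdna = 40000, min_coding_fraction = 0.10,
                           structural_threshold = 500,
                           min_opposite_fraction = 0.10,
                           methyl_border = 0.1,
                           genome_size = 6.27e9,
                           total_bases = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  maps <- lapply(reads, map_splits, ref = ref, aligner = aligner,
    split_length = split_length, min_tail = min_tail
  )

  screen <- dplyr::bind_rows(lapply(maps, function(m) {
    qrow <- if (!is.null(qc)) qc[qc$read_id == m$read_id, , drop = FALSE] else NULL
    if (!is.null(qrow) && nrow(qrow) == 0L) qrow <- NULL
    if (mode == "wgs") {
      suppressMessages(screen_wgs_read(m, ref,
        qc = qrow, min_rdna = min_rdna,
        min_coding_fraction = min_coding_fraction
      ))
    } else {
      screen_cas9_read(m, ref, cut_sites = cut_sites)
    }
  }))
  kept <- if (nrow(screen) > 0L) screen$read_id[screen$pass] else character(0)
  kept_maps <- maps[kept]

  inversions <- dplyr::bind_rows(lapply(kept_maps, function(m) {
    call <- detect_inversion(m, min_opposite_fraction)
    if (is.null(call)) {
      return(NULL)
    }
    qd <- detect_quality_drop(
      reads[[m$read_id]]$qualities, call$inversion_offset
    )
    call$quality_drop <- qd
    call$classification <- classify_palindrome(call$relative_position, qd)
    call
  }))
  inverted_ids <- if (nrow(inversions) > 0L) inversions$read_id else character(0)
  straight <- setdiff(kept, inverted_ids)

  segments <- dplyr::bind_rows(lapply(kept_maps[straight], segment_copies,
    ref = ref
  ))
  gap_events <- dplyr::bind_rows(lapply(
    kept_maps[straight], detect_structural_gaps,
    ref = ref, threshold = structural_threshold
  ))
  estimates <- dplyr::bind_rows(lapply(straight, function(id) {
    seg <- segments[segments$read_id == id, , drop = FALSE]
    estimate_repeat_lengths(reads[[id]], seg, ref, aligner)
  }))

  igs_type <- classify_igs_type(
    if (nrow(estimates) > 0L) estimates else numeric(0)
  )
  n_copies <- if (nrow(segments) > 0L) sum(segments$complete) else 0L
  noncanon <- summarize_noncanonical(
    gap_events, n_copies, length(kept), inversions
  )

  statuses <- NULL
  adjacency <- NULL
  switch <- NULL
  corr_45s_igs <- NULL
  if (!is.null(calls) && nrow(calls) > 0L) {
    statuses <- dplyr::bind_rows(lapply(straight, function(id) {
      seg <- segments[segments$read_id == id, , drop = FALSE]
      copy_methyl_status(seg, calls[calls$read_id == id, , drop = FALSE],
        border = methyl_border
      )
    }))
    if (nrow(statuses) > 0L) {
      adjacency <- methylation_adjacency(statuses, seed = seed)
      switch <- methylation_switch_rate(statuses)
      corr_45s_igs <- correlate_45s_igs(statuses)
    }
  }

  rdna_bases <- sum(vapply(
    reads[kept], function(r) nchar(r$sequence), numeric(1)
  ))
  total_bases <- total_bases %||% sum(vapply(
    reads, function(r) nchar(r$sequence), numeric(1)
  ))
  copy_number <- if (total_bases > 0) {
    estimate_copy_number(rdna_bases, total_bases, genome_size, ref$unit_length)
  } else {
    tibble(
      rdna_bases = 0, total_bases = 0, fraction = NA_real_,
      genome_size = genome_size, unit_length = ref$unit_length,
      copies_per_cell = NA_real_
    )
  }

  unmeth_prop <- if (!is.null(statuses) && nrow(statuses) > 0L) {
    mean(statuses$class == "unmethylated", na.rm = TRUE)
  } else {
    NA_real_
  }

  summary <- dplyr::bind_cols(
    tibble(
      n_reads_in = length(reads),
      n_reads_pass = length(kept),
      n_inverted = length(inverted_ids)
    ),
    noncanon[, setdiff(names(noncanon), "n_reads")],
    tibble(
      igs_type_call = igs_type$type,
      short_proportion = igs_type$short_proportion,
      copies_per_cell = copy_number$copies_per_cell,
      unmethylated_proportion = unmeth_prop,
      switch_rate = if (is.null(switch)) NA_real_ else switch$switch_rate
    )
  )

  list(
    summary = summary, screen = screen, maps = maps,
    inversions = inversions, segments = segments,
    gap_events = gap_events, estimates = estimates,
    statuses = statuses, igs_type = igs_type, adjacency = adjacency,
    switch = switch, corr_45s_igs = corr_45s_igs,
    copy_number = copy_number
  )
}

#' Run the pipeline from a config file
#'
#' The YAML config names the inputs and thresholds:
#' ```yaml
#' fastq: reads.fastq
#' reference: reference.fa
#' annotation: landmarks.bed
#' mode: wgs            # or cas9
#' methylation: methylation.tsv   # optional
#' sequencing_summary: summary.tsv  # optional
#' guides: [ACGT...]    # cas9 mode; located by exact match
#' seed: 1
#' # any analyze_sample() threshold may be set by name
#' ```
#' All thresholds in force are logged at startup. Outputs (screen report,
#' per-copy tables, summary JSON) are written under `out_dir`.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory.
#' @return The [analyze_sample()] result list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (need in c("fastq", "reference", "annotation")) {
    if (is.null(cfg[[need]])) abort(sprintf("config lacks '%s'.", need))
  }
  ref <- load_reference(cfg$reference, cfg$annotation,
    anchor_positions = unlist(cfg$anchors %||% c(10000L, 20000L, 30000L)),
    anchor_length = cfg$anchor_length %||% 500L
  )
  reads <- read_fastq(cfg$fastq)
  calls <- if (!is.null(cfg$methylation)) {
    read_methylation_calls(cfg$methylation)
  } else {
    NULL
  }
  qc <- if (!is.null(cfg$sequencing_summary)) {
    read_sequencing_summary(cfg$sequencing_summary)
  } else {
    NULL
  }
  mode <- cfg$mode %||% "wgs"
  cut_sites <- NULL
  if (mode == "cas9") {
    if (is.null(cfg$guides)) abort("cas9 mode requires 'guides' in config.")
    cut_sites <- locate_guide_sites(ref, unlist(cfg$guides))
  }
  thr <- list(
    split_length = cfg$split_length %||% 300L,
    min_rdna = cfg$min_rdna %||% 40000,
    min_coding_fraction = cfg$min_coding_fraction %||% 0.10,
    structural_threshold = cfg$structural_threshold %||% 500,
    min_opposite_fraction = cfg$min_opposite_fraction %||% 0.10,
    methyl_border = cfg$methyl_border %||% 0.1,
    genome_size = cfg$genome_size %||% 6.27e9,
    seed = cfg$seed %||% 1L
  )
  inform(sprintf(
    "run_pipeline: mode=%s reads=%d coords=0-based half-open %s",
    mode, length(reads),
    paste(names(thr), unlist(thr), sep = "=", collapse = " ")
  ))
  res <- analyze_sample(reads, ref,
    calls = calls, mode = mode, qc = qc,
    cut_sites = cut_sites,
    split_length = as.integer(thr$split_length),
    min_rdna = thr$min_rdna,
    min_coding_fraction = thr$min_coding_fraction,
    structural_threshold = thr$structural_threshold,
    min_opposite_fraction = thr$min_opposite_fraction,
    methyl_border = thr$methyl_border,
    genome_size = thr$genome_size,
    seed = as.integer(thr$seed)
  )

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) {
    write.table(d, file.path(out_dir, f),
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }
  screen_flat <- res$screen
  screen_flat$reasons <- vapply(screen_flat$reasons, paste,
    character(1),
    collapse = ","
  )
  wt(screen_flat, "screen.tsv")
  wt(dplyr::bind_rows(lapply(res$maps, tidy)), "split_alignments.tsv")
  wt(res$segments, "segments.tsv")
  wt(res$gap_events, "gap_events.tsv")
  wt(res$estimates, "repeat_estimates.tsv")
  if (nrow(res$inversions %||% tibble()) > 0L) {
    wt(res$inversions, "inversions.tsv")
  }
  if (!is.null(res$statuses)) wt(res$statuses, "methylation_status.tsv")
  jsonlite::write_json(as.list(res$summary),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(res)
}
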