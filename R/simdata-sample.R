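# Whole-sample simulation: a seeded scenario mixing rDNA array reads
# (with planted structural events, repeat-count variation and methylation
# states), template-switch artifacts, non-rDNA background reads and
# pseudogene-like decoys, with a truth table sufficient to score every
# pipeline output.

#' Simulate a full sequencing sample with truth
#'
#' @param ref An `rdna_reference` from [make_synthetic_reference()];
#'   `NULL` builds one with defaults.
#' @param mode `"wgs"` (random read phases) or `"cas9"` (fragments cut at
#'   `cut_sites` on both ends).
#' @param n_rdna_reads Number of rDNA array reads.
#' @param units_per_read Complete rDNA copies per read.
#' @param q Adjacent-copy repeat-count cloning probability.
#' @param switch_prob Methylation switch probability between adjacent
#'   copies.
#' @param p_unmethylated Stationary unmethylated proportion.
#' @param noncanonical_rate Probability a copy carries one planted
#'   structural event (deletion or duplication of 600-8000 bases in the
#'   coding region).
#' @param artifact_rate Probability an rDNA read is turned into a
#'   template-switch palindromic artifact.
#' @param n_background Number of uniform-random non-rDNA reads.
#' @param background_length Length range of background reads.
#' @param n_decoys Number of pseudogene-like decoy reads (a short rDNA
#'   fragment embedded in random flanks, total < 40 kb of rDNA).
#' @param error An [error_model()].
#' @param cut_sites Unit-space cut sites (required in cas9 mode).
#' @param meth Simulate methylation calls for rDNA reads?
#' @param cpg_density CpG sites per base.
#' @param seed Integer seed; the whole sample is a pure function of the
#'   configuration and this seed.
#' @param out_dir Optional directory; when given, writes `reads.fastq`,
#'   `reference.fa`, `landmarks.bed`, `methylation.tsv` and `truth.json`.
#' @return List: `ref`, `reads` (named list), `read_info` (tibble:
#'   `read_id`, `kind`, `artifact`, `n_copies`), `truths` (per-read truth
#'   list for rDNA reads), `calls` (methylation tibble), `specs`.
#' @export
simulate_sample <- function(ref = NULL,
                            mode = c("wgs", "cas9"),
                            n_rdna_reads = 20L,
                            units_per_read = 2L,
                            q = 0.8,
                            switch_prob = 0.05,
                            p_unmethylated = 0.5,
                            noncanonical_rate = 0,
                            artifact_rate = 0,
                            n_background = 0L,
                            background_length = c(20000L, 60000L),
                            n_decoys = 0L,
                            error = error_model(),
                            cut_sites = NULL,
                            meth = TRUE,
                            cpg_density = 0.02,
                            seed = 1L,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "cas9" && (is.null(cut_sites) || length(cut_sites) == 0L)) {
    abort("cas9 mode requires `cut_sites` (see locate_guide_sites()).")
  }
  withr::with_seed(seed, {
    if (is.null(ref)) {
      ref <- make_synthetic_reference(seed = sample.int(2^31 - 2L, 1L))
    }
    L <- ref$unit_length
    n_copies_gen <- units_per_read + 1L
    specs <- simulate_array_specs(
      n_rdna_reads, n_copies_gen,
      q = q,
      switch_prob = switch_prob, p_unmethylated = p_unmethylated,
      seed = sample.int(2^31 - 2L, 1L)
    )

    reads <- list()
    truths <- list()
    info <- list()
    calls <- list()

    for (r in seq_len(n_rdna_reads)) {
      rid <- sprintf("rdna%04d", r)
      spc <- specs[specs$read_id == sprintf("read%04d", r), , drop = FALSE]
      if (mode == "wgs") {
        phase <- sample.int(L, 1L) - 1L
        end_phase <- phase
      } else {
        phase <- cut_sites[sample.int(length(cut_sites), 1L)]
        end_phase <- phase
      }
      ev <- NULL
      hit <- runif(n_copies_gen) < noncanonical_rate
      if (any(hit)) {
        ce <- ref$coding_interval[2]
        ev <- dplyr::bind_rows(lapply(which(hit), function(i) {
          size <- round(runif(1, 600, 8000))
          tibble(
            copy_index = i,
            type = sample(c("deletion", "duplication"), 1L),
            unit_pos = round(runif(1, size + 1000, ce - 1000)),
            size = size
          )
        }))
      }
      sim <- simulate_array_read(ref, spc,
        start_phase = phase, end_phase = end_phase, error = error,
        events = ev, seed = sample.int(2^31 - 2L, 1L), read_id = rid
      )
      artifact <- runif(1) < artifact_rate
      if (artifact) {
        ts <- simulate_template_switch(sim$read,
          seed = sample.int(2^31 - 2L, 1L)
        )
        reads[[ts$read$read_id]] <- ts$read
        sim$truth$artifact <- ts$truth
        truths[[ts$read$read_id]] <- sim$truth
        info[[length(info) + 1L]] <- tibble(
          read_id = ts$read$read_id, kind = "rdna", artifact = TRUE,
          n_copies = sum(sim$truth$copies$complete)
        )
      } else {
        reads[[rid]] <- sim$read
        truths[[rid]] <- sim$truth
        info[[length(info) + 1L]] <- tibble(
          read_id = rid, kind = "rdna", artifact = FALSE,
          n_copies = sum(sim$truth$copies$complete)
        )
        if (meth) {
          calls[[rid]] <- simulate_methylation_calls(
            sim$truth,
            cpg_density = cpg_density,
            seed = sample.int(2^31 - 2L, 1L)
          )
        }
      }
    }

    for (b in seq_len(n_background)) {
      rid <- sprintf("bg%04d", b)
      n <- round(runif(1, background_length[1], background_length[2]))
      reads[[rid]] <- list(
        read_id = rid, sequence = random_dna(n),
        qualities = rep(12L, n)
      )
      info[[length(info) + 1L]] <- tibble(
        read_id = rid, kind = "background", artifact = FALSE, n_copies = 0L
      )
    }

    for (d in seq_len(n_decoys)) {
      rid <- sprintf("decoy%04d", d)
      frag_len <- round(runif(1, 10000, 30000))
      start <- sample.int(L - frag_len, 1L)
      frag <- substr(ref$unit_sequence, start, start + frag_len - 1L)
      er <- apply_errors(
        paste0(random_dna(8000L), frag, random_dna(8000L)), error
      )
      reads[[rid]] <- list(
        read_id = rid, sequence = er$sequence, qualities = er$qualities
      )
      info[[length(info) + 1L]] <- tibble(
        read_id = rid, kind = "decoy", artifact = FALSE, n_copies = 0L
      )
    }

    read_info <- dplyr::bind_rows(info)
    calls <- if (length(calls) > 0L) {
      dplyr::bind_rows(calls)
    } else {
      tibble(
        read_id = character(0), position = integer(0),
        posterior = numeric(0), region = character(0)
      )
    }

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fastq(reads, file.path(out_dir, "reads.fastq"))
      write_reference(
        ref, file.path(out_dir, "reference.fa"),
        file.path(out_dir, "landmarks.bed")
      )
      write_methylation_calls(
        calls[, c("read_id", "position", "posterior")],
        file.path(out_dir, "methylation.tsv")
      )
      truth_json <- list(
        read_info = read_info,
        copies = dplyr::bind_rows(lapply(truths, `[[`, "copies"))
      )
      jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
        auto_unbox = TRUE, digits = NA
      )
    }

    list(
      ref = ref, reads = reads, read_info = read_info, truths = truths,
      calls = calls, specs = specs
    )
  })
}
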