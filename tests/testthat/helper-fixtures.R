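# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# default synthetic reference (3 R units, 2 Butterfly/Long units, 41040 bp)
test_ref <- function() {
  if (is.null(.fixtures$ref)) {
    .fixtures$ref <- make_synthetic_reference(seed = 7)
  }
  .fixtures$ref
}

# a read map built directly from a splits table (no alignment), for
# boundary tests of the structure rules
fake_map <- function(ref_pos, strand, read_id = "fake", split_length = 300L,
                     unit_length = test_ref()$unit_length,
                     read_length = length(ref_pos) * split_length) {
  splits <- tibble::tibble(
    read_offset = as.integer((seq_along(ref_pos) - 1L) * split_length),
    length = split_length,
    ref_pos = as.integer(ref_pos),
    strand = as.character(strand),
    score = ifelse(is.na(ref_pos), NA_real_, 100)
  )
  rdnarray:::new_read_map(read_id, read_length, split_length, splits,
    ref_unit_length = unit_length
  )
}

# per-copy methylation status rows without running the pipeline
fake_statuses <- function(read_id, mean_45s, border = 0.1) {
  read_id <- rep(read_id, length.out = length(mean_45s))
  tibble::tibble(
    read_id = read_id,
    copy_index = stats::ave(seq_along(read_id), read_id, FUN = seq_along),
    n_cpg = 50L,
    mean_45s = mean_45s,
    class = ifelse(is.na(mean_45s), NA_character_,
      ifelse(mean_45s > border, "methylated", "unmethylated")
    )
  )
}
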