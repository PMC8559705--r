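test_that("segment_copies counts origin crossings", {
  ref <- test_ref()
  L <- ref$unit_length

  # exactly two concatenated units from the origin: two complete copies
  m2 <- map_splits(
    list(read_id = "x", sequence = strrep(ref$unit_sequence, 2)), ref
  )
  seg <- segment_copies(m2, ref)
  expect_equal(sum(seg$complete), 2L)
  expect_equal(seg$read_start[seg$complete], c(0, L))
  # coding/Butterfly-Long sub-intervals land at the annotated coordinates
  expect_equal(
    seg$coding_read_start[seg$complete],
    c(0, L) + ref$coding_interval[1]
  )
  expect_equal(
    seg$bl_read_start[seg$complete],
    c(0, L) + ref$butterfly_long_interval[1]
  )

  # read shorter than one unit: no crossing, no complete segment
  sub <- list(read_id = "y", sequence = substring(ref$unit_sequence, 5001, 30000))
  expect_equal(sum(segment_copies(map_splits(sub, ref), ref)$complete), 0L)

  # 2.5 units starting mid-IGS: 2 complete + incomplete flank(s)
  sim <- simulate_array_read(ref,
    n_units = 3, start_phase = 35000,
    error = error_model(0, 0, 0), seed = 1
  )
  seg25 <- segment_copies(map_splits(sim$read, ref), ref)
  expect_equal(sum(seg25$complete), 2L)
  expect_gte(nrow(seg25), 3L)
})

test_that("segment_copies rejects inverted reads", {
  ref <- test_ref()
  base <- simulate_array_read(ref,
    n_units = 1, start_phase = 5000,
    error = error_model(0, 0, 0), seed = 2
  )
  ts <- simulate_template_switch(base$read, termination = 1, seed = 3)
  m <- map_splits(ts$read, ref)
  expect_error(segment_copies(m, ref), "inversion analysis")
})

test_that("structural gaps: detection, sign convention and suppression", {
  ref <- test_ref()
  # error-free unmodified read: no events
  clean <- simulate_array_read(ref,
    n_units = 2, start_phase = 30000,
    error = error_model(0, 0, 0), seed = 4
  )
  expect_equal(nrow(detect_structural_gaps(map_splits(clean$read, ref), ref)), 0L)

  # planted 5-kb deletion in the coding region: one unsuppressed event
  ev <- tibble::tibble(
    copy_index = 2L, type = "deletion", unit_pos = 6000, size = 5000
  )
  sim <- simulate_array_read(ref,
    n_units = 3, start_phase = 30000,
    error = error_model(), events = ev, seed = 5
  )
  g <- detect_structural_gaps(map_splits(sim$read, ref), ref)
  expect_equal(nrow(g), 1L)
  expect_false(g$suppressed)
  expect_equal(g$class, "deletion")
  expect_lt(abs(g$deviation - 5000), 150)

  # planted 800-base expansion with both flanks inside the R repeat:
  # reported but suppressed
  ev2 <- tibble::tibble(
    copy_index = 2L, type = "duplication", unit_pos = 16020, size = 800
  )
  sim2 <- simulate_array_read(ref,
    n_units = 3, start_phase = 30000,
    error = error_model(), events = ev2, seed = 6
  )
  g2 <- detect_structural_gaps(map_splits(sim2$read, ref), ref)
  expect_gte(nrow(g2), 1L)
  expect_true(all(g2$suppressed))

  # an insertion (negative deviation) is labelled duplication
  ev3 <- tibble::tibble(
    copy_index = 2L, type = "insertion", unit_pos = 6000, size = 2000
  )
  sim3 <- simulate_array_read(ref,
    n_units = 2, start_phase = 30000,
    error = error_model(0, 0, 0), events = ev3, seed = 99
  )
  g3 <- detect_structural_gaps(map_splits(sim3$read, ref), ref)
  expect_equal(nrow(g3), 1L)
  expect_equal(g3$class, "duplication")
  expect_lt(abs(g3$deviation + 2000), 150)
})

test_that("the 500-base structural threshold is strict", {
  ref <- test_ref()
  u <- ref$unit_sequence
  mk <- function(size) {
    list(read_id = "d", sequence = paste0(
      substring(u, 1, 6000), substring(u, 6001 + size, 41040)
    ))
  }
  g500 <- detect_structural_gaps(map_splits(mk(500), ref), ref)
  expect_equal(nrow(g500), 0L)
  g501 <- detect_structural_gaps(map_splits(mk(501), ref), ref)
  expect_equal(nrow(g501), 1L)
})

test_that("inversion detection applies the strict 10% opposite rule", {
  ref <- test_ref()
  pos <- (seq_len(100) - 1L) * 300L %% ref$unit_length
  # 0/100 opposite
  expect_null(detect_inversion(fake_map(pos, rep("+", 100))))
  # exactly 10/100 opposite: still below the strict threshold
  s10 <- c(rep("+", 90), rep("-", 10))
  expect_null(detect_inversion(fake_map(pos, s10)))
  # 15/100 opposite: inverted
  s15 <- c(rep("+", 85), rep("-", 15))
  call <- detect_inversion(fake_map(pos, s15))
  expect_false(is.null(call))
  expect_equal(call$opposite_fraction, 0.15)
})

test_that("locate_inversion_point finds single transitions and flags complex", {
  ref <- test_ref()
  # forward-only read: error
  pos <- (seq_len(40) - 1L) * 300L
  expect_error(
    locate_inversion_point(fake_map(pos, rep("+", 40))),
    "no strand transition"
  )
  # two transitions: complex, no single point
  s <- c(rep("+", 20), rep("-", 10), rep("+", 10))
  pt <- locate_inversion_point(fake_map(pos, s))
  expect_equal(pt$n_transitions, 2L)
  expect_true(is.na(pt$inversion_offset))

  # complete template switch: relative position 0.5
  base <- simulate_array_read(test_ref(),
    n_units = 1, start_phase = 3000,
    error = error_model(0, 0, 0), seed = 8
  )
  ts <- simulate_template_switch(base$read, termination = 1, seed = 9)
  call <- detect_inversion(map_splits(ts$read, test_ref()))
  expect_equal(call$relative_position, 0.5, tolerance = 0.01)

  # second strand terminated at 25% of the first: relative 0.8
  ts2 <- simulate_template_switch(base$read, termination = 0.25, seed = 10)
  call2 <- detect_inversion(map_splits(ts2$read, test_ref()))
  expect_equal(call2$relative_position, 0.8, tolerance = 0.01)
})

test_that("quality-drop detection needs a sustained drop of >= 5 Phred", {
  flat <- rep(12, 20000)
  expect_false(detect_quality_drop(flat, 10000))
  step7 <- c(rep(14, 10000), rep(7, 1000), rep(14, 9000))
  expect_true(detect_quality_drop(step7, 10000))
  step3 <- c(rep(14, 10000), rep(11, 1000), rep(14, 9000))
  expect_false(detect_quality_drop(step3, 10000))
  # inversion too close to the read end: undetermined
  expect_true(is.na(detect_quality_drop(flat, 19500)))
})

test_that("palindrome classification follows the position/drop rules", {
  expect_equal(classify_palindrome(0.75, FALSE), "artifact_consistent")
  expect_equal(classify_palindrome(0.5, NA), "artifact_consistent")
  expect_equal(classify_palindrome(0.3, FALSE), "candidate_real")
  expect_equal(classify_palindrome(0.3, TRUE), "dubious")
  expect_equal(
    classify_palindrome(c(0.9, 0.2), c(NA, TRUE)),
    c("artifact_consistent", "dubious")
  )
})

test_that("breakpoint clustering groups recurrent inversion patterns", {
  ref <- test_ref()
  calls <- tibble::tibble(
    read_id = c("a", "b", "c"),
    breakpoint_ref = c(10000, 10200, 25000),
    orientation = c("+-", "+-", "+-")
  )
  cl <- cluster_inversion_breakpoints(calls, ref, tolerance = 500)
  expect_equal(cl$group_size[cl$read_id %in% c("a", "b")], c(2L, 2L))
  expect_true(all(cl$recurrent[cl$read_id %in% c("a", "b")]))
  expect_false(cl$recurrent[cl$read_id == "c"])

  # differing orientation blocks clustering
  calls$orientation <- c("+-", "-+", "+-")
  cl2 <- cluster_inversion_breakpoints(calls, ref, tolerance = 500)
  expect_false(any(cl2$recurrent))

  # circular wrap: breakpoints across the origin cluster together
  calls3 <- tibble::tibble(
    read_id = c("d", "e"),
    breakpoint_ref = c(100, ref$unit_length - 100),
    orientation = "+-"
  )
  cl3 <- cluster_inversion_breakpoints(calls3, ref, tolerance = 500)
  expect_true(all(cl3$recurrent))

  empty <- cluster_inversion_breakpoints(calls[0, ], ref)
  expect_equal(nrow(empty), 0L)
})

test_that("noncanonical summary computes per-copy and per-read rates", {
  events <- tibble::tibble(
    read_id = c("r1", "r1", "r2"),
    suppressed = c(FALSE, TRUE, FALSE)
  )
  s <- summarize_noncanonical(events, n_copies = 1000L, n_reads = 100L)
  expect_equal(s$n_noncanonical_events, 2L)
  expect_equal(s$noncanonical_rate_per_copy, 0.002)
  expect_equal(s$noncanonical_rate_per_read, 0.02)

  s0 <- summarize_noncanonical(events[0, ], n_copies = 0L, n_reads = 0L)
  expect_true(is.na(s0$noncanonical_rate_per_copy))

  inv <- tibble::tibble(classification = c("artifact_consistent", "candidate_real"))
  s2 <- summarize_noncanonical(events[0, ], 2000L, 50L, inversion_calls = inv)
  expect_equal(s2$n_candidate_real, 1L)
  expect_equal(s2$candidate_real_rate_per_copy, 1 / 2000)
})
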