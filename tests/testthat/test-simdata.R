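test_that("synthetic reference geometry and determinism", {
  ref <- make_synthetic_reference(n_r = 3, n_bl = 2, backbone_length = 30000,
    seed = 3
  )
  expect_equal(ref$unit_length, 30000 + 3 * 680 + 2 * 4500) # 41040
  expect_equal(diff(ref$r_repeat_interval), 3 * 680)
  expect_equal(diff(ref$butterfly_long_interval), 2 * 4500)

  ref2 <- make_synthetic_reference(n_r = 3, n_bl = 2, seed = 3)
  expect_identical(ref2$unit_sequence, ref$unit_sequence)

  # no R units: zero-width interval, annotation still present
  ref0 <- make_synthetic_reference(n_r = 0, seed = 3)
  expect_equal(diff(ref0$r_repeat_interval), 0)
  expect_equal(ref0$unit_length, 30000 + 2 * 4500)

  expect_error(make_synthetic_reference(n_r = -1), ">= 0")
})

test_that("array reads concatenate copies and honour the error model", {
  ref <- test_ref()
  sim <- simulate_array_read(ref,
    n_units = 2, start_phase = 0,
    error = error_model(0, 0, 0), seed = 4
  )
  expect_equal(nchar(sim$read$sequence), 2L * ref$unit_length)
  expect_equal(
    sim$read$sequence,
    strrep(ref$unit_sequence, 2)
  )
  expect_true(all(sim$read$qualities == 40L))

  sim2 <- simulate_array_read(ref, n_units = 2, seed = 4)
  sim3 <- simulate_array_read(ref, n_units = 2, seed = 4)
  expect_identical(sim2$read$sequence, sim3$read$sequence)
  expect_identical(sim2$read$qualities, sim3$read$qualities)
  # 5% total error: length within a few percent, quality near Q13
  expect_lt(
    abs(nchar(sim2$read$sequence) - 2 * ref$unit_length),
    0.02 * 2 * ref$unit_length
  )

  expect_error(
    simulate_array_read(ref,
      events = tibble::tibble(
        copy_index = 1, type = "deletion", unit_pos = 100, size = 1e6
      ),
      seed = 1
    ),
    "exceeds|larger"
  )
  expect_error(simulate_array_read(ref, n_units = 0, seed = 1), ">= 1")
})

test_that("error model rates are validated and mapped to qualities", {
  expect_error(error_model(sub = 0.5), "0, 0.2")
  em <- error_model(0.03, 0.01, 0.01)
  expect_equal(em$sub, 0.03)
})

test_that("template-switch artifacts put the inversion in the latter half", {
  ref <- test_ref()
  base <- simulate_array_read(ref,
    n_units = 1, start_phase = 2000,
    error = error_model(0, 0, 0), seed = 5
  )
  full <- simulate_template_switch(base$read, termination = 1, seed = 6)
  expect_equal(full$truth$relative_position, 0.5, tolerance = 1e-4)
  n1 <- nchar(base$read$sequence)
  expect_equal(nchar(full$read$sequence), 2L * n1)

  for (s in 1:10) {
    t <- simulate_template_switch(base$read, termination = "uniform", seed = s)
    expect_gte(t$truth$relative_position, 0.5)
  }
  # second-strand qualities are dropped
  q <- simulate_template_switch(base$read, termination = 0.5, seed = 7)
  expect_equal(
    mean(utils::tail(q$read$qualities, 100)),
    mean(utils::head(q$read$qualities, 100)) - 7,
    tolerance = 1
  )
  expect_identical(
    simulate_template_switch(base$read, seed = 8)$read$sequence,
    simulate_template_switch(base$read, seed = 8)$read$sequence
  )
  expect_error(
    simulate_template_switch(base$read, termination = 0, seed = 1),
    "0, 1"
  )
})

test_that("true palindromes land on both sides of the read centre", {
  ref <- test_ref()
  rels <- vapply(1:20, function(s) {
    simulate_true_palindrome(ref, breakpoint = 5000, seed = s)$truth$relative_position
  }, numeric(1))
  expect_gt(sum(rels < 0.5), 2)
  expect_gt(sum(rels >= 0.5), 2)
})

test_that("methylation calls are bimodal by planted state and seeded", {
  ref <- test_ref()
  spec <- tibble::tibble(
    copy_index = 1:2, n_r = 3L, n_bl = 2L, meth_state = c("U", "M")
  )
  sim <- simulate_array_read(ref, spec,
    start_phase = 0,
    error = error_model(0, 0, 0), seed = 9
  )
  calls <- simulate_methylation_calls(sim$truth, seed = 10)
  expect_identical(calls, simulate_methylation_calls(sim$truth, seed = 10))

  tr <- sim$truth$copies
  m45 <- function(i) {
    p <- calls$posterior[
      calls$position >= tr$coding_read_start[i] &
        calls$position < tr$coding_read_end[i]
    ]
    mean(p)
  }
  expect_lt(m45(1), 0.1) # unmethylated copy
  expect_gt(m45(2), 0.1) # methylated copy
  # no CpGs inside Butterfly/Long
  in_bl <- calls$position >= tr$bl_read_start[1] &
    calls$position < tr$bl_read_end[1]
  expect_equal(sum(in_bl), 0L)
  expect_error(
    simulate_methylation_calls(sim$truth, cpg_density = 0, seed = 1),
    "positive"
  )
})

test_that("simulate_sample is a pure function of configuration and seed", {
  ref <- test_ref()
  s1 <- simulate_sample(
    ref = ref, n_rdna_reads = 2, units_per_read = 2,
    n_background = 1, seed = 12
  )
  s2 <- simulate_sample(
    ref = ref, n_rdna_reads = 2, units_per_read = 2,
    n_background = 1, seed = 12
  )
  expect_identical(
    lapply(s1$reads, `[[`, "sequence"),
    lapply(s2$reads, `[[`, "sequence")
  )
  expect_identical(s1$calls, s2$calls)
  expect_equal(nrow(s1$read_info), 3L)
  expect_error(
    simulate_sample(ref = ref, mode = "cas9", seed = 1),
    "cut_sites"
  )
})
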