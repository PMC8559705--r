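test_that("repeat-length deltas recover planted unit counts", {
  ref <- test_ref()
  spec <- tibble::tibble(
    copy_index = 1:3, n_r = c(3L, 4L, 2L), n_bl = c(2L, 2L, 1L),
    meth_state = "M"
  )
  sim <- simulate_array_read(ref, spec,
    start_phase = 35000,
    error = error_model(0, 0, 0), seed = 11
  )
  m <- map_splits(sim$read, ref)
  seg <- segment_copies(m, ref)
  est <- estimate_repeat_lengths(sim$read, seg, ref)
  tr <- sim$truth$copies
  j <- dplyr::inner_join(est, tr, by = c("read_id", "copy_index"),
    suffix = c("", ".true")
  )
  j <- j[!is.na(j$delta_r), ]
  expect_gte(nrow(j), 2L)
  # reference-identical copy: zero delta up to aligner jitter (<= 20)
  expect_true(all(abs(j$delta_r - j$delta_r.true) <= 20))
  expect_true(all(abs(j$delta_bl - j$delta_bl.true) <= 20))
  # derived R unit count
  expect_equal(j$r_unit_delta, j$delta_r.true / 680)
})

test_that("IGS typing applies the strict -2000 boundary and 0.2 cutoff", {
  long_type <- classify_igs_type(rep(0, 50))
  expect_equal(long_type$type, "long")
  expect_equal(long_type$short_proportion, 0)

  short_type <- classify_igs_type(c(rep(-2500, 20), rep(0, 30)))
  expect_equal(short_type$type, "short")
  expect_equal(short_type$short_proportion, 0.4)

  # exactly -2000 does not count as short
  boundary <- classify_igs_type(c(rep(-2000, 30), rep(0, 20)))
  expect_equal(boundary$short_proportion, 0)
  expect_equal(boundary$type, "long")

  # just above the cutoff flips the call
  at_cutoff <- classify_igs_type(c(rep(-2100, 10), rep(0, 40)))
  expect_equal(at_cutoff$short_proportion, 0.2)
  expect_equal(at_cutoff$type, "long") # strict: 0.2 is not > 0.2

  few <- classify_igs_type(rep(-2500, 10))
  expect_equal(few$type, "undetermined")
})

test_that("adjacent differences pair consecutive copies within reads", {
  est <- tibble::tibble(
    read_id = c("a", "a", "b", "b", "b", "c"),
    copy_index = c(1L, 2L, 1L, 2L, 3L, 1L),
    delta_r = c(0, 0, 680, 0, 0, 340),
    delta_bl = c(0, 0, 0, 0, -4500, 0)
  )
  d <- adjacent_pair_differences(est)
  dr <- d$abs_diff[d$metric == "delta_r"]
  expect_equal(sort(dr), c(0, 0, 680))
  dbl <- d$abs_diff[d$metric == "delta_bl"]
  expect_equal(sort(dbl), c(0, 0, 4500))

  # single-copy reads contribute nothing
  single <- adjacent_pair_differences(est[est$read_id == "c", ])
  expect_equal(nrow(single), 0L)

  # non-consecutive copy indices (a missing middle copy) are not paired
  gap <- est[c(3, 5), ]
  expect_equal(nrow(adjacent_pair_differences(gap)), 0L)
})

test_that("randomised control pairs reproduce the enumeration expectation", {
  pool <- tibble::tibble(
    read_id = "x", copy_index = 1:100,
    delta_r = rep(c(0, 680), c(30, 70)),
    delta_bl = rep(c(0, -4500), c(50, 50))
  )
  ctl <- randomized_pair_differences(pool, n_pairs = 4000, seed = 5)
  # oracle: enumerate all ordered distinct pairs
  enum_mean <- function(v) {
    d <- abs(outer(v, v, "-"))
    sum(d) / (length(v) * (length(v) - 1))
  }
  got_r <- mean(ctl$abs_diff[ctl$metric == "delta_r"])
  expect_equal(got_r, enum_mean(pool$delta_r), tolerance = 0.05)
  got_bl <- mean(ctl$abs_diff[ctl$metric == "delta_bl"])
  expect_equal(got_bl, enum_mean(pool$delta_bl), tolerance = 0.05)

  # identical pool: all zero differences
  same <- pool
  same$delta_r <- 680
  same$delta_bl <- 0
  ctl0 <- randomized_pair_differences(same, 100, seed = 1)
  expect_true(all(ctl0$abs_diff == 0))

  # seeded reproducibility
  expect_identical(
    randomized_pair_differences(pool, 50, seed = 9),
    randomized_pair_differences(pool, 50, seed = 9)
  )

  expect_error(
    randomized_pair_differences(pool[1, ], 10, seed = 1),
    "fewer than 2"
  )
})

test_that("adjacent-vs-random rank test behaves at the extremes", {
  r <- compare_adjacent_vs_random(rep(0, 20), rep(680, 20))
  expect_lt(r$p_value, 0.01)

  same <- c(rep(0, 10), rep(680, 10))
  r2 <- compare_adjacent_vs_random(same, same)
  expect_gte(r2$p_value, 0.5)

  tied <- compare_adjacent_vs_random(rep(5, 10), rep(5, 10))
  expect_equal(tied$p_value, 1)
  expect_true(tied$all_tied)

  expect_error(compare_adjacent_vs_random(numeric(0), 1:5), "non-empty")
})

test_that("gene-conversion correlation is detected against the random null", {
  specs <- simulate_array_specs(100, 3, q = 0.8, seed = 21)
  est <- tibble::tibble(
    read_id = specs$read_id, copy_index = specs$copy_index,
    delta_r = 680 * (specs$n_r - 3), delta_bl = 4500 * (specs$n_bl - 2)
  )
  adj <- adjacent_pair_differences(est)
  ctl <- randomized_pair_differences(est, n_pairs = 200, seed = 22)
  res <- compare_adjacent_vs_random(
    adj$abs_diff[adj$metric == "delta_r"],
    ctl$abs_diff[ctl$metric == "delta_r"]
  )
  expect_lt(res$p_value, 0.01)
})
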