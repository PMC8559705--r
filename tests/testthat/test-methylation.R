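test_that("bin_methylation matches a brute-force oracle on random calls", {
  oracle <- function(calls, bin = 200L, threshold = 0.8) {
    out <- list()
    for (b in sort(unique(calls$position %/% bin))) {
      p <- calls$posterior[calls$position %/% bin == b]
      out[[length(out) + 1L]] <- tibble::tibble(
        bin_start = as.integer(b * bin), n_cpg = length(p),
        avg_freq = mean(p), thresh_freq = mean(p >= threshold)
      )
    }
    dplyr::bind_rows(out)
  }
  set.seed(31)
  for (i in 1:50) {
    n <- sample(1:80, 1)
    calls <- tibble::tibble(
      read_id = "r",
      position = sample.int(5000, n) - 1L,
      posterior = runif(n)
    )
    expect_equal(
      bin_methylation(calls, read_length = 5000),
      oracle(calls)
    )
  }
})

test_that("bin_methylation handles worked examples and bad records", {
  calls <- tibble::tibble(
    read_id = "r", position = c(10L, 150L, 210L, 290L),
    posterior = c(1, 1, 0.9, 0.7)
  )
  b <- bin_methylation(calls, read_length = 1000)
  expect_equal(b$avg_freq, c(1, 0.8))
  expect_equal(b$thresh_freq, c(1, 0.5))
  expect_equal(b$n_cpg, c(2L, 2L))
  # a bin with no CpG carries no row
  expect_equal(b$bin_start, c(0L, 200L))

  bad <- rbind(calls, tibble::tibble(
    read_id = "r", position = 300L,
    posterior = 1.4
  ))
  expect_warning(b2 <- bin_methylation(bad, 1000), "outside")
  expect_equal(b2, b)

  expect_error(
    bin_methylation(
      tibble::tibble(read_id = "r", position = 2000L, posterior = 0.5),
      read_length = 1000
    ),
    "within the read"
  )
})

make_seg <- function(read_id = "r", n = 1L, unit = 41040L,
                     coding = c(0L, 13000L), bl = c(20500L, 29500L)) {
  starts <- (seq_len(n) - 1L) * unit
  tibble::tibble(
    read_id = read_id, copy_index = seq_len(n),
    read_start = starts, read_end = starts + unit,
    complete = TRUE, strand = "+",
    coding_read_start = starts + coding[1],
    coding_read_end = starts + coding[2],
    bl_read_start = starts + bl[1], bl_read_end = starts + bl[2]
  )
}

test_that("copy classification applies the strict 0.1 border", {
  seg <- make_seg()
  mk_calls <- function(p) {
    tibble::tibble(
      read_id = "r", position = seq(100L, 12900L, by = 100L),
      posterior = p
    )
  }
  low <- copy_methylation(seg, mk_calls(0.02))
  expect_equal(low$mean_45s, 0.02)
  expect_equal(low$class, "unmethylated")

  mid <- copy_methylation(seg, mk_calls(0.4))
  expect_equal(mid$class, "methylated")

  border <- copy_methylation(seg, mk_calls(0.1))
  expect_equal(border$class, "unmethylated") # exactly 0.1 is not > 0.1

  none <- copy_methylation(seg, mk_calls(0.4)[0, ])
  expect_true(is.na(none$mean_45s))
  expect_true(is.na(none$class))

  # threshold metric counts CpGs at posterior >= 0.8
  thr <- copy_methylation(seg,
    tibble::tibble(
      read_id = "r", position = c(100L, 200L, 300L, 400L),
      posterior = c(0.9, 0.85, 0.2, 0.1)
    ),
    metric = "threshold"
  )
  expect_equal(thr$mean_45s, 0.5)
})

test_that("IGS methylation excludes the Butterfly/Long span", {
  seg <- make_seg()
  # calls only inside Butterfly/Long: missing
  bl_only <- tibble::tibble(
    read_id = "r", position = seq(21000L, 29000L, 500L), posterior = 1
  )
  expect_true(is.na(igs_methylation(seg, bl_only)$igs_methylation))

  # half 1.0 / half 0.0 outside Butterfly/Long
  igs_calls <- tibble::tibble(
    read_id = "r",
    position = c(seq(14000L, 15900L, 100L), seq(31000L, 32900L, 100L)),
    posterior = rep(c(1, 0), each = 20)
  )
  expect_equal(igs_methylation(seg, igs_calls)$igs_methylation, 0.5)

  all_one <- igs_calls
  all_one$posterior <- 1
  expect_equal(igs_methylation(seg, all_one)$igs_methylation, 1)
})

test_that("45S-IGS correlation is computed on the strong stratum only", {
  set.seed(41)
  st <- tibble::tibble(
    mean_45s = runif(60, 0.31, 0.9),
    igs_methylation = NA_real_
  )
  st$igs_methylation <- st$mean_45s + rnorm(60, 0, 0.01)
  res <- correlate_45s_igs(st)
  expect_gt(res$r, 0.9)
  expect_equal(res$n, 60L)

  # copies below the 0.3 cutoff are excluded
  st2 <- rbind(st, tibble::tibble(
    mean_45s = rep(0.05, 100),
    igs_methylation = runif(100)
  ))
  expect_equal(correlate_45s_igs(st2)$n, 60L)

  small <- correlate_45s_igs(st[1:5, ])
  expect_match(small$note, "too small")

  const <- tibble::tibble(mean_45s = runif(20, 0.4, 0.9), igs_methylation = 0.5)
  expect_match(correlate_45s_igs(const)$note, "zero variance")
})

test_that("methylation adjacency uses within-read pairs and a seeded control", {
  st <- fake_statuses(
    rep(c("a", "b"), c(3, 2)),
    c(0.0, 0.0, 0.9, 0.5, 0.5)
  )
  adj <- methylation_adjacency(st, n_random = 200, seed = 7)
  expect_equal(sort(adj$adjacent$abs_diff), c(0, 0, 0.9))
  expect_identical(
    adj$control,
    methylation_adjacency(st, n_random = 200, seed = 7)$control
  )
  single <- fake_statuses("a", 0.5)
  expect_message(
    out <- methylation_adjacency(single, seed = 1),
    "undefined"
  )
  expect_equal(nrow(out$adjacent), 0L)
})

test_that("switch rate counts class changes between adjacent copies", {
  st <- fake_statuses("a", c(0.0, 0.0, 0.9, 0.9)) # U U M M
  s <- methylation_switch_rate(st)
  expect_equal(s$switch_rate, 1 / 3)
  expect_equal(s$mean_run_length, 3)

  st_same <- fake_statuses("a", rep(0.9, 5))
  expect_equal(methylation_switch_rate(st_same)$switch_rate, 0)

  st_alt <- fake_statuses("a", c(0, 0.9, 0, 0.9)) # U M U M
  expect_equal(methylation_switch_rate(st_alt)$switch_rate, 1)

  none <- methylation_switch_rate(fake_statuses("a", 0.5))
  expect_true(is.na(none$switch_rate))
})

test_that("switch-rate estimator is unbiased on a two-state Markov chain", {
  specs <- simulate_array_specs(150, 9, q = 0, switch_prob = 0.05, seed = 51)
  st <- fake_statuses(
    specs$read_id,
    ifelse(specs$meth_state == "U", 0.02, 0.5)
  )
  s <- methylation_switch_rate(st)
  se <- sqrt(0.05 * 0.95 / s$n_pairs)
  expect_equal(s$n_pairs, 150L * 8L)
  expect_lt(abs(s$switch_rate - 0.05), 2 * se)
})

test_that("copy-number estimation follows the depth-ratio formula", {
  z <- estimate_copy_number(0, 1e9, unit_length = 44800)
  expect_equal(z$copies_per_cell, 0)

  e <- estimate_copy_number(5e6, 1e9, genome_size = 6.2e9, unit_length = 44800)
  expect_equal(e$fraction, 0.005)
  expect_equal(round(e$copies_per_cell), 692) # 0.005 * 6.2e9 / 44800

  e2 <- estimate_copy_number(1e7, 1e9, genome_size = 6.2e9, unit_length = 44800)
  expect_equal(e2$copies_per_cell, 2 * e$copies_per_cell)

  expect_error(estimate_copy_number(1, 1, unit_length = 0), "positive")
  expect_error(estimate_copy_number(2, 1, unit_length = 10), "exceed")
})

test_that("active-copy analysis recovers a constant and its correlations", {
  set.seed(61)
  N <- round(seq(250, 700, length.out = 10))
  p <- 230 / N + rnorm(10, 0, 0.005)
  fit <- active_copy_analysis(
    tibble::tibble(copies_per_cell = N, unmethylated_proportion = p)
  )
  expect_equal(fit$A, 230, tolerance = 0.05)
  expect_lt(fit$r_proportion, -0.9)
  expect_lt(abs(fit$r_count), 0.6)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "A"], fit$A)
  expect_equal(glance(fit)$n, 10L)

  # proportion independent of copy number: weak correlation
  p2 <- rep(0.4, 10) + rnorm(10, 0, 0.02)
  fit2 <- active_copy_analysis(
    tibble::tibble(copies_per_cell = N, unmethylated_proportion = p2)
  )
  expect_lt(abs(fit2$r_proportion), 0.7)

  flat <- tibble::tibble(
    copies_per_cell = rep(400, 6),
    unmethylated_proportion = runif(6)
  )
  expect_match(active_copy_analysis(flat)$note, "no variance")
  expect_error(active_copy_analysis(flat[1:3, ]), ">= 5 samples")
})

test_that("R-repeat/methylation correlation is FDR-corrected per sample", {
  set.seed(71)
  mk <- function(sid, rho_planted) {
    r <- sample(0:4, 60, TRUE)
    m <- if (rho_planted) {
      0.1 * r + runif(60, 0, 0.05)
    } else {
      runif(60)
    }
    tibble::tibble(sample_id = sid, r_units = r, mean_45s = m)
  }
  d <- dplyr::bind_rows(
    mk("s1", TRUE), mk("s2", TRUE), mk("s3", FALSE)
  )
  res <- correlate_r_repeat_methylation(d)
  expect_gt(res$rho[res$sample_id == "s1"], 0.8)
  expect_true(all(res$significant[res$sample_id %in% c("s1", "s2")]))

  # constant R count: sample skipped
  d2 <- tibble::tibble(sample_id = "k", r_units = 3, mean_45s = runif(30))
  expect_true(correlate_r_repeat_methylation(d2)$skipped)
})
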