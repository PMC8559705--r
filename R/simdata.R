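# Synthetic data: a generative model of tandem rDNA arrays, Nanopore-like
# read errors, template-switch palindromic artifacts and bimodal per-copy
# methylation posteriors, with full truth records. Every generator is a
# pure function of (configuration, seed).

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitute a fraction `rate` of positions with a different base
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit) > 0L) {
    idx <- match(ch[hit], BASES)
    ch[hit] <- BASES[(idx + sample.int(3L, length(hit), replace = TRUE) - 1L) %% 4L + 1L]
  }
  paste(ch, collapse = "")
}

#' Nanopore-like sequencing error model
#'
#' @param sub,ins,del Per-base substitution, insertion and deletion rates;
#'   each must lie in `[0, 0.2]`.
#' @return A named list of rates.
#' @export
error_model <- function(sub = 0.03, ins = 0.01, del = 0.01) {
  r <- c(sub = sub, ins = ins, del = del)
  if (any(r < 0 | r > 0.2)) abort("error rates must lie in [0, 0.2].")
  as.list(r)
}

# Apply the error model to a sequence. Returns the mutated sequence, a
# per-base Phred quality vector consistent with the total error rate, and
# a coordinate map from pre-error to post-error 0-based offsets.
# Consumes RNG; callers fix the seed.
apply_errors <- function(seq, model) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  total <- model$sub + model$ins + model$del
  if (total > 0) {
    hit <- which(runif(n) < model$sub)
    if (length(hit) > 0L) {
      idx <- match(ch[hit], BASES)
      ch[hit] <- BASES[(idx + sample.int(3L, length(hit), replace = TRUE) - 1L) %% 4L + 1L]
    }
    del <- runif(n) < model$del
    insc <- as.integer(runif(n) < model$ins)
    times <- as.integer(!del) + insc
    grp <- rep.int(seq_len(n), times)
    out <- ch[grp]
    first <- !duplicated(grp)
    is_orig <- first & !del[grp]
    k <- sum(!is_orig)
    if (k > 0L) out[!is_orig] <- sample(BASES, k, replace = TRUE)
    cum <- c(0L, cumsum(times))
    map <- function(old) cum[pmin(pmax(old, 0L), n) + 1L]
    m <- length(out)
    seq_out <- paste(out, collapse = "")
  } else {
    m <- n
    map <- function(old) pmin(pmax(old, 0L), n)
    seq_out <- seq
  }
  if (total > 0) {
    base_q <- round(-10 * log10(total))
    qual <- pmin(pmax(base_q + round(rnorm(m, 0, 1.5)), 2L), 40L)
  } else {
    qual <- rep(40L, m)
  }
  list(sequence = seq_out, qualities = as.integer(qual), map = map)
}

#' Generate a synthetic repeat-unit reference
#'
#' Builds a random backbone with an embedded R-repeat block (`n_r` units
#' of 680 bases) and a Butterfly/Long block (`n_bl` units of 4500 bases)
#' at annotated intervals. Repeat units are internally composite (two or
#' three diverged sub-periods) and block copies are mutually diverged
#' (each copy independently mutated at `copy_divergence` from a base
#' unit), emulating real satellite divergence. Layout: coding (45S)
#' occupies `[0, 13000)`; the R block starts at 15000; the Butterfly/Long
#' block sits between the second and third anchors. Unit length is
#' `backbone_length + 680 * n_r + 4500 * n_bl`.
#'
#' @param n_r,n_bl Number of R and Butterfly/Long units (>= 0).
#' @param backbone_length Non-repeat bases (default 30000; must be >=
#'   17000).
#' @param copy_divergence Per-copy substitution divergence of repeat units
#'   from their base unit (default 0.025).
#' @param seed Integer seed; a fixed seed gives a byte-identical
#'   reference.
#' @param name Reference name.
#' @return An `rdna_reference` whose `sim` field records the generator
#'   state needed by [simulate_array_read()].
#' @export
make_synthetic_reference <- function(n_r = 3L, n_bl = 2L,
                                     backbone_length = 30000L,
                                     copy_divergence = 0.025,
                                     seed = 1L,
                                     name = "synthetic_rdna_unit") {
  if (n_r < 0L || n_bl < 0L) abort("repeat counts must be >= 0.")
  if (backbone_length < 17000L) {
    abort("`backbone_length` must be >= 17000 to hold the landmarks.")
  }
  withr::with_seed(seed, {
    u <- random_dna(340L)
    r_base <- paste0(u, mutate_seq(u, 0.03))
    v <- random_dna(1500L)
    bl_base <- paste0(v, mutate_seq(v, 0.03), mutate_seq(v, 0.05))

    r_block <- paste(
      vapply(seq_len(n_r), function(i) mutate_seq(r_base, copy_divergence),
        character(1)
      ),
      collapse = ""
    )
    bl_block <- paste(
      vapply(seq_len(n_bl), function(i) mutate_seq(bl_base, copy_divergence),
        character(1)
      ),
      collapse = ""
    )

    coding_len <- 13000L
    r_start <- 15000L
    r_end <- r_start + 680L * n_r
    bl_start <- max(20500L, r_end + 500L)
    gap2 <- bl_start - r_end
    sp3 <- backbone_length - coding_len - 2000L - gap2
    if (sp3 < 1000L) {
      abort("`backbone_length` too small for this many R units.")
    }
    bl_end <- bl_start + 4500L * n_bl

    unit <- paste0(
      random_dna(coding_len), random_dna(2000L), r_block,
      random_dna(gap2), bl_block, random_dna(sp3)
    )
    L <- nchar(unit)
    stopifnot(L == backbone_length + 680L * n_r + 4500L * n_bl)

    a1 <- 10000L
    a2 <- if (r_end <= 19500L) 20000L else r_end + (bl_start - r_end - 500L) %/% 2L
    a3 <- if (bl_end <= 29500L) 30000L else bl_end + 500L
    if (a3 + 500L > L) abort("unit too short for the third anchor.")

    reference_model(
      unit_sequence = unit,
      coding_interval = c(0L, coding_len),
      r_repeat_interval = c(r_start, r_end),
      butterfly_long_interval = c(bl_start, bl_end),
      anchor_positions = c(a1, a2, a3),
      anchor_length = 500L,
      name = name,
      sim = list(
        r_base = r_base, bl_base = bl_base, n_r = n_r, n_bl = n_bl,
        copy_divergence = copy_divergence,
        r_unit_size = 680L, bl_unit_size = 4500L
      )
    )
  })
}

#' Simulate per-copy array specifications
#'
#' Draws per-copy R and Butterfly/Long unit counts and methylation states
#' for a set of reads. With probability `q` an adjacent copy clones its
#' neighbour's repeat counts (the gene-conversion correlation); with
#' `q = 0` copies are i.i.d. Methylation states follow a two-state Markov
#' chain along the array with the given switch probability.
#'
#' @param n_reads Number of reads.
#' @param copies_per_read Copies per read.
#' @param q Adjacent-copy cloning probability (default 0.8).
#' @param r_weights Sampling weights for 0-4 R units (defaults give a
#'   population mean between 2 and 3).
#' @param bl_weights Sampling weights for 1-3 Butterfly/Long units.
#' @param switch_prob Expected fraction of adjacent copy pairs with
#'   different methylation state (default 0.05, i.e. 1 in 20). The
#'   two-state chain is parameterised so its stationary distribution is
#'   `p_unmethylated` and its stationary switch frequency is
#'   `switch_prob`.
#' @param p_unmethylated Stationary probability a copy is unmethylated.
#' @param seed Integer seed.
#' @return Tibble: `read_id`, `copy_index`, `n_r`, `n_bl`, `meth_state`
#'   (`"U"`/`"M"`).
#' @export
simulate_array_specs <- function(n_reads, copies_per_read, q = 0.8,
                                 r_weights = c(0.05, 0.15, 0.3, 0.3, 0.2),
                                 bl_weights = c(0.2, 0.7, 0.1),
                                 switch_prob = 0.05,
                                 p_unmethylated = 0.5,
                                 seed = 1L) {
  # transition rates with stationary p and switch frequency sigma:
  # p * P(U->M) = (1-p) * P(M->U) and
  # p * P(U->M) + (1-p) * P(M->U) = sigma
  p <- p_unmethylated
  s_um <- if (p > 0) min(1, switch_prob / (2 * p)) else 0
  s_mu <- if (p < 1) min(1, switch_prob / (2 * (1 - p))) else 0
  withr::with_seed(seed, {
    one_read <- function(r) {
      n_r <- integer(copies_per_read)
      n_bl <- integer(copies_per_read)
      st <- character(copies_per_read)
      for (i in seq_len(copies_per_read)) {
        if (i > 1L && runif(1) < q) {
          n_r[i] <- n_r[i - 1L]
          n_bl[i] <- n_bl[i - 1L]
        } else {
          n_r[i] <- sample(0:4, 1L, prob = r_weights)
          n_bl[i] <- sample(1:3, 1L, prob = bl_weights)
        }
        st[i] <- if (i == 1L) {
          if (runif(1) < p) "U" else "M"
        } else if (st[i - 1L] == "U") {
          if (runif(1) < s_um) "M" else "U"
        } else {
          if (runif(1) < s_mu) "U" else "M"
        }
      }
      tibble(
        read_id = sprintf("read%04d", r),
        copy_index = seq_len(copies_per_read),
        n_r = n_r, n_bl = n_bl, meth_state = st
      )
    }
    dplyr::bind_rows(lapply(seq_len(n_reads), one_read))
  })
}

# Build one (possibly modified) copy of the unit. Returns seq, landmark
# coordinates in copy space, and planted deltas. Consumes RNG.
build_copy <- function(ref, n_r = NULL, n_bl = NULL, events = NULL) {
  sim <- ref$sim
  unit <- ref$unit_sequence
  L <- ref$unit_length
  riv <- ref$r_repeat_interval
  bliv <- ref$butterfly_long_interval
  n_r <- n_r %||% if (!is.null(sim)) sim$n_r else NA_integer_
  n_bl <- n_bl %||% if (!is.null(sim)) sim$n_bl else NA_integer_

  modified <- !is.null(sim) && (n_r != sim$n_r || n_bl != sim$n_bl)
  if (modified) {
    # contract blocks by dropping trailing units of the reference block,
    # expand by appending freshly diverged units; interior units stay
    # identical to the reference, as array copies homogenised by gene
    # conversion do
    resize_block <- function(block, n0, n, base, usize) {
      if (n <= n0) {
        substr(block, 1L, usize * n)
      } else {
        paste0(block, paste(
          vapply(seq_len(n - n0), function(i) {
            mutate_seq(base, sim$copy_divergence)
          }, character(1)),
          collapse = ""
        ))
      }
    }
    r_block <- resize_block(
      substr(unit, riv[1] + 1L, riv[2]), sim$n_r, n_r,
      sim$r_base, sim$r_unit_size
    )
    bl_block <- resize_block(
      substr(unit, bliv[1] + 1L, bliv[2]), sim$n_bl, n_bl,
      sim$bl_base, sim$bl_unit_size
    )
    seq <- paste0(
      substr(unit, 1L, riv[1]), r_block,
      substr(unit, riv[2] + 1L, bliv[1]), bl_block,
      substr(unit, bliv[2] + 1L, L)
    )
    dr <- sim$r_unit_size * (n_r - sim$n_r)
    dbl <- sim$bl_unit_size * (n_bl - sim$n_bl)
  } else {
    seq <- unit
    dr <- 0
    dbl <- 0
  }
  coding <- as.numeric(ref$coding_interval)
  bl <- c(bliv[1] + dr, bliv[2] + dr + dbl)
  len <- L + dr + dbl

  ev_out <- NULL
  if (!is.null(events) && nrow(events) > 0L) {
    events <- events[order(-events$unit_pos), , drop = FALSE]
    shift_after <- function(x, pos, by) ifelse(x > pos, x + by, x)
    for (i in seq_len(nrow(events))) {
      type <- events$type[i]
      pos <- events$unit_pos[i]
      size <- events$size[i]
      if (size >= len) abort("event larger than the unit copy.")
      if (type == "deletion") {
        if (pos + size > len) abort("deletion exceeds copy bounds.")
        seq <- paste0(substr(seq, 1L, pos), substr(seq, pos + size + 1L, len))
        by <- -size
      } else if (type == "duplication") {
        if (pos - size < 0L) abort("duplication source outside copy.")
        seq <- paste0(
          substr(seq, 1L, pos), substr(seq, pos - size + 1L, pos),
          substr(seq, pos + 1L, len)
        )
        by <- size
      } else if (type == "insertion") {
        seq <- paste0(
          substr(seq, 1L, pos), random_dna(size),
          substr(seq, pos + 1L, len)
        )
        by <- size
      } else {
        abort(sprintf("unknown event type '%s'.", type))
      }
      coding <- shift_after(coding, pos, by)
      bl <- shift_after(bl, pos, by)
      len <- len + by
    }
    ev_out <- events
  }

  list(
    seq = seq, len = len, coding = coding, bl = bl,
    delta_r = dr, delta_bl = dbl, events = ev_out
  )
}

#' Simulate one multi-unit array read with truth
#'
#' Concatenates per-copy modified units (repeat-count changes and planted
#' structural events), trims to the requested phase, applies the
#' sequencing error model and emits per-base qualities. The returned truth
#' records copy boundaries, landmark sub-intervals and planted deltas in
#' post-error read coordinates.
#'
#' @param ref An `rdna_reference` (from [make_synthetic_reference()] when
#'   repeat counts are to be varied).
#' @param spec Optional per-copy tibble (`n_r`, `n_bl`, `meth_state`); one
#'   row per copy. When `NULL`, `n_units` unmodified copies are used.
#' @param n_units Number of copies when `spec` is `NULL`.
#' @param start_phase Unit coordinate at which the read starts within the
#'   first copy.
#' @param end_phase Optional unit coordinate at which the read ends within
#'   the last copy (used for Cas9-cut fragments); `NULL` reads to the end
#'   of the last copy.
#' @param error An [error_model()].
#' @param events Optional tibble of planted structural events
#'   (`copy_index`, `type` in deletion/duplication/insertion, `unit_pos`,
#'   `size`).
#' @param seed Integer seed.
#' @param read_id Read identifier.
#' @return List with `read` (list: `read_id`, `sequence`, `qualities`) and
#'   `truth` (list: `copies` tibble, `events` tibble, `read_length`,
#'   `start_phase`).
#' @export
simulate_array_read <- function(ref, spec = NULL, n_units = 2L,
                                start_phase = 0L, end_phase = NULL,
                                error = error_model(), events = NULL,
                                seed = 1L, read_id = "sim_read") {
  if (is.null(spec)) {
    if (n_units < 1L) abort("`n_units` must be >= 1.")
    spec <- tibble(
      copy_index = seq_len(n_units),
      n_r = rep(if (!is.null(ref$sim)) ref$sim$n_r else NA_integer_, n_units),
      n_bl = rep(if (!is.null(ref$sim)) ref$sim$n_bl else NA_integer_, n_units),
      meth_state = rep("M", n_units)
    )
  }
  n_units <- nrow(spec)
  withr::with_seed(seed, {
    copies <- lapply(seq_len(n_units), function(i) {
      ev <- if (!is.null(events)) {
        events[events$copy_index == i, , drop = FALSE]
      } else {
        NULL
      }
      build_copy(ref, spec$n_r[i], spec$n_bl[i], ev)
    })
    lens <- vapply(copies, `[[`, numeric(1), "len")
    cum <- c(0, cumsum(lens))
    full <- paste(vapply(copies, `[[`, character(1), "seq"), collapse = "")
    total <- nchar(full)
    from <- start_phase + 1L
    to <- if (is.null(end_phase)) {
      total
    } else {
      cum[n_units] + end_phase
    }
    if (from > to) abort("empty read: start_phase beyond end.")
    pre <- substr(full, from, to)
    n_pre <- nchar(pre)

    er <- apply_errors(pre, error)
    mp <- er$map
    n_post <- nchar(er$sequence)

    clamp_iv <- function(s, e) {
      # pre-error read coords -> post-error; NA when outside the read
      if (is.na(s) || is.na(e) || e <= 0 || s >= n_pre) {
        return(c(NA_real_, NA_real_))
      }
      c(mp(max(0, s)), mp(min(n_pre, e)))
    }
    rows <- lapply(seq_len(n_units), function(i) {
      off <- cum[i] - start_phase
      s <- off
      e <- off + lens[i]
      if (e <= 0 || s >= n_pre) {
        return(NULL)
      }
      cod <- clamp_iv(off + copies[[i]]$coding[1], off + copies[[i]]$coding[2])
      bl <- clamp_iv(off + copies[[i]]$bl[1], off + copies[[i]]$bl[2])
      tibble(
        read_id = read_id, copy_index = i,
        n_r = spec$n_r[i], n_bl = spec$n_bl[i],
        meth_state = spec$meth_state[i],
        delta_r = copies[[i]]$delta_r, delta_bl = copies[[i]]$delta_bl,
        read_start = mp(max(0, s)), read_end = mp(min(n_pre, e)),
        complete = s >= 0 && e <= n_pre,
        coding_read_start = cod[1], coding_read_end = cod[2],
        bl_read_start = bl[1], bl_read_end = bl[2]
      )
    })
    ev_rows <- NULL
    if (!is.null(events) && nrow(events) > 0L) {
      ev_rows <- events
      ev_rows$read_pos <- vapply(seq_len(nrow(events)), function(j) {
        i <- events$copy_index[j]
        as.numeric(mp(max(0, cum[i] - start_phase + events$unit_pos[j])))
      }, numeric(1))
    }
    list(
      read = list(
        read_id = read_id, sequence = er$sequence,
        qualities = er$qualities
      ),
      truth = list(
        read_id = read_id, start_phase = start_phase,
        unit_length = ref$unit_length,
        copies = dplyr::bind_rows(rows),
        events = ev_rows,
        read_length = n_post
      )
    )
  })
}

#' Simulate a template-switch palindromic artifact
#'
#' Appends the reverse complement of the read, truncated to a
#' `termination` fraction of its length (drawn uniformly in (0, 1] when
#' `"uniform"`), with second-strand qualities reduced by `quality_drop`.
#' By construction the inversion point sits at relative position
#' `1 / (1 + termination) >= 0.5`.
#'
#' @param read A read list (`read_id`, `sequence`, `qualities`).
#' @param termination Fraction of the second strand sequenced, or
#'   `"uniform"`.
#' @param quality_drop Phred units subtracted from second-strand
#'   qualities (default 7).
#' @param seed Integer seed.
#' @return List with `read` (the artifact) and `truth`
#'   (`inversion_offset`, `relative_position`, `termination`).
#' @export
simulate_template_switch <- function(read, termination = "uniform",
                                     quality_drop = 7, seed = 1L) {
  if (nchar(read$sequence) == 0L) abort("read must be non-empty.")
  withr::with_seed(seed, {
    t <- if (identical(termination, "uniform")) runif(1) else termination
    if (!is.numeric(t) || t <= 0 || t > 1) {
      abort("`termination` must lie in (0, 1].")
    }
    n1 <- nchar(read$sequence)
    m <- max(1L, round(t * n1))
    second <- substr(revcomp(read$sequence), 1L, m)
    q2 <- pmax(rev(read$qualities)[seq_len(m)] - quality_drop, 2L)
    list(
      read = list(
        read_id = paste0(read$read_id, "_ts"),
        sequence = paste0(read$sequence, second),
        qualities = c(read$qualities, q2)
      ),
      truth = list(
        inversion_offset = n1,
        relative_position = n1 / (n1 + m),
        termination = t
      )
    )
  })
}

#' Simulate a genuine palindromic read with random framing
#'
#' A true genomic palindrome at unit coordinate `breakpoint`: the read
#' runs into the breakpoint and back out on the complementary strand, with
#' the two arm lengths drawn independently, so the inversion point lands
#' on either side of the read centre.
#'
#' @param ref An `rdna_reference`.
#' @param breakpoint Unit-space coordinate of the palindrome axis.
#' @param arm_range Range (bases) the two arm lengths are drawn from.
#' @param error An [error_model()].
#' @param seed Integer seed.
#' @param read_id Read identifier.
#' @return List with `read` and `truth` (`inversion_offset`,
#'   `relative_position`, `breakpoint`).
#' @export
simulate_true_palindrome <- function(ref, breakpoint = 5000L,
                                     arm_range = c(15000, 45000),
                                     error = error_model(), seed = 1L,
                                     read_id = "palindrome") {
  L <- ref$unit_length
  withr::with_seed(seed, {
    arms <- round(runif(2, arm_range[1], arm_range[2]))
    reps <- ceiling((max(arms) - breakpoint) / L) + 1L
    arr <- strrep(ref$unit_sequence, reps)
    p <- (reps - 1L) * L + breakpoint
    left <- substr(arr, p - arms[1] + 1L, p)
    right <- revcomp(substr(arr, p - arms[2] + 1L, p))
    er <- apply_errors(paste0(left, right), error)
    list(
      read = list(
        read_id = read_id, sequence = er$sequence,
        qualities = er$qualities
      ),
      truth = list(
        inversion_offset = er$map(arms[1]),
        relative_position = er$map(arms[1]) / nchar(er$sequence),
        breakpoint = breakpoint
      )
    )
  })
}

#' Simulate per-CpG methylation calls for a read
#'
#' CpG sites are placed at the stated density. Inside a copy's coding
#' (45S) sub-interval posteriors are drawn from the state's Beta
#' distribution (unmethylated ~ Beta(1, 20), methylated ~ Beta(8, 8) by
#' default); IGS CpGs are drawn methylated-like regardless of the copy's
#' 45S state; the Butterfly/Long sub-interval carries no CpGs
#' (microsatellite).
#'
#' @param truth Truth record from [simulate_array_read()].
#' @param cpg_density CpG sites per base (default 0.02).
#' @param unmeth_shape,meth_shape,igs_shape Beta shape pairs.
#' @param seed Integer seed.
#' @return Tibble of calls: `read_id`, `position`, `posterior`, `region`.
#' @export
simulate_methylation_calls <- function(truth, cpg_density = 0.02,
                                       unmeth_shape = c(1, 20),
                                       meth_shape = c(8, 8),
                                       igs_shape = c(8, 8),
                                       seed = 1L) {
  if (cpg_density <= 0) abort("`cpg_density` must be positive.")
  cp <- truth$copies
  withr::with_seed(seed, {
    span_calls <- function(s, e, shape, region, rid) {
      if (!is.finite(s) || !is.finite(e)) {
        return(NULL)
      }
      len <- floor(e - s)
      if (is.na(len) || len < 1L) {
        return(NULL)
      }
      k <- rbinom(1L, len, cpg_density)
      if (k == 0L) {
        return(NULL)
      }
      pos <- sort(sample.int(len, k)) + floor(s) - 1L
      tibble(
        read_id = rid, position = as.integer(pos),
        posterior = rbeta(k, shape[1], shape[2]), region = region
      )
    }
    out <- lapply(seq_len(nrow(cp)), function(i) {
      rid <- cp$read_id[i]
      shape45 <- if (cp$meth_state[i] == "U") unmeth_shape else meth_shape
      dplyr::bind_rows(
        span_calls(
          cp$coding_read_start[i], cp$coding_read_end[i], shape45,
          "45S", rid
        ),
        # IGS pieces: segment minus coding minus Butterfly/Long
        span_calls(
          cp$coding_read_end[i],
          if (is.na(cp$bl_read_start[i])) {
            cp$read_end[i]
          } else {
            min(cp$bl_read_start[i], cp$read_end[i])
          },
          igs_shape, "IGS", rid
        ),
        if (!is.na(cp$bl_read_end[i])) {
          span_calls(
            cp$bl_read_end[i], cp$read_end[i], igs_shape, "IGS", rid
          )
        }
      )
    })
    dplyr::bind_rows(out) |> dplyr::arrange(.data$position)
  })
}
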