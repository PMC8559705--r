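# Alignment backends.
#
# An aligner maps query sequences against a target sequence and returns
# zero or more hits (position, strand, score), one of them primary. The
# built-in backend uses exact 15-mer seeding with voting on the
# (target position - query position) diagonal, on both strands, with
# nearby diagonals (indel jitter) merged into one cluster. It is
# deterministic and seed-free. External backends (minimap2) satisfy the
# same contract through the same align_query() generic.

#' Built-in exact k-mer seed-and-vote aligner
#'
#' @param k Seed length in bases.
#' @param min_votes Minimum number of seed votes in a diagonal cluster for
#'   the cluster to count as a hit.
#' @param cluster_gap Diagonals closer than this are merged into one
#'   cluster (absorbs indel jitter within a query).
#' @return An aligner object usable with [align_query()] and
#'   [map_splits()].
#' @export
aligner_builtin <- function(k = 15L, min_votes = 8L, cluster_gap = 30L) {
  structure(
    list(
      k = as.integer(k), min_votes = as.integer(min_votes),
      cluster_gap = as.integer(cluster_gap)
    ),
    class = c("rdna_aligner_builtin", "rdna_aligner")
  )
}

#' minimap2 external aligner backend
#'
#' Thin wrapper over the `minimap2` executable (must be on `PATH`).
#' Used as an independent cross-check of the built-in backend.
#'
#' @param preset minimap2 preset (`-x`).
#' @param extra_args Additional command-line arguments.
#' @return An aligner object usable with [align_query()].
#' @export
aligner_minimap2 <- function(preset = "map-ont", extra_args = character()) {
  structure(
    list(preset = preset, extra_args = extra_args),
    class = c("rdna_aligner_minimap2", "rdna_aligner")
  )
}

#' Map query sequences against a target sequence
#'
#' @param aligner An aligner object ([aligner_builtin()] or
#'   [aligner_minimap2()]).
#' @param queries Named character vector of query sequences.
#' @param target Single target sequence (character).
#' @param circular Treat the target as circular (tandem repeat unit)?
#' @param all_hits Return all hits per query, or only the primary hit?
#' @return A tibble with columns `query`, `ref_pos` (0-based start of the
#'   hit on the forward target, for reverse hits the start of the
#'   reverse-complemented query's match), `strand` (`"+"`/`"-"`), `score`
#'   and `primary`. Queries without a hit are absent.
#' @export
align_query <- function(aligner, queries, target, circular = FALSE,
                        all_hits = FALSE) {
  UseMethod("align_query")
}

# Extract all k-mers of a sequence as a character vector; position i
# (0-based) is element i+1.
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) {
    return(character(0))
  }
  substring(seq, 1:(n - k + 1L), k:n)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @export
align_query.rdna_aligner_builtin <- function(aligner, queries, target,
                                             circular = FALSE,
                                             all_hits = FALSE) {
  stopifnot(is.character(target), length(target) == 1L)
  if (length(queries) == 0L) {
    return(empty_hits())
  }
  if (is.null(names(queries))) {
    names(queries) <- as.character(seq_along(queries))
  }
  k <- aligner$k
  L <- nchar(target)
  tseq <- if (circular) paste0(target, substr(target, 1L, k - 1L)) else target
  tk <- seq_kmers(tseq, k)
  idx <- data.table::data.table(kmer = tk, tpos = seq_along(tk) - 1L)
  data.table::setkey(idx, kmer)

  qtab <- function(strand) {
    qs <- if (strand == "+") queries else revcomp(queries)
    kl <- lapply(qs, seq_kmers, k = k)
    nk <- lengths(kl)
    if (sum(nk) == 0L) {
      return(NULL)
    }
    data.table::data.table(
      qid = rep(names(queries), nk),
      qpos = unlist(lapply(nk, function(n) seq_len(n) - 1L),
        use.names = FALSE
      ),
      kmer = unlist(kl, use.names = FALSE),
      strand = strand
    )
  }
  qk <- data.table::rbindlist(
    Filter(Negate(is.null), list(qtab("+"), qtab("-")))
  )
  if (nrow(qk) == 0L) {
    return(empty_hits())
  }
  hits <- idx[qk, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) == 0L) {
    return(empty_hits())
  }
  if (circular) {
    hits[, diag := (tpos - qpos) %% L]
  } else {
    hits[, diag := tpos - qpos]
  }
  votes <- hits[, .N, by = c("qid", "strand", "diag")]
  data.table::setorder(votes, qid, strand, diag)
  gap <- aligner$cluster_gap
  votes[, cl := cumsum(c(1L, as.integer(diff(diag) > gap))),
    by = c("qid", "strand")
  ]
  clusters <- votes[, list(
    score = sum(N),
    ref_pos = diag[which.max(N)]
  ), by = c("qid", "strand", "cl")]
  clusters <- clusters[clusters$score >= aligner$min_votes, ]
  if (nrow(clusters) == 0L) {
    return(empty_hits())
  }
  # primary: max score; ties broken by forward strand then lowest position
  data.table::setorder(clusters, qid, -score, strand, ref_pos)
  clusters[, primary := seq_len(.N) == 1L, by = "qid"]
  out <- tibble(
    query = clusters$qid,
    ref_pos = as.integer(clusters$ref_pos),
    strand = clusters$strand,
    score = as.numeric(clusters$score),
    primary = clusters$primary
  )
  if (!all_hits) out <- out[out$primary, , drop = FALSE]
  out[order(match(out$query, names(queries))), , drop = FALSE]
}

empty_hits <- function() {
  tibble(
    query = character(0), ref_pos = integer(0), strand = character(0),
    score = numeric(0), primary = logical(0)
  )
}

#' @export
align_query.rdna_aligner_minimap2 <- function(aligner, queries, target,
                                              circular = FALSE,
                                              all_hits = FALSE) {
  if (length(queries) == 0L) {
    return(empty_hits())
  }
  if (is.null(names(queries))) {
    names(queries) <- as.character(seq_along(queries))
  }
  L <- nchar(target)
  # emulate a circular unit by padding the target with its own head; hit
  # positions are reduced mod L afterwards
  tgt <- if (circular) {
    paste0(target, substr(target, 1L, min(L, 1000L)))
  } else {
    target
  }
  td <- tempfile(fileext = ".fa")
  qd <- tempfile(fileext = ".fa")
  on.exit(unlink(c(td, qd)), add = TRUE)
  writeLines(c(">target", tgt), td)
  writeLines(rbind(paste0(">", names(queries)), unname(queries)), qd)
  out <- suppressWarnings(system2(
    "minimap2",
    c("-x", aligner$preset, "--secondary=yes", aligner$extra_args, td, qd),
    stdout = TRUE, stderr = FALSE
  ))
  if (length(out) == 0L) {
    return(empty_hits())
  }
  f <- strsplit(out, "\t")
  paf <- tibble(
    query = vapply(f, `[`, "", 1L),
    qlen = as.integer(vapply(f, `[`, "", 2L)),
    qstart = as.integer(vapply(f, `[`, "", 3L)),
    qend = as.integer(vapply(f, `[`, "", 4L)),
    strand = vapply(f, `[`, "", 5L),
    tstart = as.integer(vapply(f, `[`, "", 8L)),
    tend = as.integer(vapply(f, `[`, "", 9L)),
    score = as.numeric(vapply(f, `[`, "", 10L))
  )
  # infer the start of the full query's alignment on the forward target
  pos <- ifelse(paf$strand == "+",
    paf$tstart - paf$qstart,
    paf$tstart - (paf$qlen - paf$qend)
  )
  if (circular) pos <- pos %% L
  res <- tibble(
    query = paf$query, ref_pos = as.integer(pos),
    strand = paf$strand, score = paf$score, primary = FALSE
  )
  res <- res[order(match(res$query, names(queries)), -res$score,
    res$strand, res$ref_pos), , drop = FALSE]
  res$primary <- !duplicated(res$query)
  if (!all_hits) res <- res[res$primary, , drop = FALSE]
  res
}
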