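# De novo satellite monomer discovery: quality filtering, subsampling,
# k-mer graph cycle detection, read masking, and the iterative
# mine-mask-repeat protocol.

#' Quality-filter reads
#'
#' A read is retained only if every base quality meets `quality_threshold`
#' and the sequence contains no N; when a read fails, its mate is dropped too
#' (whole-read drop rather than trimming keeps the fixed read length that
#' haplotype extraction relies on).
#'
#' @param reads read tibble (from [read_fastq_pairs()] or [simulate_reads()]).
#' @param quality_threshold minimum Phred score allowed at any base.
#' @return filtered read tibble.
#' @export
qc_filter <- function(reads, quality_threshold = 20L) {
  if (nrow(reads) == 0) return(reads)
  if (quality_threshold > 0) {
    # any character below the threshold in Phred+33 space
    bad_q <- grepl(sprintf("[\x21-%s]", intToUtf8(33L + quality_threshold - 1L)),
                   reads$qualities)
  } else {
    bad_q <- rep(FALSE, nrow(reads))
  }
  bad <- bad_q | grepl("N", reads$sequence, fixed = TRUE)
  if ("pair_id" %in% names(reads)) {
    bad_pairs <- unique(reads$pair_id[bad])
    reads[!(reads$pair_id %in% bad_pairs), , drop = FALSE]
  } else {
    reads[!bad, , drop = FALSE]
  }
}

#' Uniformly subsample read pairs without replacement
#'
#' If the library holds fewer pairs than requested, the whole library is
#' returned (with a logged notice). Pair order is preserved.
#'
#' @param reads read tibble with a `pair_id` column.
#' @param n_pairs pairs to draw.
#' @param seed integer seed.
#' @return subsampled read tibble.
#' @export
subsample_pairs <- function(reads, n_pairs, seed = 1L) {
  ids <- unique(reads$pair_id)
  if (length(ids) <= n_pairs) {
    if (length(ids) < n_pairs) {
      log_msg("subsample_pairs: library holds ", length(ids),
              " pairs < requested ", n_pairs, "; using all")
    }
    return(reads)
  }
  keep <- local_seed(seed, sample(ids, n_pairs))
  reads[reads$pair_id %in% keep, , drop = FALSE]
}

#' Detect candidate satellite monomers from a read subsample
#'
#' Builds the graph of canonical k-mers (count >= `min_kmer_count`, edges
#' between k-mers overlapping by k-1 weighted by co-occurrence in reads and
#' filtered at the same threshold), then within each connected component
#' searches for the maximum-mean-weight simple cycle by a greedy
#' highest-weight-first walk with backtracking bounded by the component size.
#' A tandem array of monomer length m yields a single cycle of exactly m
#' nodes regardless of k, and the cycle spells the array consensus; components
#' without a cycle (dispersed, non-tandem repeats) are discarded.
#'
#' @param reads read tibble.
#' @param k odd k-mer size.
#' @param min_kmer_count count threshold for nodes and edges.
#' @param min_cycle_length discard cycles shorter than this (default 6 bp,
#'   the shortest biologically reported repeat unit).
#' @param max_component_size components larger than this are skipped with a
#'   logged note (default 5000 nodes, room for monomers to ~2.8 kb plus
#'   variant bubbles): a clean tandem-repeat cycle has about one node per
#'   monomer base, so an oversized component signals a count threshold set
#'   below the background coverage, not a satellite.
#' @return tibble of class `sat_candidates`: `sequence` (one cycle traversal,
#'   not yet canonicalized), `length`, `support` (mean edge weight along the
#'   cycle), `component` (component index).
#' @export
detect_monomers <- function(reads, k = 21L, min_kmer_count = 5L,
                            min_cycle_length = 6L,
                            max_component_size = 5000L) {
  stopifnot(nrow(reads) > 0)
  g <- cpp_kmer_graph(reads$sequence, as.integer(k), as.integer(min_kmer_count))
  nodes <- g$nodes
  edges <- g$edges
  if (nrow(nodes) == 0 || nrow(edges) == 0) {
    return(empty_candidates())
  }
  ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = nodes$kmer)
  comp <- igraph::components(ig)$membership
  # edges per component: a connected component holds a cycle iff it has at
  # least as many edges as nodes, so acyclic (tree-like, dispersed-repeat)
  # components are dropped without walking them
  comp_edges <- table(comp[edges$from])

  ew <- new.env(parent = emptyenv(), size = nrow(edges))
  for (i in seq_len(nrow(edges))) {
    assign(paste(edges$from[i], edges$to[i], sep = "|"), edges$weight[i],
           envir = ew)
  }

  res <- list()
  # deterministic component order: by lexicographically smallest member k-mer
  comp_split <- split(names(comp), comp)
  ne <- as.integer(comp_edges[names(comp_split)])
  ne[is.na(ne)] <- 0L
  ord <- order(vapply(comp_split, min, character(1)))
  comp_split <- comp_split[ord]
  ne <- ne[ord]
  ci <- 0L
  n_skipped <- 0L
  for (members in comp_split) {
    ci <- ci + 1L
    if (ne[ci] < length(members)) next # acyclic
    if (length(members) > max_component_size) {
      n_skipped <- n_skipped + 1L
      next
    }
    cyc <- greedy_cycle(sort(members), k, ew)
    if (is.null(cyc) || cyc$length < min_cycle_length) next
    res[[length(res) + 1L]] <-
      tibble(sequence = cyc$sequence, length = cyc$length,
             support = cyc$support, component = ci)
  }
  if (n_skipped > 0) {
    log_msg("detect_monomers: skipped ", n_skipped, " component(s) above ",
            max_component_size, " nodes; min_kmer_count (", min_kmer_count,
            ") likely sits below the background k-mer coverage")
  }
  out <- if (length(res)) bind_rows(res) else empty_candidates()
  class(out) <- c("sat_candidates", class(out))
  out
}

empty_candidates <- function() {
  out <- tibble(sequence = character(), length = integer(),
                support = numeric(), component = integer())
  class(out) <- c("sat_candidates", class(out))
  out
}

# fast single-string reverse complement
rc1 <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

canon1 <- function(x) {
  y <- rc1(x)
  if (x <= y) x else y
}

# Greedy max-mean-weight simple cycle within one component. Nodes are
# canonical k-mers; traversal tracks oriented k-mers so the cycle can be
# spelled as a sequence. Starts are tried in lexicographic order; steps
# (forward moves + backtracks) are bounded by a multiple of component size.
greedy_cycle <- function(members, k, ew, step_factor = 50L) {
  in_comp <- new.env(parent = emptyenv(), size = length(members))
  for (m in members) assign(m, TRUE, envir = in_comp)
  edge_w <- function(a, b) {
    key <- if (a <= b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
    get0(key, envir = ew, ifnotfound = NA_real_)
  }
  successors <- function(x) {
    suf <- substring(x, 2L)
    ys <- paste0(suf, DNA_BASES)
    cx <- canon1(x)
    ws <- numeric(4)
    cys <- character(4)
    for (i in 1:4) {
      cys[i] <- canon1(ys[i])
      ws[i] <- if (get0(cys[i], envir = in_comp, ifnotfound = FALSE))
        edge_w(cx, cys[i]) else NA_real_
    }
    ok <- !is.na(ws)
    ys <- ys[ok]; ws <- ws[ok]; cys <- cys[ok]
    o <- order(-ws, ys)
    list(y = ys[o], w = ws[o], cy = cys[o])
  }

  budget <- step_factor * length(members)
  steps <- 0L
  for (start in members) {
    visited <- new.env(parent = emptyenv())
    assign(canon1(start), TRUE, envir = visited)
    frames <- list(list(node = start, alts = successors(start), i = 1L))
    path <- start
    while (length(frames) > 0L) {
      steps <- steps + 1L
      if (steps > budget) return(NULL)
      f <- frames[[length(frames)]]
      if (f$i > length(f$alts$y)) {
        # exhausted: backtrack
        frames[[length(frames)]] <- NULL
        if (length(frames) > 0L) rm(list = canon1(f$node), envir = visited)
        path <- path[-length(path)]
        next
      }
      y <- f$alts$y[f$i]
      cy <- f$alts$cy[f$i]
      frames[[length(frames)]]$i <- f$i + 1L
      if (y == start && length(path) >= 3L) {
        return(spell_cycle(path, k, edge_w))
      }
      if (!get0(cy, envir = visited, ifnotfound = FALSE)) {
        assign(cy, TRUE, envir = visited)
        frames[[length(frames) + 1L]] <- list(node = y, alts = successors(y),
                                              i = 1L)
        path <- c(path, y)
      }
    }
  }
  NULL
}

spell_cycle <- function(path, k, edge_w) {
  seq <- paste(substring(path, 1L, 1L), collapse = "")
  nxt <- c(path[-1L], path[1L])
  ws <- mapply(function(a, b) edge_w(canon1(a), canon1(b)), path, nxt)
  list(sequence = seq, length = nchar(seq), support = mean(ws))
}

#' Mask reads matching a set of monomers
#'
#' Each read is locally aligned (Smith-Waterman) against each monomer
#' dimerized (concatenated to itself, so hits can cross the arbitrary phase
#' boundary), both strands. A read is masked — removed from the working
#' library — when some alignment reaches `min_identity` over at least
#' `min_coverage` of the read; the best hit (highest identity, ties to the
#' lower monomer index) is credited with the aligned read bases.
#'
#' @param reads read tibble.
#' @param monomers character vector of monomer sequences, or a tibble with
#'   `name` and `sequence`.
#' @param min_identity,min_coverage masking thresholds.
#' @param seed_kmer exact shared k-mer prefilter length (0 = align all).
#' @return list with `unmasked` (retained reads), `masked_summary` (tibble:
#'   monomer, sex, n_reads, masked_bp) and `hits` (per-read best-hit table
#'   aligned with `reads` rows).
#' @export
mask_reads <- function(reads, monomers, min_identity = 0.8,
                       min_coverage = 0.5, seed_kmer = 12L) {
  seqs <- if (is.data.frame(monomers)) monomers$sequence else monomers
  nms <- if (is.data.frame(monomers)) monomers$name else
    sprintf("monomer%02d", seq_along(seqs))
  stopifnot("monomers must be non-empty" = length(seqs) > 0)
  dimers <- tile_reference(seqs, max(nchar(reads$sequence), 0L))
  hits <- as_tibble(cpp_best_hits(reads$sequence, dimers, min_identity,
                                  min_coverage, as.integer(seed_kmer)))
  masked <- !is.na(hits$hit)
  msum <- tibble(monomer = nms[hits$hit[masked]],
                 sex = reads$sex[masked],
                 masked_bp = hits$masked_bp[masked]) %>%
    group_by(.data$monomer, .data$sex) %>%
    summarise(n_reads = n(), masked_bp = sum(.data$masked_bp),
              .groups = "drop")
  list(unmasked = reads[!masked, , drop = FALSE],
       masked_summary = msum,
       hits = hits)
}

#' Iterative satellite mining (mine - mask - repeat)
#'
#' The discovery protocol: quality-filter both libraries, then repeatedly
#' (1) subsample pairs from what remains of each library, (2) mine the joint
#' male+female subsample for monomer candidates, (3) keep candidates that are
#' novel against everything found so far (rotation/strand-aware identity
#' below the variant threshold), (4) mask the full working libraries with the
#' cumulative catalog. Iteration stops when a round yields no novel candidate
#' or after `max_rounds` (with a warning if novelty was still appearing).
#'
#' @param reads_male,reads_female read tibbles.
#' @param config a [sat_config()].
#' @return list of class `sat_mining`: `candidates` (tibble with
#'   `round_found`), `rounds` (per-round report), `library_male`,
#'   `library_female` (QC-passed, fully masked libraries).
#' @export
iterate_mining <- function(reads_male, reads_female, config = sat_config()) {
  lib_m <- qc_filter(reads_male, config$quality_threshold)
  lib_f <- qc_filter(reads_female, config$quality_threshold)
  stopifnot("male library empty after QC" = nrow(lib_m) > 0,
            "female library empty after QC" = nrow(lib_f) > 0)

  catalog <- empty_candidates()
  catalog$round_found <- integer()
  rounds <- list()
  sub_seed <- derive_seed(config$seed, "subsample")

  for (round in seq_len(config$max_rounds)) {
    sub <- bind_rows(
      subsample_pairs(lib_m, config$subsample_pairs_discovery,
                      seed = sub_seed + 2L * round),
      subsample_pairs(lib_f, config$subsample_pairs_discovery,
                      seed = sub_seed + 2L * round + 1L)
    )
    cands <- detect_monomers(sub, config$kmer_size, config$min_kmer_count)
    novel <- keep_novel(cands, catalog$sequence,
                        config$identity_thresholds[["variant"]])
    rounds[[round]] <- tibble(
      round = round, candidates = nrow(cands), novel = nrow(novel),
      reads_male = nrow(lib_m), reads_female = nrow(lib_f)
    )
    log_msg("mining round ", round, ": ", nrow(cands), " candidates, ",
            nrow(novel), " novel")
    if (nrow(novel) == 0) break
    novel$round_found <- round
    catalog <- bind_rows(catalog, novel)
    lib_m <- mask_reads(lib_m, catalog$sequence, config$masking_min_identity,
                        config$masking_min_read_coverage,
                        config$seed_kmer)$unmasked
    lib_f <- mask_reads(lib_f, catalog$sequence, config$masking_min_identity,
                        config$masking_min_read_coverage,
                        config$seed_kmer)$unmasked
    if (round == config$max_rounds) {
      warning("max_rounds (", config$max_rounds,
              ") reached with novel candidates still appearing; ",
              "returning partial result")
    }
  }

  structure(list(candidates = catalog, rounds = bind_rows(rounds),
                 library_male = lib_m, library_female = lib_f),
            class = "sat_mining")
}

# candidates whose rotation/strand-aware identity to every known sequence
# (and every earlier candidate in this batch) stays below the threshold
keep_novel <- function(cands, known, threshold) {
  if (nrow(cands) == 0) return(cands)
  keep <- logical(nrow(cands))
  pool <- known
  for (i in seq_len(nrow(cands))) {
    s <- cands$sequence[i]
    is_novel <- !length(pool) ||
      all(vapply(pool, function(p) cpp_pair_identity(s, p), numeric(1)) <
            threshold)
    keep[i] <- is_novel
    if (is_novel) pool <- c(pool, s)
  }
  cands[keep, , drop = FALSE]
}
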