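# Shared fixtures and independent oracles, built in code at test time.

# deterministic random DNA under a local seed
fix_dna <- function(n, seed, gc = 0.5) {
  satmine:::local_seed(seed, random_dna(n, gc))
}

# substitute exactly k bases at evenly spaced positions (keeps identity exact
# and avoids chance local re-alignments)
spaced_subs <- function(seq, k) {
  m <- nchar(seq)
  pos <- round(seq(1, m, length.out = k + 2))[2:(k + 1)]
  s <- strsplit(seq, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  s[pos] <- rot[s[pos]]
  paste(s, collapse = "")
}

# error-free reads tiled across a tandem array of `copies` monomers
tandem_reads <- function(monomer, copies = 60, read_length = 60, step = 7,
                        sex = "male") {
  array <- strrep(monomer, copies)
  starts <- seq(1, nchar(array) - read_length + 1, by = step)
  tibble::tibble(
    pair_id = seq_along(starts), mate = 1L,
    id = sprintf("t%04d", seq_along(starts)),
    sequence = substring(array, starts, starts + read_length - 1L),
    qualities = strrep("I", read_length),
    sex = sex
  )
}

# wrap plain sequences as a read tibble
as_reads <- function(seqs, sex = "male", qual = NULL) {
  tibble::tibble(
    pair_id = seq_along(seqs), mate = 1L,
    id = sprintf("r%04d", seq_along(seqs)),
    sequence = seqs,
    qualities = qual %||% strrep("I", nchar(seqs)),
    sex = sex
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent MST oracle: enumerate every labelled spanning tree -------
# via Pruefer sequences (n^(n-2) trees for n nodes), return the minimum
# total weight. Feasible for n <= 6 (<= 1296 trees).
prufer_to_edges <- function(pr, n) {
  degree <- rep(1L, n)
  for (x in pr) degree[x] <- degree[x] + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  k <- 1L
  for (x in pr) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, x)
    k <- k + 1L
    degree[leaf] <- degree[leaf] - 1L
    degree[x] <- degree[x] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

brute_force_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1) return(0)
  if (n == 2) return(d[1, 2])
  prufers <- expand.grid(rep(list(seq_len(n)), n - 2L))
  best <- Inf
  for (i in seq_len(nrow(prufers))) {
    e <- prufer_to_edges(as.integer(prufers[i, ]), n)
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

# small two-satellite experiment reused by several tests
tiny_experiment <- function(seed = 11, error = 0, coverage = 6) {
  sats <- planted_satellites(
    name = c("tinyA", "tinyB"),
    monomer = c(fix_dna(80, 301, gc = 0.4), fix_dna(50, 302, gc = 0.45)),
    copies_autosomal = c(60L, 48L),
    per_copy_divergence = c(0.01, 0)
  )
  simulate_experiment(sats, genome_length = 150000,
                      params = read_sim_params(base_error_rate = error),
                      coverage = coverage, seed = seed)
}
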