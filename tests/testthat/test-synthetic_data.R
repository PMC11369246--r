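# The read/genome simulator and its exactly computable ground truth.

test_that("planted truth fractions are exact for autosomal and Y-linked arrays", {
  sats <- planted_satellites(
    name = c("autoSat", "ySat"),
    monomer = c(fix_dna(100, 21), fix_dna(100, 22)),
    copies_autosomal = c(50L, 0L),
    copies_y_linked = c(0L, 50L)
  )
  g <- build_genomes(sats, genome_length = 1e6, seed = 3)
  tr <- g$truth
  # 50 copies x 100 bp / 1 Mb
  expect_equal(tr$true_abundance_male, c(0.005, 0.005))
  expect_equal(tr$true_abundance_female, c(0.005, 0))
  expect_equal(tr$true_mf_ratio[1], 1)
  expect_true(tr$mf_infinite[2])
  expect_equal(nchar(g$male), 1e6)
  expect_equal(nchar(g$female), 1e6)
  # conservation: planted bp equals genome_length x summed abundance, per sex
  expect_equal(sum(tr$planted_bp_male), 1e6 * sum(tr$true_abundance_male))
  expect_equal(sum(tr$planted_bp_female), 1e6 * sum(tr$true_abundance_female))
  # sex design: the Y-only monomer leaves no trace in the female genome
  expect_equal(satmine:::cpp_shared_kmer_count(g$female, sats$monomer[2], 21L),
               0L)
})

test_that("per-copy divergence lands on target when copies are realigned", {
  mono <- fix_dna(100, 31)
  sats <- planted_satellites("divSat", mono, copies_autosomal = 200L,
                             per_copy_divergence = 0.02)
  g <- build_genomes(sats, genome_length = 4e5, seed = 7)
  arr <- g$arrays_female[g$arrays_female$name == "divSat", ]
  expect_equal(nrow(arr), 1L)
  array_seq <- substr(g$female, arr$start, arr$end)
  if (arr$strand == "-") array_seq <- satmine:::rc(array_seq)
  copies <- substring(array_seq, seq(1, 200 * 100, by = 100),
                      seq(100, 200 * 100, by = 100))
  mism <- satmine:::cpp_count_mismatches(copies, rep(mono, 200))
  mean_identity <- mean(1 - mism / 100)
  expect_equal(mean_identity, 0.98, tolerance = 0.005 / 0.98)
})

test_that("error-free reads are exact genome substrings with exact base totals", {
  g <- fix_dna(50000, 41)
  p <- read_sim_params(base_error_rate = 0)
  reads <- simulate_reads(g, p, n_pairs = 1000, "male", seed = 5)
  expect_equal(sum(nchar(reads$sequence)), 300000L)
  # reconstruct each read from its source coordinates
  expected <- ifelse(
    (reads$mate == 1) == (reads$strand == "+"),
    substring(g, reads$frag_start, reads$frag_start + 149L),
    satmine:::rc(substring(g, reads$frag_end - 149L, reads$frag_end))
  )
  expect_identical(reads$sequence, expected)
})

test_that("substitution errors match the configured rate", {
  g <- fix_dna(100000, 43)
  p <- read_sim_params(base_error_rate = 0.01)
  reads <- simulate_reads(g, p, n_pairs = 10000, "female", seed = 17)
  targets <- ifelse(
    (reads$mate == 1) == (reads$strand == "+"),
    substring(g, reads$frag_start, reads$frag_start + 149L),
    satmine:::rc(substring(g, reads$frag_end - 149L, reads$frag_end))
  )
  mism <- satmine:::cpp_count_mismatches(reads$sequence, targets)
  rate <- sum(mism) / sum(nchar(reads$sequence))
  expect_equal(rate, 0.01, tolerance = 0.001 / 0.01)
  expect_equal(sum(mism), sum(reads$n_errors))
})

test_that("read sampling is uniform: 5 kb windowed coverage CV below 0.15 at 10x", {
  # per-base coverage of independent 150 bp reads is Poisson (CV 1/sqrt(10)
  # at 10x by construction), and reads/mates correlate coverage over ~300 bp;
  # uniformity of the sampler is judged on 5 kb windows, where systematic
  # positional bias would survive averaging but sampling noise does not
  G <- 1e6
  g <- fix_dna(G, 47)
  p <- read_sim_params(base_error_rate = 0)
  reads <- simulate_reads(g, p, n_pairs = G * 10 / 300, "male", seed = 23)
  m1 <- reads[reads$mate == 1, ]
  r1s <- ifelse(m1$strand == "+", m1$frag_start, m1$frag_end - 149L)
  r2s <- ifelse(m1$strand == "+", m1$frag_end - 149L, m1$frag_start)
  starts <- c(r1s, r2s)
  d <- tabulate(starts, G + 1L) - tabulate(starts + 150L, G + 1L)
  cov <- cumsum(d)[seq_len(G)]
  expect_equal(mean(cov), 10, tolerance = 0.05)
  win <- vapply(split(cov[1:(5000 * floor(G / 5000))],
                      rep(seq_len(floor(G / 5000)), each = 5000)),
                mean, numeric(1))
  interior <- win[2:(length(win) - 1)]
  expect_lt(stats::sd(interior) / mean(interior), 0.15)
})

test_that("simulation is deterministic under a fixed seed", {
  a <- tiny_experiment(seed = 99)
  b <- tiny_experiment(seed = 99)
  expect_identical(a$reads_male, b$reads_male)
  expect_identical(a$genomes$female, b$genomes$female)
  c <- tiny_experiment(seed = 100)
  expect_false(identical(a$reads_male$sequence, c$reads_male$sequence))
})

test_that("simulator guards its preconditions", {
  sats <- planted_satellites("big", fix_dna(100, 51), copies_autosomal = 600L)
  expect_error(build_genomes(sats, genome_length = 1e5, seed = 1),
               "half the genome")
  expect_error(planted_satellites("s", "ACGT", 1L), "length")
  expect_error(planted_satellites("s", fix_dna(20, 1),
                                  copies_autosomal = 5L,
                                  per_copy_divergence = 0.5),
               "0.3")
  g <- fix_dna(1000, 52)
  expect_error(simulate_reads(g, read_sim_params(), 0, "male"), "n_pairs")
  expect_error(read_sim_params(base_error_rate = 0.2), "0.05")
  expect_error(read_sim_params(fragment_mean = 50), "read_length")
})

test_that("two-state quality model produces low-quality tails that QC drops", {
  g <- fix_dna(20000, 53)
  p <- read_sim_params(base_error_rate = 0, quality_model = "two_state",
                       tail_prob = 0.3, q_low = 10)
  reads <- simulate_reads(g, p, 500, "male", seed = 9)
  qmin <- vapply(reads$qualities, function(q) min(utf8ToInt(q)) - 33L,
                 integer(1), USE.NAMES = FALSE)
  expect_true(any(qmin == 10L))
  kept <- qc_filter(reads, 20L)
  expect_true(all(vapply(kept$qualities,
                         function(q) min(utf8ToInt(q)) - 33L >= 20L,
                         logical(1))))
})
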