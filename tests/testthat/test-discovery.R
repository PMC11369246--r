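# QC filtering, subsampling, k-mer-cycle monomer detection, read masking,
# and the iterative mining protocol.

test_that("QC keeps only reads with all bases at or above the threshold", {
  q40 <- strrep("I", 10)
  q_mixed <- paste0(strrep("I", 5), "+", strrep("I", 4)) # one base Q10
  reads <- tibble::tibble(
    pair_id = c(1L, 1L, 2L, 2L, 3L, 3L),
    mate = rep(c(1L, 2L), 3),
    id = sprintf("r%d", 1:6),
    sequence = c(rep(strrep("ACGTT", 2), 4), "ACGTNACGTA", strrep("AC", 5)),
    qualities = c(q40, q40, q_mixed, q40, q40, q40),
    sex = "male"
  )
  kept <- qc_filter(reads, 20L)
  # pair 2 lost to the low-quality base (mate dropped too), pair 3 to the N
  expect_equal(unique(kept$pair_id), 1L)
  expect_equal(nrow(kept), 2L)
  expect_equal(nrow(qc_filter(reads, 0L)), 4L) # only the N rule applies
})

test_that("QC retains exactly the pairs whose both mates are clean", {
  # library where ~10% of reads carry one low-quality base; oracle = direct
  # per-pair bookkeeping on the generated fixture
  n <- 500L
  qual <- satmine:::local_seed(77, {
    bad <- runif(2 * n) < 0.1
    ifelse(bad, paste0(strrep("I", 49), "+"), strrep("I", 50))
  })
  reads <- tibble::tibble(
    pair_id = rep(seq_len(n), each = 2), mate = rep(c(1L, 2L), n),
    id = sprintf("r%04d", seq_len(2 * n)),
    sequence = strrep("ACGTA", 10), qualities = qual, sex = "female"
  )
  clean_pairs <- sum(tapply(!grepl("+", qual, fixed = TRUE),
                            rep(seq_len(n), each = 2), all))
  expect_equal(nrow(qc_filter(reads, 20L)) / 2L, clean_pairs)
})

test_that("pair subsampling is uniform, seeded, and an identity when n = total", {
  reads <- as_reads(rep(strrep("ACGT", 10), 10))
  expect_identical(subsample_pairs(reads, 10L, seed = 1), reads)
  s1 <- subsample_pairs(reads, 5L, seed = 42)
  expect_identical(subsample_pairs(reads, 5L, seed = 42), s1)
  expect_equal(nrow(s1), 5L)
  # Monte-Carlo inclusion frequency of a fixed pair at half sampling
  hits <- vapply(seq_len(10000), function(s) {
    3L %in% subsample_pairs(reads, 5L, seed = s)$pair_id
  }, logical(1))
  expect_equal(mean(hits), 0.5, tolerance = 0.02 / 0.5)
})

test_that("a pure tandem array yields exactly one cycle spelling the monomer", {
  mono <- "ACGGTTACAGGTTCAATCGTGCAATCCGTAGGATCCTTAA" # 40 bp
  reads <- tandem_reads(mono, copies = 80, read_length = 60, step = 3)
  cand <- detect_monomers(reads, k = 15L, min_kmer_count = 5L)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$length, 40L)
  expect_identical(canonical_form(cand$sequence), canonical_form(mono))
  expect_gt(cand$support, 5)
})

test_that("non-repetitive reads produce no candidates at 1x coverage", {
  g <- fix_dna(20000, 61)
  reads <- simulate_reads(g, read_sim_params(base_error_rate = 0),
                          n_pairs = ceiling(20000 / 300), "male", seed = 3)
  cand <- detect_monomers(reads, k = 21L, min_kmer_count = 5L)
  expect_equal(nrow(cand), 0L)
})

test_that("k-mer counting agrees with a brute-force tally", {
  reads <- as_reads(vapply(1:20, function(i) fix_dna(60, 600 + i), ""))
  k <- 11L
  g <- satmine:::cpp_kmer_graph(reads$sequence, k, 1L)
  # dumb oracle: enumerate every k-mer of every read, canonicalize, tabulate
  all_kmers <- unlist(lapply(reads$sequence, function(s)
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))))
  canon <- pmin(all_kmers, satmine:::rc(all_kmers))
  tab <- sort(table(canon))
  expect_equal(nrow(g$nodes), length(tab))
  expect_equal(setNames(g$nodes$count[match(names(tab), g$nodes$kmer)],
                        names(tab)),
               setNames(as.integer(tab), names(tab)))
})

test_that("two satellites at ~60% identity give two components and candidates", {
  a <- fix_dna(60, 62, gc = 0.45)
  b <- spaced_subs(a, 24) # 60% identity to a
  expect_lt(pairwise_identity(a, b), 0.8)
  reads <- dplyr::bind_rows(tandem_reads(a, 60, 60, 4),
                            tandem_reads(b, 60, 60, 4))
  reads$pair_id <- seq_len(nrow(reads))
  cand <- detect_monomers(reads, k = 15L, min_kmer_count = 5L)
  expect_equal(nrow(cand), 2L)
  ids <- vapply(cand$sequence, function(s)
    max(pairwise_identity(s, a), pairwise_identity(s, b)), numeric(1))
  expect_true(all(ids == 1))
})

test_that("masking removes matching reads and credits their bases", {
  mono <- fix_dna(100, 63)
  exact <- substring(strrep(mono, 2), 41, 110) # exact 70 bp substring
  far <- spaced_subs(mono, 33)                 # ~67% identity, spaced
  bg <- fix_dna(70, 64)
  reads <- as_reads(c(exact, far, bg))
  res <- mask_reads(reads, mono, min_identity = 0.8, min_coverage = 0.5)
  expect_equal(nrow(res$unmasked), 2L)
  expect_false("r0001" %in% res$unmasked$id)
  expect_equal(res$masked_summary$masked_bp, 70L) # all 70 bases credited
  expect_equal(res$masked_summary$monomer, "monomer01")
})

test_that("masked base-pair fraction recovers a planted 1% satellite", {
  mono <- fix_dna(100, 65)
  sats <- planted_satellites("one", mono, copies_autosomal = 20L) # 2 kb / 200 kb
  g <- build_genomes(sats, 2e5, seed = 19)
  reads <- simulate_reads(g$female, read_sim_params(base_error_rate = 0),
                          n_pairs = round(2e5 * 10 / 300), "female", seed = 21)
  res <- mask_reads(reads, mono, 0.8, 0.5)
  frac <- sum(res$masked_summary$masked_bp) / sum(nchar(reads$sequence))
  expect_equal(frac, 0.01, tolerance = 0.002 / 0.01)
})

test_that("iterative mining terminates and masks monotonically", {
  sim <- tiny_experiment(seed = 31, error = 0.005)
  cfg <- sat_config(seed = 8, min_kmer_count = recommend_min_kmer_count(48 * 6),
                    subsample_pairs_discovery = 10000L)
  mining <- iterate_mining(sim$reads_male, sim$reads_female, cfg)
  # both planted satellites found in round 1, round 2 finds nothing new
  expect_equal(nrow(mining$rounds), 2L)
  expect_equal(mining$rounds$novel, c(2L, 0L))
  expect_equal(nrow(mining$candidates), 2L)
  expect_true(all(mining$candidates$round_found == 1L))
  # working library is non-increasing across rounds
  expect_true(all(diff(mining$rounds$reads_male) <= 0))
  expect_true(all(diff(mining$rounds$reads_female) <= 0))
  ids <- vapply(mining$candidates$sequence, function(s)
    max(vapply(sim$truth$monomer, function(m) pairwise_identity(s, m),
               numeric(1))), numeric(1))
  expect_true(all(ids >= 0.95))
})

test_that("a satellite-free genome terminates in one empty round", {
  g <- fix_dna(60000, 67)
  p <- read_sim_params(base_error_rate = 0)
  rm_ <- simulate_reads(g, p, 600, "male", seed = 1)
  rf_ <- simulate_reads(g, p, 600, "female", seed = 2)
  mining <- iterate_mining(rm_, rf_, sat_config(seed = 4, min_kmer_count = 10L))
  expect_equal(nrow(mining$rounds), 1L)
  expect_equal(nrow(mining$candidates), 0L)
})

test_that("five satellites across a 50-fold abundance range are all recovered", {
  lens <- c(100L, 80L, 60L, 40L, 20L)
  abund <- c(5, 1, 0.5, 0.2, 0.1) / 100
  G <- 3e5
  copies <- as.integer(round(abund * G / lens))
  sats <- planted_satellites(
    name = sprintf("five%02d", 1:5),
    monomer = vapply(seq_along(lens),
                     function(i) fix_dna(lens[i], 400 + i, gc = 0.42),
                     character(1)),
    copies_autosomal = copies,
    per_copy_divergence = 0.01
  )
  sim <- simulate_experiment(sats, G,
                             read_sim_params(base_error_rate = 0.005),
                             coverage = 5, seed = 77)
  cfg <- sat_config(seed = 5,
                    min_kmer_count = recommend_min_kmer_count(min(copies) * 2 * 5))
  mining <- iterate_mining(sim$reads_male, sim$reads_female, cfg)
  expect_lte(nrow(mining$rounds), 5L)
  expect_equal(nrow(mining$candidates), 5L)
  hit <- vapply(sats$monomer, function(m)
    any(vapply(mining$candidates$sequence, function(s)
      pairwise_identity(s, m) >= 0.95, logical(1))), logical(1))
  expect_true(all(hit))
})

test_that("detection is deterministic for identical input", {
  reads <- tandem_reads(fix_dna(50, 68), copies = 60, read_length = 60)
  c1 <- detect_monomers(reads, 15L, 5L)
  c2 <- detect_monomers(reads, 15L, 5L)
  expect_identical(c1, c2)
})
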