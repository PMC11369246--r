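# Kimura-2-parameter distances, abundance estimation, sex-bias calls,
# divergence landscapes.

test_that("K2P matches the closed form and rejects the invalid domain", {
  expect_equal(kimura_two_parameter(0, 0), 0)
  # frozen from an independent evaluation of -0.5*ln((1-2p-q)*sqrt(1-2q))
  expect_equal(kimura_two_parameter(0.1, 0.05), 0.1701811651, tolerance = 1e-8)
  # saturation: 1 - 2p - q <= 0
  expect_true(is.na(kimura_two_parameter(0.3, 0.45)))
  expect_true(is.na(kimura_two_parameter(0.25, 0.5)))
  expect_error(kimura_two_parameter(-0.1, 0), ">= 0")
  expect_error(kimura_two_parameter(0.9, 0.2), "exceed 1")
})

test_that("K2P is monotone in p and q and consistent with ape's estimator", {
  ps <- seq(0, 0.2, by = 0.02)
  expect_true(all(diff(kimura_two_parameter(ps, 0.05)) > 0))
  qs <- seq(0, 0.2, by = 0.02)
  expect_true(all(diff(kimura_two_parameter(0.03, qs)) > 0))

  # independent route: ape::dist.dna(model = "K80") on sequences built with
  # known transition/transversion counts
  a <- strsplit(fix_dna(300, 83), "")[[1]]
  b <- a
  b[1:30] <- c(A = "G", G = "A", C = "T", T = "C")[a[1:30]]    # 30 transitions
  b[101:115] <- c(A = "C", C = "A", G = "T", T = "G")[a[101:115]] # 15 transversions
  bin <- ape::as.DNAbin(rbind(a = a, b = b))
  expect_equal(kimura_two_parameter(30 / 300, 15 / 300),
               as.numeric(ape::dist.dna(bin, model = "K80")),
               tolerance = 1e-12)
})

test_that("abundance, M/F ratio and bias calls recover engineered libraries", {
  mono <- fix_dna(100, 84)
  sat_read <- function(n, off = 0) {
    vapply(seq_len(n), function(i)
      substring(strrep(mono, 3), 1 + ((i * 7 + off) %% 100), ((i * 7 + off) %% 100) + 100),
      character(1))
  }
  bg_m <- fix_dna(100 * 80, 85)
  bg_f <- fix_dna(100 * 90, 86)
  reads_m <- as_reads(c(sat_read(20), substring(bg_m, 0:79 * 100 + 1, 0:79 * 100 + 100)), "male")
  reads_f <- as_reads(c(sat_read(10, 3), substring(bg_f, 0:89 * 100 + 1, 0:89 * 100 + 100)), "female")
  q <- quantify(reads_m, reads_f, tibble::tibble(name = "sat", sequence = mono),
                sat_config(seed = 2, read_length = 100L,
                           mst_max_monomer_length = 100L))
  ab <- q$abundance
  expect_equal(ab$masked_bp_male, 2000L)
  expect_equal(ab$masked_bp_female, 1000L)
  # 2000 of 100 x 100 bp male bases, 1000 of the female bases
  expect_equal(ab$abundance_male, 0.2)
  expect_equal(ab$abundance_female, 0.1)
  expect_equal(ab$mf_ratio, 2.0)
  expect_equal(ab$bias_call, "male")
  # every error-free hit sits at distance zero
  expect_true(all(q$hits$k2p == 0))
})

test_that("an equal planted satellite is unbiased; a Y-only one is male-called", {
  sats <- planted_satellites(
    name = c("eq", "yonly"),
    monomer = c(fix_dna(80, 87), fix_dna(80, 88)),
    copies_autosomal = c(50L, 0L),
    copies_y_linked = c(0L, 50L)
  )
  sim <- simulate_experiment(sats, 2e5,
                             read_sim_params(base_error_rate = 0.005),
                             coverage = 10, seed = 13)
  q <- quantify(sim$reads_male, sim$reads_female, sats$monomer |>
                  (\(m) tibble::tibble(name = sats$name, sequence = m))(),
                sat_config(seed = 14))
  ab <- q$abundance
  # one contiguous 4 kb array sampled by ~280 reads per sex: the ratio's
  # sampling sd is ~12% at this problem size, well inside the 1.5 margin
  expect_equal(ab$mf_ratio[ab$name == "eq"], 1, tolerance = 0.3)
  expect_equal(ab$bias_call[ab$name == "eq"], "none")
  expect_equal(ab$abundance_female[ab$name == "yonly"], 0, tolerance = 1e-4)
  expect_true(ab$mf_infinite[ab$name == "yonly"] ||
                ab$mf_ratio[ab$name == "yonly"] > 10)
  expect_equal(ab$bias_call[ab$name == "yonly"], "male")
  # abundance within 20% relative of the exact planted truth
  tr <- sim$truth
  expect_equal(ab$abundance_male[ab$name == "eq"],
               tr$true_abundance_male[tr$name == "eq"], tolerance = 0.2)
})

test_that("landscapes conserve masked bp and sit at the planted divergence", {
  mono <- fix_dna(100, 89)
  sats <- planted_satellites("div5", mono, copies_autosomal = 60L,
                             per_copy_divergence = 0.05)
  sim <- simulate_experiment(sats, 2e5,
                             read_sim_params(base_error_rate = 0.002),
                             coverage = 8, seed = 23)
  q <- quantify(sim$reads_male, sim$reads_female,
                tibble::tibble(name = "div5", sequence = mono),
                sat_config(seed = 24))
  ls <- landscape_table(q)
  expect_s3_class(ls, "sat_landscape")
  expect_equal(sum(ls$masked_bp),
               sum(q$hits$masked_bp[!is.na(q$hits$k2p)]))
  expect_equal(sort(unique(ls$bin)), 0:50)
  mode_bin <- ls$bin[which.max(ls$masked_bp)]
  expect_gte(mode_bin, 4L)
  expect_lte(mode_bin, 7L)

  # degenerate inputs
  empty <- landscape_table(tibble::tibble(name = character(), sex = character(),
                                          masked_bp = integer(), k2p = numeric()))
  expect_equal(nrow(empty), 0L)
  zero <- landscape_table(tibble::tibble(name = "x", sex = "male",
                                         masked_bp = 500L, k2p = 0))
  expect_equal(zero$masked_bp[zero$bin == 0], 500L)
  expect_true(all(zero$masked_bp[zero$bin != 0] == 0))
})

test_that("read-count abundance mode is available behind a flag", {
  mono <- fix_dna(100, 90)
  reads_m <- as_reads(c(mono, mono, fix_dna(100, 91), fix_dna(100, 92)), "male")
  reads_f <- as_reads(c(mono, fix_dna(100, 93), fix_dna(100, 94), fix_dna(100, 95)), "female")
  q <- quantify(reads_m, reads_f, tibble::tibble(name = "s", sequence = mono),
                sat_config(seed = 1, read_length = 100L,
                           mst_max_monomer_length = 100L), unit = "reads")
  expect_equal(q$abundance$abundance_male, 0.5)
  expect_equal(q$abundance$abundance_female, 0.25)
})
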