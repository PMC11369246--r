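# Canonical forms, rotation-aware identity, homology tiers, catalog naming.

test_that("canonical form is the minimum over rotations and strands", {
  expect_equal(canonical_form("GAT"), "ATC")
  expect_equal(canonical_form("AAAA"), "AAAA")
  expect_error(canonical_form("ACGU"), "ACGT")

  # brute-force oracle: enumerate every rotation of both strands explicitly
  s <- fix_dna(200, 71)
  m <- nchar(s)
  rots <- substring(strrep(s, 2), 1:m, m:(2 * m - 1))
  rc_s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rots_rc <- substring(strrep(rc_s, 2), 1:m, m:(2 * m - 1))
  expect_equal(canonical_form(s), min(c(rots, rots_rc)))
  # invariance under rotation and strand flip of the input
  for (r in c(1, 57, 133)) {
    rotated <- paste0(substr(s, r + 1, m), substr(s, 1, r))
    expect_equal(canonical_form(rotated), canonical_form(s))
    expect_equal(canonical_form(satmine:::rc(rotated)), canonical_form(s))
  }
})

test_that("pairwise identity is phase- and strand-invariant and counts matches", {
  a <- fix_dna(100, 72)
  expect_equal(pairwise_identity(a, a), 1)
  rot <- paste0(substr(a, 31, 100), substr(a, 1, 30))
  expect_equal(pairwise_identity(a, rot), 1)
  expect_equal(pairwise_identity(a, satmine:::rc(rot)), 1)
  expect_equal(pairwise_identity(a, strrep(a, 2)), 1) # length mismatch

  mut <- spaced_subs(a, 10)
  expect_equal(pairwise_identity(a, mut), 0.90)
  # independent check: global alignment identity via Biostrings
  pa <- Biostrings::pairwiseAlignment(a, mut, type = "global")
  expect_equal(Biostrings::pid(pa) / 100, 0.90)
})

test_that("single linkage joins chains: AB and BC similar, AC less so", {
  a <- fix_dna(100, 73)
  b <- spaced_subs(a, 3)                    # 0.97 to a
  cc <- local({ # 3 fresh substitutions on b, clear of b's own (26/50/75)
    s <- strsplit(b, "")[[1]]
    rot <- c(A = "G", C = "A", G = "C", T = "G")
    s[c(2, 40, 99)] <- rot[s[c(2, 40, 99)]]
    paste(s, collapse = "")
  })
  expect_gte(pairwise_identity(a, b), 0.97)
  expect_gte(pairwise_identity(b, cc), 0.97)
  expect_lt(pairwise_identity(a, cc), 0.95)
  part <- build_partition(tibble::tibble(name = c("A", "B", "C"),
                                         sequence = c(a, b, cc)))
  expect_equal(length(unique(part$variant_id)), 1L)
})

test_that("planted pairs fall into the tier their identity dictates", {
  base <- fix_dna(100, 74, gc = 0.45)
  v85 <- spaced_subs(base, 15)
  v40 <- spaced_subs(base, 60)
  part <- build_partition(tibble::tibble(
    name = c("base", "v85", "v40"),
    sequence = c(base, v85, v40)
  ))
  p <- function(nm, col) part[[col]][part$name == nm]
  # 85%: same family, different variant groups
  expect_equal(p("base", "family_id"), p("v85", "family_id"))
  expect_false(p("base", "variant_id") == p("v85", "variant_id"))
  # 40%: not even the same superfamily
  expect_false(p("base", "superfamily") == p("v40", "superfamily"))
})

test_that("partitions nest, cover, and ignore input order", {
  set.seed(75)
  base1 <- fix_dna(120, 751)
  base2 <- fix_dna(80, 752)
  mono <- tibble::tibble(
    name = sprintf("m%02d", 1:6),
    sequence = c(base1, spaced_subs(base1, 10), spaced_subs(base1, 40),
                 base2, spaced_subs(base2, 6), fix_dna(100, 753)),
    abundance_male = c(0.05, 0.01, 0.005, 0.03, 0.002, 0.001),
    abundance_female = c(0.05, 0.01, 0.005, 0.03, 0.002, 0.001)
  )
  part <- build_partition(mono)
  expect_setequal(part$name, mono$name)
  # nesting: a variant group never straddles families, a family never
  # straddles superfamilies
  for (v in unique(part$variant_id)) {
    expect_equal(length(unique(part$family_id[part$variant_id == v])), 1L)
  }
  for (f in unique(part$family_id)) {
    expect_equal(length(unique(part$superfamily[part$family_id == f])), 1L)
  }
  # superfamily labels ordered by summed abundance: m01's group is SF1
  expect_equal(part$superfamily[part$name == "m01"], "SF1")
  # input order must not matter
  shuf <- mono[c(4, 2, 6, 1, 3, 5), ]
  part2 <- build_partition(shuf)
  expect_equal(part2[match(part$name, part2$name), ], part,
               ignore_attr = TRUE)
})

test_that("near-duplicate candidates merge keeping the best-supported form", {
  mono <- fix_dna(60, 76)
  rot <- paste0(substr(mono, 21, 60), substr(mono, 1, 20))
  cands <- tibble::tibble(
    sequence = c(mono, rot, fix_dna(50, 77)),
    length = nchar(sequence), support = c(10, 30, 5), component = 1:3
  )
  dd <- dedup_candidates(cands, 0.95)
  expect_equal(nrow(dd), 2L)
  # the rotation pair collapsed to one canonical sequence
  expect_true(canonical_form(mono) %in% dd$sequence)
  expect_equal(dd$support[dd$sequence == canonical_form(mono)], 30)
})

test_that("catalog naming follows decreasing abundance with filled descriptors", {
  s1 <- fix_dna(52, 78)
  s2 <- fix_dna(80, 79)
  cands <- tibble::tibble(sequence = c(s1, s2), length = nchar(sequence),
                          support = c(5, 5), component = 1:2)
  ab <- tibble::tibble(
    sequence = c(s1, s2),
    abundance_male = c(0.01, 0.03), abundance_female = c(0.01, 0.03)
  )
  cat <- finalize_catalog(cands, ab, sat_config(name_prefix = "DemoSat"))
  m <- cat$monomers
  expect_equal(m$name, c("DemoSat01", "DemoSat02"))
  # the more abundant sequence got the lower number
  expect_equal(m$sequence[1], canonical_form(s2))
  expect_equal(m$rul, nchar(m$sequence))
  expect_equal(m$at_fraction,
               vapply(m$sequence, function(s)
                 sum(strsplit(s, "")[[1]] %in% c("A", "T")) / nchar(s),
                 numeric(1), USE.NAMES = FALSE))
  expect_equal(m$mf_ratio, c(1, 1))
  expect_equal(m$bias_call, c("none", "none"))
})

test_that("catalog statistics summarise the monomer table", {
  mono <- tibble::tibble(
    name = sprintf("s%d", 1:4),
    sequence = c(strrep("AT", 60), fix_dna(40, 80, gc = 0.7),
                 fix_dna(150, 81, gc = 0.3), fix_dna(90, 82, gc = 0.5))
  )
  st <- catalog_stats(mono)
  expect_equal(st$n_monomers, 4L)
  expect_equal(st$rul_min, 40L)
  expect_equal(st$rul_max, 150L)
  expect_equal(st$rul_mean, mean(c(120, 40, 150, 90)))
  expect_equal(st$n_rul_gt100, 2L)
  expect_gte(st$n_at_rich, 2L)
})
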