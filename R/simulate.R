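# Synthetic genomes with planted tandem satellite arrays, and paired-end
# reads with exactly known ground truth.

#' Describe a set of satellites to plant
#'
#' Each row describes one satellite family: its monomer, how many head-to-tail
#' copies to plant on the autosomal background (present in both sexes) and how
#' many extra Y-linked copies (male genome only), and the expected per-copy
#' substitution divergence from the consensus.
#'
#' @param name character; unique family labels.
#' @param monomer DNA strings (length >= 6 bp each).
#' @param copies_autosomal,copies_y_linked integer copy counts (>= 0).
#' @param per_copy_divergence expected substitutions per site per copy, in
#'   \[0, 0.3\].
#' @param family_seed_of optional character; name of another planted satellite
#'   this one was derived from (bookkeeping for homology-tier tests).
#' @return tibble of class `sat_planted`.
#' @export
#' @examples
#' planted_satellites("SatA", strrep("ACGGT", 8), copies_autosomal = 50)
planted_satellites <- function(name, monomer, copies_autosomal,
                               copies_y_linked = 0L,
                               per_copy_divergence = 0,
                               family_seed_of = NA_character_) {
  x <- tibble(
    name = name, monomer = toupper(monomer),
    copies_autosomal = as.integer(copies_autosomal),
    copies_y_linked = as.integer(rep_len(copies_y_linked, length(name))),
    per_copy_divergence = rep_len(per_copy_divergence, length(name)),
    family_seed_of = rep_len(family_seed_of, length(name))
  )
  stopifnot(
    "satellite names must be unique" = !anyDuplicated(x$name),
    "monomers must be ACGT" = is_dna(x$monomer),
    "monomer length must be >= 6 bp" = all(nchar(x$monomer) >= 6),
    "copy counts must be >= 0" =
      all(x$copies_autosomal >= 0) && all(x$copies_y_linked >= 0),
    "per_copy_divergence must lie in [0, 0.3]" =
      all(x$per_copy_divergence >= 0 & x$per_copy_divergence <= 0.3)
  )
  class(x) <- c("sat_planted", class(x))
  x
}

#' Random DNA sequence with a given GC content
#' @param length sequence length in bp.
#' @param gc fraction of G+C.
#' @return a DNA string. Uses the current RNG stream.
#' @export
random_dna <- function(length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  idx <- sample.int(4L, length, replace = TRUE, prob = p)
  intToUtf8(c(65L, 67L, 71L, 84L)[idx])
}

# i.i.d. substitutions at the given per-site rate; no indels, so planted
# abundance and haplotype phase stay exactly computable
mutate_sequence <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  m <- nchar(seq)
  k <- rbinom(1L, m, divergence)
  if (k == 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(m, k)
  s[pos] <- vapply(s[pos],
                   function(b) sample(setdiff(DNA_BASES, b), 1L), character(1),
                   USE.NAMES = FALSE)
  paste(s, collapse = "")
}

#' The default study design: ten planted satellites
#'
#' A realistic desk-scale satellitome: abundances spanning 5 down to 0.1
#' percent of the genome, monomer lengths 20-300 bp (so every family keeps a
#' copy number of at least ~80, the hallmark of a satellite array), per-copy
#' divergence up to 2 percent, one family with a true male/female abundance
#' ratio of 3 (autosomal plus Y-linked extra copies) and one strictly Y-linked
#' family. Monomer sequences are drawn once from `seed`, slightly AT-rich as
#' typical of satellite DNA.
#'
#' @param genome_length genome size per sex in bp.
#' @param seed integer seed for monomer sequence generation.
#' @return a [planted_satellites()] tibble.
#' @export
default_planted_satellites <- function(genome_length = 2e6, seed = 101L) {
  lens <- c(300L, 250L, 200L, 170L, 150L, 120L, 90L, 60L, 50L, 20L)
  abund <- c(5, 3, 2, 1.5, 1, 0.7, 0.5, 0.3, 0.2, 0.1) / 100
  div <- c(0.01, 0.02, 0, 0.015, 0.01, 0.02, 0.01, 0.005, 0.02, 0.01)
  n <- length(lens)
  monomers <- local_seed(seed, {
    gc <- runif(n, 0.30, 0.50)
    vapply(seq_len(n), function(i) random_dna(lens[i], gc[i]), character(1))
  })
  copies <- as.integer(round(abund * genome_length / lens))
  aut <- copies
  y <- integer(n)
  # family 5 (1%): male carries 2x extra Y-linked copies -> true M/F = 3
  y[5] <- 2L * copies[5]
  # family 7 (0.5%): strictly Y-linked -> female abundance 0, M/F infinite
  y[7] <- copies[7]
  aut[7] <- 0L
  planted_satellites(
    name = sprintf("planted%02d", seq_len(n)),
    monomer = monomers,
    copies_autosomal = aut,
    copies_y_linked = y,
    per_copy_divergence = div
  )
}

#' Build male and female genomes with planted satellite arrays
#'
#' Both sexes share one random background and identical autosomal arrays (the
#' same independently mutated copies, as in a conspecific pair); Y-linked
#' arrays are additionally inserted into the male genome only. Arrays are
#' uninterrupted head-to-tail tandem runs placed at non-overlapping random
#' positions on random strands. Background sequence sharing a k-mer with any
#' planted monomer is redrawn, so k-mer-based discovery cannot be confounded
#' by chance collisions.
#'
#' @param satellites a [planted_satellites()] tibble.
#' @param genome_length genome size per sex in bp (each sex's genome is
#'   exactly this long).
#' @param gc_background background GC fraction.
#' @param seed integer seed.
#' @param screen_k k-mer size for the background collision screen (0 skips).
#' @param max_retries redraws allowed for the collision screen.
#' @return list with `male`, `female` (DNA strings); `truth`, a tibble of
#'   class `sat_truth` with exact planted base-pair fractions per sex and the
#'   true M/F ratio (`mf_infinite` flags division by a zero female fraction);
#'   and `arrays_male` / `arrays_female`, the final coordinates and strand of
#'   every planted array.
#' @export
build_genomes <- function(satellites, genome_length, gc_background = 0.5,
                          seed = 1L, screen_k = 21L, max_retries = 5L) {
  stopifnot(inherits(satellites, "sat_planted") || is.data.frame(satellites))
  sat <- satellites
  rul <- nchar(sat$monomer)
  bp_aut <- rul * sat$copies_autosomal
  bp_y <- rul * sat$copies_y_linked
  bp_female <- sum(bp_aut)
  bp_male <- sum(bp_aut) + sum(bp_y)
  if (max(bp_male, bp_female) >= genome_length / 2) {
    stop("planted satellite bp (", bp_male,
         ") must stay below half the genome length; increase genome_length")
  }

  local_seed(seed, {
    # arrays: one tandem run per (family, compartment), copies mutated i.i.d.
    arr_aut <- lapply(seq_len(nrow(sat)), function(i) {
      if (sat$copies_autosomal[i] == 0) return(NULL)
      paste(vapply(seq_len(sat$copies_autosomal[i]),
                   function(j) mutate_sequence(sat$monomer[i],
                                               sat$per_copy_divergence[i]),
                   character(1)), collapse = "")
    })
    arr_y <- lapply(seq_len(nrow(sat)), function(i) {
      if (sat$copies_y_linked[i] == 0) return(NULL)
      paste(vapply(seq_len(sat$copies_y_linked[i]),
                   function(j) mutate_sequence(sat$monomer[i],
                                               sat$per_copy_divergence[i]),
                   character(1)), collapse = "")
    })

    bg_len <- genome_length - min(bp_female, bp_male)
    bg_need <- max(genome_length - bp_female, genome_length - bp_male)
    background <- NULL
    for (try in seq_len(max_retries)) {
      cand <- random_dna(bg_need, gc_background)
      if (screen_k <= 0 ||
          cpp_shared_kmer_count(cand, sat$monomer, screen_k) == 0L) {
        background <- cand
        break
      }
    }
    if (is.null(background)) {
      stop("could not draw a background free of planted k-mers after ",
           max_retries, " tries; enlarge the genome or shorten the monomers")
    }

    aut_names <- sat$name[sat$copies_autosomal > 0]
    y_names <- sat$name[sat$copies_y_linked > 0]
    female <- insert_arrays(substr(background, 1L, genome_length - bp_female),
                            unlist(arr_aut), aut_names)
    male <- insert_arrays(substr(background, 1L, genome_length - bp_male),
                          c(unlist(arr_aut), unlist(arr_y)),
                          c(aut_names, y_names))
  })

  frac_male <- (bp_aut + bp_y) / genome_length
  frac_female <- bp_aut / genome_length
  truth <- tibble(
    name = sat$name,
    monomer = sat$monomer,
    rul = rul,
    copies_male = sat$copies_autosomal + sat$copies_y_linked,
    copies_female = sat$copies_autosomal,
    planted_bp_male = bp_aut + bp_y,
    planted_bp_female = bp_aut,
    true_abundance_male = frac_male,
    true_abundance_female = frac_female,
    true_mf_ratio = ifelse(frac_female > 0, frac_male / frac_female, Inf),
    mf_infinite = frac_female == 0 & frac_male > 0
  )
  class(truth) <- c("sat_truth", class(truth))
  list(male = male$genome, female = female$genome, truth = truth,
       arrays_male = male$arrays, arrays_female = female$arrays)
}

# splice arrays (shuffled, random strand) into the background at sorted
# random non-overlapping cut points; returns the genome and the final array
# coordinates so tests can recover every planted copy exactly
insert_arrays <- function(background, arrays, names = NULL) {
  names <- names %||% rep(NA_character_, length(arrays))
  if (length(arrays) == 0) {
    return(list(genome = background,
                arrays = tibble(name = character(), start = integer(),
                                end = integer(), strand = character())))
  }
  ord <- sample(length(arrays))
  arrays <- arrays[ord]
  names <- names[ord]
  flip <- runif(length(arrays)) < 0.5
  arrays[flip] <- rc(arrays[flip])
  nb <- nchar(background)
  cuts <- sort(sample.int(nb + 1L, length(arrays), replace = FALSE)) - 1L
  pieces <- substring(background, c(1L, cuts + 1L), c(cuts, nb))
  k <- length(arrays)
  starts <- cuts + c(0L, cumsum(nchar(arrays)))[seq_len(k)] + 1L
  genome <- paste0(paste0(pieces[-length(pieces)], arrays, collapse = ""),
                   pieces[length(pieces)])
  list(genome = genome,
       arrays = tibble(name = names, start = starts,
                       end = starts + nchar(arrays) - 1L,
                       strand = ifelse(flip, "-", "+")))
}

#' Read simulation parameters
#'
#' @param read_length mate length in bp (default 150).
#' @param fragment_mean,fragment_sd insert size distribution (normal, rounded,
#'   clamped to \[read_length, genome length\]).
#' @param base_error_rate i.i.d. substitution error rate per base, in
#'   \[0, 0.05\].
#' @param quality_model `"constant"` (every base `q_high`) or `"two_state"`
#'   (high-quality body, a low-quality tail of `tail_length` bases at `q_low`
#'   on a fraction `tail_prob` of reads — the classic degrading-3'-end
#'   pattern that the Q>=20 filter is meant to catch).
#' @param q_high,q_low,tail_prob,tail_length two-state model knobs.
#' @return list of class `sat_read_sim_params`.
#' @export
read_sim_params <- function(read_length = 150L, fragment_mean = 400,
                            fragment_sd = 60, base_error_rate = 0.01,
                            quality_model = c("constant", "two_state"),
                            q_high = 37L, q_low = 12L, tail_prob = 0.1,
                            tail_length = 15L) {
  quality_model <- match.arg(quality_model)
  stopifnot(
    "read_length must be positive" = read_length > 0,
    "fragment_mean must be >= read_length" = fragment_mean >= read_length,
    "base_error_rate must lie in [0, 0.05]" =
      base_error_rate >= 0 && base_error_rate <= 0.05,
    "qualities must lie in [0, 60]" =
      q_high >= 0 && q_high <= 60 && q_low >= 0 && q_low <= 60
  )
  structure(list(read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 base_error_rate = base_error_rate,
                 quality_model = quality_model, q_high = as.integer(q_high),
                 q_low = as.integer(q_low), tail_prob = tail_prob,
                 tail_length = as.integer(tail_length)),
            class = "sat_read_sim_params")
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly along the genome with normal lengths; mate 1
#' is the fragment start, mate 2 the reverse complement of the fragment end
#' (FR orientation, fragment strand random). Substitution errors are i.i.d.
#' at `params$base_error_rate`. Source coordinates are kept on every read so
#' tests can realign reads to their origin exactly.
#'
#' @param genome DNA string.
#' @param params a [read_sim_params()] object.
#' @param n_pairs number of read pairs (> 0).
#' @param sex_label `"male"` or `"female"`.
#' @param seed integer seed.
#' @return tibble with `pair_id`, `mate`, `id`, `sequence`, `qualities`,
#'   `sex`, plus truth columns `frag_start`, `frag_end`, `strand`, `n_errors`.
#' @export
simulate_reads <- function(genome, params, n_pairs, sex_label = c("male", "female"),
                           seed = 1L) {
  sex_label <- match.arg(sex_label)
  stopifnot("genome must be non-empty" = nchar(genome) > 0,
            "n_pairs must be > 0" = n_pairs > 0)
  G <- nchar(genome)
  rl <- params$read_length
  stopifnot("genome shorter than read_length" = G >= rl)

  local_seed(seed, {
    frag <- pmin(pmax(round(rnorm(n_pairs, params$fragment_mean,
                                  params$fragment_sd)), rl), G)
    start <- 1L + floor(runif(n_pairs) * (G - frag + 1))
    end <- start + frag - 1L
    strand <- ifelse(runif(n_pairs) < 0.5, "+", "-")
    left <- substring(genome, start, start + rl - 1L)
    right <- rc(substring(genome, end - rl + 1L, end))
    r1 <- ifelse(strand == "+", left, right)
    r2 <- ifelse(strand == "+", right, left)

    e1 <- add_read_errors(r1, params$base_error_rate)
    e2 <- add_read_errors(r2, params$base_error_rate)
    q1 <- make_qualities(n_pairs, rl, params)
    q2 <- make_qualities(n_pairs, rl, params)
  })

  base_id <- sprintf("%s_%07d", substr(sex_label, 1, 1), seq_len(n_pairs))
  out <- bind_rows(
    tibble(pair_id = seq_len(n_pairs), mate = 1L,
           id = paste0(base_id, "/1"), sequence = e1$seqs, qualities = q1,
           sex = sex_label, frag_start = start, frag_end = end,
           strand = strand, n_errors = e1$n_err),
    tibble(pair_id = seq_len(n_pairs), mate = 2L,
           id = paste0(base_id, "/2"), sequence = e2$seqs, qualities = q2,
           sex = sex_label, frag_start = start, frag_end = end,
           strand = strand, n_errors = e2$n_err)
  )
  arrange(out, .data$pair_id, .data$mate)
}

add_read_errors <- function(seqs, rate) {
  n_err <- integer(length(seqs))
  if (rate > 0 && length(seqs)) {
    L <- nchar(seqs)
    n_err <- rbinom(length(seqs), L, rate)
    for (i in which(n_err > 0)) {
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(L[i], n_err[i])
      s[pos] <- vapply(s[pos],
                       function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1), USE.NAMES = FALSE)
      seqs[i] <- paste(s, collapse = "")
    }
  }
  list(seqs = seqs, n_err = n_err)
}

make_qualities <- function(n, rl, params) {
  hi <- intToUtf8(params$q_high + 33L)
  if (params$quality_model == "constant") {
    return(rep(strrep(hi, rl), n))
  }
  lo <- intToUtf8(params$q_low + 33L)
  tl <- pmin(params$tail_length, rl)
  has_tail <- runif(n) < params$tail_prob
  ifelse(has_tail,
         paste0(strrep(hi, rl - tl), strrep(lo, tl)),
         strrep(hi, rl))
}

#' Simulate a full two-sex sequencing experiment
#'
#' Convenience wrapper: builds both genomes and draws the number of pairs per
#' sex implied by `coverage`.
#'
#' @inheritParams build_genomes
#' @param params a [read_sim_params()] object.
#' @param coverage fold sequencing depth per sex.
#' @return list with `reads_male`, `reads_female` (read tibbles), `truth`,
#'   and `genomes`.
#' @export
simulate_experiment <- function(satellites, genome_length, params = read_sim_params(),
                                coverage = 10, gc_background = 0.5, seed = 1L) {
  g <- build_genomes(satellites, genome_length, gc_background = gc_background,
                     seed = derive_seed(seed, "simulate"))
  n_pairs <- max(1L, round(genome_length * coverage / (2 * params$read_length)))
  rm_ <- simulate_reads(g$male, params, n_pairs, "male",
                        seed = derive_seed(seed, "simulate") + 1L)
  rf_ <- simulate_reads(g$female, params, n_pairs, "female",
                        seed = derive_seed(seed, "simulate") + 2L)
  list(reads_male = rm_, reads_female = rf_, truth = g$truth, genomes = g)
}
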