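# Per-sex abundance by read masking, Kimura-2-parameter divergence
# landscapes, and male/female bias calls.

#' Kimura two-parameter distance
#'
#' `K = -1/2 * ln((1 - 2p - q) * sqrt(1 - 2q))` where `p` is the transition
#' and `q` the transversion fraction of aligned sites. Vectorized. Outside
#' the model's domain (`1 - 2p - q <= 0` or `1 - 2q <= 0`) the distance is
#' undefined (substitution saturation) and `NA` is returned; callers exclude
#' such hits and keep a counter.
#'
#' @param p transition fraction (>= 0).
#' @param q transversion fraction (>= 0).
#' @return numeric distances; `NA` where undefined.
#' @export
#' @examples
#' kimura_two_parameter(0, 0)        # 0
#' kimura_two_parameter(0.1, 0.05)   # 0.1701812
kimura_two_parameter <- function(p, q) {
  stopifnot("p and q must be >= 0" = all(p >= 0) && all(q >= 0),
            "p + q cannot exceed 1" = all(p + q <= 1))
  n <- max(length(p), length(q))
  p <- rep_len(p, n)
  q <- rep_len(q, n)
  d1 <- 1 - 2 * p - q
  d2 <- 1 - 2 * q
  out <- rep(NA_real_, length(d1))
  ok <- d1 > 0 & d2 > 0
  out[ok] <- -0.5 * log(d1[ok] * sqrt(d2[ok]))
  out
}

#' Quantify satellite abundance and divergence per sex
#'
#' Quality-filters and subsamples each sex's library, aligns every read
#' against each dimerized catalog monomer (both strands, as in
#' [mask_reads()]), and from each best hit records the masked base pairs and
#' the transition/transversion fractions feeding the Kimura two-parameter
#' distance. Abundance is the masked-bp fraction of the subsampled library
#' (robust to partial-read hits; set `unit = "reads"` for the plain
#' read-count fraction). A monomer is called male-biased when
#' M/F > `config$mf_bias_ratio`, female-biased when below the reciprocal.
#'
#' @param reads_male,reads_female read tibbles.
#' @param catalog a `sat_catalog`, a tibble with `name` + `sequence`, or a
#'   character vector of monomer sequences.
#' @param config a [sat_config()].
#' @param unit `"bp"` (masked-bp fraction, default) or `"reads"` (fraction of
#'   reads with a hit).
#' @return object of class `sat_quant`: list with
#'   * `abundance`: tibble (`name`, `sequence`, masked/library bp per sex,
#'     `abundance_male`, `abundance_female`, `mf_ratio`, `mf_infinite`,
#'     `bias_call`),
#'   * `hits`: per-hit tibble (`name`, `sex`, `masked_bp`, `p`, `q`, `k2p`),
#'   * `n_saturated`: hits excluded for undefined K2P.
#' @export
quantify <- function(reads_male, reads_female, catalog,
                     config = sat_config(), unit = c("bp", "reads")) {
  unit <- match.arg(unit)
  cat_tbl <- as_catalog_tbl(catalog)
  stopifnot("catalog must be non-empty" = nrow(cat_tbl) > 0)

  qseed <- derive_seed(config$seed, "quantify")
  prep <- function(reads, off) {
    subsample_pairs(qc_filter(reads, config$quality_threshold),
                    config$subsample_pairs_discovery, seed = qseed + off)
  }
  sub_m <- prep(reads_male, 0L)
  sub_f <- prep(reads_female, 1L)

  dimers <- tile_reference(cat_tbl$sequence, config$read_length)
  hit_tbl <- function(sub, sex) {
    h <- as_tibble(cpp_best_hits(sub$sequence, dimers,
                                 config$masking_min_identity,
                                 config$masking_min_read_coverage,
                                 config$seed_kmer))
    h <- h[!is.na(h$hit), , drop = FALSE]
    tibble(name = cat_tbl$name[h$hit], sex = sex,
           masked_bp = h$masked_bp,
           p = ifelse(h$pairs > 0, h$transitions / h$pairs, 0),
           q = ifelse(h$pairs > 0, h$transversions / h$pairs, 0))
  }
  hits <- bind_rows(hit_tbl(sub_m, "male"), hit_tbl(sub_f, "female"))
  hits$k2p <- if (nrow(hits)) kimura_two_parameter(hits$p, hits$q) else numeric()
  n_sat <- sum(is.na(hits$k2p))

  lib_bp <- c(male = sum(nchar(sub_m$sequence)),
              female = sum(nchar(sub_f$sequence)))
  lib_n <- c(male = nrow(sub_m), female = nrow(sub_f))

  agg <- hits %>%
    group_by(.data$name, .data$sex) %>%
    summarise(masked_bp = sum(.data$masked_bp), n_reads = n(),
              .groups = "drop")
  full <- tidyr::expand_grid(name = cat_tbl$name, sex = c("male", "female")) %>%
    left_join(agg, by = c("name", "sex")) %>%
    mutate(masked_bp = ifelse(is.na(.data$masked_bp), 0L, .data$masked_bp),
           n_reads = ifelse(is.na(.data$n_reads), 0L, .data$n_reads),
           library_bp = unname(lib_bp[.data$sex]),
           library_reads = unname(lib_n[.data$sex]),
           abundance = if (unit == "bp") .data$masked_bp / .data$library_bp
                       else .data$n_reads / .data$library_reads)

  ab <- full %>%
    tidyr::pivot_wider(id_cols = "name",
                       names_from = "sex",
                       values_from = c("masked_bp", "library_bp", "abundance")) %>%
    mutate(
      sequence = cat_tbl$sequence[match(.data$name, cat_tbl$name)],
      mf_infinite = .data$abundance_female == 0 & .data$abundance_male > 0,
      mf_ratio = ifelse(.data$abundance_female > 0,
                        .data$abundance_male / .data$abundance_female,
                        ifelse(.data$mf_infinite, Inf, NA_real_)),
      bias_call = mf_bias_call(.data$abundance_male, .data$abundance_female,
                               config$mf_bias_ratio)
    ) %>%
    select("name", "sequence", "masked_bp_male", "masked_bp_female",
           "library_bp_male", "library_bp_female", "abundance_male",
           "abundance_female", "mf_ratio", "mf_infinite", "bias_call")
  ab <- ab[match(cat_tbl$name, ab$name), , drop = FALSE]

  structure(list(abundance = ab, hits = hits, n_saturated = n_sat,
                 library_bp = lib_bp, unit = unit),
            class = "sat_quant")
}

as_catalog_tbl <- function(catalog) {
  if (inherits(catalog, "sat_catalog")) {
    catalog$monomers[, c("name", "sequence")]
  } else if (is.data.frame(catalog)) {
    stopifnot(all(c("name", "sequence") %in% names(catalog)))
    catalog[, c("name", "sequence")]
  } else {
    tibble(name = names(catalog) %||%
             sprintf("monomer%02d", seq_along(catalog)),
           sequence = unname(catalog))
  }
}

#' @export
print.sat_quant <- function(x, ...) {
  cat("<sat_quant> ", nrow(x$abundance), " monomers; library bp M/F ",
      x$library_bp[["male"]], "/", x$library_bp[["female"]],
      if (x$n_saturated) paste0("; ", x$n_saturated, " saturated hits dropped"),
      "\n", sep = "")
  print(x$abundance, ...)
  invisible(x)
}

#' Divergence landscape table
#'
#' Bins each monomer's masked base pairs by the Kimura two-parameter distance
#' of the hit they came from: 1-percent-wide bins from 0 to 50 percent (the
#' final bin collects any saturated-but-defined hits beyond 50). Base pairs
#' are conserved: each monomer's bins sum to its masked bp over the hits with
#' a defined distance.
#'
#' @param quant a `sat_quant` object, or its `hits` tibble.
#' @param by_sex keep male/female separate (default pools them).
#' @return tibble of class `sat_landscape`: `name`, (`sex`,) `bin` (lower
#'   bound, percent), `masked_bp` — every bin present for every monomer.
#' @export
landscape_table <- function(quant, by_sex = FALSE) {
  hits <- if (inherits(quant, "sat_quant")) quant$hits else quant
  bins <- 0:50
  if (nrow(hits) == 0) {
    out <- tibble(name = character(), bin = integer(), masked_bp = integer())
    class(out) <- c("sat_landscape", class(out))
    return(out)
  }
  h <- hits[!is.na(hits$k2p), , drop = FALSE]
  h$bin <- pmin(floor(h$k2p * 100), 50L)
  keys <- if (by_sex) c("name", "sex") else "name"
  agg <- h %>%
    group_by(across(dplyr::all_of(c(keys, "bin")))) %>%
    summarise(masked_bp = sum(.data$masked_bp), .groups = "drop")
  grid <- tidyr::expand_grid(dplyr::distinct(h[, keys, drop = FALSE]),
                             bin = bins)
  out <- grid %>%
    left_join(agg, by = c(keys, "bin")) %>%
    mutate(masked_bp = ifelse(is.na(.data$masked_bp), 0, .data$masked_bp)) %>%
    arrange(across(dplyr::all_of(keys)), .data$bin)
  class(out) <- c("sat_landscape", class(out))
  out
}
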