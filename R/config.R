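#' Run configuration
#'
#' Bundles every tunable of the pipeline with validated defaults. All
#' randomness in a run flows from `seed`; two runs with equal configuration
#' and inputs produce identical outputs.
#'
#' @param seed integer; master seed for the run.
#' @param read_length integer bp; length of each mate (default 150, standard
#'   short-read libraries).
#' @param subsample_pairs_discovery integer; read pairs subsampled per sex for
#'   each discovery round and for abundance estimation (default 500000).
#' @param subsample_pairs_haplonet integer; read pairs subsampled per sex for
#'   haplotype extraction (default 5e6).
#' @param quality_threshold integer Phred; a read is kept only if every base
#'   quality is at least this (default 20) and it contains no N.
#' @param kmer_size odd integer, k for the discovery k-mer graph (default 21).
#' @param min_kmer_count integer; k-mers (and graph edges) below this count are
#'   dropped. Default 5; see [recommend_min_kmer_count()] for a coverage-aware
#'   choice.
#' @param masking_min_identity,masking_min_read_coverage fractions; a read is
#'   masked when some monomer alignment reaches this identity over at least
#'   this fraction of the read (defaults 0.80 / 0.50).
#' @param identity_thresholds named numeric: `variant`, `family`,
#'   `superfamily` lower identity bounds for the nested homology tiers
#'   (defaults 0.95 / 0.80 / 0.50); must be strictly decreasing.
#' @param mf_bias_ratio float; a monomer is called male-biased when its
#'   male/female abundance ratio exceeds this, female-biased when below its
#'   reciprocal. Default 1.5 (a margin against sampling noise); set to 1.0 for
#'   the strict rule that any excess counts.
#' @param mst_max_monomer_length integer bp; monomers longer than this are
#'   excluded from haplotype network analysis (default 150, the read length:
#'   a full monomer copy must fit inside one read).
#' @param min_haplotype_count integer; haplotypes seen fewer times (both sexes
#'   pooled) are dropped as putative sequencing errors (default 2: singletons
#'   removed).
#' @param min_identity_for_extraction fraction; minimum full-read identity for
#'   a read to contribute a haplotype (default 0.8).
#' @param max_rounds integer; cap on discovery iterations (default 10).
#' @param name_prefix character; stem for catalog names (default "Sat").
#' @param seed_kmer integer; exact shared k-mer length used to prefilter
#'   read-monomer alignments (default 12; 0 disables the prefilter and aligns
#'   every read against every monomer).
#'
#' @return A validated list of class `sat_config`.
#' @export
#' @examples
#' cfg <- sat_config(seed = 1, kmer_size = 21)
#' cfg$identity_thresholds
sat_config <- function(seed = 1L,
                       read_length = 150L,
                       subsample_pairs_discovery = 500000L,
                       subsample_pairs_haplonet = 5000000L,
                       quality_threshold = 20L,
                       kmer_size = 21L,
                       min_kmer_count = 5L,
                       masking_min_identity = 0.80,
                       masking_min_read_coverage = 0.50,
                       identity_thresholds = c(variant = 0.95, family = 0.80,
                                               superfamily = 0.50),
                       mf_bias_ratio = 1.5,
                       mst_max_monomer_length = 150L,
                       min_haplotype_count = 2L,
                       min_identity_for_extraction = 0.8,
                       max_rounds = 10L,
                       name_prefix = "Sat",
                       seed_kmer = 12L) {
  cfg <- list(
    seed = as.integer(seed),
    read_length = as.integer(read_length),
    subsample_pairs_discovery = as.integer(subsample_pairs_discovery),
    subsample_pairs_haplonet = as.integer(subsample_pairs_haplonet),
    quality_threshold = as.integer(quality_threshold),
    kmer_size = as.integer(kmer_size),
    min_kmer_count = as.integer(min_kmer_count),
    masking_min_identity = masking_min_identity,
    masking_min_read_coverage = masking_min_read_coverage,
    identity_thresholds = identity_thresholds,
    mf_bias_ratio = mf_bias_ratio,
    mst_max_monomer_length = as.integer(mst_max_monomer_length),
    min_haplotype_count = as.integer(min_haplotype_count),
    min_identity_for_extraction = min_identity_for_extraction,
    max_rounds = as.integer(max_rounds),
    name_prefix = name_prefix,
    seed_kmer = as.integer(seed_kmer)
  )
  validate_sat_config(cfg)
  structure(cfg, class = "sat_config")
}

validate_sat_config <- function(cfg) {
  th <- cfg$identity_thresholds
  stopifnot(
    "seed must be a finite integer" = is.finite(cfg$seed),
    "subsample sizes must be >= 1" =
      cfg$subsample_pairs_discovery >= 1 && cfg$subsample_pairs_haplonet >= 1,
    "kmer_size must be odd and >= 3" =
      cfg$kmer_size >= 3 && cfg$kmer_size %% 2 == 1,
    "kmer_size must be <= 31" = cfg$kmer_size <= 31,
    "min_kmer_count must be >= 1" = cfg$min_kmer_count >= 1,
    "quality_threshold must be >= 0" = cfg$quality_threshold >= 0,
    "identity_thresholds needs variant/family/superfamily" =
      all(c("variant", "family", "superfamily") %in% names(th)),
    "thresholds must lie in (0, 1]" =
      all(th > 0 & th <= 1) &&
      cfg$masking_min_identity > 0 && cfg$masking_min_identity <= 1 &&
      cfg$masking_min_read_coverage > 0 && cfg$masking_min_read_coverage <= 1,
    "tiers must satisfy variant > family > superfamily" =
      th[["variant"]] > th[["family"]] && th[["family"]] > th[["superfamily"]],
    "mf_bias_ratio must be >= 1" = cfg$mf_bias_ratio >= 1,
    "read_length must be positive" = cfg$read_length > 0,
    "mst_max_monomer_length cannot exceed read_length" =
      cfg$mst_max_monomer_length <= cfg$read_length
  )
  invisible(cfg)
}

#' @export
print.sat_config <- function(x, ...) {
  cat("<sat_config>\n")
  flat <- x
  flat$identity_thresholds <-
    paste(names(x$identity_thresholds), x$identity_thresholds,
          sep = "=", collapse = " ")
  for (nm in names(flat)) cat(sprintf("  %-28s %s\n", nm, flat[[nm]]))
  invisible(x)
}

#' Coverage-aware k-mer count threshold
#'
#' Picks the discovery count threshold as a quarter of the expected k-mer
#' coverage of the rarest satellite of interest (floored at 5), which places it
#' well above single-copy background coverage while tolerating the k-mer loss
#' caused by copy divergence and sequencing error.
#'
#' @param expected_min_coverage expected k-mer coverage of the least covered
#'   satellite: roughly copy number times per-sex read depth.
#' @return integer threshold.
#' @export
#' @examples
#' recommend_min_kmer_count(1000) # 250
recommend_min_kmer_count <- function(expected_min_coverage) {
  as.integer(max(5, ceiling(0.25 * expected_min_coverage)))
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @param cfg a [sat_config()] object.
#' @return `read_config()` returns a `sat_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$identity_thresholds))
    raw$identity_thresholds <- unlist(raw$identity_thresholds)
  do.call(sat_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$identity_thresholds <- as.list(out$identity_thresholds)
  yaml::write_yaml(out, path)
  invisible(path)
}
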