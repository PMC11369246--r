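# End-to-end orchestration: simulate -> discover -> catalog -> quantify ->
# haplotype networks, with a run manifest and (on synthetic input) an
# evaluation against the planted truth.

#' Run the whole satellitome pipeline
#'
#' Executes the stages in order on either a synthetic design (pass
#' `satellites`; genomes and reads are generated with exactly known truth) or
#' user-supplied read tibbles. Stage randomness is derived deterministically
#' from `config$seed` (see [derive_seed()]), so a rerun with the same
#' configuration and inputs is byte-identical.
#'
#' @param config a [sat_config()].
#' @param satellites optional [planted_satellites()] design; when given,
#'   reads are simulated and the result carries an evaluation against truth.
#' @param genome_length,sim_params,coverage,gc_background simulation knobs
#'   (used only with `satellites`).
#' @param reads_male,reads_female read tibbles (used when `satellites` is
#'   `NULL`).
#' @param truth optional `sat_truth` tibble when supplying reads that came
#'   from a known design.
#' @param build_msts build haplotype networks for catalog monomers short
#'   enough for the analysis (default TRUE).
#' @param out_dir optional directory; when given, all artifacts (catalog
#'   FASTA/TSV, abundance and landscape tables, GraphML networks, per-round
#'   report, evaluation, JSON manifest) are written there.
#' @return object of class `sat_run`: list with `catalog`, `quant`,
#'   `landscape`, `haplonets`, `mining`, `evaluation` (NULL without truth),
#'   `truth`, `manifest`.
#' @export
run_satellitome <- function(config = sat_config(),
                            satellites = NULL,
                            genome_length = 2e6,
                            sim_params = read_sim_params(),
                            coverage = 10,
                            gc_background = 0.5,
                            reads_male = NULL, reads_female = NULL,
                            truth = NULL,
                            build_msts = TRUE,
                            out_dir = NULL) {
  validate_sat_config(config)
  if (!is.null(satellites)) {
    log_msg("stage simulate: ", nrow(satellites), " planted satellites, ",
            genome_length, " bp per sex, ", coverage, "x")
    sim <- simulate_experiment(satellites, genome_length, sim_params,
                               coverage = coverage,
                               gc_background = gc_background,
                               seed = config$seed)
    reads_male <- sim$reads_male
    reads_female <- sim$reads_female
    truth <- sim$truth
  }
  stopifnot(!is.null(reads_male), !is.null(reads_female))

  log_msg("stage discover")
  mining <- iterate_mining(reads_male, reads_female, config)

  if (nrow(mining$candidates) == 0) {
    log_msg("no candidate monomers found; returning empty result")
    out <- structure(list(catalog = NULL, quant = NULL,
                          landscape = landscape_table(tibble(
                            name = character(), sex = character(),
                            masked_bp = integer(), k2p = numeric())),
                          haplonets = list(), mining = mining,
                          evaluation = NULL, truth = truth,
                          manifest = build_manifest(config, truth, NULL)),
                     class = "sat_run")
    if (!is.null(out_dir)) write_run(out, out_dir)
    return(out)
  }

  dd <- dedup_candidates(mining$candidates,
                         config$identity_thresholds[["variant"]])
  prov <- mutate(dd, name = sprintf("cand%03d", row_number()))

  log_msg("stage quantify: ", nrow(prov), " monomers")
  quant <- quantify(reads_male, reads_female, prov, config)

  catalog <- finalize_catalog(prov, quant$abundance, config)
  # re-key the hit table to the final catalog names (match by sequence)
  key <- setNames(catalog$monomers$name,
                  prov$name[match(catalog$monomers$sequence, prov$sequence)])
  quant$hits$name <- unname(key[quant$hits$name])
  quant$abundance <- catalog$monomers %>%
    select("name", "sequence", "abundance_male", "abundance_female",
           "mf_ratio", "mf_infinite", "bias_call")
  landscape <- landscape_table(quant)

  haplonets <- list()
  if (build_msts) {
    eligible <- catalog$monomers$name[
      catalog$monomers$rul <= config$mst_max_monomer_length]
    for (nm in eligible) {
      mono <- catalog$monomers$sequence[catalog$monomers$name == nm]
      hap <- extract_haplotypes(reads_male, reads_female, mono, config)
      if (nrow(hap) >= 1) haplonets[[nm]] <- build_mst(hap, nm)
    }
    log_msg("stage haplonet: ", length(haplonets), " networks")
  }

  evaluation <- if (!is.null(truth)) {
    evaluate_run(catalog, truth, config)
  }

  out <- structure(list(catalog = catalog, quant = quant,
                        landscape = landscape, haplonets = haplonets,
                        mining = mining, evaluation = evaluation,
                        truth = truth,
                        manifest = build_manifest(config, truth, catalog)),
                   class = "sat_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' Compare a catalog and its abundance estimates against planted truth
#'
#' For every planted satellite, finds the best-matching catalog monomer by
#' rotation/strand-aware identity; a satellite counts as recovered when that
#' identity reaches `recover_identity`. Abundance recovery is the relative
#' error of the estimated masked-bp fraction against the exact planted
#' fraction, per sex. Purity looks the other way: every reported monomer must
#' match some planted satellite at `purity_identity` or better.
#'
#' @param catalog a `sat_catalog` (with abundances filled).
#' @param truth a `sat_truth` tibble from [build_genomes()].
#' @param config a [sat_config()] (for the bias margin).
#' @param recover_identity,purity_identity identity cutoffs.
#' @return list of class `sat_eval`: `per_planted`, `per_reported`,
#'   `summary` (one row: recall, purity, worst abundance error, bias-call
#'   accuracy).
#' @export
evaluate_run <- function(catalog, truth, config = sat_config(),
                         recover_identity = 0.95, purity_identity = 0.80) {
  m <- catalog$monomers
  idm <- matrix(0, nrow(truth), nrow(m))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(m))) {
      idm[i, j] <- cpp_pair_identity(truth$monomer[i], m$sequence[j])
    }
  }
  best_j <- apply(idm, 1, which.max)
  best_id <- idm[cbind(seq_len(nrow(truth)), best_j)]

  rel_err <- function(est, tru) ifelse(tru > 0, (est - tru) / tru, NA_real_)
  bias_expected <- dplyr::case_when(
    truth$mf_infinite | truth$true_mf_ratio > config$mf_bias_ratio ~ "male",
    truth$true_mf_ratio < 1 / config$mf_bias_ratio ~ "female",
    TRUE ~ "none"
  )
  per_planted <- tibble(
    name = truth$name,
    matched = m$name[best_j],
    best_identity = best_id,
    recovered = best_id >= recover_identity,
    true_abundance_male = truth$true_abundance_male,
    true_abundance_female = truth$true_abundance_female,
    est_abundance_male = m$abundance_male[best_j],
    est_abundance_female = m$abundance_female[best_j],
    rel_err_male = rel_err(m$abundance_male[best_j],
                           truth$true_abundance_male),
    rel_err_female = rel_err(m$abundance_female[best_j],
                             truth$true_abundance_female),
    true_mf_ratio = truth$true_mf_ratio,
    est_mf_ratio = m$mf_ratio[best_j],
    bias_expected = bias_expected,
    bias_called = m$bias_call[best_j]
  )
  per_planted$bias_correct <- per_planted$bias_expected ==
    per_planted$bias_called | !per_planted$recovered

  rep_best <- apply(idm, 2, max)
  per_reported <- tibble(
    name = m$name,
    best_identity_to_planted = rep_best,
    matched_planted = truth$name[apply(idm, 2, which.max)],
    pure = rep_best >= purity_identity
  )

  worst <- suppressWarnings(max(abs(c(
    per_planted$rel_err_male[per_planted$recovered],
    per_planted$rel_err_female[per_planted$recovered])), na.rm = TRUE))
  summary <- tibble(
    n_planted = nrow(truth),
    n_recovered = sum(per_planted$recovered),
    recall = mean(per_planted$recovered),
    mean_identity_recovered =
      mean(per_planted$best_identity[per_planted$recovered]),
    purity = mean(per_reported$pure),
    worst_abundance_rel_err = worst,
    bias_call_accuracy =
      mean(per_planted$bias_correct[per_planted$recovered])
  )
  structure(list(per_planted = per_planted, per_reported = per_reported,
                 summary = summary),
            class = "sat_eval")
}

#' @export
print.sat_eval <- function(x, ...) {
  cat("<sat_eval>\n")
  print(x$summary, ...)
  invisible(x)
}

#' @export
print.sat_run <- function(x, ...) {
  cat("<sat_run>\n")
  if (!is.null(x$catalog)) {
    cat("  catalog: ", nrow(x$catalog$monomers), " monomers, ",
        length(unique(x$catalog$partition$superfamily)),
        " superfamilies\n", sep = "")
  } else {
    cat("  catalog: empty\n")
  }
  cat("  mining rounds: ", nrow(x$mining$rounds), "\n", sep = "")
  cat("  haplotype networks: ", length(x$haplonets), "\n", sep = "")
  if (!is.null(x$evaluation)) print(x$evaluation$summary, ...)
  invisible(x)
}

build_manifest <- function(config, truth, catalog) {
  list(
    package = "satmine",
    version = as.character(utils::packageVersion("satmine")),
    seed = config$seed,
    stage_seeds = lapply(
      setNames(nm = c("simulate", "discover", "quantify", "haplonet",
                      "subsample")),
      function(s) derive_seed(config$seed, s)),
    config = {
      cfg <- unclass(config)
      cfg$identity_thresholds <- as.list(cfg$identity_thresholds)
      cfg
    },
    input = if (!is.null(truth)) {
      list(kind = "synthetic",
           satellites = truth$name,
           planted_bp_male = sum(truth$planted_bp_male),
           planted_bp_female = sum(truth$planted_bp_female))
    } else {
      list(kind = "fastq")
    },
    n_monomers = if (!is.null(catalog)) nrow(catalog$monomers) else 0L
  )
}

# write every artifact of a run into out_dir; returns file paths with md5s
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (!is.null(run$catalog)) {
    paths["catalog_fasta"] <- file.path(out_dir, "catalog.fasta")
    paths["catalog_tsv"] <- file.path(out_dir, "catalog.tsv")
    write_catalog(run$catalog$monomers, paths["catalog_fasta"],
                  paths["catalog_tsv"])
    paths["partition_tsv"] <- file.path(out_dir, "partition.tsv")
    write.table(run$catalog$partition, paths["partition_tsv"], sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    paths["abundance_tsv"] <- file.path(out_dir, "abundance.tsv")
    write.table(run$quant$abundance, paths["abundance_tsv"], sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    paths["landscape_tsv"] <- file.path(out_dir, "landscape.tsv")
    write.table(run$landscape, paths["landscape_tsv"], sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  paths["rounds_tsv"] <- file.path(out_dir, "mining_rounds.tsv")
  write.table(run$mining$rounds, paths["rounds_tsv"], sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  for (nm in names(run$haplonets)) {
    p <- file.path(out_dir, paste0("haplonet_", nm, ".graphml"))
    write_network(run$haplonets[[nm]], p)
    paths[paste0("haplonet_", nm)] <- p
  }
  if (!is.null(run$evaluation)) {
    paths["evaluation_tsv"] <- file.path(out_dir, "evaluation.tsv")
    write.table(run$evaluation$per_planted, paths["evaluation_tsv"],
                sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  }
  manifest <- run$manifest
  manifest$outputs <- lapply(setNames(nm = names(paths)), function(k) {
    list(path = unname(paths[[k]]),
         md5 = unname(tools::md5sum(paths[[k]])))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
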