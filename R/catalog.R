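# Catalog construction: canonical forms, rotation/strand-aware identity,
# nested variant/family/superfamily partition, naming by abundance rank.

#' Canonical form of a circularly equivalent monomer
#'
#' Satellite monomers have arbitrary phase and strand; the canonical form is
#' the lexicographic minimum over all rotations of the sequence and of its
#' reverse complement, so two monomers describing the same array always
#' compare equal.
#'
#' @param sequence DNA string(s) over ACGT.
#' @return character vector of canonical sequences.
#' @export
#' @examples
#' canonical_form("GAT") # "ATC"
canonical_form <- function(sequence) {
  stopifnot("sequences must be non-empty ACGT" =
              length(sequence) > 0 && is_dna(sequence))
  vapply(sequence, function(s) {
    m <- nchar(s)
    dbl <- paste0(s, s)
    r <- rc1(s)
    dbr <- paste0(r, r)
    rots <- c(substring(dbl, 1:m, m:(2L * m - 1L)),
              substring(dbr, 1:m, m:(2L * m - 1L)))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

#' Rotation- and strand-aware pairwise identity
#'
#' Identity (matches / alignment columns) of the best fit alignment of the
#' shorter sequence against the dimer of the longer, taken over both strands.
#' Dimerizing the longer sequence makes the score invariant to monomer phase;
#' normalizing by alignment columns tolerates the length mismatch typical of
#' satellite families. Symmetric by construction.
#'
#' @param a,b DNA strings (or single-row tibbles with a `sequence` column).
#' @return identity fraction in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("ACGTACGTAC", "CGTACGTACA") # 1: rotation of each other
pairwise_identity <- function(a, b) {
  if (is.data.frame(a)) a <- a$sequence
  if (is.data.frame(b)) b <- b$sequence
  cpp_pair_identity(a, b)
}

#' All-vs-all identity matrix
#' @param sequences character vector.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
identity_matrix <- function(sequences) {
  n <- length(sequences)
  m <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- cpp_pair_identity(sequences[i], sequences[j])
      }
    }
  }
  dimnames(m) <- list(names(sequences), names(sequences))
  m
}

#' Group monomers into variants, families and superfamilies
#'
#' Single-linkage clustering at the three identity tiers: two monomers share
#' a variant group iff connected by pairwise identity >= the variant
#' threshold (default 0.95), a family iff connected at >= 0.80, a superfamily
#' iff connected at >= 0.50. Because the thresholds are ordered, the
#' partitions nest automatically (every variant group lies inside one family
#' group, every family group inside one superfamily). Tier bounds are closed
#' below: identity exactly at a threshold joins the group. Superfamilies are
#' labelled SF1, SF2, ... by decreasing summed abundance (ties broken by the
#' lexicographically smallest member name).
#'
#' @param monomers tibble with `name`, `sequence` and (optionally)
#'   `abundance_male` / `abundance_female` used for superfamily ordering.
#' @param thresholds named numeric with `variant`, `family`, `superfamily`.
#' @param linkage `"single"` (connectivity-based, the default) or
#'   `"complete"`.
#' @return tibble of class `sat_partition`: `name`, `variant_id`,
#'   `family_id`, `superfamily`.
#' @export
build_partition <- function(monomers,
                            thresholds = c(variant = 0.95, family = 0.80,
                                           superfamily = 0.50),
                            linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(all(c("variant", "family", "superfamily") %in% names(thresholds)))
  # sorted canonical order drives all iteration: clustering is independent of
  # input order
  ord <- order(monomers$name)
  m <- monomers[ord, , drop = FALSE]
  idm <- identity_matrix(setNames(m$sequence, m$name))

  cluster_at <- function(th) {
    if (linkage == "single") {
      adj <- idm >= th
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               diag = FALSE)
      unname(igraph::components(g)$membership)
    } else {
      d <- stats::as.dist(1 - idm)
      if (nrow(m) == 1) return(1L)
      hc <- stats::hclust(d, method = "complete")
      unname(stats::cutree(hc, h = 1 - th))
    }
  }

  vid <- cluster_at(thresholds[["variant"]])
  fid <- cluster_at(thresholds[["family"]])
  sid <- cluster_at(thresholds[["superfamily"]])

  abund <- rep(0, nrow(m))
  if ("abundance_male" %in% names(m)) abund <- abund + m$abundance_male
  if ("abundance_female" %in% names(m)) abund <- abund + m$abundance_female

  relabel <- function(ids, prefix) {
    tot <- tapply(abund, ids, sum)
    mins <- tapply(m$name, ids, min)
    rank <- order(-tot, mins)
    lab <- setNames(seq_along(rank), names(tot)[rank])
    paste0(prefix, lab[as.character(ids)])
  }

  out <- tibble(
    name = m$name,
    variant_id = relabel(vid, "V"),
    family_id = relabel(fid, "F"),
    superfamily = relabel(sid, "SF")
  )
  check_nesting(vid, fid)
  check_nesting(fid, sid)
  out <- out[match(monomers$name, out$name), , drop = FALSE]
  class(out) <- c("sat_partition", class(out))
  out
}

# every finer group must map into exactly one coarser group
check_nesting <- function(fine, coarse) {
  bad <- tapply(coarse, fine, function(x) length(unique(x)) != 1L)
  if (any(bad)) {
    stop("internal error: homology tiers do not nest (threshold ordering ",
         "violated)")
  }
  invisible(TRUE)
}

#' Merge near-duplicate candidates
#'
#' Canonicalizes candidate sequences and merges sets connected at or above
#' the variant threshold (single linkage), keeping the highest-support
#' consensus of each set (ties broken by the lexicographically smaller
#' canonical sequence).
#'
#' @param candidates `sat_candidates` tibble from [detect_monomers()] /
#'   [iterate_mining()].
#' @param threshold identity above which two candidates are the same monomer.
#' @return deduplicated candidate tibble with canonical `sequence`.
#' @export
dedup_candidates <- function(candidates, threshold = 0.95) {
  if (nrow(candidates) == 0) return(candidates)
  cand <- mutate(candidates, sequence = canonical_form(.data$sequence))
  cand <- arrange(cand, .data$sequence)
  idm <- identity_matrix(cand$sequence)
  g <- igraph::graph_from_adjacency_matrix(idm >= threshold,
                                           mode = "undirected", diag = FALSE)
  grp <- igraph::components(g)$membership
  keep <- vapply(split(seq_len(nrow(cand)), grp), function(ix) {
    ix[order(-cand$support[ix], cand$sequence[ix])][1]
  }, integer(1))
  cand[sort(keep), , drop = FALSE]
}

#' Finalize the satellite catalog
#'
#' Joins abundance estimates onto deduplicated candidates, ranks monomers by
#' decreasing mean abundance across sexes (lexicographic canonical-sequence
#' tie-break), assigns zero-padded names, fills descriptors (repeat unit
#' length, AT fraction, M/F ratio) and builds the homology partition.
#'
#' @param candidates deduplicated candidate tibble (see [dedup_candidates()]).
#' @param abundance abundance tibble from [quantify()] keyed by `sequence`
#'   (or by provisional `name` matching the candidates).
#' @param config a [sat_config()] (naming prefix and identity thresholds).
#' @return object of class `sat_catalog`: list with `monomers` tibble
#'   (`name`, `sequence`, `rul`, `at_fraction`, `abundance_male`,
#'   `abundance_female`, `mf_ratio`, `mf_infinite`, `bias_call`, `support`,
#'   `round_found`) and `partition` tibble.
#' @export
finalize_catalog <- function(candidates, abundance, config = sat_config()) {
  stopifnot(nrow(candidates) > 0)
  cand <- mutate(candidates, sequence = canonical_form(.data$sequence))
  ab <- abundance
  if (!"sequence" %in% names(ab)) {
    stop("abundance table must carry a `sequence` column")
  }
  ab$sequence <- canonical_form(ab$sequence)
  m <- left_join(cand, select(ab, -dplyr::any_of(c("name"))), by = "sequence")
  for (cc in c("abundance_male", "abundance_female")) {
    if (!cc %in% names(m)) m[[cc]] <- 0
    m[[cc]][is.na(m[[cc]])] <- 0
  }
  m <- m %>%
    mutate(mean_abundance = (.data$abundance_male + .data$abundance_female) / 2) %>%
    arrange(desc(.data$mean_abundance), .data$sequence) %>%
    mutate(
      name = sprintf("%s%0*d", config$name_prefix,
                     max(2L, nchar(nrow(cand))), row_number()),
      rul = nchar(.data$sequence),
      at_fraction = at_fraction(.data$sequence),
      mf_infinite = .data$abundance_female == 0 & .data$abundance_male > 0,
      mf_ratio = ifelse(.data$abundance_female > 0,
                        .data$abundance_male / .data$abundance_female,
                        ifelse(.data$mf_infinite, Inf, NA_real_)),
      bias_call = mf_bias_call(.data$abundance_male, .data$abundance_female,
                               config$mf_bias_ratio)
    ) %>%
    select("name", "sequence", "rul", "at_fraction", "abundance_male",
           "abundance_female", "mf_ratio", "mf_infinite", "bias_call",
           dplyr::any_of(c("support", "round_found")))
  part <- build_partition(m, config$identity_thresholds)
  m$family_id <- part$family_id[match(m$name, part$name)]
  m$superfamily <- part$superfamily[match(m$name, part$name)]
  structure(list(monomers = m, partition = part, config = config),
            class = "sat_catalog")
}

# male / female / none given the ratio margin
mf_bias_call <- function(ab_m, ab_f, margin) {
  ratio <- ifelse(ab_f > 0, ab_m / ab_f, ifelse(ab_m > 0, Inf, NA_real_))
  dplyr::case_when(
    is.na(ratio) ~ "none",
    ratio > margin ~ "male",
    ratio < 1 / margin ~ "female",
    TRUE ~ "none"
  )
}

#' @export
print.sat_catalog <- function(x, ...) {
  cat("<sat_catalog> ", nrow(x$monomers), " monomers, ",
      length(unique(x$partition$superfamily)), " superfamilies\n", sep = "")
  print(x$monomers, ...)
  invisible(x)
}

#' Summary statistics of a monomer catalog
#'
#' The descriptive surface usually reported for a satellitome: monomer count,
#' repeat-unit-length range and mean, how many monomers exceed 100 bp, how
#' many are AT-rich (AT fraction > 0.5), and the superfamily count.
#'
#' @param catalog a `sat_catalog`, or a monomer tibble with `sequence` (a
#'   partition is then computed with default thresholds).
#' @return one-row tibble.
#' @export
catalog_stats <- function(catalog) {
  if (inherits(catalog, "sat_catalog")) {
    m <- catalog$monomers
    part <- catalog$partition
  } else {
    m <- mutate(catalog, rul = nchar(.data$sequence),
                at_fraction = at_fraction(.data$sequence))
    if (!"name" %in% names(m)) m$name <- sprintf("m%03d", seq_len(nrow(m)))
    part <- build_partition(m)
  }
  tibble(
    n_monomers = nrow(m),
    rul_min = min(m$rul), rul_max = max(m$rul), rul_mean = mean(m$rul),
    n_rul_gt100 = sum(m$rul > 100),
    n_at_rich = sum(m$at_fraction > 0.5),
    n_superfamilies = length(unique(part$superfamily))
  )
}
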