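# Haplotype extraction for short monomers and minimum-spanning-tree networks.

#' Extract per-sex monomer haplotypes from reads
#'
#' Each read is aligned without gaps to the periodic extension of the monomer
#' (both strands, every phase). Reads reaching
#' `config$min_identity_for_extraction` over their full length and containing
#' a complete monomer window contribute the read substring over that window,
#' re-phased so the window starts at monomer position 0 — identical
#' biological variants sampled at different read offsets collapse to one
#' haplotype. Identical sequences are collapsed with per-sex counts and
#' haplotypes below `config$min_haplotype_count` total observations (default:
#' singletons) are dropped as likely sequencing errors.
#'
#' @param reads_male,reads_female read tibbles.
#' @param monomer monomer sequence (or single-row catalog tibble); its length
#'   must not exceed `config$mst_max_monomer_length`.
#' @param config a [sat_config()].
#' @return tibble: `sequence`, `count_male`, `count_female`, ordered by
#'   decreasing total count (ties lexicographic).
#' @export
extract_haplotypes <- function(reads_male, reads_female, monomer,
                               config = sat_config()) {
  if (is.data.frame(monomer)) monomer <- monomer$sequence
  stopifnot(length(monomer) == 1, is_dna(monomer))
  if (nchar(monomer) > config$mst_max_monomer_length) {
    stop("monomer is ", nchar(monomer), " bp but mst_max_monomer_length is ",
         config$mst_max_monomer_length,
         "; haplotypes must fit inside one read")
  }
  hseed <- derive_seed(config$seed, "haplonet")
  prep <- function(reads, off) {
    subsample_pairs(qc_filter(reads, config$quality_threshold),
                    config$subsample_pairs_haplonet, seed = hseed + off)
  }
  one_sex <- function(reads) {
    h <- cpp_extract_haplotypes(reads$sequence, monomer,
                                config$min_identity_for_extraction,
                                min(10L, nchar(monomer)))
    h <- h[h != ""]
    if (!length(h)) return(tibble(sequence = character(), n = integer()))
    cnt <- table(h)
    tibble(sequence = names(cnt), n = as.integer(cnt))
  }
  hm <- one_sex(prep(reads_male, 0L))
  hf <- one_sex(prep(reads_female, 1L))
  out <- dplyr::full_join(dplyr::rename(hm, count_male = "n"),
                          dplyr::rename(hf, count_female = "n"),
                          by = "sequence") %>%
    mutate(count_male = ifelse(is.na(.data$count_male), 0L, .data$count_male),
           count_female = ifelse(is.na(.data$count_female), 0L,
                                 .data$count_female)) %>%
    filter(.data$count_male + .data$count_female >= config$min_haplotype_count) %>%
    arrange(desc(.data$count_male + .data$count_female), .data$sequence)
  out
}

#' Minimum spanning tree over haplotypes
#'
#' Builds the complete graph of pairwise Hamming distances between
#' equal-length haplotypes and extracts a minimum spanning tree by Kruskal's
#' algorithm with fully deterministic tie-breaking (edges sorted by distance,
#' then by the lexicographic endpoint-sequence pair).
#'
#' @param haplotypes tibble from [extract_haplotypes()] (needs `sequence`,
#'   `count_male`, `count_female`; at least one row).
#' @param monomer_name label carried on the result.
#' @return object of class `sat_haplonet`: list with `monomer`, `haplotypes`,
#'   `edges` (all pairwise distances) and `tree` (the n-1 MST edges, columns
#'   `from`, `to` as haplotype row indices, `distance`).
#' @export
build_mst <- function(haplotypes, monomer_name = NA_character_) {
  stopifnot("at least one haplotype required" = nrow(haplotypes) >= 1)
  n <- nrow(haplotypes)
  if (n == 1) {
    return(structure(list(monomer = monomer_name, haplotypes = haplotypes,
                          edges = tibble(from = integer(), to = integer(),
                                         distance = integer()),
                          tree = tibble(from = integer(), to = integer(),
                                        distance = integer())),
                     class = "sat_haplonet"))
  }
  d <- cpp_hamming_matrix(haplotypes$sequence)
  ij <- which(upper.tri(d), arr.ind = TRUE)
  edges <- tibble(from = ij[, 1], to = ij[, 2],
                  distance = d[ij]) %>%
    mutate(a = pmin(haplotypes$sequence[.data$from],
                    haplotypes$sequence[.data$to]),
           b = pmax(haplotypes$sequence[.data$from],
                    haplotypes$sequence[.data$to])) %>%
    arrange(.data$distance, .data$a, .data$b)

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(edges))
  taken <- 0L
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges$from[e]); rb <- find(edges$to[e])
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  tree <- edges[keep, c("from", "to", "distance")]
  structure(list(monomer = monomer_name, haplotypes = haplotypes,
                 edges = edges[, c("from", "to", "distance")], tree = tree),
            class = "sat_haplonet")
}

#' @export
print.sat_haplonet <- function(x, ...) {
  cat("<sat_haplonet> ", x$monomer %||% "", ": ", nrow(x$haplotypes),
      " haplotypes, tree weight ", sum(x$tree$distance), "\n", sep = "")
  invisible(x)
}

#' Write / read a haplotype network as GraphML
#'
#' Nodes carry `sequence`, `count_male`, `count_female`; tree edges carry
#' `distance`. Node order is the deterministic haplotype order of the
#' network.
#'
#' @param net a `sat_haplonet`.
#' @param path output file.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a list with `nodes` and `edges` tibbles.
#' @export
write_network <- function(net, path) {
  n <- nrow(net$haplotypes)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- paste0("h", seq_len(n))
  igraph::V(g)$sequence <- net$haplotypes$sequence
  igraph::V(g)$count_male <- net$haplotypes$count_male
  igraph::V(g)$count_female <- net$haplotypes$count_female
  if (nrow(net$tree)) {
    g <- igraph::add_edges(g, rbind(net$tree$from, net$tree$to))
    igraph::E(g)$distance <- net$tree$distance
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices"))
  edges <- as_tibble(igraph::as_data_frame(g, what = "edges"))
  list(nodes = nodes, edges = edges)
}
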