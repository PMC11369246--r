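# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @describeIn tidy-satmine one row per catalog monomer with descriptors,
#'   abundances and homology assignment.
#' @method tidy sat_catalog
#' @export
tidy.sat_catalog <- function(x, ...) {
  left_join(x$monomers, select(x$partition, "name", "variant_id"),
            by = "name")
}

#' Tidy and summarize pipeline results
#'
#' `tidy()` returns the per-unit table of each result object (monomers,
#' abundance records, haplotypes, mining rounds, planted-truth comparisons);
#' `glance()` a one-row summary.
#'
#' @param x a `sat_catalog`, `sat_quant`, `sat_haplonet`, `sat_mining` or
#'   `sat_eval` object.
#' @param ... unused.
#' @return a tibble.
#' @name tidy-satmine
NULL

#' @describeIn tidy-satmine catalog-level summary statistics
#'   (see [catalog_stats()]).
#' @method glance sat_catalog
#' @export
glance.sat_catalog <- function(x, ...) {
  catalog_stats(x)
}

#' @describeIn tidy-satmine abundance records, one row per monomer.
#' @method tidy sat_quant
#' @export
tidy.sat_quant <- function(x, ...) {
  x$abundance
}

#' @describeIn tidy-satmine library sizes and bias-call counts.
#' @method glance sat_quant
#' @export
glance.sat_quant <- function(x, ...) {
  tibble(
    n_monomers = nrow(x$abundance),
    library_bp_male = unname(x$library_bp[["male"]]),
    library_bp_female = unname(x$library_bp[["female"]]),
    n_male_biased = sum(x$abundance$bias_call == "male"),
    n_female_biased = sum(x$abundance$bias_call == "female"),
    n_saturated_hits = x$n_saturated
  )
}

#' @describeIn tidy-satmine haplotypes with node ids and per-sex counts.
#' @method tidy sat_haplonet
#' @export
tidy.sat_haplonet <- function(x, ...) {
  mutate(x$haplotypes, node = row_number(), .before = 1)
}

#' @describeIn tidy-satmine node/edge counts and total tree weight.
#' @method glance sat_haplonet
#' @export
glance.sat_haplonet <- function(x, ...) {
  tibble(
    monomer = x$monomer,
    n_haplotypes = nrow(x$haplotypes),
    n_tree_edges = nrow(x$tree),
    tree_weight = sum(x$tree$distance),
    n_male_specific = sum(x$haplotypes$count_female == 0),
    n_female_specific = sum(x$haplotypes$count_male == 0)
  )
}

#' @describeIn tidy-satmine per-round mining report.
#' @method tidy sat_mining
#' @export
tidy.sat_mining <- function(x, ...) {
  x$rounds
}

#' @describeIn tidy-satmine candidate count and round summary.
#' @method glance sat_mining
#' @export
glance.sat_mining <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$candidates),
    n_rounds = nrow(x$rounds),
    reads_male_final = nrow(x$library_male),
    reads_female_final = nrow(x$library_female)
  )
}

#' @describeIn tidy-satmine per-planted-satellite recovery table.
#' @method tidy sat_eval
#' @export
tidy.sat_eval <- function(x, ...) {
  x$per_planted
}

#' @describeIn tidy-satmine recall / purity / abundance-error summary.
#' @method glance sat_eval
#' @export
glance.sat_eval <- function(x, ...) {
  x$summary
}

#' Plot methods
#'
#' `autoplot()` for the result objects: per-sex abundance profile of a
#' catalog, divergence landscapes, and haplotype minimum spanning trees
#' (node area proportional to haplotype abundance, colour by sex share —
#' the conventional rendering of satellite haplotype networks).
#'
#' @param object a `sat_catalog`, `sat_landscape` or `sat_haplonet`.
#' @param ... unused.
#' @return a ggplot object.
#' @name autoplot-satmine
NULL

#' @describeIn autoplot-satmine paired bars of male/female abundance per
#'   monomer.
#' @method autoplot sat_catalog
#' @export
autoplot.sat_catalog <- function(object, ...) {
  df <- object$monomers %>%
    select("name", "abundance_male", "abundance_female") %>%
    tidyr::pivot_longer(cols = c("abundance_male", "abundance_female"),
                        names_to = "sex", values_to = "abundance",
                        names_prefix = "abundance_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name, y = 100 * .data$abundance,
                                   fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "abundance (% of library bp)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn autoplot-satmine divergence landscape: masked bp per 1%
#'   Kimura-distance bin, one panel per monomer.
#' @method autoplot sat_landscape
#' @export
autoplot.sat_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$masked_bp)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "Kimura-2-parameter distance (%)", y = "masked bp") +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot-satmine minimum spanning tree with node area
#'   proportional to haplotype count and colour giving the male share.
#' @method autoplot sat_haplonet
#' @export
autoplot.sat_haplonet <- function(object, ...) {
  hap <- object$haplotypes
  n <- nrow(hap)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(object$tree)) {
    g <- igraph::add_edges(g, rbind(object$tree$from, object$tree$to))
  }
  xy <- igraph::layout_with_kk(g)
  nodes <- tibble(x = xy[, 1], y = xy[, 2],
                  total = hap$count_male + hap$count_female,
                  male_share = ifelse(hap$count_male + hap$count_female > 0,
                                      hap$count_male /
                                        (hap$count_male + hap$count_female),
                                      0.5))
  segs <- if (nrow(object$tree)) {
    tibble(x = xy[object$tree$from, 1], y = xy[object$tree$from, 2],
           xend = xy[object$tree$to, 1], yend = xy[object$tree$to, 2],
           distance = object$tree$distance)
  } else {
    tibble(x = numeric(), y = numeric(), xend = numeric(), yend = numeric(),
           distance = integer())
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$total,
                                     colour = .data$male_share)) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "forestgreen",
                                   limits = c(0, 1)) +
    ggplot2::labs(title = object$monomer, size = "haplotype count",
                  colour = "male share") +
    ggplot2::theme_void()
}
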