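#' Tidy an alignment graph
#'
#' One row per (vertex, genome) segment, carrying the vertex attributes, in
#' the broom long-format style.
#'
#' @param x An `alignment_graph`.
#' @param ... Unused.
#' @return A tibble with columns `vertex`, `kind`, `length`, `identity`,
#'   `n_support`, `genome`, `start`, `end` (1-based inclusive, in display
#'   coordinates).
#' @export
tidy.alignment_graph <- function(x, ...) {
  off <- x$genomes$info$coord_offset
  x$segments |>
    left_join(x$vertices, by = "vertex") |>
    mutate(start = .data$start + off[.data$genome_index],
           end = .data$end + off[.data$genome_index]) |>
    select("vertex", "kind", "length", "identity", "n_support", "genome",
           "start", "end") |>
    arrange(.data$vertex, .data$genome)
}

#' One-row summary of an alignment graph
#'
#' @param x An `alignment_graph`.
#' @param ... Unused.
#' @return A tibble with `n_genomes`, `total_length` (N_l), `m`,
#'   `total_match_length` (M_l, when the graph was built by
#'   [align_genomes()]), `vertices`, `vertices_ge2`, `contracted_vertices`,
#'   `anchors`.
#' @export
glance.alignment_graph <- function(x, ...) {
  tibble(
    n_genomes = n_genomes(x$genomes),
    total_length = total_length(x$genomes),
    m = x$m %||% NA_integer_,
    total_match_length = if (!is.null(x$matches)) {
      attr(x$matches, "total_match_length")
    } else NA_integer_,
    vertices = nrow(x$vertices),
    vertices_ge2 = sum(x$vertices$n_support >= 2),
    contracted_vertices = sum(x$vertices$kind == "contracted"),
    anchors = length(x$anchors)
  )
}

#' Plot an alignment graph as genome tracks
#'
#' Each genome is a horizontal track; vertices are drawn as segments
#' colored by the number of genomes they align. Anchors (full-support
#' vertices) are emphasized.
#'
#' @param object An `alignment_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.alignment_graph <- function(object, ...) {
  df <- tidy(object) |>
    mutate(is_anchor = .data$vertex %in% object$anchors)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$genome, yend = .data$genome,
                                   color = factor(.data$n_support))) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::geom_segment(data = df |> filter(.data$is_anchor),
                          linewidth = 5) +
    ggplot2::labs(x = "position (bp)", y = NULL, color = "genomes aligned") +
    ggplot2::theme_minimal()
}

#' Dot-plot of a match set
#'
#' Diagonal segments for every maximal exact match, faceted by genome pair.
#'
#' @param object A `mem_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mem_set <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(pair = paste(.data$genome_a, "vs", .data$genome_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_a,
                                   xend = .data$start_a + .data$length - 1,
                                   y = .data$start_b,
                                   yend = .data$start_b + .data$length - 1)) +
    ggplot2::geom_segment() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "position in first genome (bp)",
                  y = "position in second genome (bp)") +
    ggplot2::theme_minimal()
}
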