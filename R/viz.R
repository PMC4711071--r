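#' Rendering options for Graphviz output
#'
#' @param mask_threshold Vertices shorter than this many bp are masked
#'   (not drawn); their base pairs are accounted on dotted edges. Default
#'   20 bp.
#' @param color_map Optional named vector of colors, one per genome id;
#'   colors must be unique. Defaults to a fixed palette.
#' @param show_positions Draw per-genome coordinates in node labels.
#' @param anchor_view Reserved flag used by the CLI.
#' @return A `render_options` list.
#' @export
render_options <- function(mask_threshold = 20L, color_map = NULL,
                           show_positions = TRUE, anchor_view = FALSE) {
  if (mask_threshold < 0) ph_abort("bad_input", "mask_threshold must be >= 0")
  if (!is.null(color_map) && anyDuplicated(color_map)) {
    ph_abort("bad_input", "genome colors must be unique")
  }
  structure(list(mask_threshold = as.integer(mask_threshold),
                 color_map = color_map,
                 show_positions = isTRUE(show_positions),
                 anchor_view = isTRUE(anchor_view)),
            class = "render_options")
}

PH_PALETTE <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
                "#a65628", "#f781bf", "#999999", "#66c2a5", "#fc8d62",
                "#8da0cb", "#e78ac3")

genome_colors <- function(genomes, opts) {
  ids <- genomes$info$id
  if (!is.null(opts$color_map)) {
    missing <- setdiff(ids, names(opts$color_map))
    if (length(missing) > 0) {
      ph_abort("bad_input", paste0("no color for genome(s): ",
                                   paste(missing, collapse = ", ")))
    }
    return(opts$color_map[ids])
  }
  n <- length(ids)
  cols <- if (n <= length(PH_PALETTE)) PH_PALETTE[seq_len(n)] else {
    grDevices::hcl(h = seq(15, 375, length.out = n + 1)[seq_len(n)],
                   c = 100, l = 65)
  }
  setNames(cols, ids)
}

# Truncated (floor) integer percent identity, matching the displayed style:
# 167/169 columns conserved shows as 98 %.
identity_percent <- function(identity_num, length) {
  as.integer((as.numeric(identity_num) * 100) %/% as.numeric(length))
}

vertex_label <- function(graph, v, opts) {
  vt <- graph$vertices
  k <- match(v, vt$vertex)
  lines <- character(0)
  if (opts$show_positions) {
    sg <- graph$segments |> filter(.data$vertex == v) |>
      arrange(.data$genome_index)
    off <- graph$genomes$info$coord_offset[sg$genome_index]
    lines <- sprintf("%s:%d-%d", sg$genome, sg$start + off, sg$end + off)
  }
  lines <- c(lines, sprintf("len=%d id=%d%%", vt$length[k],
                            identity_percent(vt$identity_num[k],
                                             vt$length[k])))
  paste(lines, collapse = "\\n")
}

#' Render an alignment graph as Graphviz DOT
#'
#' One box per unmasked vertex, labeled with per-genome 1-based coordinates,
#' alignment length and truncated percent identity; one edge color per
#' genome. Vertices shorter than the mask threshold are not drawn: any edge
#' whose path hides at least one bp (masked vertices or skipped bases) is
#' dotted and annotated with the hidden bp count. Output is deterministic
#' (sorted nodes and edges).
#'
#' @param graph An `alignment_graph`.
#' @param opts A [render_options()] list.
#' @return A single DOT string.
#' @export
to_dot <- function(graph, opts = render_options()) {
  stopifnot(inherits(graph, "alignment_graph"))
  cols <- genome_colors(graph$genomes, opts)
  vt <- graph$vertices |> arrange(.data$vertex)
  visible <- vt$vertex[vt$length >= opts$mask_threshold]
  out <- c("digraph alignment {",
           "  rankdir=LR;",
           "  node [shape=box, fontname=\"Helvetica\"];")
  for (v in visible) {
    out <- c(out, sprintf("  v%d [label=\"%s\"];", v,
                          vertex_label(graph, v, opts)))
  }
  edge_lines <- character(0)
  for (g in seq_len(n_genomes(graph$genomes))) {
    sg <- graph$segments |> filter(.data$genome_index == g) |>
      arrange(.data$start)
    vis <- sg |> filter(.data$vertex %in% visible)
    if (nrow(vis) < 2) next
    for (i in seq_len(nrow(vis) - 1)) {
      hidden <- vis$start[i + 1] - vis$end[i] - 1L
      style <- if (hidden >= 1L) {
        sprintf(" style=dotted, label=\"%d bp\",", hidden)
      } else ""
      edge_lines <- c(edge_lines, sprintf(
        "  v%d -> v%d [%s color=\"%s\"];",
        vis$vertex[i], vis$vertex[i + 1], style,
        cols[graph$genomes$info$id[g]]))
    }
  }
  out <- c(out, edge_lines, "}")
  paste(out, collapse = "\n")
}

#' Render the anchor (backbone) view as Graphviz DOT
#'
#' A linear chain of the full-support vertices in backbone order.
#' Consecutive anchors bounding a gapless alignment (identical inter-anchor
#' distance in every genome) are grouped in a cluster box; runs of such
#' pairs share one box. Edges between anchors are dotted and annotated with
#' the per-genome hidden bp range whenever sequence lies between them.
#'
#' @param graph An `alignment_graph` with at least one anchor.
#' @param opts A [render_options()] list.
#' @return A single DOT string.
#' @export
anchor_view_dot <- function(graph, opts = render_options()) {
  stopifnot(inherits(graph, "alignment_graph"))
  an <- compute_anchors(graph)
  out <- c("digraph anchors {",
           "  rankdir=LR;",
           "  node [shape=box, fontname=\"Helvetica\"];")
  if (nrow(an) == 0) {
    return(paste(c(out, "}"), collapse = "\n"))
  }
  # cluster maximal runs of gapless-linked anchors
  runs <- list()
  i <- 1
  while (i <= nrow(an)) {
    j <- i
    while (j < nrow(an) && isTRUE(an$gapless_with_next[j])) j <- j + 1
    if (j > i) runs[[length(runs) + 1L]] <- an$anchor[i:j]
    i <- j + 1
  }
  clustered <- unlist(runs)
  for (r in seq_along(runs)) {
    out <- c(out, sprintf("  subgraph cluster_%d {", r))
    for (v in runs[[r]]) {
      out <- c(out, sprintf("    v%d [label=\"%s\"];", v,
                            vertex_label(graph, v, opts)))
    }
    out <- c(out, "  }")
  }
  for (v in setdiff(an$anchor, clustered)) {
    out <- c(out, sprintf("  v%d [label=\"%s\"];", v,
                          vertex_label(graph, v, opts)))
  }
  if (nrow(an) > 1) {
    for (i in seq_len(nrow(an) - 1)) {
      s1 <- graph$segments |> filter(.data$vertex == an$anchor[i]) |>
        arrange(.data$genome_index)
      s2 <- graph$segments |> filter(.data$vertex == an$anchor[i + 1]) |>
        arrange(.data$genome_index)
      d <- s2$start - s1$end - 1L
      if (max(d) >= 1L) {
        lab <- if (min(d) == max(d)) sprintf("%d bp", max(d)) else {
          sprintf("%d-%d bp", min(d), max(d))
        }
        out <- c(out, sprintf(
          "  v%d -> v%d [style=dotted, label=\"%s\"];",
          an$anchor[i], an$anchor[i + 1], lab))
      } else {
        out <- c(out, sprintf("  v%d -> v%d;", an$anchor[i],
                              an$anchor[i + 1]))
      }
    }
  }
  paste(c(out, "}"), collapse = "\n")
}
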