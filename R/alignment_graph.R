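#' Build the column graph
#'
#' The column graph is the directed multigraph whose vertices are the
#' columns of a (valid) partition, with an edge from column `C1` to `C2` for
#' every genome that has a position in `C1` immediately followed by a
#' position in `C2`. Acyclicity of this graph is the formal definition of
#' functional collinearity. The partition is split with [split_invalid()]
#' first if that has not been done (splitting is idempotent).
#'
#' @param partition A `column_partition`.
#' @return A `column_graph` object holding the per-genome edge table and the
#'   partition it was built from.
#' @export
build_column_graph <- function(partition) {
  stopifnot(inherits(partition, "column_partition"))
  if (!partition$split) partition <- split_invalid(partition)
  genomes <- partition$genomes
  lens <- genomes$info$length
  ends <- cumsum(lens)
  p <- setdiff(seq_len(sum(lens)), ends)  # positions with a successor
  edges <- tibble(
    from = partition$col_of[p],
    to = partition$col_of[p + 1L],
    genome_index = position_genome_index(genomes)[p]
  )
  structure(list(edges = edges, partition = partition),
            class = "column_graph")
}

#' @export
print.column_graph <- function(x, ...) {
  cat(sprintf("<column_graph> %d column(s), %d edge(s)\n",
              x$partition$n_columns, nrow(x$edges)))
  invisible(x)
}

#' Test functional collinearity
#'
#' A set of genomes is functionally collinear with respect to a match set
#' when the column graph is acyclic. Non-collinearity is a result, not an
#' error: when cycles exist, every nontrivial strongly connected component
#' is reported with the genomic intervals it touches, as rearrangement
#' evidence (e.g. a transposed block).
#'
#' @param x A `column_graph`.
#' @return A `collinearity_report`: list with `collinear` (logical) and
#'   `sccs` (tibble `scc`, `genome`, `start`, `end`, one row per genome
#'   interval touched by each nontrivial strongly connected component).
#' @export
check_collinear <- function(x) {
  stopifnot(inherits(x, "column_graph"))
  n_col <- x$partition$n_columns
  ed <- distinct(x$edges, .data$from, .data$to)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(ed$from), to = as.character(ed$to)),
    directed = TRUE, vertices = data.frame(name = as.character(seq_len(n_col))))
  if (igraph::is_dag(g)) {
    return(structure(list(collinear = TRUE, sccs = empty_scc_table()),
                     class = "collinearity_report"))
  }
  comp <- igraph::components(g, mode = "strong")
  member <- comp$membership[as.character(seq_len(n_col))]
  big <- which(comp$csize > 1)
  cols_tb <- as_tibble(x$partition)
  sccs <- cols_tb |>
    mutate(scc = member[.data$column_id]) |>
    filter(.data$scc %in% big) |>
    group_by(.data$scc, .data$genome, .data$genome_index) |>
    summarise(start = min(.data$position), end = max(.data$position),
              .groups = "drop") |>
    mutate(scc = match(.data$scc, sort(unique(.data$scc)))) |>
    arrange(.data$scc, .data$genome_index) |>
    select("scc", "genome", "start", "end")
  structure(list(collinear = FALSE, sccs = sccs),
            class = "collinearity_report")
}

empty_scc_table <- function() {
  tibble(scc = integer(), genome = character(), start = integer(),
         end = integer())
}

#' @export
print.collinearity_report <- function(x, ...) {
  if (x$collinear) {
    cat("<collinearity_report> collinear: column graph is acyclic\n")
  } else {
    cat(sprintf(
      "<collinearity_report> NOT collinear: %d strongly connected component(s)\n",
      n_distinct(x$sccs$scc)))
    print(x$sccs, ...)
  }
  invisible(x)
}

new_alignment_graph <- function(vertices, segments, edges, genomes, m,
                                level, members) {
  anchors <- vertices$vertex[vertices$n_support == n_genomes(genomes)]
  if (length(anchors) > 0) {
    g1 <- segments |> filter(.data$genome_index == 1L)
    anchors <- anchors[order(g1$start[match(anchors, g1$vertex)])]
  }
  structure(list(vertices = vertices, segments = segments, edges = edges,
                 anchors = anchors, genomes = genomes, m = m, level = level,
                 members = members),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(sprintf(
    "<alignment_graph> (%s) %d vertex(es), %d anchor(s), %d genome(s), m = %s\n",
    x$level, nrow(x$vertices), length(x$anchors), n_genomes(x$genomes),
    x$m %||% "?"))
  invisible(x)
}

#' Merge consecutive same-support columns into exact alignment vertices
#'
#' Maximal runs of columns that have identical support and are consecutive
#' in every supported genome are merged into a single vertex. Each vertex of
#' the resulting (expanded) alignment graph is an exact alignment: all its
#' rows are character-identical, one per supported genome. Runs of
#' unmatched positions of a single genome collapse the same way into
#' singleton vertices, so the vertices tile every genome completely.
#'
#' @param x A `column_graph` whose graph is acyclic (cyclic input raises a
#'   `phalign_error_cyclic` condition).
#' @return An expanded `alignment_graph`.
#' @export
merge_same_support <- function(x) {
  stopifnot(inherits(x, "column_graph"))
  rep <- check_collinear(x)
  if (!rep$collinear) {
    ph_abort("cyclic", "cannot merge a cyclic column graph", sccs = rep$sccs)
  }
  part <- x$partition
  genomes <- part$genomes
  col_of <- part$col_of
  n_col <- part$n_columns
  sizes <- tabulate(col_of, nbins = n_col)
  lens <- genomes$info$length
  ends <- cumsum(lens)
  p <- setdiff(seq_len(sum(lens)), ends)
  agg <- tibble(c1 = col_of[p], c2 = col_of[p + 1L]) |>
    group_by(.data$c1) |>
    summarise(nn = n(), u = n_distinct(.data$c2), nxt = .data$c2[1],
              .groups = "drop")
  # column c merges with its successor column iff every one of its positions
  # has a successor, all successors fall in one column, and that column has
  # the same number of positions (hence, both being valid, the same support)
  ok <- agg$nn == sizes[agg$c1] & agg$u == 1L & sizes[agg$nxt] == sizes[agg$c1]
  nxt_of <- integer(n_col)
  nxt_of[agg$c1[ok]] <- agg$nxt[ok]
  is_target <- logical(n_col)
  is_target[nxt_of[nxt_of > 0L]] <- TRUE
  starts <- which(!is_target)
  vmap <- integer(n_col)
  vid <- 0L
  for (s in starts) {
    vid <- vid + 1L
    c <- s
    while (c != 0L) {
      vmap[c] <- vid
      c <- nxt_of[c]
    }
  }
  gidx <- position_genome_index(genomes)
  pos_in_g <- sequence(lens)
  seg <- tibble(v = vmap[col_of], genome_index = gidx, position = pos_in_g) |>
    group_by(.data$v, .data$genome_index) |>
    summarise(start = min(.data$position), end = max(.data$position),
              .groups = "drop")
  build_graph_tables(seg, genomes, m = attr(part, "m"), level = "expanded",
                     kind_of = NULL, identity_num = NULL, members = NULL)
}

# Assemble an alignment_graph from a raw vertex-segment table. Vertices are
# renumbered along the canonical topological order (Kahn, ties broken by the
# smallest coordinate in the lowest-index supported genome).
build_graph_tables <- function(seg, genomes, m, level, kind_of, identity_num,
                               members) {
  vs <- sort(unique(seg$v))
  seg$v <- match(seg$v, vs)
  if (!is.null(members)) members <- members[vs]
  if (!is.null(kind_of)) kind_of <- kind_of[vs]
  if (!is.null(identity_num)) identity_num <- identity_num[vs]
  K <- length(vs)
  lenv <- seg |>
    mutate(seg_len = .data$end - .data$start + 1L) |>
    group_by(.data$v) |>
    summarise(length = .data$seg_len[1],
              gapless = n_distinct(.data$seg_len) == 1L,
              n_support = n(),
              g0 = min(.data$genome_index), .groups = "drop")
  stopifnot(all(lenv$gapless))
  s0 <- seg |>
    group_by(.data$v) |>
    summarise(g0 = min(.data$genome_index), .groups = "drop") |>
    left_join(seg, by = "v") |>
    filter(.data$genome_index == .data$g0) |>
    select("v", s0 = "start")
  keys <- lenv |> left_join(s0, by = "v") |> arrange(.data$v)
  # per-genome successor edges
  edge_raw <- seg |>
    group_by(.data$genome_index) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(nxt = dplyr::lead(.data$v),
           skipped_bp = dplyr::lead(.data$start) - .data$end - 1L) |>
    ungroup() |>
    filter(!is.na(.data$nxt))
  ord <- topo_order_canonical(K, edge_raw$v, edge_raw$nxt,
                              keys$g0, keys$s0)
  relab <- integer(K)
  relab[ord] <- seq_len(K)
  if (!is.null(members)) members <- members[ord]
  vertices <- tibble(
    vertex = relab[keys$v],
    length = keys$length,
    n_support = keys$n_support
  ) |> arrange(.data$vertex)
  # row r now describes new vertex id r, whose pre-relabel id is ord[r]
  if (is.null(kind_of)) {
    vertices$kind <- ifelse(vertices$n_support == 1L, "singleton", "exact")
  } else {
    vertices$kind <- kind_of[ord]
  }
  if (is.null(identity_num)) {
    vertices$identity_num <- vertices$length
  } else {
    vertices$identity_num <- identity_num[ord]
  }
  vertices$identity <- vertices$identity_num / vertices$length
  vertices <- vertices |>
    select("vertex", "kind", "length", "n_support", "identity_num",
           "identity")
  segments <- seg |>
    mutate(vertex = relab[.data$v],
           genome = genomes$info$id[.data$genome_index]) |>
    select("vertex", "genome_index", "genome", "start", "end") |>
    arrange(.data$vertex, .data$genome_index)
  edges <- edge_raw |>
    mutate(from = relab[.data$v], to = relab[.data$nxt],
           genome = genomes$info$id[.data$genome_index]) |>
    select("genome_index", "genome", "from", "to", "skipped_bp") |>
    arrange(.data$genome_index, .data$from)
  if (is.null(members)) {
    members <- as.list(seq_len(K))
  }
  new_alignment_graph(vertices, segments, edges, genomes, m, level, members)
}

# Kahn's algorithm with deterministic tie-break: among ready vertices pick
# the one with the smallest (lowest supported genome, coordinate) key.
topo_order_canonical <- function(K, efrom, eto, g0, s0) {
  if (K == 0) return(integer(0))
  adj <- split(eto, factor(efrom, levels = seq_len(K)))
  indeg <- tabulate(eto, nbins = K)
  key <- order(g0, s0)           # key[r] = vertex with rank r
  rank_of <- integer(K)
  rank_of[key] <- seq_len(K)
  ready <- rank_of[indeg == 0L]
  out <- integer(K)
  for (i in seq_len(K)) {
    r <- min(ready)
    v <- key[r]
    ready <- ready[ready != r]
    out[i] <- v
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, rank_of[w])
    }
  }
  out
}

#' Contract the alignment graph into gapless alignments
#'
#' A pair of vertices `(U, V)` with identical support is contractible when
#' `U` precedes `V` in the partial order, the support of every vertex
#' between them is included in the support of `V`, and the base-pair spans
#' from the start of `U` to the end of `V` are the same in every supported
#' genome. Contraction merges every such chain (greedy left-to-right over
#' the canonical topological order) into a single gapless vertex whose
#' percent identity is the fraction of its columns in which all supported
#' genomes carry the same nucleotide (an `N` never counts as conserved).
#'
#' @param expanded An expanded `alignment_graph` from
#'   [merge_same_support()].
#' @param max_length Optional cap on contracted vertex length (default
#'   `Inf`, i.e. no cap): candidate contractions that would exceed it are
#'   skipped.
#' @return A contracted `alignment_graph`. Element `members` maps every
#'   vertex back to the expanded vertices it contains.
#' @export
contract_graph <- function(expanded, max_length = Inf) {
  stopifnot(inherits(expanded, "alignment_graph"),
            expanded$level == "expanded")
  genomes <- expanded$genomes
  n <- n_genomes(genomes)
  K <- nrow(expanded$vertices)
  if (K == 0) return(expanded_to_level(expanded, "contracted"))
  smat <- matrix(NA_integer_, nrow = K, ncol = n)
  emat <- matrix(NA_integer_, nrow = K, ncol = n)
  idx <- cbind(expanded$segments$vertex, expanded$segments$genome_index)
  smat[idx] <- expanded$segments$start
  emat[idx] <- expanded$segments$end
  support <- lapply(seq_len(K), function(v) which(!is.na(smat[v, ])))
  alive <- rep(TRUE, K)
  kind <- expanded$vertices$kind[order(expanded$vertices$vertex)]
  members <- lapply(seq_len(K), function(v) expanded$members[[v]])
  # per-genome start-position -> vertex lookup
  sv <- lapply(seq_len(n), function(g) {
    e <- new.env(parent = emptyenv(), size = K)
    vs <- which(!is.na(smat[, g]))
    for (v in vs) assign(as.character(smat[v, g]), v, envir = e)
    e
  })
  succ <- function(v, g) {
    nxt <- emat[v, g] + 1L
    get0(as.character(nxt), envir = sv[[g]], ifnotfound = NA_integer_)
  }
  order0 <- seq_len(K)  # vertices are already numbered in canonical order
  for (u in order0) {
    if (!alive[u]) next
    repeat {
      S <- support[[u]]
      target <- NA_integer_
      absorbed <- integer(0)
      ok <- TRUE
      for (g in S) {
        w <- succ(u, g)
        g_absorbed <- integer(0)
        while (!is.na(w)) {
          sw <- support[[w]]
          if (!all(sw %in% S)) {
            ok <- FALSE
            break
          }
          if (length(sw) == length(S)) break  # same support: candidate V
          g_absorbed <- c(g_absorbed, w)
          w <- succ(w, g)
        }
        if (!ok || is.na(w)) {
          ok <- FALSE
          break
        }
        if (is.na(target)) target <- w
        else if (target != w) {
          ok <- FALSE
          break
        }
        absorbed <- union(absorbed, g_absorbed)
      }
      if (!ok) break
      v <- target
      spans <- emat[v, S] - smat[u, S] + 1L
      if (n_distinct(spans) != 1L || spans[1] > max_length) break
      # merge u..v (and everything between) into u
      for (w in c(absorbed, v)) {
        for (g in support[[w]]) {
          rm(list = as.character(smat[w, g]), envir = sv[[g]])
        }
        alive[w] <- FALSE
      }
      emat[u, S] <- emat[v, S]
      kind[u] <- "contracted"
      members[[u]] <- c(members[[u]],
                        unlist(members[sort(c(absorbed, v))], use.names = FALSE))
      # loop: try to extend the chain further from the enlarged u
    }
  }
  keep <- which(alive)
  seg_rows <- list()
  for (v in keep) {
    S <- support[[v]]
    s_v <- smat[v, S]
    e_v <- emat[v, S]
    seg_rows[[length(seg_rows) + 1L]] <-
      tibble(v = v, genome_index = S, start = s_v, end = e_v)
  }
  seg <- bind_rows(seg_rows)
  identity_num <- integer(max(keep))
  for (v in keep) {
    S <- support[[v]]
    if (kind[v] != "contracted") {
      identity_num[v] <- emat[v, S[1]] - smat[v, S[1]] + 1L
    } else {
      identity_num[v] <- count_conserved_columns(
        genomes, S, smat[v, S], emat[v, S[1]] - smat[v, S[1]] + 1L)
    }
  }
  build_graph_tables(seg, genomes, m = expanded$m, level = "contracted",
                     kind_of = kind[seq_len(max(keep))],
                     identity_num = identity_num,
                     members = members[seq_len(max(keep))])
}

expanded_to_level <- function(graph, level) {
  graph$level <- level
  graph
}

# Number of columns in which all supported genomes carry the same A/C/G/T.
count_conserved_columns <- function(genomes, support, starts, len) {
  rows <- lapply(seq_along(support), function(k) {
    g <- support[k]
    utf8ToInt(substr(genomes$seq[[g]], starts[k], starts[k] + len - 1L))
  })
  ref <- rows[[1]]
  same <- rep(TRUE, len)
  for (k in seq_along(rows)[-1]) same <- same & rows[[k]] == ref
  sum(same & ref != utf8ToInt("N"))
}

#' Anchors and the backbone
#'
#' Anchors are vertices supported by every genome in the set; ordered along
#' the genomes they form the backbone (the common core). Consecutive anchor
#' pairs whose inter-anchor distances are identical in every genome bound a
#' gapless alignment and are flagged, mirroring the boxed pairs of the
#' anchor view.
#'
#' @param graph An `alignment_graph`.
#' @return A tibble with columns `anchor` (vertex id, in backbone order),
#'   `length`, `identity`, and `gapless_with_next` (logical; `NA` for the
#'   last anchor).
#' @export
compute_anchors <- function(graph) {
  stopifnot(inherits(graph, "alignment_graph"))
  a <- graph$anchors
  if (length(a) == 0) {
    return(tibble(anchor = integer(), length = integer(),
                  identity = double(), gapless_with_next = logical()))
  }
  seg <- graph$segments |> filter(.data$vertex %in% a)
  gap_ok <- rep(NA, length(a))
  if (length(a) > 1) {
    for (k in seq_len(length(a) - 1)) {
      s1 <- seg |> filter(.data$vertex == a[k]) |> arrange(.data$genome_index)
      s2 <- seg |> filter(.data$vertex == a[k + 1]) |> arrange(.data$genome_index)
      d <- s2$start - s1$end - 1L
      gap_ok[k] <- n_distinct(d) == 1L
    }
  }
  vt <- graph$vertices
  tibble(anchor = a,
         length = vt$length[match(a, vt$vertex)],
         identity = vt$identity[match(a, vt$vertex)],
         gapless_with_next = gap_ok)
}

#' Re-align the region between two anchors
#'
#' Extracts the per-genome sub-sequences strictly between two anchors and
#' runs the full pipeline on them, either at a caller-chosen `m` or at the
#' smallest acyclic `m` found by [auto_m()] (generally much smaller than the
#' global one). Coordinates of the returned graph are reported in original
#' genome coordinates via the `coord_offset` bookkeeping of the sub-genomes.
#'
#' @param graph An `alignment_graph` computed on the full genomes.
#' @param anchor_a,anchor_b Vertex ids of two anchors, `anchor_a` preceding
#'   `anchor_b` (violations raise `phalign_error_anchor_order`).
#' @param m Optional fixed minimum match length; `NULL` (default) searches
#'   with [auto_m()] starting at `m_start`.
#' @param m_start,m_max Search range when `m` is `NULL`.
#' @return An `alignment_graph` for the sub-region (contracted), or an empty
#'   graph when no genome has interior sequence between the anchors.
#' @export
realign_between <- function(graph, anchor_a, anchor_b, m = NULL,
                            m_start = 15L, m_max = 500L) {
  stopifnot(inherits(graph, "alignment_graph"))
  if (!(anchor_a %in% graph$anchors) || !(anchor_b %in% graph$anchors)) {
    ph_abort("anchor_order", "both vertices must be anchors of the graph")
  }
  sa <- graph$segments |> filter(.data$vertex == anchor_a) |>
    arrange(.data$genome_index)
  sb <- graph$segments |> filter(.data$vertex == anchor_b) |>
    arrange(.data$genome_index)
  if (!all(sb$start > sa$end)) {
    ph_abort("anchor_order", "anchor_a must precede anchor_b in every genome")
  }
  lo <- sa$end + 1L
  hi <- sb$start - 1L
  len <- hi - lo + 1L
  keep <- which(len > 0L)
  genomes <- graph$genomes
  if (length(keep) == 0) {
    return(empty_alignment_graph(genomes[integer(0)], m = m))
  }
  sub_seq <- vapply(keep, function(k) {
    substr(genomes$seq[[sa$genome_index[k]]], lo[k], hi[k])
  }, character(1))
  names(sub_seq) <- genomes$info$id[sa$genome_index[keep]]
  sub <- genome_set(sub_seq)
  sub$info$coord_offset <- genomes$info$coord_offset[sa$genome_index[keep]] +
    lo[keep] - 1L
  if (n_genomes(sub) >= 2) {
    if (is.null(m)) {
      found <- auto_m(sub, m_start = m_start, m_max = m_max)
      m_use <- found$m
      matches <- found$matches
    } else {
      m_use <- as.integer(m)
      matches <- find_mems(sub, m_use)
    }
  } else {
    m_use <- as.integer(m %||% m_start)
    matches <- mem_set(tibble(genome_a = character(), start_a = integer(),
                              genome_b = character(), start_b = integer(),
                              length = integer()), sub, m_use)
  }
  part <- split_invalid(build_columns(sub, matches))
  cg <- build_column_graph(part)
  rep <- check_collinear(cg)
  if (!rep$collinear) {
    ph_abort("not_collinear", "sub-region is not collinear at this m",
             sccs = rep$sccs)
  }
  expanded <- merge_same_support(cg)
  expanded$m <- m_use
  out <- contract_graph(expanded)
  out$expanded <- expanded
  out
}

empty_alignment_graph <- function(genomes, m = NULL) {
  new_alignment_graph(
    vertices = tibble(vertex = integer(), kind = character(),
                      length = integer(), n_support = integer(),
                      identity_num = integer(), identity = double()),
    segments = tibble(vertex = integer(), genome_index = integer(),
                      genome = character(), start = integer(),
                      end = integer()),
    edges = tibble(genome_index = integer(), genome = character(),
                   from = integer(), to = integer(), skipped_bp = integer()),
    genomes = genomes, m = m, level = "contracted", members = list())
}

#' Vertex-count statistics of an alignment
#'
#' The summary usually reported for a dataset: number of vertices before and
#' after contraction, number of (contracted-graph) vertices aligning at
#' least two sequences, and number of contracted vertices.
#'
#' @param expanded,contracted The two graphs of the same input.
#' @return A one-row tibble `vertices_before`, `vertices_after`,
#'   `vertices_ge2`, `contracted_count`.
#' @export
graph_stats <- function(expanded, contracted) {
  stopifnot(inherits(expanded, "alignment_graph"),
            inherits(contracted, "alignment_graph"))
  tibble(
    vertices_before = nrow(expanded$vertices),
    vertices_after = nrow(contracted$vertices),
    vertices_ge2 = sum(contracted$vertices$n_support >= 2),
    contracted_count = sum(contracted$vertices$kind == "contracted")
  )
}

#' Check per-genome base-pair conservation
#'
#' In a well-formed alignment graph the vertices tile every genome: walking
#' a genome's vertices in coordinate order, segment lengths plus skipped
#' base pairs on the edges must sum to the genome length, with no overlap.
#'
#' @param graph An `alignment_graph`.
#' @return A tibble of violations (zero rows when the graph is consistent),
#'   with columns `genome`, `expected_bp`, `covered_bp`, `overlapping`.
#' @export
check_conservation <- function(graph) {
  stopifnot(inherits(graph, "alignment_graph"))
  out <- list()
  for (g in seq_len(n_genomes(graph$genomes))) {
    seg <- graph$segments |> filter(.data$genome_index == g) |>
      arrange(.data$start)
    if (nrow(seg) == 0) next
    covered <- sum(seg$end - seg$start + 1L)
    skipped <- sum(graph$edges$skipped_bp[graph$edges$genome_index == g])
    lead_gap <- seg$start[1] - 1L
    trail_gap <- graph$genomes$info$length[g] - seg$end[nrow(seg)]
    overlap <- any(seg$start[-1] <= seg$end[-nrow(seg)])
    total <- covered + skipped + lead_gap + trail_gap
    L <- graph$genomes$info$length[g]
    if (total != L || overlap || lead_gap != 0L || trail_gap != 0L) {
      out[[length(out) + 1L]] <- tibble(
        genome = graph$genomes$info$id[g], expected_bp = L,
        covered_bp = covered + skipped, overlapping = overlap)
    }
  }
  if (length(out) == 0) {
    tibble(genome = character(), expected_bp = integer(),
           covered_bp = integer(), overlapping = logical())
  } else {
    bind_rows(out)
  }
}

#' Align a set of genomes end to end
#'
#' The whole pipeline: (optional) circular normalization, maximal exact
#' match enumeration, union-find column construction, invalid-column
#' splitting, collinearity check, same-support merging, and gapless
#' contraction.
#'
#' Normalization: `"on"` always normalizes, `"off"` never does, and
#' `"auto"` (default) normalizes when the longest all-genome common
#' substring does not start within 1 kb of position 1 in every genome, or
#' when the column graph at the requested `m` turns out cyclic (a circular
#' permutation of otherwise collinear genomes looks like one giant
#' rearrangement until starts are synchronized).
#'
#' @param genomes A `genome_set`.
#' @param m Minimum exact-match length (default 15).
#' @param auto If `TRUE`, search the smallest acyclic `m >= m` with
#'   [auto_m()] instead of failing on cycles.
#' @param normalize `"auto"`, `"off"` or `"on"`.
#' @param contract If `FALSE`, stop at the expanded graph.
#' @param m_max Ceiling for the `auto` search.
#' @return A contracted `alignment_graph` (expanded when
#'   `contract = FALSE`) with extra elements: `expanded` (the pre-contraction
#'   graph), `matches` (the `mem_set` used), `normalization` (offsets tibble
#'   or `NULL`), and `m` (the value actually used). Non-collinear input
#'   without `auto` raises `phalign_error_not_collinear` carrying the SCC
#'   report in its `sccs` field.
#' @examples
#' gs <- generate_mosaic(mosaic_spec(n_genomes = 3, n_modules = 3, seed = 7))
#' g <- align_genomes(gs$genomes, m = 15)
#' glance(g)
#' @export
align_genomes <- function(genomes, m = 15L, auto = FALSE,
                          normalize = c("auto", "off", "on"),
                          contract = TRUE, m_max = 500L) {
  stopifnot(inherits(genomes, "genome_set"))
  normalize <- match.arg(normalize)
  m <- as.integer(m)
  norm_offsets <- NULL
  if (normalize == "on" ||
      (normalize == "auto" && n_genomes(genomes) >= 2 &&
       offsets_suggest_normalization(genomes, m = m))) {
    nr <- normalize_genomes(genomes, m = min(m, min(genomes$info$length)))
    genomes <- nr$genomes
    norm_offsets <- nr$offsets
  }
  build <- function(gset) {
    if (n_genomes(gset) >= 2) {
      if (auto) {
        found <- auto_m(gset, m_start = m, m_max = m_max)
        list(m = found$m, matches = found$matches)
      } else {
        list(m = m, matches = find_mems(gset, m))
      }
    } else {
      list(m = m, matches = mem_set(
        tibble(genome_a = character(), start_a = integer(),
               genome_b = character(), start_b = integer(),
               length = integer()), gset, m))
    }
  }
  bb <- build(genomes)
  part <- split_invalid(build_columns(genomes, bb$matches))
  cg <- build_column_graph(part)
  rep <- check_collinear(cg)
  if (!rep$collinear && normalize == "auto" && is.null(norm_offsets) &&
      n_genomes(genomes) >= 2) {
    nr <- tryCatch(
      normalize_genomes(genomes, m = min(m, min(genomes$info$length))),
      phalign_error = function(e) NULL)
    if (!is.null(nr) && any(nr$offsets$offset > 0)) {
      genomes <- nr$genomes
      norm_offsets <- nr$offsets
      bb <- build(genomes)
      part <- split_invalid(build_columns(genomes, bb$matches))
      cg <- build_column_graph(part)
      rep <- check_collinear(cg)
    }
  }
  if (!rep$collinear) {
    ph_abort("not_collinear",
             "genomes are not functionally collinear at this m",
             sccs = rep$sccs)
  }
  expanded <- merge_same_support(cg)
  expanded$m <- bb$m
  out <- if (contract) contract_graph(expanded) else expanded
  out$m <- bb$m
  out$expanded <- expanded
  out$matches <- bb$matches
  out$normalization <- norm_offsets
  out
}

#' Serialize an alignment graph to JSON
#'
#' Stable key order, exact integers for lengths and identity numerators, so
#' output is diff-able across runs.
#'
#' @param graph An `alignment_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "alignment_graph"))
  vs <- graph$vertices |> arrange(.data$vertex)
  segs <- split(graph$segments, graph$segments$vertex)
  verts <- lapply(seq_len(nrow(vs)), function(k) {
    v <- vs$vertex[k]
    sg <- segs[[as.character(v)]]
    segl <- setNames(
      lapply(seq_len(nrow(sg)), function(i) c(sg$start[i], sg$end[i])),
      sg$genome)
    list(id = v, kind = vs$kind[k], length = vs$length[k],
         identity_num = vs$identity_num[k], identity = vs$identity[k],
         segments = segl)
  })
  ed <- graph$edges |> arrange(.data$genome_index, .data$from)
  edges <- lapply(seq_len(nrow(ed)), function(k) {
    list(genome = ed$genome[k], from = ed$from[k], to = ed$to[k],
         skipped_bp = ed$skipped_bp[k])
  })
  obj <- list(
    genomes = lapply(seq_len(n_genomes(graph$genomes)), function(g) {
      list(id = graph$genomes$info$id[g],
           length = graph$genomes$info$length[g])
    }),
    m = graph$m, level = graph$level, vertices = verts, edges = edges,
    anchors = as.list(graph$anchors)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
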