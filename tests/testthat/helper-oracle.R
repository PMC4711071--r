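# Independent reference implementations ("oracles") used to cross-check the
# suffix-array / union-find pipeline on small instances. They deliberately
# use different mechanics: graph-component closure instead of union-find,
# set-based successor tests instead of count-based ones, and
# reachability-based contraction straight from the contractibility
# definition.

# Columns as connected components of the position-equality graph.
oracle_columns <- function(genomes, matches) {
  lens <- genomes$info$length
  n_total <- sum(lens)
  cumb <- c(0L, cumsum(lens))[seq_along(lens)]
  ia <- match(matches$genome_a, genomes$info$id)
  ib <- match(matches$genome_b, genomes$info$id)
  efrom <- integer(0)
  eto <- integer(0)
  for (k in seq_len(nrow(matches))) {
    off <- seq_len(matches$length[k]) - 1L
    efrom <- c(efrom, cumb[ia[k]] + matches$start_a[k] + off)
    eto <- c(eto, cumb[ib[k]] + matches$start_b[k] + off)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(efrom), to = as.character(eto)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n_total))))
  memb <- igraph::components(g)$membership[as.character(seq_len(n_total))]
  match(memb, unique(memb))  # dense, in order of first appearance
}

# Invalid-column splitting, plain base R.
oracle_split <- function(col_of, genomes) {
  gidx <- rep(seq_len(nrow(genomes$info)), genomes$info$length)
  key <- paste(col_of, gidx)
  bad_cols <- unique(col_of[duplicated(key)])
  hit <- col_of %in% bad_cols
  col_of[hit] <- max(col_of) + seq_len(sum(hit))
  match(col_of, unique(col_of))
}

# Column-graph edge table (per-genome adjacency); the construction is
# definitional, shared with the implementation on purpose.
oracle_column_edges <- function(col_of, genomes) {
  lens <- genomes$info$length
  ends <- cumsum(lens)
  p <- setdiff(seq_len(sum(lens)), ends)
  data.frame(from = col_of[p], to = col_of[p + 1L],
             genome_index = rep(seq_along(lens), lens)[p])
}

# Merge consecutive same-support columns, testing successors by exact
# position-set equality rather than counts.
oracle_merge_vmap <- function(col_of, genomes) {
  lens <- genomes$info$length
  ends <- cumsum(lens)
  n_total <- sum(lens)
  pos_by_col <- split(seq_len(n_total), col_of)
  n_col <- max(col_of)
  succ <- rep(NA_integer_, n_col)
  for (c in seq_len(n_col)) {
    p <- pos_by_col[[as.character(c)]]
    if (any(p %in% ends)) next
    q <- p + 1L
    d <- unique(col_of[q])
    if (length(d) != 1L) next
    if (!identical(sort(pos_by_col[[as.character(d)]]), sort(q))) next
    succ[c] <- d
  }
  is_target <- logical(n_col)
  is_target[succ[!is.na(succ)]] <- TRUE
  vmap <- integer(n_col)
  vid <- 0L
  for (s in which(!is_target)) {
    vid <- vid + 1L
    c <- s
    while (!is.na(c)) {
      vmap[c] <- vid
      c <- succ[c]
    }
  }
  vmap
}

oracle_merge_segments <- function(col_of, genomes) {
  vmap <- oracle_merge_vmap(col_of, genomes)
  lens <- genomes$info$length
  df <- data.frame(v = vmap[col_of],
                   genome_index = rep(seq_along(lens), lens),
                   position = sequence(lens))
  agg <- aggregate(position ~ v + genome_index, df,
                   function(x) c(min(x), max(x)))
  data.frame(vertex = agg$v, genome_index = agg$genome_index,
             start = agg$position[, 1], end = agg$position[, 2])
}

# Definition-based contraction: U precedes V (reachability), same support,
# every vertex on a directed path from U to V has support within sp(V),
# equal spans. Applied greedily, smallest vertex first, until fixpoint.
oracle_contract_segments <- function(seg, genomes) {
  seg <- seg[order(seg$vertex, seg$genome_index), ]
  kind <- ifelse(tabulate(seg$vertex)[sort(unique(seg$vertex))] == 1L,
                 "singleton", "exact")
  names(kind) <- as.character(sort(unique(seg$vertex)))
  repeat {
    ids <- sort(unique(seg$vertex))
    sup <- lapply(split(seg$genome_index, seg$vertex), sort)
    ed <- do.call(rbind, lapply(seq_len(nrow(genomes$info)), function(g) {
      sg <- seg[seg$genome_index == g, ]
      sg <- sg[order(sg$start), ]
      if (nrow(sg) < 2) return(NULL)
      data.frame(from = sg$vertex[-nrow(sg)], to = sg$vertex[-1])
    }))
    if (is.null(ed)) ed <- data.frame(from = integer(0), to = integer(0))
    gr <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$from), to = as.character(ed$to)),
      vertices = data.frame(name = as.character(ids)))
    reach <- igraph::distances(gr, mode = "out")
    can <- function(a, b) a != b && is.finite(reach[as.character(a),
                                                    as.character(b)])
    merged <- FALSE
    for (u in ids) {
      S <- sup[[as.character(u)]]
      same <- ids[vapply(ids, function(v) {
        v != u && identical(sup[[as.character(v)]], S) && can(u, v)
      }, logical(1))]
      if (length(same) == 0) next
      sg1 <- seg[seg$genome_index == S[1], ]
      startg <- setNames(sg1$start, sg1$vertex)
      v <- same[which.min(startg[as.character(same)])]
      between <- ids[vapply(ids, function(w) {
        w != u && w != v && can(u, w) && can(w, v)
      }, logical(1))]
      if (any(vapply(between, function(w) {
        !all(sup[[as.character(w)]] %in% S)
      }, logical(1)))) next
      su <- seg[seg$vertex == u, ]
      su <- su[order(su$genome_index), ]
      sv <- seg[seg$vertex == v, ]
      sv <- sv[order(sv$genome_index), ]
      spans <- sv$end - su$start + 1L
      if (length(unique(spans)) != 1L) next
      seg <- seg[!(seg$vertex %in% c(u, v, between)), ]
      seg <- rbind(seg, data.frame(vertex = u, genome_index = S,
                                   start = su$start, end = sv$end))
      kind[as.character(u)] <- "contracted"
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  list(segments = seg[order(seg$vertex, seg$genome_index), ], kind = kind)
}

# Conserved-column count straight from the sequences, one column at a time.
oracle_identity_num <- function(genomes, seg_v) {
  seg_v <- seg_v[order(seg_v$genome_index), ]
  len <- seg_v$end[1] - seg_v$start[1] + 1L
  chars <- lapply(seq_len(nrow(seg_v)), function(i) {
    strsplit(substr(genomes$seq[[seg_v$genome_index[i]]], seg_v$start[i],
                    seg_v$end[i]), "")[[1]]
  })
  n_ok <- 0L
  for (k in seq_len(len)) {
    col <- vapply(chars, `[`, character(1), k)
    if (length(unique(col)) == 1L && col[1] != "N") n_ok <- n_ok + 1L
  }
  n_ok
}

# Canonical, id-free serialization of an alignment graph for comparison:
# vertices keyed by their segment sets, edges rewritten over those keys.
graph_signature <- function(segments, kinds, identity_nums, genomes) {
  segments <- segments[order(segments$vertex, segments$genome_index), ]
  keys <- vapply(split(segments, segments$vertex), function(sg) {
    paste(sprintf("%d:%d-%d", sg$genome_index, sg$start, sg$end),
          collapse = ";")
  }, character(1))
  ids <- as.integer(names(keys))
  vt <- data.frame(key = unname(keys), kind = kinds[as.character(ids)],
                   identity_num = identity_nums[as.character(ids)])
  vt <- vt[order(vt$key), ]
  rownames(vt) <- NULL
  emap <- setNames(unname(keys), ids)
  ed <- do.call(rbind, lapply(seq_len(nrow(genomes$info)), function(g) {
    sg <- segments[segments$genome_index == g, ]
    sg <- sg[order(sg$start), ]
    if (nrow(sg) < 2) return(NULL)
    data.frame(genome_index = g,
               from = emap[as.character(sg$vertex[-nrow(sg)])],
               to = emap[as.character(sg$vertex[-1])],
               skipped = sg$start[-1] - sg$end[-nrow(sg)] - 1L)
  }))
  if (!is.null(ed)) {
    ed <- ed[order(ed$genome_index, ed$from), ]
    rownames(ed) <- NULL
  }
  list(vertices = vt, edges = ed)
}

# Signature of a phalign alignment_graph object.
impl_signature <- function(graph) {
  segs <- as.data.frame(graph$segments[, c("vertex", "genome_index",
                                           "start", "end")])
  kinds <- setNames(graph$vertices$kind, graph$vertices$vertex)
  idn <- setNames(graph$vertices$identity_num, graph$vertices$vertex)
  graph_signature(segs, kinds, idn, graph$genomes)
}

# Full oracle pipeline: naive MEMs -> component columns -> split -> merge ->
# contract, returning the canonical signature.
oracle_signature <- function(genomes, m) {
  matches <- find_mems_naive(genomes, m)
  col_of <- oracle_split(oracle_columns(genomes, matches), genomes)
  seg <- oracle_merge_segments(col_of, genomes)
  ctr <- oracle_contract_segments(seg, genomes)
  idn <- vapply(split(ctr$segments, ctr$segments$vertex), function(sg) {
    if (ctr$kind[as.character(sg$vertex[1])] == "contracted") {
      oracle_identity_num(genomes, sg)
    } else {
      sg$end[1] - sg$start[1] + 1L
    }
  }, integer(1))
  names(idn) <- names(split(ctr$segments, ctr$segments$vertex))
  graph_signature(ctr$segments, ctr$kind, idn, genomes)
}
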