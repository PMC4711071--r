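test_that("a single genome without matches is a path of singleton columns", {
  gs <- genome_set(c(g = "ACGT"))
  empty <- mem_set(data.frame(genome_a = character(), start_a = integer(),
                              genome_b = character(), start_b = integer(),
                              length = integer()), gs)
  cg <- build_column_graph(build_columns(gs, empty))
  expect_equal(cg$partition$n_columns, 4L)
  expect_equal(nrow(cg$edges), 3L)
  expect_true(check_collinear(cg)$collinear)
  ex <- merge_same_support(cg)
  expect_equal(nrow(ex$vertices), 1L)
  expect_equal(ex$vertices$kind, "singleton")
  expect_equal(ex$vertices$length, 4L)
})

test_that("two overlapping matches over three genomes merge to the
           five-vertex shape", {
  # matches: {G1[2..5], G2[1..4]} and {G2[2..5], G3[1..4]}, total length 8
  gs <- genome_set(c(G1 = "AACCT", G2 = "ACCTG", G3 = "CCTGG"))
  mm <- mem_set(data.frame(genome_a = c("G1", "G2"), start_a = c(2L, 2L),
                           genome_b = c("G2", "G3"), start_b = c(1L, 1L),
                           length = c(4L, 4L)), gs)
  part <- split_invalid(build_columns(gs, mm))
  cg <- build_column_graph(part)
  ex <- merge_same_support(cg)
  expect_equal(nrow(ex$vertices), 5L)
  sig <- impl_signature(ex)
  expect_setequal(sig$vertices$key,
                  c("1:1-1", "1:2-2;2:1-1", "1:3-5;2:2-4;3:1-3",
                    "2:5-5;3:4-4", "3:5-5"))
  # the central vertex aligns all three genomes over the shared "CCT..."
  expect_equal(sort(ex$vertices$n_support), c(1L, 1L, 2L, 2L, 3L))
})

test_that("a transposed block creates a cycle reported as one SCC", {
  gs <- transposition_pair(20, seed = 201)
  mm <- find_mems(gs, 15)
  cg <- build_column_graph(split_invalid(build_columns(gs, mm)))
  rep <- check_collinear(cg)
  expect_false(rep$collinear)
  expect_equal(dplyr::n_distinct(rep$sccs$scc), 1L)
  # the SCC interval spans both planted blocks (A: X at 61-80, Y at 121-140)
  a_int <- rep$sccs[rep$sccs$genome == "A", ]
  expect_lte(a_int$start, 80)
  expect_gte(a_int$end, 121)
  expect_ph_error(merge_same_support(cg), "cyclic")
})

test_that("random unrelated genomes are collinear at m = 15", {
  for (seed in 211:215) {
    gs <- random_genome_set(2, c(400, 700), seed = seed)
    g <- align_genomes(gs, m = 15, normalize = "off")
    expect_s3_class(g, "alignment_graph")
  }
})

test_that("contraction merges same-support vertices across mismatch
           columns and computes exact identity", {
  gs <- identity_fixture()
  g <- align_genomes(gs, m = 15, normalize = "off")
  ctr <- g$vertices[g$vertices$kind == "contracted", ]
  expect_equal(nrow(ctr), 1L)
  expect_equal(ctr$length, 169L)
  expect_equal(ctr$identity_num, 167L)
  expect_equal(ctr$identity, 167 / 169)
  # all four genomes participate and spans are gapless
  seg <- g$segments[g$segments$vertex == ctr$vertex, ]
  expect_equal(nrow(seg), 4L)
  expect_equal(unique(seg$end - seg$start + 1L), 169L)
})

test_that("no contraction when an in-between vertex leaves the support", {
  # S1/S2 share blocks U and V; S3 shares a block W that sits between them
  # in S1 only, so sp(W) is not within sp(V) on S1's path
  withr::with_seed(301, {
    u <- random_dna(40); v <- random_dna(40); w <- random_dna(30)
    gs <- genome_set(c(
      S1 = paste0(random_dna(20), u, w, v, random_dna(20)),
      S2 = paste0(random_dna(25), u, random_dna(30), v, random_dna(25)),
      S3 = paste0(random_dna(60), w, random_dna(60))))
  })
  g <- align_genomes(gs, m = 15, normalize = "off")
  expect_equal(sum(g$vertices$kind == "contracted"), 0L)
  uv <- g$vertices[g$vertices$n_support == 2 & g$vertices$length >= 40, ]
  expect_equal(nrow(uv), 2L)  # U and V remain separate exact vertices
  expect_true(all(uv$kind == "exact"))
})

test_that("contraction soundness: members re-expand to the expanded graph", {
  sim <- oracle_instance(302, n_genomes = 3)
  g <- align_genomes(sim$genomes, m = 15, normalize = "off")
  ex <- g$expanded
  # members partition the expanded vertex set
  all_members <- sort(unlist(g$members))
  expect_identical(all_members, sort(ex$vertices$vertex))
  # each contracted vertex's members tile its span exactly, per genome
  for (k in which(g$vertices$kind == "contracted")) {
    v <- g$vertices$vertex[k]
    mem <- g$members[[v]]
    seg_c <- g$segments[g$segments$vertex == v, ]
    seg_e <- ex$segments[ex$segments$vertex %in% mem, ]
    for (gi in seg_c$genome_index) {
      covered <- seg_e[seg_e$genome_index == gi, ]
      lo <- seg_c$start[seg_c$genome_index == gi]
      hi <- seg_c$end[seg_c$genome_index == gi]
      pos <- unlist(mapply(seq, covered$start, covered$end,
                           SIMPLIFY = FALSE))
      expect_identical(sort(pos), seq(lo, hi))
    }
  }
})

test_that("anchors: identical genomes give one all-covering anchor;
           planted blocks appear in order", {
  set.seed(303)
  s <- random_dna(400)
  gs <- genome_set(c(a = s, b = s, c = s))
  g <- align_genomes(gs, m = 15, normalize = "off")
  expect_equal(nrow(g$vertices), 1L)
  expect_equal(length(g$anchors), 1L)
  an <- compute_anchors(g)
  expect_equal(an$length, 400L)

  sim <- generate_mosaic(mosaic_spec(seed = 304))
  g2 <- align_genomes(sim$genomes, m = 15, normalize = "off")
  an2 <- compute_anchors(g2)
  ub <- sim$truth[grepl("^universal:", sim$truth$feature) &
                    sim$truth$genome == "g1", ]
  ub <- ub[order(ub$start), ]
  expect_equal(nrow(an2), 3L)
  seg_g1 <- g2$segments[g2$segments$genome == "g1", ]
  starts <- seg_g1$start[match(an2$anchor, seg_g1$vertex)]
  # backbone order matches planted genomic order, each anchor contains its block
  expect_false(is.unsorted(starts))
  for (i in 1:3) {
    s1 <- seg_g1[seg_g1$vertex == an2$anchor[i], ]
    expect_lte(s1$start, ub$start[i])
    expect_gte(s1$end, ub$end[i])
  }
})

test_that("anchors are articulation points of the underlying graph", {
  sim <- generate_mosaic(mosaic_spec(seed = 305))
  g <- align_genomes(sim$genomes, m = 15, normalize = "off")
  ed <- g$edges
  gr <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(g$vertices$vertex)))
  arts <- as.integer(names(igraph::articulation_points(gr)))
  # interior anchors (not first/last vertex of the whole graph) disconnect it
  interior <- setdiff(g$anchors, c(min(g$vertices$vertex),
                                   max(g$vertices$vertex)))
  expect_true(all(interior %in% arts))
})

test_that("re-aligning between anchors reveals short shared blocks at a
           smaller m", {
  withr::with_seed(306, {
    u1 <- random_dna(80)
    u2 <- random_dna(80)
    hidden <- random_dna(18)
    gs <- genome_set(c(
      a = paste0(u1, random_dna(70), hidden, random_dna(70), u2),
      b = paste0(u1, random_dna(90), hidden, random_dna(52), u2),
      c = paste0(u1, random_dna(60), hidden, random_dna(85), u2)))
  })
  g <- align_genomes(gs, m = 50, normalize = "off")
  expect_equal(length(g$anchors), 2L)
  sub <- realign_between(g, g$anchors[1], g$anchors[2], m = 15)
  hit <- sub$vertices[sub$vertices$n_support == 3, ]
  expect_gte(nrow(hit), 1L)
  expect_true(any(hit$length >= 18))
  # coordinates come back in original frame via display offsets
  td <- tidy(sub)
  a_rows <- td[td$genome == "a" & td$n_support == 3, ]
  expect_true(all(a_rows$start > 80 & a_rows$end <= 80 + 70 + 18 + 70))
  expect_ph_error(realign_between(g, g$anchors[2], g$anchors[1]),
                  "anchor_order")
})

test_that("adjacent anchors with nothing between give an empty interior", {
  set.seed(307)
  core <- random_dna(200)
  gs <- genome_set(c(a = core, b = core))
  g <- align_genomes(gs, m = 15, normalize = "off")
  expect_equal(length(g$anchors), 1L)
  # split the single anchor artificially by mutating one base in b
  s2 <- core
  substr(s2, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                  substr(core, 100, 100))[1]
  gs2 <- genome_set(c(a = core, b = s2))
  g2 <- align_genomes(gs2, m = 15, normalize = "off", contract = FALSE)
  expect_equal(length(g2$anchors), 2L)
  sub <- realign_between(g2, g2$anchors[1], g2$anchors[2], m = 15)
  # only the single mismatched base lies between: one singleton per genome
  expect_true(all(sub$vertices$n_support == 1))
  expect_equal(sum(sub$vertices$length), 2L)
})

test_that("graph stats count vertices as published tables do", {
  gs <- genome_set(c(g = "ACGTACGTAC"))
  g <- align_genomes(gs, m = 15, normalize = "off")
  st <- graph_stats(g$expanded, g)
  expect_equal(st$vertices_ge2, 0L)
  expect_equal(st$contracted_count, 0L)

  sim <- generate_mosaic(mosaic_spec(seed = 308))
  g2 <- align_genomes(sim$genomes, m = 15, normalize = "off")
  st2 <- graph_stats(g2$expanded, g2)
  expect_equal(st2$vertices_before, nrow(g2$expanded$vertices))
  expect_equal(st2$vertices_after, nrow(g2$vertices))
  expect_gte(st2$vertices_before, st2$vertices_after)
  expect_equal(st2$vertices_ge2,
               sum(g2$vertices$n_support >= 2))
})

test_that("per-genome conservation and the DAG invariant hold on every
           build", {
  for (seed in 311:314) {
    sim <- generate_mosaic(mosaic_spec(seed = seed))
    g <- align_genomes(sim$genomes, m = 15, normalize = "off")
    expect_equal(nrow(check_conservation(g)), 0L)
    expect_equal(nrow(check_conservation(g$expanded)), 0L)
    ed <- g$edges
    gr <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$from), to = as.character(ed$to)),
      vertices = data.frame(name = as.character(g$vertices$vertex)))
    expect_true(igraph::is_dag(gr))
    # vertex ids are a topological order: every edge goes forward
    expect_true(all(ed$from < ed$to))
  }
})
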