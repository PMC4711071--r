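test_that("generation is deterministic for a given spec and seed", {
  sp <- mosaic_spec(n_genomes = 3, n_modules = 3, seed = 501)
  a <- generate_mosaic(sp)
  b <- generate_mosaic(sp)
  expect_identical(a$genomes$seq, b$genomes$seq)
  expect_identical(a$truth, b$truth)
  c <- generate_mosaic(mosaic_spec(n_genomes = 3, n_modules = 3, seed = 502))
  expect_false(identical(a$genomes$seq, c$genomes$seq))
})

test_that("truth intervals tile each genome without overlap", {
  sim <- generate_mosaic(mosaic_spec(seed = 503))
  for (id in sim$genomes$info$id) {
    tr <- sim$truth[sim$truth$genome == id, ]
    tr <- tr[order(tr$start), ]
    expect_equal(tr$start[1], 1L)
    expect_equal(tr$end[nrow(tr)],
                 sim$genomes$info$length[sim$genomes$info$id == id])
    expect_true(all(tr$start[-1] == tr$end[-nrow(tr)] + 1L))
  }
})

test_that("spec validation rejects impossible settings", {
  expect_ph_error(mosaic_spec(n_genomes = 0), "infeasible_spec")
  expect_ph_error(mosaic_spec(substitution_rate = 1), "infeasible_spec")
  expect_ph_error(mosaic_spec(module_length_range = c(0, 10)),
                  "infeasible_spec")
  expect_ph_error(mosaic_spec(n_genomes = 500, n_modules = 500,
                              module_length_range = c(4000, 5000)),
                  "infeasible_spec")
})

test_that("distinct variants share no 15-mer; universal blocks are exact", {
  sim <- generate_mosaic(mosaic_spec(seed = 504, n_genomes = 4,
                                     variants_per_module = 2))
  gs <- sim$genomes
  # planted universal blocks are exactly equal across genomes
  ub <- sim$truth[grepl("^universal:", sim$truth$feature), ]
  for (u in unique(ub$feature)) {
    rows <- ub[ub$feature == u, ]
    pieces <- vapply(seq_len(nrow(rows)), function(i) {
      substr(gs$seq[[rows$genome[i]]], rows$start[i], rows$end[i])
    }, character(1))
    expect_equal(length(unique(pieces)), 1L)
  }
  # no maximal exact match links different variants of one module
  mm <- find_mems(gs, 15)
  tr <- sim$truth
  feat_at <- function(genome, pos) {
    r <- tr[tr$genome == genome & tr$start <= pos & tr$end >= pos, ]
    r$feature[1]
  }
  mod_of <- function(f) if (grepl("^module", f)) sub(":v\\d+$", "", f) else NA
  for (k in seq_len(nrow(mm))) {
    fa <- feat_at(mm$genome_a[k], mm$start_a[k] + mm$length[k] %/% 2)
    fb <- feat_at(mm$genome_b[k], mm$start_b[k] + mm$length[k] %/% 2)
    ma <- mod_of(fa)
    mb <- mod_of(fb)
    if (!is.na(ma) && !is.na(mb) && ma == mb) {
      expect_identical(fa, fb)  # same module implies same variant
    }
  }
})

test_that("uniform single-variant spec without linkers gives identical
           genomes and one full-support vertex", {
  sp <- mosaic_spec(n_genomes = 4, n_modules = 3, variants_per_module = 1,
                    linker_length_range = c(0, 0), substitution_rate = 0,
                    indel_rate = 0, universal_block_lengths = integer(0),
                    seed = 505)
  sim <- generate_mosaic(sp)
  expect_equal(length(unique(sim$genomes$seq)), 1L)
  g <- align_genomes(sim$genomes, m = 15, normalize = "off")
  expect_equal(nrow(g$vertices), 1L)
  expect_equal(g$vertices$n_support, 4L)
  expect_equal(length(g$anchors), 1L)
})

test_that("variant partitions switch between modules (mosaic signature)", {
  # with 2 variants and 4 genomes some pair of modules splits the genomes
  # differently; the alignment reflects both groupings
  found <- FALSE
  for (seed in 506:512) {
    sp <- mosaic_spec(n_genomes = 4, n_modules = 4, variants_per_module = 2,
                      seed = seed)
    sim <- generate_mosaic(sp)
    groupings <- vapply(1:4, function(j) {
      tr <- sim$truth[grepl(sprintf("^module%d:", j), sim$truth$feature), ]
      tr <- tr[order(tr$genome), ]
      paste(tr$feature, collapse = ",")
    }, character(1))
    two_sided <- vapply(1:4, function(j) {
      tr <- sim$truth[grepl(sprintf("^module%d:", j), sim$truth$feature), ]
      length(unique(tr$feature)) == 2 && all(table(tr$feature) == 2)
    }, logical(1))
    pair <- which(two_sided)
    if (length(pair) >= 2 && groupings[pair[1]] != groupings[pair[2]]) {
      found <- TRUE
      g <- align_genomes(sim$genomes, m = 15, normalize = "off")
      for (j in pair[1:2]) {
        tr <- sim$truth[grepl(sprintf("^module%d:", j), sim$truth$feature), ]
        for (v in unique(tr$feature)) {
          members <- sort(tr$genome[tr$feature == v])
          # some vertex aligns exactly this genome pair inside the module
          seg <- g$segments |>
            dplyr::inner_join(tr[tr$feature == v, ], by = "genome",
                              suffix = c("", ".t")) |>
            dplyr::filter(start >= start.t, end <= end.t)
          counts <- table(seg$vertex)
          cand <- names(counts)[counts == 2]
          ok <- vapply(cand, function(vv) {
            setequal(seg$genome[seg$vertex == as.integer(vv)], members)
          }, logical(1))
          expect_true(any(ok))
        }
      }
      break
    }
  }
  expect_true(found)
})
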