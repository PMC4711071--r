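test_that("worked example: every reported MEM is a maximal true equality", {
  gs <- genome_set(c(G1 = "ACGTACGTAA", G2 = "TTACGTACGG"))
  mm <- find_mems(gs, m = 5)
  # the 7 bp match {G1[1..7], G2[3..9]} = "ACGTACG" must be found; the
  # repeat structure of these strings yields one further maximal match,
  # {G1[4..9], G2[2..7]} = "TACGTA" (verified by the diagonal brute force)
  expect_equal(nrow(mm), 2L)
  expect_true(any(mm$start_a == 1 & mm$start_b == 3 & mm$length == 7))
  expect_true(any(mm$start_a == 4 & mm$start_b == 2 & mm$length == 6))
  for (k in seq_len(nrow(mm))) {
    sa <- substr(gs$seq[[mm$genome_a[k]]], mm$start_a[k],
                 mm$start_a[k] + mm$length[k] - 1)
    sb <- substr(gs$seq[[mm$genome_b[k]]], mm$start_b[k],
                 mm$start_b[k] + mm$length[k] - 1)
    expect_identical(sa, sb)
  }
  expect_identical(as.data.frame(find_mems_naive(gs, 5)), as.data.frame(mm))
})

test_that("two identical genomes give one full-length match", {
  set.seed(61)
  s <- random_dna(300)
  gs <- genome_set(c(a = s, b = s))
  mm <- find_mems(gs, m = 20)
  expect_equal(nrow(mm), sum(mm$length == 300 & mm$start_a == 1 &
                               mm$start_b == 1))
  expect_equal(attr(mm, "total_match_length"), sum(mm$length))
})

test_that("suffix-array engine agrees with the diagonal brute force", {
  for (seed in 1:8) {
    gs <- if (seed <= 4) {
      random_genome_set(2, c(150, 300), seed = 100 + seed)
    } else {
      oracle_instance(100 + seed, n_genomes = 3)$genomes
    }
    for (m in c(8L, 15L)) {
      a <- as.data.frame(find_mems(gs, m))
      b <- as.data.frame(find_mems_naive(gs, m))
      expect_identical(a, b)
    }
  }
})

test_that("match count and total length are non-increasing in m", {
  sim <- oracle_instance(77, n_genomes = 3)
  prev_n <- Inf
  prev_ml <- Inf
  for (m in c(10L, 15L, 25L, 60L)) {
    mm <- find_mems(sim$genomes, m)
    expect_lte(nrow(mm), prev_n)
    expect_lte(attr(mm, "total_match_length"), prev_ml)
    expect_true(all(mm$length >= m))
    prev_n <- nrow(mm)
    prev_ml <- attr(mm, "total_match_length")
  }
})

test_that("output is invariant under genome order reversal", {
  sim <- oracle_instance(78, n_genomes = 3)
  gs <- sim$genomes
  rev_gs <- gs[rev(gs$info$id)]
  a <- as.data.frame(find_mems(gs, 15))
  b <- as.data.frame(find_mems(rev_gs, 15))
  # canonicalize both on (id pair sorted lexicographically)
  canon <- function(df) {
    flip <- df$genome_a > df$genome_b
    tmp <- df
    tmp$genome_a[flip] <- df$genome_b[flip]
    tmp$start_a[flip] <- df$start_b[flip]
    tmp$genome_b[flip] <- df$genome_a[flip]
    tmp$start_b[flip] <- df$start_a[flip]
    tmp[order(tmp$genome_a, tmp$genome_b, tmp$start_a, tmp$start_b), ]
  }
  expect_equal(unname(as.matrix(canon(a)[, -1])),
               unname(as.matrix(canon(b)[, -1])))
  expect_equal(canon(a)$genome_a, canon(b)$genome_a)
})

test_that("N never participates in a match", {
  gs <- genome_set(c(a = "ACGTNNNNACGTACGT", b = "TTTTNNNNACGTACGA"))
  mm <- find_mems(gs, m = 4)
  for (k in seq_len(nrow(mm))) {
    sa <- substr(gs$seq[[mm$genome_a[k]]], mm$start_a[k],
                 mm$start_a[k] + mm$length[k] - 1)
    expect_false(grepl("N", sa))
  }
  expect_identical(as.data.frame(find_mems_naive(gs, 4)),
                   as.data.frame(mm))
})

test_that("m larger than every genome yields an empty match set", {
  gs <- genome_set(c(a = "ACGTACGT", b = "ACGTACGA"))
  expect_equal(nrow(find_mems(gs, 50)), 0L)
  expect_ph_error(find_mems(genome_set(c(a = "ACGT")), 2),
                  "too_few_genomes")
})

test_that("auto_m returns m_start on collinear input and k+1 past a
           transposed block of length k", {
  sim <- oracle_instance(79, n_genomes = 3)
  found <- auto_m(sim$genomes, m_start = 15)
  expect_equal(found$m, 15L)

  for (k in c(12L, 30L)) {
    sp <- mosaic_spec(n_genomes = 2, n_modules = 4, variants_per_module = 1,
                      module_length_range = c(80, 160),
                      linker_length_range = c(20, 40),
                      substitution_rate = 0, indel_rate = 0,
                      universal_block_lengths = integer(0),
                      transpositions = list(list(genome = 2,
                                                 block_length = k)),
                      seed = 900 + k)
    sim_t <- generate_mosaic(sp)
    # cyclic at m = min(m_start, k), acyclic at k + 1
    start <- min(11L, k)
    found <- auto_m(sim_t$genomes, m_start = start)
    expect_equal(found$m, k + 1L)
  }
})

test_that("auto_m reports SCCs when the ceiling is reached", {
  gs <- transposition_pair(40, seed = 81)
  err <- tryCatch(auto_m(gs, m_start = 15, m_max = 25),
                  phalign_error_m_ceiling = function(e) e)
  expect_s3_class(err, "phalign_error_m_ceiling")
  expect_gt(nrow(err$sccs), 0)
})

test_that("match TSV export/import round-trips", {
  sim <- oracle_instance(82)
  mm <- find_mems(sim$genomes, 15)
  withr::with_tempdir({
    write_matches(mm, "matches.tsv")
    back <- read_matches("matches.tsv", sim$genomes, m = 15)
    expect_identical(as.data.frame(back), as.data.frame(mm))
  })
})
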