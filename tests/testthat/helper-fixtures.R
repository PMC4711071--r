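# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random unrelated genomes (no construction constraints).
random_genome_set <- function(n_genomes, length_range, seed) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_genomes), function(i) {
      random_dna(sample(length_range[1]:length_range[2], 1))
    }, character(1))
    names(seqs) <- sprintf("r%d", seq_len(n_genomes))
    genome_set(seqs)
  })
}

# Small related instances for oracle cross-checks: a scaled-down mosaic.
oracle_instance <- function(seed, n_genomes = 2, n_modules = 3,
                            duplication = NULL) {
  generate_mosaic(mosaic_spec(
    n_genomes = n_genomes, n_modules = n_modules, variants_per_module = 2,
    module_length_range = c(80, 160), linker_length_range = c(20, 40),
    substitution_rate = 0.01, indel_rate = 1e-3,
    universal_block_lengths = c(40, 60), duplication = duplication,
    seed = seed))
}

# Two genomes sharing blocks X and Y in swapped order (a transposition),
# with genome-specific sequence around them.
transposition_pair <- function(block_len, seed) {
  withr::with_seed(seed, {
    x <- random_dna(block_len)
    y <- random_dna(block_len)
    f1 <- random_dna(60); f2 <- random_dna(60)
    g1 <- random_dna(60); g2 <- random_dna(60)
    mid1 <- random_dna(40); mid2 <- random_dna(40)
    genome_set(c(A = paste0(f1, x, mid1, y, f2),
                 B = paste0(g1, y, mid2, x, g2)))
  })
}

# Four genomes with a 169 bp contractible core carrying exactly two single
# nucleotide differences in genome 2 (at core offsets 60 and 120), flanked
# by genome-specific sequence. The flank bases touching the core are pinned
# to distinct letters per genome so no match can extend past the core and
# the contracted vertex has length exactly 169 for any seed. Mirrors the
# displayed 98 % identity example.
identity_fixture <- function(seed = 4021) {
  withr::with_seed(seed, {
    core <- random_dna(169)
    core2 <- core
    for (p in c(60L, 120L)) {
      old <- substr(core2, p, p)
      substr(core2, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    pin <- c("A", "C", "G", "T")
    cores <- c(core, core2, core, core)
    seqs <- vapply(1:4, function(i) {
      paste0(random_dna(29), pin[i], cores[i], pin[i], random_dna(29))
    }, character(1))
    names(seqs) <- paste0("s", 1:4)
    genome_set(seqs)
  })
}

# Three genomes sharing a 587 bp core at ~99 % identity (4 mismatch columns)
# between genome-specific flanks; contracts to one vertex displayed as
# len=587 id=99%.
big_vertex_fixture <- function(seed = 5870) {
  withr::with_seed(seed, {
    core <- random_dna(587)
    core2 <- core
    for (p in c(101L, 202L, 303L, 404L)) {
      old <- substr(core2, p, p)
      substr(core2, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    genome_set(c(p1 = paste0(random_dna(39), "A", core, "A", random_dna(39)),
                 p2 = paste0(random_dna(39), "C", core2, "C", random_dna(39)),
                 p3 = paste0(random_dna(39), "G", core, "G", random_dna(39))))
  })
}

# Expect a named phalign condition class.
expect_ph_error <- function(expr, what) {
  testthat::expect_error(expr, class = paste0("phalign_error_", what))
}
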