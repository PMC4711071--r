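#' Specify a synthetic mosaic genome set
#'
#' The generator emulates the modular organization of tailed-bacteriophage
#' genomes: biological functions come in modules whose order is conserved,
#' each module has several sequence-dissimilar variants, genomes pick one
#' variant per module independently (emulating horizontal exchange, so the
#' variant partition can switch from one module to the next), and a few
#' universal blocks are shared exactly by all genomes (planted anchors).
#' Per-genome substitutions and short indels are applied inside modules
#' only. Optional planted transpositions (a pair of shared blocks in
#' swapped order in one genome) exercise cycle detection, and an optional
#' duplication (several copies of a segment in one genome) exercises
#' invalid-column splitting.
#'
#' All random sequence is drawn under a global unique-15-mer discipline: no
#' 15-mer occurs twice anywhere except inside deliberately shared pieces.
#' Distinct variants therefore share no 15-mer, planted universal blocks
#' are guaranteed to be exact full-support matches, and collinear instances
#' are guaranteed cycle-free at match lengths >= 15.
#'
#' @param n_genomes,n_modules,variants_per_module Set dimensions.
#' @param module_length_range,linker_length_range Ranges (bp) for random
#'   module-variant and inter-element linker lengths.
#' @param substitution_rate,indel_rate Per-bp mutation rates applied to
#'   each genome's module copies (indels are 1-3 bp).
#' @param universal_block_lengths Lengths (bp) of the planted anchors,
#'   inserted identically in all genomes; `integer(0)` for none.
#' @param transpositions List of `list(genome =, block_length =)` entries:
#'   a pair of shared blocks of exactly `block_length` bp is planted in all
#'   genomes, in swapped order in the target genome. Flanking bases are set
#'   so that the crossing matches have length exactly `block_length`.
#' @param duplication `NULL` or `list(genome =, segment_length =, copies =)`.
#' @param gc_content Base composition knob (probability of G or C);
#'   default 0.5 (uniform).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A `mosaic_spec` list.
#' @export
mosaic_spec <- function(n_genomes = 6L, n_modules = 8L,
                        variants_per_module = 3L,
                        module_length_range = c(150L, 300L),
                        linker_length_range = c(30L, 60L),
                        substitution_rate = 0.005, indel_rate = 5e-4,
                        universal_block_lengths = c(120L, 150L, 180L),
                        transpositions = list(), duplication = NULL,
                        gc_content = 0.5, seed = 1L) {
  sp <- list(n_genomes = as.integer(n_genomes),
             n_modules = as.integer(n_modules),
             variants_per_module = as.integer(variants_per_module),
             module_length_range = as.integer(module_length_range),
             linker_length_range = as.integer(linker_length_range),
             substitution_rate = substitution_rate,
             indel_rate = indel_rate,
             universal_block_lengths = as.integer(universal_block_lengths),
             transpositions = transpositions,
             duplication = duplication,
             gc_content = gc_content,
             seed = as.integer(seed))
  if (sp$n_genomes < 1 || sp$n_modules < 1 || sp$variants_per_module < 1) {
    ph_abort("infeasible_spec", "counts must be >= 1")
  }
  if (sp$substitution_rate < 0 || sp$substitution_rate >= 1 ||
      sp$indel_rate < 0 || sp$indel_rate >= 1) {
    ph_abort("infeasible_spec", "rates must be in [0, 1)")
  }
  if (any(sp$module_length_range < 1) || any(sp$universal_block_lengths < 1)) {
    ph_abort("infeasible_spec", "all lengths must be >= 1")
  }
  if (any(sp$linker_length_range < 0)) {
    ph_abort("infeasible_spec", "linker lengths must be >= 0")
  }
  est <- sp$n_genomes * (sp$n_modules * max(sp$module_length_range) +
                           sum(sp$universal_block_lengths) +
                           (sp$n_modules + 8) * max(sp$linker_length_range))
  if (est > 5e7) {
    ph_abort("infeasible_spec", "spec would generate > 50 Mb of sequence")
  }
  structure(sp, class = "mosaic_spec")
}

PH_BASES <- c("A", "C", "G", "T")
PH_GUARD_K <- 15L  # unique-k-mer discipline scale

reg_new <- function() new.env(hash = TRUE, parent = emptyenv())

reg_has <- function(reg, kmer) {
  !is.null(get0(kmer, envir = reg, inherits = FALSE))
}

reg_add <- function(reg, kmers) {
  for (km in kmers) assign(km, TRUE, envir = reg)
  invisible(NULL)
}

seq_kmers <- function(s, k = PH_GUARD_K) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

base_probs <- function(gc_content) {
  c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
    (1 - gc_content) / 2)
}

# Random sequence whose k-mers collide neither with the registry nor with
# each other; offending windows get their last base redrawn until clean.
draw_piece <- function(n, reg, gc_content = 0.5, k = PH_GUARD_K) {
  pr <- base_probs(gc_content)
  v <- sample(PH_BASES, n, replace = TRUE, prob = pr)
  if (n >= k) {
    for (iter in 1:50) {
      s <- paste(v, collapse = "")
      kms <- seq_kmers(s, k)
      bad <- which(vapply(kms, reg_has, logical(1), reg = reg) |
                     duplicated(kms))
      if (length(bad) == 0) {
        reg_add(reg, kms)
        return(s)
      }
      at <- unique(pmin(bad + k - 1L, n))
      v[at] <- sample(PH_BASES, length(at), replace = TRUE, prob = pr)
    }
    s <- paste(v, collapse = "")
    reg_add(reg, seq_kmers(s, k))  # give up: vanishingly unlikely
    return(s)
  }
  paste(v, collapse = "")
}

# Substitutions and short indels inside a module copy, keeping the
# unique-k-mer guarantee: edits whose new k-mers would collide are skipped.
mutate_module <- function(s, reg, sub_rate, indel_rate, gc_content,
                          k = PH_GUARD_K) {
  v <- strsplit(s, "")[[1]]
  n_sub <- stats::rbinom(1, length(v), sub_rate)
  if (n_sub > 0) {
    at <- sample(length(v), n_sub)
    for (p in at) {
      for (b in sample(setdiff(PH_BASES, v[p]))) {
        w <- v
        w[p] <- b
        if (edit_window_clean(w, p, p, reg, k)) {
          v <- w
          register_window(v, p, p, reg, k)
          break
        }
      }
    }
  }
  n_ind <- stats::rbinom(1, length(v), indel_rate)
  if (n_ind > 0) {
    for (i in seq_len(n_ind)) {
      size <- sample(3L, 1)
      p <- sample(length(v) - size, 1)
      if (stats::runif(1) < 0.5 && length(v) - size >= 2L * k) {
        w <- v[-(p:(p + size - 1L))]
        if (edit_window_clean(w, p, p, reg, k)) {
          v <- w
          register_window(v, p, p, reg, k)
        }
      } else {
        ins <- sample(PH_BASES, size, replace = TRUE,
                      prob = base_probs(gc_content))
        w <- append(v, ins, after = p)
        if (edit_window_clean(w, p, p + size, reg, k)) {
          v <- w
          register_window(v, p, p + size, reg, k)
        }
      }
    }
  }
  paste(v, collapse = "")
}

# k-mers of w overlapping positions [lo, hi]; clean when none is registered.
edit_kmers <- function(w, lo, hi, k) {
  n <- length(w)
  if (n < k) return(character(0))
  s0 <- max(1L, lo - k + 1L)
  s1 <- min(hi, n - k + 1L)
  if (s1 < s0) return(character(0))
  s <- paste(w, collapse = "")
  substring(s, s0:s1, (s0:s1) + k - 1L)
}

edit_window_clean <- function(w, lo, hi, reg, k) {
  kms <- edit_kmers(w, lo, hi, k)
  !any(vapply(kms, reg_has, logical(1), reg = reg))
}

register_window <- function(w, lo, hi, reg, k) {
  reg_add(reg, edit_kmers(w, lo, hi, k))
}

#' Generate a mosaic genome set with ground truth
#'
#' @param spec A [mosaic_spec()].
#' @return A list with elements `genomes` (a `genome_set`), `truth` (tibble
#'   `genome`, `start`, `end`, `feature`, 1-based inclusive intervals that
#'   tile each genome; features are `linker`, `module<i>:v<j>`,
#'   `universal:<u>`, `tblock:<t>:<X|Y>`, `dup`), and `spec`.
#' @examples
#' sim <- generate_mosaic(mosaic_spec(n_genomes = 3, n_modules = 4, seed = 2))
#' sim$genomes
#' @export
generate_mosaic <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  withr::with_seed(spec$seed, generate_mosaic_impl(spec))
}

generate_mosaic_impl <- function(spec) {
  k <- PH_GUARD_K
  gc <- spec$gc_content
  reg <- reg_new()
  nm <- spec$n_modules
  # piece library -----------------------------------------------------------
  variants <- vector("list", nm)
  for (j in seq_len(nm)) {
    variants[[j]] <- vapply(seq_len(spec$variants_per_module), function(v) {
      L <- sample(spec$module_length_range[1]:spec$module_length_range[2], 1)
      draw_piece(L, reg, gc)
    }, character(1))
  }
  ublocks <- vapply(spec$universal_block_lengths, draw_piece,
                    character(1), reg = reg, gc_content = gc)
  tblocks <- lapply(spec$transpositions, function(t) {
    list(X = draw_piece(t$block_length, reg, gc),
         Y = draw_piece(t$block_length, reg, gc),
         genome = t$genome)
  })
  dup_seq <- if (!is.null(spec$duplication)) {
    draw_piece(spec$duplication$segment_length, reg, gc)
  } else NULL
  # element schedule: functional elements in global order ------------------
  n_ub <- length(ublocks)
  ub_after <- if (n_ub > 0) {
    pos <- floor(seq_len(n_ub) * nm / (n_ub + 1))
    pmin(pmax(pos, 1L), nm)
  } else integer(0)
  elements <- list()
  for (j in seq_len(nm)) {
    elements[[length(elements) + 1L]] <- list(type = "module", id = j)
    for (u in which(ub_after == j)) {
      elements[[length(elements) + 1L]] <- list(type = "universal", id = u)
    }
    for (t in seq_along(tblocks)) {
      span <- max(2L, nm %/% 2L)
      x_at <- min(t, nm)
      y_at <- min(x_at + span, nm)
      if (x_at == j) {
        elements[[length(elements) + 1L]] <- list(type = "tblock", id = t,
                                                  part = "X")
      }
      if (y_at == j) {
        elements[[length(elements) + 1L]] <- list(type = "tblock", id = t,
                                                  part = "Y")
      }
    }
    if (!is.null(dup_seq)) {
      copies <- spec$duplication$copies
      d_after <- pmin(seq_len(copies), nm)
      for (cpy in which(d_after == j)) {
        elements[[length(elements) + 1L]] <- list(type = "dup", id = cpy)
      }
    }
  }
  # variant choices, independent across genomes and modules ----------------
  choice <- matrix(sample.int(spec$variants_per_module,
                              spec$n_genomes * nm, replace = TRUE),
                   nrow = spec$n_genomes)
  genome_ids <- sprintf("g%d", seq_len(spec$n_genomes))
  t_target <- vapply(tblocks, function(t) resolve_genome(t$genome, genome_ids),
                     integer(1))
  d_target <- if (!is.null(dup_seq)) {
    resolve_genome(spec$duplication$genome, genome_ids)
  } else NA_integer_
  seqs <- character(spec$n_genomes)
  truth_rows <- list()
  locked <- vector("list", spec$n_genomes)
  for (g in seq_len(spec$n_genomes)) {
    parts <- character(0)
    feats <- character(0)
    add <- function(s, f) {
      parts[[length(parts) + 1L]] <<- s
      feats[[length(feats) + 1L]] <<- f
    }
    linker <- function() {
      L <- sample(spec$linker_length_range[1]:spec$linker_length_range[2], 1)
      add(draw_piece(L, reg, gc), "linker")
    }
    for (el in elements) {
      if (el$type == "dup" && el$id > 1L && g != d_target) next
      linker()
      if (el$type == "module") {
        v <- choice[g, el$id]
        s <- mutate_module(variants[[el$id]][v], reg, spec$substitution_rate,
                           spec$indel_rate, gc)
        add(s, sprintf("module%d:v%d", el$id, v))
      } else if (el$type == "universal") {
        add(ublocks[el$id], sprintf("universal:%d", el$id))
      } else if (el$type == "tblock") {
        tb <- tblocks[[el$id]]
        part <- el$part
        if (g == t_target[el$id]) part <- if (part == "X") "Y" else "X"
        add(tb[[part]], sprintf("tblock:%d:%s", el$id, part))
      } else if (el$type == "dup") {
        add(dup_seq, "dup")
      }
    }
    linker()
    lens <- nchar(parts)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seq_g <- paste(parts, collapse = "")
    # enforce flanks around transposition blocks and duplication copies:
    # one shared flank base in non-target genomes, a different one in the
    # target, so cross-slot matches have exactly the planted length and
    # cannot leak order-inverting columns into the flanking linkers
    lock_g <- integer(0)
    tb_rows <- which(grepl("^tblock:|^dup$", feats))
    for (r in tb_rows) {
      target <- if (feats[r] == "dup") {
        d_target
      } else {
        t_target[as.integer(sub("^tblock:(\\d+):.*$", "\\1", feats[r]))]
      }
      flank <- if (g == target) "C" else "A"
      for (p in c(starts[r] - 1L, ends[r] + 1L)) {
        if (p >= 1 && p <= nchar(seq_g)) {
          substr(seq_g, p, p) <- flank
          lock_g <- c(lock_g, p)
        }
      }
    }
    locked[[g]] <- lock_g
    seq_g <- repair_junctions(seq_g, ends[-length(ends)], feats, starts, ends,
                              reg, lock_g, gc)
    seqs[g] <- seq_g
    nonempty <- lens > 0L
    truth_rows[[g]] <- tibble(genome = genome_ids[g], start = starts,
                              end = ends, feature = feats)[nonempty, ]
  }
  names(seqs) <- genome_ids
  list(genomes = genome_set(seqs), truth = bind_rows(truth_rows),
       spec = spec)
}

resolve_genome <- function(x, ids) {
  if (is.character(x)) match(x, ids) else as.integer(x)
}

# Redraw linker bases so no k-mer spanning a piece boundary collides with
# the registry; enforced (locked) flank bases are never touched.
repair_junctions <- function(seq_g, boundaries, feats, starts, ends, reg,
                             locked, gc, k = PH_GUARD_K) {
  v <- strsplit(seq_g, "")[[1]]
  n <- length(v)
  is_linker <- logical(n)
  for (r in which(feats == "linker" & starts <= ends)) {
    is_linker[starts[r]:ends[r]] <- TRUE
  }
  is_linker[locked] <- FALSE
  pr <- base_probs(gc)
  accepted <- character(0)
  for (b in boundaries) {
    s0 <- max(1L, b - k + 2L)
    s1 <- min(b, n - k + 1L)
    if (s1 < s0) next
    for (iter in 1:50) {
      s <- paste(v[s0:(s1 + k - 1L)], collapse = "")
      kms <- substring(s, 1:(s1 - s0 + 1L), (1:(s1 - s0 + 1L)) + k - 1L)
      coll <- which(vapply(kms, reg_has, logical(1), reg = reg) |
                      kms %in% accepted)
      if (length(coll) == 0) break
      fixed <- FALSE
      for (ci in coll) {
        span <- (s0 + ci - 1L):(s0 + ci + k - 2L)
        redo <- span[is_linker[span]]
        if (length(redo) > 0) {
          p <- redo[which.min(abs(redo - b))]
          v[p] <- sample(PH_BASES, 1, prob = pr)
          fixed <- TRUE
        }
      }
      if (!fixed) break
    }
    s <- paste(v[s0:(s1 + k - 1L)], collapse = "")
    accepted <- c(accepted, substring(s, 1:(s1 - s0 + 1L),
                                      (1:(s1 - s0 + 1L)) + k - 1L))
  }
  reg_add(reg, accepted)
  paste(v, collapse = "")
}

#' Compare an alignment against generator ground truth
#'
#' Reports (a) the fraction of planted universal blocks recovered as
#' anchors (a block is recovered when some full-support vertex contains its
#' interval in every genome), (b) the number of cross-variant merges
#' (vertex columns that align positions of two different variants of the
#' same module; must be 0 when variants share no match-length substring),
#' and (c) agreement between planted transpositions and reported strongly
#' connected components.
#'
#' @param result An `alignment_graph` (collinear case) or a
#'   `collinearity_report` (rearranged case).
#' @param truth The `truth` tibble from [generate_mosaic()].
#' @return A one-row tibble: `anchors_planted`, `anchors_recovered`,
#'   `anchor_recovery`, `cross_variant_merges`, `transpositions_planted`,
#'   `transpositions_detected`.
#' @export
recover_check <- function(result, truth) {
  ub <- truth |> filter(grepl("^universal:", .data$feature))
  ub_ids <- unique(ub$feature)
  n_planted <- length(ub_ids)
  n_recovered <- 0L
  n_cross <- 0L
  if (inherits(result, "alignment_graph")) {
    anchor_seg <- result$segments |>
      filter(.data$vertex %in% result$anchors)
    for (u in ub_ids) {
      rows <- ub |> filter(.data$feature == u)
      hit_by <- anchor_seg |>
        left_join(rows, by = "genome") |>
        filter(.data$start.x <= .data$start.y, .data$end.x >= .data$end.y) |>
        group_by(.data$vertex) |>
        summarise(ngen = n(), .groups = "drop") |>
        filter(.data$ngen == nrow(rows))
      if (nrow(hit_by) > 0) n_recovered <- n_recovered + 1L
    }
    n_cross <- count_cross_variant(result, truth)
  }
  tp <- truth |> filter(grepl("^tblock:", .data$feature)) |>
    mutate(tid = sub("^tblock:(\\d+):.*$", "\\1", .data$feature))
  tp_ids <- unique(tp$tid)
  n_tp <- length(tp_ids)
  n_det <- 0L
  sccs <- if (inherits(result, "collinearity_report")) result$sccs else NULL
  if (!is.null(sccs) && nrow(sccs) > 0) {
    for (t in tp_ids) {
      rows <- tp |> filter(.data$tid == t)
      ov <- sccs |>
        left_join(rows, by = "genome") |>
        filter(!is.na(.data$start.y),
               .data$start.x <= .data$end.y, .data$end.x >= .data$start.y)
      if (nrow(ov) > 0) n_det <- n_det + 1L
    }
  }
  tibble(
    anchors_planted = n_planted,
    anchors_recovered = n_recovered,
    anchor_recovery = if (n_planted == 0) 1 else n_recovered / n_planted,
    cross_variant_merges = n_cross,
    transpositions_planted = n_tp,
    transpositions_detected = n_det
  )
}

# A cross-variant merge: within one vertex, overlapping alignment columns
# carry positions annotated with different variants of the same module.
count_cross_variant <- function(graph, truth) {
  mod <- truth |> filter(grepl("^module", .data$feature)) |>
    mutate(module = sub(":v\\d+$", "", .data$feature),
           variant = sub("^.*:", "", .data$feature)) |>
    rename(t_start = "start", t_end = "end")
  seg <- graph$segments |>
    left_join(select(graph$vertices, "vertex", "n_support"), by = "vertex") |>
    filter(.data$n_support >= 2)
  if (nrow(seg) == 0 || nrow(mod) == 0) return(0L)
  ov <- seg |>
    left_join(mod, by = "genome", relationship = "many-to-many") |>
    filter(!is.na(.data$t_start),
           .data$start <= .data$t_end, .data$end >= .data$t_start) |>
    mutate(col_lo = pmax(.data$start, .data$t_start) - .data$start,
           col_hi = pmin(.data$end, .data$t_end) - .data$start)
  bad <- 0L
  for (grp in split(ov, paste(ov$vertex, ov$module))) {
    if (n_distinct(grp$variant) < 2) next
    hit <- FALSE
    for (i in seq_len(nrow(grp) - 1)) {
      for (j in (i + 1):nrow(grp)) {
        if (grp$variant[i] != grp$variant[j] &&
            grp$col_lo[i] <= grp$col_hi[j] &&
            grp$col_lo[j] <= grp$col_hi[i]) hit <- TRUE
      }
    }
    if (hit) bad <- bad + 1L
  }
  bad
}

#' Write generator ground truth as TSV
#'
#' BED-like layout `genome<TAB>start<TAB>end<TAB>feature` (1-based
#' inclusive coordinates, matching the aligner's display convention).
#'
#' @param truth Truth tibble from [generate_mosaic()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
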