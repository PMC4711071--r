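#' Maximal exact matches between genome pairs
#'
#' Enumerates every maximal exact match (MEM) of length at least `m` between
#' every unordered pair of distinct genomes, on the forward strand. A MEM is
#' an exact match that cannot be extended by one position on either side
#' without breaking equality or crossing a sequence boundary; `N` never
#' matches anything, including another `N`. Matches within a single genome
#' are never reported: duplications are handled downstream by column
#' splitting.
#'
#' The default engine builds a generalized suffix array with LCP over the
#' concatenated genomes; `method = "naive"` uses the quadratic
#' diagonal-scan reference implementation (see [find_mems_naive()]).
#'
#' @param genomes A `genome_set` with at least two genomes.
#' @param m Minimum match length (>= 1).
#' @param method `"suffix_array"` (default) or `"naive"`.
#' @return A `mem_set`: a tibble with columns `genome_a`, `start_a`,
#'   `genome_b`, `start_b`, `length` (1-based starts; genome pairs ordered
#'   by genome index, rows sorted by pair, `start_a`, `start_b`), with
#'   attributes `m` and `total_match_length` (the summed match length M_l,
#'   each pairwise match counted once).
#' @examples
#' gs <- genome_set(c(G1 = "ACGTACGTAA", G2 = "TTACGTACGG"))
#' find_mems(gs, m = 5)
#' @export
find_mems <- function(genomes, m = 15L,
                      method = c("suffix_array", "naive")) {
  stopifnot(inherits(genomes, "genome_set"))
  method <- match.arg(method)
  m <- as.integer(m)
  if (m < 1) ph_abort("bad_input", "m must be >= 1")
  if (n_genomes(genomes) < 2) {
    ph_abort("too_few_genomes", "match enumeration needs at least two genomes")
  }
  if (method == "naive") return(find_mems_naive(genomes, m))
  enc <- encode_seqs(unname(genomes$seq))
  raw <- mems_sa_cpp(enc$code, enc$gid, enc$gpos, m)
  new_mem_set(
    tibble(
      genome_a = genomes$info$id[raw$ga], start_a = raw$start_a,
      genome_b = genomes$info$id[raw$gb], start_b = raw$start_b,
      length = raw$length
    ),
    genomes, m
  )
}

new_mem_set <- function(tb, genomes, m) {
  ids <- genomes$info$id
  tb <- tb |>
    mutate(.ia = match(.data$genome_a, ids), .ib = match(.data$genome_b, ids)) |>
    arrange(.data$.ia, .data$.ib, .data$start_a, .data$start_b) |>
    select(-".ia", -".ib")
  structure(tb,
            class = c("mem_set", class(tibble())),
            m = m,
            total_match_length = sum(tb$length),
            genome_ids = ids)
}

#' @export
print.mem_set <- function(x, ...) {
  cat(sprintf("<mem_set> %d match(es), m = %d, total match length M_l = %d bp\n",
              nrow(x), attr(x, "m"), attr(x, "total_match_length")))
  NextMethod()
}

#' Quadratic reference MEM finder
#'
#' Independent reference implementation of [find_mems()]: for every genome
#' pair it scans each alignment diagonal, computes the base-wise equality
#' vector, and reports maximal runs of equality of length at least `m`.
#' It is the test oracle for the suffix-array engine and a usable fallback
#' for small inputs.
#'
#' @inheritParams find_mems
#' @return A `mem_set`, identical to the suffix-array result.
#' @export
find_mems_naive <- function(genomes, m = 15L) {
  stopifnot(inherits(genomes, "genome_set"))
  m <- as.integer(m)
  if (m < 1) ph_abort("bad_input", "m must be >= 1")
  n <- n_genomes(genomes)
  if (n < 2) {
    ph_abort("too_few_genomes", "match enumeration needs at least two genomes")
  }
  # N codes must be unique across the whole set, not merely within a genome
  n_seen <- 0L
  codes <- lapply(unname(genomes$seq), function(s) {
    v <- encode_one_unique_n(s)
    ns <- v < 0L
    v[ns] <- v[ns] - n_seen
    n_seen <<- n_seen + sum(ns)
    v
  })
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xa <- codes[[i]]
      xb <- codes[[j]]
      La <- length(xa)
      Lb <- length(xb)
      for (d in (-(La - 1)):(Lb - 1)) {
        ia <- max(1L, 1L - d)
        ib <- min(La, Lb - d)
        if (ib - ia + 1L < m) next
        eq <- xa[ia:ib] == xb[(ia + d):(ib + d)]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        hit <- which(r$values & r$lengths >= m)
        for (h in hit) {
          rows[[length(rows) + 1L]] <- c(i, ia + starts[h] - 1L,
                                         j, ia + starts[h] - 1L + d,
                                         r$lengths[h])
        }
      }
    }
  }
  if (length(rows) == 0) {
    tb <- tibble(genome_a = character(), start_a = integer(),
                 genome_b = character(), start_b = integer(),
                 length = integer())
  } else {
    mat <- do.call(rbind, rows)
    tb <- tibble(genome_a = genomes$info$id[mat[, 1]], start_a = mat[, 2],
                 genome_b = genomes$info$id[mat[, 3]], start_b = mat[, 4],
                 length = mat[, 5])
  }
  new_mem_set(tb, genomes, m)
}

# Integer codes with every N given its own negative code, so N == N is FALSE
# for matching purposes.
encode_one_unique_n <- function(seq) {
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  v <- lut[utf8ToInt(seq)]
  ns <- which(v == 0L)
  if (length(ns) > 0) v[ns] <- -seq_along(ns)
  v
}

#' Smallest m yielding an acyclic column graph
#'
#' The only substantive parameter of the method is the minimum match length
#' `m`. It is normally chosen as the smallest value such that the column
#' graph (after invalid-column splitting) is acyclic: small unrelated
#' repeats or planted transpositions create cycles that disappear once `m`
#' exceeds their length. The search increments `m` from `m_start` until the
#' graph is acyclic or `m_max` is reached.
#'
#' @param genomes A `genome_set`.
#' @param m_start Starting value of the search (default 15).
#' @param m_max Search ceiling; reaching it while still cyclic raises a
#'   `phalign_error_m_ceiling` condition whose `sccs` field lists the
#'   strongly connected components as rearrangement evidence.
#' @return A list with elements `m` (the chosen value) and `matches` (the
#'   `mem_set` computed at that `m`).
#' @export
auto_m <- function(genomes, m_start = 15L, m_max = 500L) {
  stopifnot(inherits(genomes, "genome_set"))
  m_start <- as.integer(m_start)
  if (m_start < 1) ph_abort("bad_input", "m_start must be >= 1")
  m <- m_start
  repeat {
    matches <- find_mems(genomes, m)
    part <- split_invalid(build_columns(genomes, matches))
    cg <- build_column_graph(part)
    rep <- check_collinear(cg)
    if (rep$collinear) return(list(m = m, matches = matches))
    if (m >= m_max) {
      ph_abort("m_ceiling", sprintf(
        "column graph still cyclic at m = %d; rearrangements suspected", m),
        sccs = rep$sccs)
    }
    m <- m + 1L
  }
}

#' Read and write match tables
#'
#' Matches are exchanged as TSV
#' `genome_a<TAB>start_a<TAB>genome_b<TAB>start_b<TAB>length` so an external
#' MEM finder can be substituted for the built-in engine.
#'
#' @param matches A `mem_set`.
#' @param path File path.
#' @param genomes The `genome_set` the matches refer to (for id checking and
#'   canonical ordering on read).
#' @param m Minimum match length recorded on the imported set.
#' @return `write_matches()` returns `path` invisibly; `read_matches()`
#'   returns a `mem_set`.
#' @export
write_matches <- function(matches, path) {
  stopifnot(inherits(matches, "mem_set"))
  write.table(as.data.frame(matches), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path, genomes, m = 1L) {
  if (!file.exists(path)) {
    ph_abort("missing_file", paste0("no such file: ", path))
  }
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("genome_a", "start_a", "genome_b", "start_b", "length")
                %in% names(df)))
  unknown <- setdiff(unique(c(df$genome_a, df$genome_b)), genomes$info$id)
  if (length(unknown) > 0) {
    ph_abort("bad_match", paste0("matches refer to unknown genomes: ",
                                 paste(unknown, collapse = ", ")))
  }
  new_mem_set(as_tibble(df) |>
                mutate(start_a = as.integer(.data$start_a),
                       start_b = as.integer(.data$start_b),
                       length = as.integer(.data$length)),
              genomes, as.integer(m))
}

#' Assemble a match set from a data frame
#'
#' Mostly useful in tests and when feeding hand-constructed matches to
#' [build_columns()]. Coordinates are validated lazily by the column
#' builder.
#'
#' @param df Data frame with columns `genome_a`, `start_a`, `genome_b`,
#'   `start_b`, `length`.
#' @param genomes The `genome_set` the matches refer to.
#' @param m Nominal minimum match length.
#' @return A `mem_set`.
#' @export
mem_set <- function(df, genomes, m = 1L) {
  stopifnot(all(c("genome_a", "start_a", "genome_b", "start_b", "length")
                %in% names(df)))
  new_mem_set(as_tibble(df), genomes, as.integer(m))
}
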