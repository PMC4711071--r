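#' Build alignment columns from matches
#'
#' A column is an equivalence class of genome positions under the transitive
#' closure of the base-wise equalities asserted by the matches: position
#' `j` of genome `i` is equivalent to position `l` of genome `k` when some
#' match, or a chain of matches, links them. Columns are built with
#' union-find (union by rank, path compression) over the concatenated
#' genome positions; unmatched positions remain singleton columns.
#'
#' @param genomes A `genome_set`.
#' @param matches A `mem_set` (or any data frame with the same columns).
#' @return A `column_partition` object. Use [as_tibble()] to get the
#'   `column_id` / `genome` / `position` view.
#' @export
build_columns <- function(genomes, matches) {
  stopifnot(inherits(genomes, "genome_set"))
  ids <- genomes$info$id
  lens <- genomes$info$length
  n_total <- sum(lens)
  cumb <- genome_cum_before(genomes)
  ia <- match(matches$genome_a, ids)
  ib <- match(matches$genome_b, ids)
  if (anyNA(ia) || anyNA(ib)) {
    ph_abort("bad_match", "match refers to a genome not in the set")
  }
  bad <- which(matches$start_a < 1L | matches$start_b < 1L |
                 matches$length < 1L |
                 matches$start_a + matches$length - 1L > lens[ia] |
                 matches$start_b + matches$length - 1L > lens[ib] |
                 ia == ib)
  if (length(bad) > 0) {
    k <- bad[1]
    ph_abort("bad_match", sprintf(
      "match out of genome bounds or self-match: {%s[%d..%d], %s[%d..%d]}",
      matches$genome_a[k], matches$start_a[k],
      matches$start_a[k] + matches$length[k] - 1L,
      matches$genome_b[k], matches$start_b[k],
      matches$start_b[k] + matches$length[k] - 1L))
  }
  ga0 <- cumb[ia] + matches$start_a - 1L  # 0-based global starts
  gb0 <- cumb[ib] + matches$start_b - 1L
  col_of <- uf_components_cpp(n_total, as.integer(ga0), as.integer(gb0),
                              as.integer(matches$length))
  new_column_partition(col_of, genomes, split = FALSE)
}

new_column_partition <- function(col_of, genomes, split) {
  structure(list(col_of = col_of, genomes = genomes, split = split,
                 n_columns = max(col_of)),
            class = "column_partition")
}

#' @export
print.column_partition <- function(x, ...) {
  cat(sprintf(
    "<column_partition> %d column(s) over %d position(s) in %d genome(s)%s\n",
    x$n_columns, length(x$col_of), n_genomes(x$genomes),
    if (x$split) ", invalid columns split" else ""))
  invisible(x)
}

#' @export
as_tibble.column_partition <- function(x, ...) {
  info <- x$genomes$info
  tibble(
    column_id = x$col_of,
    genome = rep(info$id, info$length),
    genome_index = rep(seq_len(nrow(info)), info$length),
    position = sequence(info$length)
  )
}

# Genome index of each global position, as a plain integer vector.
position_genome_index <- function(genomes) {
  rep(seq_len(n_genomes(genomes)), genomes$info$length)
}

#' Split invalid columns into singletons
#'
#' A column is valid when it has at most one position per genome. Invalid
#' columns arise from duplicated segments and tandem repeats, whose
#' overlapping matches place two or more positions of one genome in the same
#' equivalence class; such a class would force a cycle in the column graph.
#' Every invalid column is split into singleton columns, one per position;
#' valid columns pass through untouched. The operation is idempotent.
#'
#' @param partition A `column_partition`.
#' @return A `column_partition` in which every column is valid.
#' @export
split_invalid <- function(partition) {
  stopifnot(inherits(partition, "column_partition"))
  col_of <- partition$col_of
  gidx <- position_genome_index(partition$genomes)
  # a column is invalid iff some (column, genome) pair occurs twice
  key <- paste(col_of, gidx)
  invalid_cols <- unique(col_of[duplicated(key)])
  if (length(invalid_cols) > 0) {
    hit <- col_of %in% invalid_cols
    new_ids <- seq_len(sum(hit)) + partition$n_columns
    col_of[hit] <- new_ids
    # renumber densely, in order of first appearance along the genomes
    col_of <- match(col_of, unique(col_of))
  }
  new_column_partition(col_of, partition$genomes, split = TRUE)
}

#' Dump columns as TSV (debugging aid for small inputs)
#'
#' @param partition A `column_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_columns <- function(partition, path) {
  tb <- as_tibble(partition) |>
    select("column_id", "genome", "position") |>
    arrange(.data$column_id, .data$genome, .data$position)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
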