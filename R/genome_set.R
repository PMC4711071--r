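#' Genome sets
#'
#' A `genome_set` holds an ordered collection of named DNA sequences
#' (uppercase, alphabet `A`/`C`/`G`/`T`/`N`) together with bookkeeping about
#' how each sequence was derived from its source record: the trimming region
#' (1-based inclusive), the circular rotation applied during normalization,
#' and a display offset used when a graph was computed on a sub-region of
#' larger genomes.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param regions Optional trimming regions: a data frame with columns
#'   `id`, `start`, `end` (1-based inclusive), or a named list of
#'   length-2 vectors.
#' @return A `genome_set` object.
#' @examples
#' gs <- genome_set(c(g1 = "ACGTACGT", g2 = "TTACGTAA"))
#' gs
#' @export
genome_set <- function(seqs, regions = NULL) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    ph_abort("bad_input", "all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) {
    ph_abort("duplicate_ids", paste0(
      "duplicate genome ids: ",
      paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")
    ))
  }
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ph_abort("bad_characters", paste0(
      "non-DNA characters (outside A/C/G/T/N) in: ",
      paste(names(seqs)[bad], collapse = ", ")
    ))
  }
  regions <- normalize_regions(regions)
  if (!is.null(regions)) {
    unknown <- setdiff(regions$id, names(seqs))
    if (length(unknown) > 0) {
      ph_abort("unknown_region_id",
               paste0("region ids not present in input: ",
                      paste(unknown, collapse = ", ")))
    }
    for (k in seq_len(nrow(regions))) {
      id <- regions$id[k]
      s <- regions$start[k]
      e <- regions$end[k]
      L <- nchar(seqs[[id]])
      if (s < 1 || e > L || s > e) {
        ph_abort("region_bounds", sprintf(
          "region [%d, %d] out of bounds for genome '%s' (length %d)",
          s, e, id, L))
      }
      seqs[[id]] <- substr(seqs[[id]], s, e)
    }
  }
  if (any(nchar(seqs) < 1)) {
    ph_abort("bad_input", "genomes must have length >= 1")
  }
  info <- tibble(
    id = names(seqs),
    length = unname(nchar(seqs)),
    region_start = NA_integer_,
    region_end = NA_integer_,
    rotation_offset = 0L,
    coord_offset = 0L
  )
  if (!is.null(regions)) {
    idx <- match(regions$id, info$id)
    info$region_start[idx] <- as.integer(regions$start)
    info$region_end[idx] <- as.integer(regions$end)
  }
  structure(list(seq = seqs, info = info), class = "genome_set")
}

normalize_regions <- function(regions) {
  if (is.null(regions)) return(NULL)
  if (is.data.frame(regions)) {
    stopifnot(all(c("id", "start", "end") %in% names(regions)))
    return(tibble(id = as.character(regions$id),
                  start = as.integer(regions$start),
                  end = as.integer(regions$end)))
  }
  tibble(id = names(regions),
         start = as.integer(vapply(regions, `[`, numeric(1), 1)),
         end = as.integer(vapply(regions, `[`, numeric(1), 2)))
}

#' Read genomes from a multi-FASTA file
#'
#' Reads DNA sequences (wrapped or single-line FASTA), optionally trims each
#' record to a 1-based inclusive region, and returns a [genome_set()].
#' Record ids are the first whitespace-delimited word of each header.
#'
#' @param fasta_path Path to a FASTA file.
#' @param regions Optional regions as in [genome_set()], or a path to a TSV
#'   file `id<TAB>start<TAB>end` (see [read_regions()]).
#' @return A `genome_set`.
#' @export
read_genomes <- function(fasta_path, regions = NULL) {
  if (!file.exists(fasta_path)) {
    ph_abort("missing_file", paste0("no such file: ", fasta_path))
  }
  if (is.character(regions) && length(regions) == 1) {
    regions <- read_regions(regions)
  }
  ss <- Biostrings::readBStringSet(fasta_path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1), 1)
  genome_set(seqs, regions = regions)
}

#' Read a trimming-region table
#'
#' @param path TSV file with columns `id`, `start`, `end` (no header, or a
#'   header line starting with `id`).
#' @return A tibble with columns `id`, `start`, `end`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) {
    ph_abort("missing_file", paste0("no such file: ", path))
  }
  first <- readLines(path, n = 1)
  hdr <- grepl("^id\\b", first)
  df <- read.delim(path, header = hdr, sep = "\t",
                   col.names = c("id", "start", "end"),
                   stringsAsFactors = FALSE)
  tibble(id = as.character(df$id), start = as.integer(df$start),
         end = as.integer(df$end))
}

#' Write genomes to FASTA
#'
#' @param genomes A `genome_set`.
#' @param path Output FASTA path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path, width = 70L) {
  stopifnot(inherits(genomes, "genome_set"))
  ss <- Biostrings::DNAStringSet(genomes$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> %d genome(s), total length %d bp\n",
              n_genomes(x), total_length(x)))
  print(x$info, ...)
  invisible(x)
}

#' @export
as_tibble.genome_set <- function(x, ...) x$info

#' Number of genomes and total length
#'
#' `total_length()` is the quantity usually written N_l: the summed length of
#' all genomes in the set.
#'
#' @param genomes A `genome_set`.
#' @return An integer.
#' @export
n_genomes <- function(genomes) length(genomes$seq)

#' @rdname n_genomes
#' @export
total_length <- function(genomes) sum(genomes$info$length)

#' Extract a subset of genomes
#'
#' @param x A `genome_set`.
#' @param i Genome ids or indices.
#' @param ... Unused.
#' @export
`[.genome_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$info$id)
  structure(list(seq = x$seq[i], info = x$info[i, ]), class = "genome_set")
}

#' Rotate circular genomes
#'
#' Rotates each named genome left by the given offset: the returned sequence
#' is `seq[offset+1..L]` followed by `seq[1..offset]` (1-based), so the base
#' formerly at position `offset + 1` becomes position 1. Rotation offsets
#' accumulate modulo the genome length, so
#' `rotate_genomes(rotate_genomes(g, a), L - a)` restores `g`.
#'
#' @param genomes A `genome_set`.
#' @param offsets Named integer vector of offsets in `[0, length)`; genomes
#'   not named are left untouched. An unnamed scalar is allowed for a
#'   single-genome set.
#' @return The rotated `genome_set`.
#' @export
rotate_genomes <- function(genomes, offsets) {
  stopifnot(inherits(genomes, "genome_set"))
  if (is.null(names(offsets))) {
    if (length(offsets) == 1 && n_genomes(genomes) == 1) {
      names(offsets) <- genomes$info$id
    } else {
      ph_abort("bad_input", "offsets must be named by genome id")
    }
  }
  unknown <- setdiff(names(offsets), genomes$info$id)
  if (length(unknown) > 0) {
    ph_abort("bad_input", paste0("unknown genome ids in offsets: ",
                                 paste(unknown, collapse = ", ")))
  }
  for (id in names(offsets)) {
    off <- as.integer(offsets[[id]])
    L <- nchar(genomes$seq[[id]])
    if (off < 0 || off >= L) {
      ph_abort("offset_range", sprintf(
        "rotation offset %d out of range [0, %d) for genome '%s'",
        off, L, id))
    }
    if (off == 0) next
    s <- genomes$seq[[id]]
    genomes$seq[[id]] <- paste0(substr(s, off + 1L, L), substr(s, 1L, off))
    k <- match(id, genomes$info$id)
    genomes$info$rotation_offset[k] <-
      (genomes$info$rotation_offset[k] + off) %% L
  }
  genomes
}

# Longest substring present in all genomes, each treated as circular
# (searched on seq ++ seq[1..L-1], depth capped at the shortest genome).
# Returns NULL when no common substring exists, otherwise
# list(substring, depth, occurrence = named first-occurrence starts in the
# doubled sequences, all <= L).
all_genome_lcs <- function(genomes, circular = TRUE) {
  n <- n_genomes(genomes)
  lens <- genomes$info$length
  doubled <- if (circular) {
    paste0(genomes$seq, substr(genomes$seq, 1L, lens - 1L))
  } else {
    unname(genomes$seq)
  }
  enc <- encode_seqs(doubled)
  win <- lcs_windows_cpp(enc$code, enc$gid, enc$gpos, n)
  if (length(win$depth) == 0) return(NULL)
  cap <- min(lens)
  depth <- pmin(win$depth, cap)
  dmax <- max(depth)
  keep <- which(depth == dmax)
  cand <- unique(vapply(keep, function(k) {
    substr(doubled[[win$gid[k]]], win$gpos[k], win$gpos[k] + dmax - 1L)
  }, character(1)))
  # Tie-break: the candidate whose first occurrence in genome 1 is smallest.
  occ1 <- vapply(cand, function(s) {
    as.integer(regexpr(s, doubled[[1]], fixed = TRUE))
  }, integer(1))
  best <- cand[which.min(occ1)]
  occ <- vapply(doubled, function(d) {
    as.integer(regexpr(best, d, fixed = TRUE))
  }, integer(1))
  names(occ) <- genomes$info$id
  list(substring = best, depth = dmax, occurrence = occ)
}

#' Normalize circular genome start positions
#'
#' Bacteriophage genomes deposited by different projects start at arbitrary
#' points of the circular chromosome. Normalization finds the longest exact
#' substring present in all genomes (each treated as circular) and rotates
#' every genome so that this substring starts at position 1. If several
#' longest common substrings exist, the one with the smallest start in the
#' first genome is used, which makes the procedure deterministic and
#' idempotent.
#'
#' @param genomes A `genome_set` with at least two genomes, each of length
#'   >= `m`.
#' @param m Minimum acceptable length of the shared substring; shorter
#'   common substrings raise a `phalign_error_no_common_anchor` condition.
#' @return A list with elements `genomes` (the rotated set) and `offsets`
#'   (tibble `id`, `offset` of the applied rotations).
#' @export
normalize_genomes <- function(genomes, m = 15L) {
  stopifnot(inherits(genomes, "genome_set"))
  if (n_genomes(genomes) < 2) {
    ph_abort("too_few_genomes", "normalization needs at least two genomes")
  }
  if (any(genomes$info$length < m)) {
    ph_abort("bad_input", "every genome must be at least m bp long")
  }
  lcs <- all_genome_lcs(genomes, circular = TRUE)
  if (is.null(lcs) || lcs$depth < m) {
    ph_abort("no_common_anchor", sprintf(
      "no common anchor for normalization: no substring of length >= %d shared by all genomes", m))
  }
  offsets <- lcs$occurrence - 1L
  rotated <- rotate_genomes(genomes, offsets)
  list(genomes = rotated,
       offsets = tibble(id = genomes$info$id, offset = unname(offsets)))
}

# Heuristic half of the auto-normalization trigger: TRUE when the longest
# all-genome common substring does not start within `slack` bp of position 1
# in every genome (the cyclic-graph half of the trigger is evaluated by
# align_genomes() itself).
offsets_suggest_normalization <- function(genomes, m = 15L, slack = 1000L) {
  lcs <- tryCatch(all_genome_lcs(genomes, circular = TRUE),
                  error = function(e) NULL)
  if (is.null(lcs) || lcs$depth < m) return(FALSE)
  any(lcs$occurrence - 1L > slack)
}

# Encode a character vector of sequences into one integer text with unique
# codes for Ns and sentinels; see src/core.cpp for the contract.
encode_seqs <- function(seqs) {
  n <- length(seqs)
  lens <- nchar(seqs)
  total <- sum(lens) + n
  code <- integer(total)
  gid <- integer(total)
  gpos <- integer(total)
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  nxt <- 5L
  at <- 1L
  for (g in seq_len(n)) {
    L <- lens[g]
    raw <- utf8ToInt(seqs[[g]])
    v <- lut[raw]
    ns <- which(v == 0L)
    if (length(ns) > 0) {
      v[ns] <- nxt + seq_along(ns) - 1L
      nxt <- nxt + length(ns)
    }
    idx <- at:(at + L - 1L)
    code[idx] <- v
    gid[idx] <- g
    gpos[idx] <- seq_len(L)
    at <- at + L
    code[at] <- nxt
    nxt <- nxt + 1L
    gid[at] <- 0L
    gpos[at] <- 0L
    at <- at + 1L
  }
  list(code = code, gid = gid, gpos = gpos)
}

# Global (concatenated) coordinates used by the union-find column builder:
# position j of genome i maps to cum_before[i] + j.
genome_cum_before <- function(genomes) {
  c(0L, cumsum(genomes$info$length))[seq_len(n_genomes(genomes))]
}
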