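---
title: "Partial-order alignment of functionally collinear phage genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-order alignment of functionally collinear phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phalign)
```

## The problem

Tailed bacteriophage genomes are mosaics. Biological functions are grouped
into modules whose order along the chromosome is strongly conserved —
lysogeny, DNA assembly, head, tail, lysis — but each module comes in
*variants* that perform the same function while sharing no detectable
sequence similarity. Horizontal exchange shuffles variants between strains,
so two phages can be nearly identical over one module and completely
dissimilar over the next. Score-based whole-genome aligners read that
dissimilarity as rearrangement or loss and either misalign the region or
refuse to align it; yet for these genomes the informative signal is the
*position* of a sequence, not its similarity.

`phalign` aligns sets of such genomes (typically 2–30 sequences of
30–60 kb) by exploiting *functional collinearity*: the assumption that
functions appear in the same order in every genome, up to a circular
permutation. The method uses only the equality relation — exact matches —
and one substantive parameter, the minimum match length $m$.

## The model

A *match* $M = \{G[s..t], H[u..v]\}$ asserts the base-wise equalities
$G[s]=H[u],\dots,G[t]=H[v]$ between two genomes. Given all maximal exact
matches of length $\ge m$ between all genome pairs, two positions are
*equivalent* when a match, or a chain of matches, links them. The
equivalence classes are the *columns* of the alignment; the *support* of a
column is the set of genomes contributing a position to it.

Columns are built with union-find (union by rank, path compression) over
the $N_\ell$ genome positions, at a cost proportional to the total match
length $M_\ell$. A column is *valid* when it holds at most one position per
genome. Invalid columns — the footprint of duplications and tandem repeats
— are split entirely into singleton columns. Splitting the whole column,
rather than only the multi-copy genome's positions, discards some pairings
that were individually consistent; it is the simplest rule that restores
validity, and duplicated segments simply remain unaligned.

The *column graph* links columns by per-genome adjacency: an edge runs from
one column to another for every genome whose consecutive positions fall in
them. The genome set is *functionally collinear* with respect to the
matches exactly when this graph is acyclic. Cycles are therefore not an
error but a finding: `check_collinear()` returns every nontrivial strongly
connected component (Tarjan, via igraph) with the genomic intervals
involved, which is how planted or real transpositions surface.

Runs of consecutive columns with identical support merge into the vertices
of the *expanded alignment graph*; each vertex is an exact alignment, and
the vertices tile every genome completely. Vertices are then *contracted*:
a pair $(U, V)$ with identical support is contractible when $U$ precedes
$V$ in the partial order, the support of every vertex between them is
contained in the support of $V$, and the base-pair spans from the start of
$U$ to the end of $V$ agree in every supported genome. A contracted vertex
is a gapless alignment; its *percent identity* is the fraction of columns
in which all supported genomes carry the same nucleotide.

*Anchors* are vertices supported by every genome; ordered along the
genomes they form the *backbone*. Because every genome passes through an
anchor, anchors are articulation points of the graph, and the region
between two anchors can be re-aligned on its own — usually at a much
smaller, automatically chosen $m$ (`realign_between()`).

## Parameters

* **`m` — minimum exact-match length** (bp, default 15). The only
  substantive parameter. Small values recover short homologies but risk
  spurious matches and cycles from chance repeats; the standard policy,
  implemented by `auto_m()`, is the smallest $m$ whose column graph is
  acyclic, searched upward from 15 (ceiling 500). Large values (for
  example 175 on large sets) give a sparse, highly reliable backbone for a
  first look at a data set.
* **Normalization** (`on` / `off` / `auto`). Database submissions of
  circular genomes start at arbitrary points. Normalization finds the
  longest substring common to all genomes — each searched as
  `seq + seq[1..L-1]`, depth capped at the shortest genome — and rotates
  every genome so it starts there. Ties are broken toward the smallest
  start position in the first genome, which makes the procedure
  deterministic and idempotent. The `auto` trigger (the criterion the
  original tool leaves unstated; ours is a documented heuristic) fires
  when the common substring does not start within 1 kb of position 1 in
  every genome, or when the column graph at the requested `m` is cyclic.
* **`mask_threshold`** (bp, default 20). Display only: vertices shorter
  than this are hidden in DOT output, and any edge hiding at least 1 bp is
  drawn dotted and annotated with the hidden count, so base-pair
  accounting survives masking.
* **Contraction cap** (`max_length`, default off). Without an upper bound
  a contracted vertex could, in principle, pair long same-length regions
  of low similarity; phage data are well behaved in this respect, so the
  cap is exposed but disabled by default.

## Numerical and design choices

* Identity display is **truncated**, not rounded: 167/169 = 98.8 % shows
  as `98%`. The exact rational (numerator and length) is kept on the
  vertex.
* `N` is accepted on input but never matches anything, including another
  `N`; a column containing `N` is never counted as conserved. This
  prevents masked regions from gluing columns together.
* Matches are inter-genome and forward-strand only. Self-matches would
  only create invalid columns that are immediately split; reverse-strand
  input is out of scope (same-strand input is required).
* Vertex ids are assigned along a canonical topological order (Kahn's
  algorithm, ties broken by the smallest coordinate in the lowest-index
  supported genome), so identical inputs give byte-identical outputs.
* Contraction scans that order greedily left to right, extending each
  chain as far as the contractibility conditions allow. "Between" is read
  as "on any directed path from $U$ to $V$"; the per-genome walk
  implements it because any vertex whose support stays inside the chain's
  support lies on a supported genome's path.
* Degenerate inputs: a single genome yields one singleton vertex per run;
  `m` larger than every genome yields an empty match set (not an error);
  an empty region between adjacent anchors re-aligns to an empty graph.

## The synthetic generator

`generate_mosaic()` produces the data every pipeline stage is tested on:
modules in conserved order, a pool of mutually dissimilar variants per
module, independent variant picks per genome (so the variant partition can
switch from one module to the next, the signature of horizontal exchange),
per-genome linkers between elements, planted universal blocks (the ground
truth for anchors), per-genome substitutions and 1–3 bp indels inside
modules, and optional planted transpositions and duplications.

Defaults are the package's study conditions: 6 genomes, 8 modules, 3
variants per module (tests also exercise 2), module lengths 150–300 bp,
linkers 30–60 bp, substitution rate 0.005/bp, indel rate 5e-4/bp, and
universal blocks of 120/150/180 bp — roughly the divergence of
closely related strains within a phage cluster, scaled to a few kb per
genome so a full run takes well under a second and whole test batteries
(50 oracle instances, 20 recovery seeds) finish in about a minute.

Two constructions turn with-high-probability properties into guarantees:

* **Unique-15-mer discipline.** All random sequence is drawn so that no
  15-mer occurs twice anywhere except inside deliberately shared pieces;
  junction windows are repaired and mutations that would create a
  duplicate 15-mer are redrawn or skipped. Since any exact match of
  length $\ge 15$ contains a shared 15-mer, distinct variants can never
  be linked, planted universal blocks are always recovered as anchors,
  and collinear instances are always acyclic at $m \ge 15$.
* **Flank pinning.** The bases flanking planted transposition blocks and
  duplication copies are set to one letter in ordinary genomes and a
  different one in the target genome, so cross-slot matches have exactly
  the planted length. A planted transposition of length $k$ is then
  cyclic for every $m \le k$ and acyclic at $k+1$, which is what makes
  `auto_m` land exactly one past the block length.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: chance repeats at the match scale (real
genomes have them; they surface as split columns and occasionally force a
larger $m$), sequence similarity between variants of a module (real
variants can be distant homologs rather than unrelated), phylogenetic
correlation between genomes, GC bias (a composition knob exists but
defaults to uniform), and capsid-scale genome sizes. The vertex counts
published for real phage datasets are reproducible only from the original
GenBank records, which the package reads from user-supplied FASTA; the
pipeline quantities logged by the CLI (`n`, $N_\ell$, $m$, $M_\ell$,
vertex counts) are exactly the ones tabulated in such studies.

## Known limitations

* Rearranged genomes are detected and reported, not aligned; aligning
  around rearrangements is future work in the underlying model.
* No gapped or scored alignment is ever produced inside contested
  regions; the method is exact-match-only by design.
* The MEM scan is output-sensitive: pathological repeat structures (long
  homopolymer runs shared across genomes) can make the candidate-pair
  scan quadratic. Phage-scale inputs are unproblematic.
* Genomes sequenced in opposite orientations must be re-oriented by the
  user; the aligner requires same-strand input.
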