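#' Retain reads mapping ambiguously within a repetitive locus
#'
#' Under the strict default policy a read is retained only when every one of
#' its alignments lies fully inside the locus interval — reads that also map
#' elsewhere would otherwise inflate the locus signal. The permissive policy
#' retains any read with at least one in-locus alignment. The retained read
#' count is the locus signal.
#'
#' @param alignments Tibble `read_id`, `chrom`, `start`, `end`, `n_align`
#'   (0-based half-open coordinates; `n_align` is the read's total alignment
#'   count).
#' @param locus List `chrom`, `start`, `end`.
#' @param policy `"strict"` (default) or `"permissive"`.
#' @return Character vector of retained read ids.
#' @export
retain_locus_reads <- function(alignments, locus,
                               policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  if (!nrow(alignments)) abort("Empty alignment set.")
  inside <- alignments$chrom == locus$chrom &
    alignments$start >= locus$start & alignments$end <= locus$end
  by_read <- tapply(inside, alignments$read_id, if (policy == "strict") all else any)
  sort(names(by_read)[by_read])
}

#' Fractional-weight coverage pile over a locus
#'
#' Each alignment of a retained read increments every covered position by
#' `1/N`, where `N` is the read's alignment count, so each read contributes
#' exactly one unit of its span in total mass.
#'
#' @inheritParams retain_locus_reads
#' @param retained Read ids to pile; defaults to
#'   `retain_locus_reads(alignments, locus)`.
#' @return Numeric vector over locus positions (named by the locus via
#'   attributes `chrom` and `start`); `sum()` of it is the pile mass.
#' @export
build_pile <- function(alignments, locus, retained = NULL) {
  if (is.null(retained)) retained <- retain_locus_reads(alignments, locus)
  aln <- alignments[alignments$read_id %in% retained, , drop = FALSE]
  width <- locus$end - locus$start
  pile <- numeric(width)
  for (i in seq_len(nrow(aln))) {
    s <- aln$start[i] - locus$start + 1
    e <- aln$end[i] - locus$start
    if (s < 1 || e > width || aln$chrom[i] != locus$chrom) {
      abort(sprintf("Alignment of %s lies outside the locus.", aln$read_id[i]))
    }
    pile[s:e] <- pile[s:e] + 1 / aln$n_align[i]
  }
  attr(pile, "chrom") <- locus$chrom
  attr(pile, "start") <- locus$start
  pile
}

comp_chars <- function(chars) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars]
}

#' Infer short insert fragments from adapter read-through
#'
#' For each read pair, finds the smallest candidate fragment length `f`
#' (1 to read length - 1) at which (i) the first `f` bases of read 1 equal
#' the reverse complement of the first `f` bases of read 2 and (ii) the
#' remainder of read 1 matches the adapter prefix over the available
#' overlap, both within `max_mismatch` mismatches. Pairs with no such `f`
#' (inserts at or beyond the read length) are reported unrecovered.
#'
#' @param pairs Tibble `pair_id`, `r1`, `r2` (equal-length reads).
#' @param adapter The read-1 sequencing adapter (at least 5 nt);
#'   default the TruSeq read-1 adapter.
#' @param max_mismatch Mismatches tolerated in each of the two checks
#'   (default 0).
#' @return Tibble `pair_id`, `length`, `sequence` of recovered fragments,
#'   with unrecovered pair ids in the `"unrecovered"` attribute.
#' @export
infer_fragments <- function(pairs, adapter = truseq_adapters()[["r1"]],
                            max_mismatch = 0) {
  if (nchar(adapter) < 5) abort("`adapter` must be at least 5 nt.")
  adapter_v <- strsplit(to_dna(adapter), "")[[1]]
  res <- purrr::pmap_dfr(pairs, function(pair_id, r1, r2, ...) {
    r1v <- strsplit(to_dna(r1), "")[[1]]
    r2v <- strsplit(to_dna(r2), "")[[1]]
    L <- length(r1v)
    if (length(r2v) != L) abort(sprintf("Pair %s: reads differ in length.", pair_id))
    c2 <- comp_chars(r2v)
    for (f in seq_len(L - 1)) {
      # (i) R1[1..f] vs revcomp(R2[1..f]) == reverse of complemented prefix
      mm1 <- sum(r1v[seq_len(f)] != c2[f:1])
      if (mm1 > max_mismatch) next
      ov <- min(length(adapter_v), L - f)
      mm2 <- sum(r1v[f + seq_len(ov)] != adapter_v[seq_len(ov)])
      if (mm2 > max_mismatch) next
      return(tibble(pair_id = pair_id, length = f,
                    sequence = paste(r1v[seq_len(f)], collapse = "")))
    }
    tibble(pair_id = pair_id, length = NA_integer_, sequence = NA_character_)
  })
  out <- res[!is.na(res$length), ]
  attr(out, "unrecovered") <- res$pair_id[is.na(res$length)]
  out
}

#' Count mature-sequence instances among inferred fragments, by length
#'
#' A fragment is an instance of the query when it contains the query
#' (fragments at least as long as the query) or is itself a substring of
#' the query (shorter fragments, e.g. a 22-bp fragment of a 23-nt mature
#' microRNA). Counts are reported as a fragment-length histogram.
#'
#' @param fragments Tibble `length`, `sequence` from [infer_fragments()].
#' @param query Mature sequence (DNA space), non-empty.
#' @return Tibble `length`, `count` (lengths with at least one instance).
#' @export
count_mature_instances <- function(fragments, query) {
  if (!nzchar(query)) abort("`query` must be non-empty.")
  query <- to_dna(query)
  if (!nrow(fragments)) return(tibble(length = integer(0), count = integer(0)))
  hit <- vapply(seq_len(nrow(fragments)), function(i) {
    sq <- to_dna(fragments$sequence[i])
    if (nchar(sq) >= nchar(query)) grepl(query, sq, fixed = TRUE)
    else grepl(sq, query, fixed = TRUE)
  }, logical(1))
  out <- fragments[hit, ] %>%
    dplyr::count(.data$length, name = "count") %>%
    dplyr::arrange(.data$length)
  attr(out, "unrecovered") <- NULL
  out
}
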