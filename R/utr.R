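#' RNA-element motifs matched in 3' UTRs
#'
#' The three destabilization-associated elements scanned in transcript-sense
#' DNA space: the 39-nt EDEN literal, the AU-rich element core `ATTA`, and
#' the YTHDF2 m6A context `RRACH` (IUPAC: R = A/G, H = A/C/T).
#'
#' @return Tibble `name`, `pattern`.
#' @export
element_motifs <- function() {
  tibble(
    name = c("EDEN", "ARE", "YTHDF2"),
    pattern = c("TATATATGTGTGTCTATCGTCACTTGTATGTCAAATATT", "ATTA", "RRACH")
  )
}

#' Default microRNA seed-match classes
#'
#' Windows of the mature microRNA (1-based, 5' to 3') whose reverse
#' complement is sought in UTRs: the canonical 7-mer (nt 2-8), the offset
#' 6-mer (nt 3-8) and the extended 8-mer (nt 2-9).
#'
#' @return Tibble `class`, `from`, `to`.
#' @export
default_seed_classes <- function() {
  tibble(class = c("canonical7", "offset6", "extended8"),
         from = c(2L, 3L, 2L), to = c(8L, 8L, 9L))
}

#' Minimum mismatch distance to the extended miR427 seed
#'
#' Minimum Hamming distance of `seed` to any equal-length window of the
#' reverse-complemented first 11 nt of miR427, `AAAGCACTTTC`; 0 means the
#' seed is an exact substring.
#'
#' @param seed Seed string in transcriptome (DNA) space, length <= 11.
#' @param reference Extended-seed reference (default `AAAGCACTTTC`).
#' @return Integer mismatch count.
#' @examples
#' mismatch_class("AGCACTT") # exact internal match: 0
#' @export
mismatch_class <- function(seed, reference = "AAAGCACTTTC") {
  seed <- to_dna(seed)
  k <- nchar(seed); n <- nchar(reference)
  if (k > n) abort("Seed longer than the extended reference.")
  s <- strsplit(seed, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  min(vapply(0:(n - k), function(off) {
    sum(s != r[seq_len(k) + off])
  }, integer(1)))
}

#' Build a microRNA seed catalog in transcriptome space
#'
#' For each mature microRNA and each seed class, extracts the class window,
#' reverse-complements it and exchanges U for T, yielding the string whose
#' perfect instances are counted in 3' UTRs; the minimum mismatch distance
#' to the extended miR427 seed is recorded per entry.
#'
#' @param mirnas Tibble `mirna_id`, `seq` (mature sequences, 5' to 3', RNA
#'   or DNA alphabet) or a named character vector.
#' @param classes Seed-class windows; default [default_seed_classes()].
#' @return Tibble `mirna_id`, `seed_class`, `seed`,
#'   `mismatch_to_mir427`.
#' @export
build_seed_catalog <- function(mirnas, classes = default_seed_classes()) {
  if (is.character(mirnas)) {
    mirnas <- tibble(mirna_id = names(mirnas), seq = unname(mirnas))
  }
  if (!all(c("mirna_id", "seq") %in% names(mirnas))) {
    abort("`mirnas` needs columns mirna_id and seq.")
  }
  purrr::pmap_dfr(mirnas, function(mirna_id, seq, ...) {
    sq <- to_dna(seq)
    purrr::pmap_dfr(classes, function(class, from, to) {
      if (nchar(sq) < to) {
        abort(sprintf("%s is shorter than the %s window (needs %d nt).",
                      mirna_id, class, to))
      }
      seed <- revcomp(substr(sq, from, to))
      tibble(mirna_id = mirna_id, seed_class = class, seed = seed,
             mismatch_to_mir427 = mismatch_class(seed))
    })
  })
}

#' Count perfect (possibly overlapping) pattern matches in sequences
#'
#' Slides the pattern over every start position; IUPAC codes in the pattern
#' are honored, while `N` in the subject sequence is literal and never
#' matches an unambiguous pattern base.
#'
#' @param sequences Character vector of DNA sequences.
#' @param pattern Literal or IUPAC pattern.
#' @param overlapping Count overlapping instances (default) or greedy
#'   non-overlapping ones.
#' @return Integer vector of counts.
#' @examples
#' count_matches("AAAGCACTTTAGCACTTT", "AGCACTTT")
#' @export
count_matches <- function(sequences, pattern, overlapping = TRUE) {
  if (!nzchar(pattern)) abort("`pattern` must be non-empty.")
  pattern <- to_dna(pattern)
  vapply(to_dna(sequences), function(sq) {
    if (nchar(sq) < nchar(pattern)) return(0L)
    hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(sq),
                                     fixed = c(pattern = FALSE, subject = TRUE))
    if (!overlapping && length(hits) > 1) {
      starts <- Biostrings::start(hits)
      keep <- 1L; last_end <- Biostrings::end(hits)[1]
      for (i in seq_along(starts)[-1]) {
        if (starts[i] > last_end) { keep <- c(keep, i); last_end <- Biostrings::end(hits)[i] }
      }
      length(keep)
    } else {
      length(hits)
    }
  }, integer(1), USE.NAMES = FALSE)
}

#' Per-gene motif/seed counts over isoform UTRs
#'
#' Counts pattern instances in each isoform's 3' UTR and aggregates to the
#' gene level, by default taking the maximum over isoforms (robust to
#' isoform-count inflation), optionally the sum.
#'
#' @param utrs Tibble `gene_id`, `isoform`, `seq`.
#' @param pattern Literal or IUPAC pattern.
#' @param aggregation `"max_over_isoforms"` (default) or
#'   `"sum_over_isoforms"`.
#' @param genes Optional gene universe; genes without a UTR record get
#'   count 0 with a warning.
#' @return Tibble `gene_id`, `count`.
#' @export
gene_level_counts <- function(utrs, pattern,
                              aggregation = c("max_over_isoforms",
                                              "sum_over_isoforms"),
                              genes = NULL) {
  aggregation <- match.arg(aggregation)
  if (!all(c("gene_id", "seq") %in% names(utrs))) {
    abort("`utrs` needs columns gene_id and seq.")
  }
  per_iso <- utrs %>%
    dplyr::mutate(count = count_matches(.data$seq, pattern))
  agg <- per_iso %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(count = if (aggregation == "max_over_isoforms") {
      max(.data$count)
    } else {
      sum(.data$count)
    }, .groups = "drop")
  if (!is.null(genes)) {
    missing <- setdiff(genes, agg$gene_id)
    if (length(missing)) {
      warn(sprintf("%d gene(s) have no UTR record; counted as 0.",
                   length(missing)))
      agg <- dplyr::bind_rows(agg, tibble(gene_id = missing, count = 0L))
    }
    agg <- agg[agg$gene_id %in% genes, ]
  }
  dplyr::arrange(agg, .data$gene_id)
}

#' Right-tail Fisher exact p-value for a 2x2 table
#'
#' Upper-tail hypergeometric probability `P(X >= a)` for the table
#' `rbind(c(a, b), c(c, d))` with fixed margins — the probability of seeing
#' at least `a` motif-bearing genes in the cluster by chance.
#'
#' @param a Cluster genes with the property.
#' @param b Cluster genes without it.
#' @param c_ Background genes with the property.
#' @param d Background genes without it.
#' @return p-value in `(0, 1]`.
#' @examples
#' fisher_right_tail(4, 1, 10, 85)
#' @export
fisher_right_tail <- function(a, b, c_, d) {
  cells <- c(a, b, c_, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("Table cells must be non-negative integers.")
  }
  if (sum(cells) == 0) abort("Empty contingency table.")
  # X ~ Hypergeometric(white = a + c_, black = b + d, drawn = a + b)
  stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
}

#' Cluster enrichment of motif/seed copy numbers
#'
#' For every pattern, cluster and copy-number threshold `N`, tests the
#' association between "gene has at least `N` copies" and cluster
#' membership against all other genes, reporting right-tail Fisher
#' p-values. Element motifs are conventionally tested at `N = 1` only;
#' microRNA seeds up to `N_max` (the miR427 signal peaks at high copy
#' numbers).
#'
#' @param cluster_map Tibble `gene_id`, `cluster`; genes with `NA` or
#'   `"background"` cluster form part of the background for every test. The
#'   map must cover the filtered gene universe.
#' @param counts Tibble `gene_id`, `count` (one pattern), or `gene_id`,
#'   `pattern`, `count` for several.
#' @param N_max Largest copy-number threshold tested (default 6).
#' @return Long tibble: `pattern`, `cluster`, `N`, `a`, `b`, `c`, `d`, `p`,
#'   `neglog10p`.
#' @export
enrichment_matrix <- function(cluster_map, counts, N_max = 6) {
  if (N_max < 1) abort("`N_max` must be at least 1.")
  if (!all(c("gene_id", "cluster") %in% names(cluster_map))) {
    abort("`cluster_map` needs columns gene_id and cluster.")
  }
  if (!"pattern" %in% names(counts)) counts$pattern <- "pattern"
  missing <- setdiff(cluster_map$gene_id, unique(counts$gene_id))
  if (length(missing)) {
    abort(sprintf("Counts missing for gene(s): %s.",
                  paste(utils::head(missing, 3), collapse = ", ")))
  }
  counts <- counts[counts$gene_id %in% cluster_map$gene_id, ]
  clusters <- setdiff(unique(cluster_map$cluster), c(NA, "background"))
  n_universe <- nrow(cluster_map)
  purrr::map_dfr(unique(counts$pattern), function(pat) {
    cnt <- counts[counts$pattern == pat, ]
    cnt <- cnt$count[match(cluster_map$gene_id, cnt$gene_id)]
    purrr::map_dfr(clusters, function(cl) {
      in_cl <- !is.na(cluster_map$cluster) & cluster_map$cluster == cl
      purrr::map_dfr(seq_len(N_max), function(N) {
        has <- cnt >= N
        a <- sum(in_cl & has); b <- sum(in_cl & !has)
        c_ <- sum(!in_cl & has); d <- n_universe - a - b - c_
        p <- fisher_right_tail(a, b, c_, d)
        tibble(pattern = pat, cluster = cl, N = N,
               a = a, b = b, c = c_, d = d,
               p = p, neglog10p = -log10(p))
      })
    })
  })
}
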