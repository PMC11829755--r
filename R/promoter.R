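#' Position weight matrix from a count matrix
#'
#' Converts per-position base counts to probabilities with a
#' background-distributed pseudocount:
#' `p = (count + pseudocount * background) / (total + pseudocount)`.
#'
#' @param counts 4-row numeric matrix (rows A, C, G, T; one column per
#'   position).
#' @param pseudocount Total pseudocount per column (default 0.8, spread by
#'   the background).
#' @param background Genome base frequencies, named A/C/G/T, summing to 1.
#' @param name Motif name.
#' @param log_base Base of the log-likelihood-ratio scores (default 2).
#' @return A `pwm` object.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.8,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            name = "motif", log_base = 2) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L) {
    abort("`counts` must be a 4-row matrix with at least one position.")
  }
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  background <- background[c("A", "C", "G", "T")]
  if (abs(sum(background) - 1) > 1e-9) abort("`background` must sum to 1.")
  totals <- colSums(counts)
  if (any(totals == 0) && pseudocount == 0) {
    abort("Zero-total column with zero pseudocount.")
  }
  probs <- sweep(counts + pseudocount * background, 2,
                 totals + pseudocount, "/")
  structure(list(name = name, mat = probs, background = background,
                 width = ncol(probs), log_base = log_base),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s', width %d, max score %.2f (log base %g)\n",
              x$name, x$width, pwm_max_score(x), x$log_base))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm A [pwm_from_counts()] object.
#' @return The per-position argmax base string (the highest-scoring site).
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$mat)[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' Maximum attainable PWM score
#'
#' @param pwm A `pwm` object.
#' @return Sum over positions of the best per-position log ratio.
#' @export
pwm_max_score <- function(pwm) {
  lr <- log(pwm$mat / pwm$background, base = pwm$log_base)
  sum(apply(lr, 2, max))
}

#' Likelihood-ratio score of one site
#'
#' `sum over positions of log(p_motif(base) / p_background(base))`; an `N`
#' base contributes 0 (scored as background).
#'
#' @param pwm A `pwm` object.
#' @param site Sequence of length `pwm$width`.
#' @return Numeric score.
#' @export
score_site <- function(pwm, site) {
  site <- to_dna(site)
  if (nchar(site) != pwm$width) abort("`site` length must equal the PWM width.")
  bases <- strsplit(site, "")[[1]]
  lr <- log(pwm$mat / pwm$background, base = pwm$log_base)
  sum(vapply(seq_along(bases), function(i) {
    if (bases[i] == "N") 0 else lr[bases[i], i]
  }, numeric(1)))
}

# score every window of one sequence; returns numeric(0) if too short
scan_scores <- function(pwm, sq) {
  sq <- to_dna(sq)
  n <- nchar(sq); w <- pwm$width
  if (n < w) return(numeric(0))
  lr <- log(pwm$mat / pwm$background, base = pwm$log_base)
  lr <- rbind(lr, N = 0)
  b <- strsplit(sq, "")[[1]]
  b[!b %in% c("A", "C", "G", "T")] <- "N"
  # per-base score at each (sequence position, motif position)
  idx <- match(b, rownames(lr))
  sc <- vapply(seq_len(w), function(j) lr[cbind(idx, j)], numeric(n))
  vapply(seq_len(n - w + 1), function(s) {
    sum(sc[cbind(s:(s + w - 1), seq_len(w))])
  }, numeric(1))
}

#' Maximal motif score over a gene's promoters
#'
#' Scores every window of every promoter of the gene — on both strands by
#' default — and returns the maximum.
#'
#' @param pwm A `pwm` object.
#' @param promoter_seqs Character vector of the gene's promoter sequences.
#' @param strands `"both"` (default) or `"forward"`.
#' @return Maximal score (scalar).
#' @export
gene_max_score <- function(pwm, promoter_seqs, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (any(nchar(promoter_seqs) < pwm$width)) {
    abort("A promoter is shorter than the PWM width.")
  }
  seqs <- promoter_seqs
  if (strands == "both") seqs <- c(seqs, revcomp(promoter_seqs))
  max(unlist(lapply(seqs, function(sq) scan_scores(pwm, sq))))
}

#' Per-gene maximal PWM scores over a promoter table
#'
#' @param pwm A `pwm` object.
#' @param promoters Tibble `gene_id`, `seq` (one row per promoter; genes may
#'   have several).
#' @inheritParams gene_max_score
#' @return Tibble `gene_id`, `score`.
#' @export
gene_scores <- function(pwm, promoters, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  promoters %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(score = gene_max_score(pwm, .data$seq, strands),
                     .groups = "drop")
}

#' Select the motif score threshold maximizing cluster association
#'
#' Candidate thresholds are every distinct observed gene score above
#' `min_threshold`; for each, the right-tail Fisher p of the 2x2 table
#' (score at or above threshold x gene in any cluster) is computed, and the
#' threshold with minimal p is chosen (ties resolved toward the lower
#' threshold).
#'
#' @param scores Tibble `gene_id`, `score` for the full filtered universe.
#' @param in_any_cluster Logical vector aligned with `scores`, or a
#'   character vector of clustered gene ids.
#' @param min_threshold Thresholds must exceed this value (default 5).
#' @param motif Motif name carried into the result.
#' @return One-row tibble: `motif`, `threshold`, `max_score_observed`, `p`.
#' @export
optimize_threshold <- function(scores, in_any_cluster, min_threshold = 5,
                               motif = "motif") {
  if (is.character(in_any_cluster)) {
    in_any_cluster <- scores$gene_id %in% in_any_cluster
  }
  stopifnot(length(in_any_cluster) == nrow(scores))
  cand <- sort(unique(scores$score[scores$score > min_threshold]))
  if (!length(cand)) abort("No score exceeds `min_threshold`.")
  ps <- vapply(cand, function(t) {
    above <- scores$score >= t
    fisher_right_tail(sum(above & in_any_cluster),
                      sum(!above & in_any_cluster),
                      sum(above & !in_any_cluster),
                      sum(!above & !in_any_cluster))
  }, numeric(1))
  best <- which(ps == min(ps))[1]  # ties -> lower threshold (cand is sorted)
  tibble(motif = motif, threshold = cand[best],
         max_score_observed = max(scores$score), p = ps[best])
}

#' Per-cluster enrichment of above-threshold motif scores
#'
#' At the selected threshold, treats "maximal score at or above threshold"
#' as the gene property and tests each cluster against the rest of the
#' filtered universe by right-tail Fisher exact test.
#'
#' @param scores Tibble `gene_id`, `motif`, `score` (or `gene_id`, `score`
#'   for one motif).
#' @param thresholds Tibble `motif`, `threshold` from [optimize_threshold()].
#' @param cluster_map Tibble `gene_id`, `cluster` over the same universe.
#' @return Long tibble: `pattern` (motif), `cluster`, `a`, `b`, `c`, `d`,
#'   `p`, `neglog10p`.
#' @export
cluster_enrichment_at_threshold <- function(scores, thresholds, cluster_map) {
  if (!"motif" %in% names(scores)) scores$motif <- thresholds$motif[1]
  counts <- scores %>%
    dplyr::inner_join(thresholds, by = "motif") %>%
    dplyr::transmute(gene_id = .data$gene_id, pattern = .data$motif,
                     count = as.integer(.data$score >= .data$threshold))
  enrichment_matrix(cluster_map, counts, N_max = 1) %>%
    dplyr::select(-"N")
}

#' Read JASPAR-style count matrices
#'
#' Parses the 4-row text format: a `>name` header followed by lines
#' `A [ 1 2 3 ]` (brackets optional) for A, C, G, T.
#'
#' @param path Path to the text file (may hold several matrices).
#' @return Named list of 4-row count matrices.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) abort("No '>' header found.")
  out <- list()
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    end <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[(heads[i] + 1):end]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      list(base = parts[1], counts = as.numeric(parts[-1]))
    })
    m <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(m) <- vapply(rows, `[[`, character(1), "base")
    out[[name]] <- m
  }
  out
}
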