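#' Simulation configuration for a two-condition developmental time course
#'
#' Describes the study design the generator emulates: uninjected-control
#' (UIC) versus morphant (MO) embryos sampled at regular intervals (default
#' 20 timepoints at 0.5 h spacing, i.e. half-hourly sampling across ~10 h of
#' development), for one or both library types (polyA-selected and
#' rRNA-depleted).
#'
#' `cluster_spec` is a list of planted trajectory classes; each element is a
#' list with `label`, `n_genes`, `family` (one of `"maternal_decay"`,
#' `"zygotic_sigmoid"`, `"constant"`), `onset` (hours; when the MO trajectory
#' starts diverging) and `effect` (fold-effect of the divergence; for
#' maternal decay this is the late-time fold-elevation of MO over UIC, with
#' `Inf` meaning clearance fully blocked; for zygotic activation it scales
#' the activated amplitude). Genes not covered by `cluster_spec` are null:
#' UIC and MO share the trajectory law exactly.
#'
#' @param n_genes Total genes simulated.
#' @param n_timepoints Number of timepoints (default 20).
#' @param t_spacing Spacing in hours (default 0.5).
#' @param cluster_spec List of planted classes (see Details); empty for an
#'   all-null population.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   expression noise (default 0.1).
#' @param seed RNG seed; all outputs are deterministic given it.
#' @param library_types Character subset of `c("polyA", "ribozero")`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 600, n_timepoints = 20, t_spacing = 0.5,
                       cluster_spec = default_cluster_spec(),
                       noise_cv = 0.1, seed = 1L,
                       library_types = c("polyA", "ribozero")) {
  if (n_timepoints < 1) abort("`n_timepoints` must be positive.")
  if (t_spacing <= 0) abort("`t_spacing` must be positive.")
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")
  library_types <- match.arg(library_types, c("polyA", "ribozero"),
                             several.ok = TRUE)
  planted <- sum(vapply(cluster_spec, function(cs) cs$n_genes, numeric(1)))
  if (planted > n_genes) {
    abort("cluster_spec gene counts exceed `n_genes`; the remainder must be null.")
  }
  for (cs in cluster_spec) {
    if (!cs$family %in% c("maternal_decay", "zygotic_sigmoid", "constant")) {
      abort(sprintf("Unknown trajectory family '%s'.", cs$family))
    }
  }
  structure(list(n_genes = n_genes, n_timepoints = n_timepoints,
                 t_spacing = t_spacing, cluster_spec = cluster_spec,
                 noise_cv = noise_cv, seed = seed,
                 library_types = library_types),
            class = "sim_config")
}

#' Default planted trajectory classes
#'
#' Three increased-direction clusters (maternal transcripts whose clearance
#' is blocked in the morphant from early, mid and late onsets) and three
#' decreased-direction clusters (zygotic genes whose activation is damped),
#' mirroring the U1-U3 / D1-D3 cluster structure of a
#' maternal-to-zygotic-transition time course.
#'
#' @param n_per_cluster Genes per planted class (default 30).
#' @return A list usable as `cluster_spec` in [sim_config()].
#' @export
default_cluster_spec <- function(n_per_cluster = 30) {
  list(
    list(label = "U1", n_genes = n_per_cluster, family = "maternal_decay",
         onset = 2, effect = 8),
    list(label = "U2", n_genes = n_per_cluster, family = "maternal_decay",
         onset = 4.5, effect = 8),
    list(label = "U3", n_genes = n_per_cluster, family = "maternal_decay",
         onset = 7, effect = 8),
    list(label = "D1", n_genes = n_per_cluster, family = "zygotic_sigmoid",
         onset = 2, effect = 0.1),
    list(label = "D2", n_genes = n_per_cluster, family = "zygotic_sigmoid",
         onset = 4.5, effect = 0.1),
    list(label = "D3", n_genes = n_per_cluster, family = "zygotic_sigmoid",
         onset = 6, effect = 0.1)
  )
}

# deterministic UIC trajectory for a family over times t (hours)
base_trajectory <- function(family, t) {
  hi <- 100; lo <- 1
  switch(family,
    maternal_decay = lo + (hi - lo) * (1 - stats::plogis((t - 4) / 0.7)),
    zygotic_sigmoid = lo + (hi - lo) * stats::plogis((t - 5) / 0.7),
    constant = rep(50, length(t)),
    abort(sprintf("Unknown trajectory family '%s'.", family))
  )
}

# MO trajectory given the UIC one: divergence begins at `onset`
mo_trajectory <- function(family, t, uic, onset, effect) {
  mo <- uic
  idx <- t >= onset
  if (!any(idx)) return(mo)
  if (family == "maternal_decay") {
    # clearance damped: MO never falls below `effect` x UIC, capped at the
    # level held when divergence began (effect = Inf blocks clearance fully)
    hold <- uic[which(idx)[1]]
    mo[idx] <- pmax(uic[idx], pmin(effect * uic[idx], hold))
  } else if (family == "zygotic_sigmoid") {
    # activation proceeds normally until the onset, then further gains are
    # scaled by `effect` (0 = fully blocked); continuous at the onset
    u0 <- uic[which(idx)[1]]
    mo[idx] <- u0 + (uic[idx] - u0) * effect
  } else {
    mo[idx] <- uic[idx] * effect
  }
  mo
}

#' Simulate a two-condition expression time course with planted truth
#'
#' Generates TPM matrices for each requested library type: deterministic
#' per-gene trajectories (shared between library types) times independent
#' multiplicative lognormal noise with the configured coefficient of
#' variation. Null genes follow the identical trajectory law in both
#' conditions, so they differ only by noise.
#'
#' @param config A [sim_config()] object.
#' @return A list with `datasets` (named list of long tibbles with columns
#'   `gene_id`, `condition`, `time`, `tpm`, one per library type), `truth`
#'   (tibble `gene_id`, `cluster`, `family`, `onset`, `effect`; `cluster` is
#'   `NA` for null genes) and `config`.
#' @export
simulate_timecourse <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config().")
  t <- seq(0, by = config$t_spacing, length.out = config$n_timepoints)
  n <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))

  # assign genes to planted classes, remainder null
  truth <- tibble(gene_id = gene_ids, cluster = NA_character_,
                  family = "maternal_decay", onset = NA_real_,
                  effect = NA_real_)
  i <- 1L
  for (cs in config$cluster_spec) {
    idx <- seq(i, length.out = cs$n_genes)
    truth$cluster[idx] <- cs$label
    truth$family[idx] <- cs$family
    truth$onset[idx] <- cs$onset
    truth$effect[idx] <- cs$effect
    i <- i + cs$n_genes
  }
  if (i <= n) {
    # null genes cycle through the families with no MO effect
    fams <- c("maternal_decay", "zygotic_sigmoid", "constant")
    truth$family[i:n] <- fams[((i:n) - i) %% 3 + 1]
  }

  uic_mat <- t(vapply(seq_len(n), function(g) base_trajectory(truth$family[g], t),
                      numeric(length(t))))
  mo_mat <- uic_mat
  for (g in which(!is.na(truth$cluster))) {
    mo_mat[g, ] <- mo_trajectory(truth$family[g], t, uic_mat[g, ],
                                 truth$onset[g], truth$effect[g])
  }

  sigma <- sqrt(log(1 + config$noise_cv^2))
  datasets <- with_seed(config$seed, {
    out <- list()
    for (lib in config$library_types) {
      noisy <- function(mat) {
        if (sigma > 0) mat * exp(matrix(stats::rnorm(length(mat), 0, sigma),
                                        nrow = nrow(mat))) else mat
      }
      u <- noisy(uic_mat); m <- noisy(mo_mat)
      ds <- dplyr::bind_rows(
        tidyr::expand_grid(gene_id = gene_ids, time = t) %>%
          dplyr::mutate(condition = "UIC", tpm = as.vector(t(u))),
        tidyr::expand_grid(gene_id = gene_ids, time = t) %>%
          dplyr::mutate(condition = "MO", tpm = as.vector(t(m)))
      ) %>% dplyr::select("gene_id", "condition", "time", "tpm")
      attr(ds, "library_type") <- lib
      out[[lib]] <- ds
    }
    out
  })
  list(datasets = datasets, truth = truth, config = config)
}

#' Simulate 3' UTR sequences with planted seed-match copies
#'
#' Emits one UTR per gene containing exactly the requested number of
#' non-overlapping copies of its planted seed; background positions are
#' i.i.d. with configurable base frequencies and the whole sequence is
#' rejection-sampled until no chance copy of any planted seed remains, so
#' planted counts are exact by construction.
#'
#' @param copy_spec Tibble with columns `gene_id`, `seed` (DNA string, may
#'   be `NA` for 0 copies), `copies` (non-negative integer).
#' @param utr_len UTR length in nt (default 200).
#' @param rng_seed RNG seed.
#' @param base_freqs Background base probabilities, named A/C/G/T.
#' @return List with `utrs` (tibble `gene_id`, `isoform`, `seq`) and `truth`
#'   (the `copy_spec` as planted).
#' @export
simulate_utrs <- function(copy_spec, utr_len = 200, rng_seed = 1L,
                          base_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  need <- c("gene_id", "seed", "copies")
  if (!all(need %in% names(copy_spec))) {
    abort("`copy_spec` needs columns gene_id, seed, copies.")
  }
  seeds <- unique(stats::na.omit(copy_spec$seed))
  klens <- nchar(seeds)
  bad <- copy_spec$copies > 0 &
    (is.na(copy_spec$seed) | nchar(copy_spec$seed) * copy_spec$copies > utr_len)
  if (any(bad)) {
    abort(sprintf("UTR length %d too short for the requested copies of gene %s.",
                  utr_len, copy_spec$gene_id[which(bad)[1]]))
  }
  utrs <- with_seed(rng_seed, {
    purrr::pmap_dfr(copy_spec, function(gene_id, seed, copies, ...) {
      sq <- plant_copies(if (is.na(seed)) "" else seed, copies, utr_len,
                         base_freqs, avoid = seeds)
      tibble(gene_id = gene_id, isoform = paste0(gene_id, ".1"), seq = sq)
    })
  })
  list(utrs = utrs, truth = as_tibble(copy_spec))
}

# build one sequence of length len with exactly `copies` non-overlapping
# copies of `motif`, and no chance occurrence of any sequence in `avoid`
plant_copies <- function(motif, copies, len, base_freqs, avoid = motif,
                         max_tries = 1000) {
  bases <- names(base_freqs)
  k <- nchar(motif)
  avoid <- avoid[nzchar(avoid)]
  for (try in seq_len(max_tries)) {
    sq <- paste(sample(bases, len, replace = TRUE, prob = base_freqs),
                collapse = "")
    if (copies > 0) {
      starts <- sample_nonoverlapping(len, k, copies)
      if (is.null(starts)) next
      for (s in starts) substr(sq, s, s + k - 1) <- motif
    }
    counts <- vapply(avoid, function(p) {
      Biostrings::countPattern(p, Biostrings::DNAString(sq))
    }, integer(1))
    want <- vapply(avoid, function(p) if (copies > 0 && p == motif) copies else 0L,
                   integer(1))
    if (all(counts == want)) return(sq)
  }
  abort("Could not place the requested copies without chance matches.")
}

# sample `copies` non-overlapping start positions for a k-mer in 1..len-k+1
sample_nonoverlapping <- function(len, k, copies, max_tries = 200) {
  for (try in seq_len(max_tries)) {
    s <- sort(sample.int(len - k + 1, copies))
    if (copies == 1 || all(diff(s) >= k)) return(s)
  }
  NULL
}

#' Simulate promoter sequences with planted consensus sites
#'
#' A configurable fraction of genes receives one copy of the PWM's consensus
#' sequence at a recorded offset on the forward strand; the remaining
#' promoters are background, rejection-sampled so neither strand contains
#' the consensus by chance.
#'
#' @param gene_ids Character vector of genes (one promoter each).
#' @param pwm A [pwm_from_counts()] object; its consensus is planted.
#' @param planted_fraction Fraction of genes planted, in `[0, 1]`. The
#'   planted count is `round(planted_fraction * length(gene_ids))`.
#' @param rng_seed RNG seed.
#' @param width Promoter width in bp (default 500, the region immediately
#'   upstream of the transcription start).
#' @param base_freqs Background base probabilities.
#' @return List with `promoters` (tibble `gene_id`, `promoter_id`, `seq`)
#'   and `truth` (tibble `gene_id`, `planted`, `offset`).
#' @export
simulate_promoters <- function(gene_ids, pwm, planted_fraction, rng_seed = 1L,
                               width = 500,
                               base_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  if (planted_fraction < 0 || planted_fraction > 1) {
    abort("`planted_fraction` must lie in [0, 1].")
  }
  cons <- pwm_consensus(pwm)
  k <- nchar(cons)
  if (width < k) abort("Promoter width shorter than the motif.")
  n <- length(gene_ids)
  n_plant <- round(planted_fraction * n)
  with_seed(rng_seed, {
    planted_idx <- if (n_plant > 0) sample.int(n, n_plant) else integer(0)
    avoid <- c(cons, revcomp(cons))
    rows <- purrr::map_dfr(seq_len(n), function(i) {
      if (i %in% planted_idx) {
        sq <- plant_copies(cons, 1L, width, base_freqs, avoid = avoid)
        # plant_copies chooses the offset; recover it for the truth record
        off <- as.integer(Biostrings::start(
          Biostrings::matchPattern(cons, Biostrings::DNAString(sq)))[1])
        tibble(gene_id = gene_ids[i], seq = sq, planted = TRUE, offset = off)
      } else {
        sq <- plant_copies("", 0L, width, base_freqs, avoid = avoid)
        tibble(gene_id = gene_ids[i], seq = sq, planted = FALSE,
               offset = NA_integer_)
      }
    })
    list(promoters = tibble(gene_id = rows$gene_id,
                            promoter_id = paste0(rows$gene_id, ".p1"),
                            seq = rows$seq),
         truth = tibble(gene_id = rows$gene_id, planted = rows$planted,
                        offset = rows$offset))
  })
}

#' Simulate multi-mapping read alignments over a repetitive locus
#'
#' Each in-locus read receives `N` alignment records (drawn from
#' `multiplicity_dist`) placed uniformly within the locus; optional
#' out-of-locus reads have all alignments beyond the locus end, emulating
#' reads whose ambiguity lies elsewhere in the genome.
#'
#' @param n_reads Number of in-locus reads.
#' @param multiplicity_dist Named numeric vector: `P(N = k)` for alignment
#'   counts `k >= 1` (names are the counts).
#' @param locus_interval List/vector `(chrom, start, end)`, 0-based
#'   half-open.
#' @param read_span Alignment span in bp.
#' @param rng_seed RNG seed.
#' @param n_outside Reads with every alignment outside the locus.
#' @return List with `alignments` (tibble `read_id`, `chrom`, `start`,
#'   `end`, `n_align`), `locus`, and `truth` (tibble with the in-locus read
#'   count and per-read multiplicities).
#' @export
simulate_locus_alignments <- function(n_reads, multiplicity_dist = c("1" = 0.25, "2" = 0.25, "4" = 0.5),
                                      locus_interval = list(chrom = "Chr03", start = 133185000, end = 133320000),
                                      read_span = 150, rng_seed = 1L,
                                      n_outside = 0) {
  loc <- as.list(locus_interval)
  names(loc) <- c("chrom", "start", "end")[seq_along(loc)]
  loc$start <- as.numeric(loc$start); loc$end <- as.numeric(loc$end)
  if (loc$end - loc$start < read_span) abort("Locus shorter than `read_span`.")
  ks <- as.integer(names(multiplicity_dist))
  if (any(ks < 1)) abort("Alignment multiplicities must be >= 1.")
  with_seed(rng_seed, {
    recs <- list(); truth_n <- integer(0)
    for (i in seq_len(n_reads)) {
      N <- ks[sample.int(length(ks), 1, prob = multiplicity_dist)]
      starts <- loc$start + sample.int(loc$end - loc$start - read_span + 1, N,
                                       replace = FALSE) - 1
      recs[[length(recs) + 1L]] <- tibble(
        read_id = sprintf("read%06d", i), chrom = loc$chrom,
        start = starts, end = starts + read_span, n_align = N)
      truth_n[i] <- N
    }
    for (j in seq_len(n_outside)) {
      N <- ks[sample.int(length(ks), 1, prob = multiplicity_dist)]
      starts <- loc$end + 10000 + sample.int(1e6, N)
      recs[[length(recs) + 1L]] <- tibble(
        read_id = sprintf("out%06d", j), chrom = loc$chrom,
        start = starts, end = starts + read_span, n_align = N)
    }
    list(alignments = dplyr::bind_rows(recs), locus = loc,
         truth = list(n_in_locus = n_reads,
                      multiplicity = truth_n, read_span = read_span))
  })
}

#' Standard Illumina TruSeq adapter sequences
#'
#' @return Named character vector with elements `r1` and `r2`.
#' @export
truseq_adapters <- function() {
  c(r1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
    r2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")
}

#' Simulate paired-end reads with adapter read-through
#'
#' Fragments shorter than the read length cause read-through: read 1 is the
#' fragment followed by the read-1 adapter (padded with `pad_base` to the
#' read length), and read 2 is the reverse complement of the fragment
#' followed by the read-2 adapter, likewise padded. Fragments of the read
#' length or longer produce non-overlapping pairs marked unrecoverable.
#'
#' @param fragments Character vector of fragment sequences (DNA).
#' @param adapters Named vector `c(r1 =, r2 =)`; default [truseq_adapters()].
#' @param read_len Read length (default 150).
#' @param pad_base Base used to pad beyond the adapter.
#' @return List with `pairs` (tibble `pair_id`, `r1`, `r2`) and `truth`
#'   (tibble `pair_id`, `length`, `fragment`, `recoverable`).
#' @export
simulate_read_pairs <- function(fragments, adapters = truseq_adapters(),
                                read_len = 150, pad_base = "A") {
  fragments <- to_dna(fragments)
  pad_to <- function(x, n) {
    if (nchar(x) >= n) substr(x, 1, n)
    else paste0(x, strrep(pad_base, n - nchar(x)))
  }
  rows <- purrr::imap_dfr(fragments, function(fr, i) {
    len <- nchar(fr)
    if (len < read_len) {
      r1 <- pad_to(paste0(fr, adapters[["r1"]]), read_len)
      r2 <- pad_to(paste0(revcomp(fr), adapters[["r2"]]), read_len)
      rec <- TRUE
    } else {
      r1 <- substr(fr, 1, read_len)
      r2 <- substr(revcomp(fr), 1, read_len)
      rec <- FALSE
    }
    tibble(pair_id = sprintf("pair%05d", i), r1 = r1, r2 = r2,
           length = len, fragment = fr, recoverable = rec)
  })
  list(pairs = rows[, c("pair_id", "r1", "r2")],
       truth = rows[, c("pair_id", "length", "fragment", "recoverable")])
}
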