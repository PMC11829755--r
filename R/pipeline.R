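#' Mature miR427 sequence (DNA space)
#'
#' The 23-nt mature guide whose extended 8-mer seed match (`AGCACTTT`) and
#' extended 11-nt reverse-complement region (`AAAGCACTTTC`) drive the UTR
#' enrichment analyses.
#'
#' @return Character scalar.
#' @export
mir427_mature <- function() "GAAAGTGCTTTCTGTTTTGGGCG"

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' transform offsets `alpha = 1`, `beta = 1000`; expressed-gene filter
#' `min_tpm = 0.4` over runs of `run_len = 6`; GP hyperpriors; LR calling at
#' the `lr_rate = 0.005` null quantile (calibrated from `n_null` simulated
#' null genes unless a fixed `lr_threshold` is given); silhouette selection
#' over `k_range = 2:10`; seed copy-number thresholds up to `N_max = 6`;
#' PWM scores in log base 2 with thresholds above 5; strict ambiguous-read
#' retention; global seed 1618033.
#'
#' @param sim A [sim_config()] for `--simulate` runs.
#' @param alpha,beta VST offsets.
#' @param min_tpm,run_len Expressed-gene filter parameters.
#' @param priors [gp_priors()] for the GP stage.
#' @param lr_rate Target null false-call rate for the LR threshold.
#' @param lr_threshold Fixed LR cutoff; `NULL` to calibrate from nulls.
#' @param n_null Null genes used for calibration.
#' @param k_range Candidate cluster numbers.
#' @param N_max Largest seed copy-number threshold.
#' @param score_log_base Log base for PWM scores.
#' @param min_score_threshold PWM thresholds must exceed this (default 5).
#' @param retention_policy `"strict"` or `"permissive"` locus-read
#'   retention.
#' @param seed Global seed.
#' @param stages Stages to run, in order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(seed = 1618033),
                            alpha = 1, beta = 1000,
                            min_tpm = 0.4, run_len = 6,
                            priors = gp_priors(),
                            lr_rate = 0.005, lr_threshold = NULL,
                            n_null = 200,
                            k_range = 2:10, N_max = 6,
                            score_log_base = 2, min_score_threshold = 5,
                            retention_policy = "strict",
                            seed = 1618033,
                            stages = c("filter", "gp", "cluster", "utr",
                                       "promoter", "locus")) {
  if (run_len > sim$n_timepoints) {
    abort("`run_len` exceeds the number of timepoints in the design.")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a YAML pipeline configuration
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim`
#' block mirrors [sim_config()]. Absent keys take the defaults, which are
#' the analysis defaults throughout.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (is.null(sim_args$cluster_spec) && !is.null(sim_args$n_genes)) {
    # scale the default planted classes to the requested population
    sim_args$cluster_spec <- default_cluster_spec(
      max(1L, floor(sim_args$n_genes / 12)))
  }
  y$sim <- do.call(sim_config, sim_args)
  if (!is.null(y$priors)) y$priors <- do.call(gp_priors, y$priors)
  do.call(pipeline_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on simulated inputs
#'
#' Executes the stages in order — expressed-gene filter, GP
#' likelihood-ratio testing with a null-calibrated threshold, trajectory
#' clustering, 3' UTR seed/motif enrichment, promoter PWM enrichment, and
#' repetitive-locus read quantification — writing every stage output plus a
#' machine-readable manifest (seeds, parameter values, file hashes) to
#' `outdir`. Deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @param outdir Run directory (created if needed).
#' @return `outdir`, invisibly; see [report_summary()].
#' @export
run_pipeline <- function(config, outdir = tempfile("gptide_run_")) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message(sprintf(...))

  sim <- simulate_timecourse(config$sim)
  truth <- sim$truth
  for (lib in names(sim$datasets)) {
    write_tpm_table(sim$datasets[[lib]], file.path(outdir, paste0("tpm_", lib, ".tsv")))
  }

  keep <- unique(truth$gene_id)
  if ("filter" %in% config$stages) {
    log_line("stage filter: run of %d samples with TPM > %g",
             config$run_len, config$min_tpm)
    keep <- filter_expressed(sim$datasets, config$min_tpm, config$run_len)
    writeLines(keep, file.path(outdir, "expressed_genes.txt"))
  }

  de <- NULL; traj <- NULL; clusters <- NULL; lr_thr <- config$lr_threshold
  if ("gp" %in% config$stages) {
    if (is.null(lr_thr)) {
      log_line("stage gp: calibrating LR threshold on %d null genes", config$n_null)
      lr_thr <- as.numeric(null_lr_threshold(
        n_sim = config$n_null, rate = config$lr_rate,
        rng_seed = config$seed, priors = config$priors,
        alpha = config$alpha, beta = config$beta))
    }
    log_line("stage gp: LR testing %d genes (threshold %.3f)", length(keep), lr_thr)
    de <- gp_de(sim$datasets[[1]], keep, config$priors,
                alpha = config$alpha, beta = config$beta,
                lr_threshold = lr_thr)
    utils::write.table(de, file.path(outdir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("cluster" %in% config$stages && !is.null(de)) {
    called <- de[de$called, ]
    log_line("stage cluster: %d called genes", nrow(called))
    if (nrow(called) > max(config$k_range) + 1) {
      traj <- gp_trajectories(sim$datasets[[1]], called$gene_id,
                              config$priors, config$alpha, config$beta)
      utils::write.table(traj, file.path(outdir, "trajectories.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      k_fixed <- NULL
      by_dir <- table(called$direction)
      if (any(by_dir <= max(config$k_range))) k_fixed <- 2
      clusters <- cluster_trajectories(traj, called, k = k_fixed,
                                       k_range = config$k_range,
                                       rng_seed = config$seed)
      utils::write.table(clusters, file.path(outdir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("utr" %in% config$stages) {
    # plant the extended miR427 seed in truth-U1 genes so the enrichment
    # stage has recoverable signal, background elsewhere
    catalog <- build_seed_catalog(tibble(mirna_id = "miR427",
                                         seq = mir427_mature()))
    seed8 <- catalog$seed[catalog$seed_class == "extended8"]
    copy_spec <- tibble(
      gene_id = keep,
      seed = seed8,
      copies = ifelse(keep %in% truth$gene_id[which(truth$cluster == "U1")], 6L, 0L))
    utr_sim <- simulate_utrs(copy_spec, rng_seed = config$seed)
    write_fasta(utr_sim$utrs, file.path(outdir, "utrs.fa"))
    cl_map <- if (!is.null(clusters)) {
      tibble(gene_id = keep) %>%
        dplyr::left_join(clusters[, c("gene_id", "cluster")], by = "gene_id")
    } else {
      tibble(gene_id = keep,
             cluster = ifelse(keep %in% truth$gene_id[which(truth$cluster == "U1")],
                              "U1", NA))
    }
    pats <- dplyr::bind_rows(
      tibble(name = paste0("miR427_", catalog$seed_class), pattern = catalog$seed),
      element_motifs())
    counts <- purrr::map_dfr(seq_len(nrow(pats)), function(i) {
      gene_level_counts(utr_sim$utrs, pats$pattern[i], genes = keep) %>%
        dplyr::mutate(pattern = pats$name[i])
    })
    enr <- enrichment_matrix(cl_map, counts, N_max = config$N_max)
    utils::write.table(enr, file.path(outdir, "utr_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("stage utr: %d enrichment cells", nrow(enr))
  }

  if ("promoter" %in% config$stages) {
    pwm <- example_pwm(log_base = config$score_log_base)
    cl_map <- if (!is.null(clusters)) {
      tibble(gene_id = keep) %>%
        dplyr::left_join(clusters[, c("gene_id", "cluster")], by = "gene_id")
    } else {
      tibble(gene_id = keep,
             cluster = ifelse(keep %in% truth$gene_id[!is.na(truth$cluster)],
                              truth$cluster[match(keep, truth$gene_id)], NA))
    }
    planted_genes <- cl_map$gene_id[!is.na(cl_map$cluster)]
    prom_sim <- simulate_promoters(keep, pwm,
                                   planted_fraction = 0, rng_seed = config$seed)
    # plant consensus into clustered genes' promoters
    cons <- pwm_consensus(pwm)
    idx <- prom_sim$promoters$gene_id %in% planted_genes
    prom_sim$promoters$seq[idx] <- vapply(prom_sim$promoters$seq[idx], function(sq) {
      substr(sq, 100, 100 + nchar(cons) - 1) <- cons; sq
    }, character(1), USE.NAMES = FALSE)
    write_fasta(prom_sim$promoters, file.path(outdir, "promoters.fa"))
    sc <- gene_scores(pwm, prom_sim$promoters) %>%
      dplyr::mutate(motif = pwm$name)
    thr <- optimize_threshold(sc, planted_genes,
                              min_threshold = config$min_score_threshold,
                              motif = pwm$name)
    prom_enr <- cluster_enrichment_at_threshold(sc, thr, cl_map)
    utils::write.table(thr, file.path(outdir, "motif_thresholds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(prom_enr, file.path(outdir, "promoter_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("stage promoter: threshold %.2f (max %.2f)",
             thr$threshold, thr$max_score_observed)
  }

  if ("locus" %in% config$stages) {
    aln_sim <- simulate_locus_alignments(
      n_reads = 500, rng_seed = config$seed,
      locus_interval = list(chrom = "Chr03", start = 133185000, end = 133320000),
      n_outside = 100)
    write_bed_alignments(aln_sim$alignments, file.path(outdir, "alignments.bed"))
    retained <- retain_locus_reads(aln_sim$alignments, aln_sim$locus,
                                   policy = config$retention_policy)
    pile <- build_pile(aln_sim$alignments, aln_sim$locus, retained)
    write_bedgraph(pile, file.path(outdir, "locus_pile.bedgraph"))
    writeLines(as.character(length(retained)),
               file.path(outdir, "locus_signal.txt"))
    frag_lens <- c(22, 22, 23, 23, 24, 24, 24, 24)
    frs <- vapply(seq_along(frag_lens), function(i) {
      substr(paste0(mir427_mature(), "A"), 1, frag_lens[i])
    }, character(1))
    pr <- simulate_read_pairs(frs)
    write_fastq_pairs(pr$pairs, file.path(outdir, "reads"))
    frags <- infer_fragments(pr$pairs)
    hist <- count_mature_instances(frags, mir427_mature())
    utils::write.table(hist, file.path(outdir, "fragment_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("stage locus: %d retained reads, pile mass %.1f",
             length(retained), sum(pile))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gptide")),
    seed = config$seed,
    parameters = list(alpha = config$alpha, beta = config$beta,
                      min_tpm = config$min_tpm, run_len = config$run_len,
                      lr_rate = config$lr_rate, lr_threshold = lr_thr,
                      k_range = config$k_range, N_max = config$N_max,
                      score_log_base = config$score_log_base,
                      min_score_threshold = config$min_score_threshold,
                      retention_policy = config$retention_policy,
                      noise_cv = config$sim$noise_cv,
                      n_genes = config$sim$n_genes,
                      n_timepoints = config$sim$n_timepoints),
    stages = config$stages,
    files = {
      fs <- setdiff(list.files(outdir), "manifest.json")
      stats::setNames(lapply(fs, function(f) {
        unname(tools::md5sum(file.path(outdir, f)))
      }), fs)
    }
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

# small worked-example PWM with a 10-bp consensus, for simulated runs
example_pwm <- function(log_base = 2) {
  cons <- "TGACGTCATG"
  bases <- c("A", "C", "G", "T")
  counts <- sapply(strsplit(cons, "")[[1]], function(b) {
    v <- rep(2, 4); names(v) <- bases; v[b] <- 24; v
  })
  pwm_from_counts(counts, name = "example", log_base = log_base)
}

#' Summarize a completed pipeline run
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Tibble `metric`, `value`: called genes by direction, cluster
#'   sizes, the top UTR enrichment cell, locus signal. Also written to
#'   `summary.tsv` in the run directory.
#' @export
report_summary <- function(run_dir) {
  if (!file.exists(file.path(run_dir, "manifest.json"))) {
    abort("`run_dir` has no manifest; incomplete run.")
  }
  rows <- list()
  de_path <- file.path(run_dir, "differential.tsv")
  if (file.exists(de_path)) {
    de <- utils::read.table(de_path, header = TRUE, sep = "\t")
    called <- de[which(de$called), ]
    rows$called_increased <- sum(called$direction == "increased")
    rows$called_decreased <- sum(called$direction == "decreased")
  }
  cl_path <- file.path(run_dir, "clusters.tsv")
  if (file.exists(cl_path)) {
    cl <- utils::read.table(cl_path, header = TRUE, sep = "\t")
    for (nm in sort(unique(cl$cluster))) {
      rows[[paste0("cluster_", nm, "_size")]] <- sum(cl$cluster == nm)
    }
  }
  enr_path <- file.path(run_dir, "utr_enrichment.tsv")
  if (file.exists(enr_path)) {
    enr <- utils::read.table(enr_path, header = TRUE, sep = "\t")
    top <- enr[which.max(enr$neglog10p), ]
    rows$top_utr_enrichment_neglog10p <- top$neglog10p
  }
  sig_path <- file.path(run_dir, "locus_signal.txt")
  if (file.exists(sig_path)) {
    rows$locus_signal_reads <- as.numeric(readLines(sig_path))
  }
  out <- tibble(metric = names(rows), value = as.numeric(unlist(rows)))
  utils::write.table(out, file.path(run_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
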