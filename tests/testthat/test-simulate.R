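test_that("null genes are identical across conditions without noise, and runs are deterministic", {
  cfg <- sim_config(n_genes = 100, cluster_spec = list(), noise_cv = 0,
                    seed = 7, library_types = "polyA")
  sim <- simulate_timecourse(cfg)
  ds <- sim$datasets$polyA
  wide <- tidyr::pivot_wider(ds, names_from = condition, values_from = tpm)
  expect_equal(wide$UIC, wide$MO)
  expect_true(all(is.na(sim$truth$cluster)))

  cfg2 <- sim_config(n_genes = 50, noise_cv = 0.2, seed = 7,
                     cluster_spec = default_cluster_spec(5))
  expect_identical(simulate_timecourse(cfg2), simulate_timecourse(cfg2))
})

test_that("blocked maternal clearance keeps MO at or above UIC from the onset", {
  cfg <- sim_config(n_genes = 1, noise_cv = 0, seed = 1, library_types = "polyA",
                    cluster_spec = list(list(label = "U1", n_genes = 1,
                                             family = "maternal_decay",
                                             onset = 2, effect = Inf)))
  ds <- simulate_timecourse(cfg)$datasets$polyA
  w <- tidyr::pivot_wider(ds, names_from = condition, values_from = tpm)
  late <- w$time >= 2
  expect_true(all(w$MO[late] >= w$UIC[late]))
  expect_equal(w$MO[!late], w$UIC[!late])
})

test_that("simulation config contracts are enforced", {
  expect_error(sim_config(n_timepoints = 0), "positive")
  expect_error(sim_config(n_genes = 5, cluster_spec = default_cluster_spec(30)),
               "exceed")
  expect_error(sim_config(cluster_spec = list(list(label = "x", n_genes = 1,
                                                   family = "nope",
                                                   onset = 1, effect = 1))),
               "family")
})

test_that("planted UTR seed copies are exact and recoverable by scanning", {
  spec <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    seed = "AGCACTTT",
    copies = rep(c(6L, 0L), each = 50))
  sim <- simulate_utrs(spec, utr_len = 200, rng_seed = 11)
  counts <- count_matches(sim$utrs$seq, "AGCACTTT")
  expect_equal(counts, spec$copies)
  expect_equal(sum(counts), 300L)

  one <- simulate_utrs(tibble::tibble(gene_id = "g", seed = "AGCACTTT",
                                      copies = 2L),
                       utr_len = 60, rng_seed = 3)
  expect_equal(count_matches(one$utrs$seq, "AGCACTTT"), 2L)
  expect_error(simulate_utrs(tibble::tibble(gene_id = "g", seed = "AGCACTTT",
                                            copies = 9L), utr_len = 60),
               "too short")
})

test_that("promoter planting matches the requested fraction and consensus scores maximally", {
  pwm <- pwm_from_counts(matrix(c(20, 1, 1, 1), 4, 8,
                                dimnames = list(c("A", "C", "G", "T"), NULL)),
                         name = "polyA8")
  sim <- simulate_promoters(sprintf("g%d", 1:200), pwm, 0.25, rng_seed = 3)
  expect_equal(sum(sim$truth$planted), 50)
  cons <- pwm_consensus(pwm)
  expect_equal(count_matches(sim$promoters$seq, cons),
               as.integer(sim$truth$planted))

  all_planted <- simulate_promoters(sprintf("g%d", 1:10), pwm, 1, rng_seed = 5)
  scores <- gene_scores(pwm, all_planted$promoters)$score
  expect_equal(scores, rep(pwm_max_score(pwm), 10), tolerance = 1e-12)

  none <- simulate_promoters(sprintf("g%d", 1:20), pwm, 0, rng_seed = 9)
  expect_equal(sum(count_matches(none$promoters$seq, cons)), 0L)
  expect_error(simulate_promoters("g", pwm, 1.5), "\\[0, 1\\]")
})

test_that("simulated alignments respect the locus and the multiplicity record", {
  sim <- simulate_locus_alignments(
    n_reads = 10, multiplicity_dist = c("1" = 1),
    locus_interval = list(chrom = "c", start = 0, end = 5000),
    read_span = 100, rng_seed = 2)
  pile <- build_pile(sim$alignments, sim$locus)
  expect_equal(sum(pile), 10 * 100)

  sim4 <- simulate_locus_alignments(
    n_reads = 1, multiplicity_dist = c("4" = 1),
    locus_interval = list(chrom = "c", start = 0, end = 5000),
    read_span = 100, rng_seed = 2)
  pile4 <- build_pile(sim4$alignments, sim4$locus)
  # each of the 4 alignments contributes 1/4 per position (overlaps stack)
  expect_true(all(as.numeric(pile4) %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_equal(sum(pile4), 100)

  expect_error(simulate_locus_alignments(
    1, c("1" = 1), list(chrom = "c", start = 0, end = 50), read_span = 100),
    "shorter")
})

test_that("read pairs encode the fragment, the adapter and the boundary case", {
  fr <- mir427_mature()  # 23 nt
  pr <- simulate_read_pairs(fr, read_len = 150)
  r1 <- pr$pairs$r1[1]
  expect_equal(substr(r1, 1, 23), fr)
  ad <- truseq_adapters()[["r1"]]
  expect_equal(substr(r1, 24, 23 + nchar(ad)), ad)
  expect_equal(nchar(r1), 150)
  expect_equal(substr(pr$pairs$r2[1], 1, 23), revcomp(fr))

  exact <- simulate_read_pairs(strrep("ACGT", 10), read_len = 40)
  expect_equal(exact$pairs$r1[1], strrep("ACGT", 10))
  expect_false(exact$truth$recoverable[1])
})
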