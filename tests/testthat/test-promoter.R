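toy_pwm <- function(width = 2, pA = 0.8, log_base = 2) {
  counts <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", ] <- pA * 100
  counts["C", ] <- (1 - pA) / 3 * 100
  counts["G", ] <- (1 - pA) / 3 * 100
  counts["T", ] <- (1 - pA) / 3 * 100
  pwm_from_counts(counts, pseudocount = 0, log_base = log_base)
}

test_that("PWM probabilities follow the pseudocount arithmetic", {
  m <- matrix(c(10, 0, 0, 0), 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  p0 <- pwm_from_counts(m, pseudocount = 0)
  expect_equal(unname(p0$mat["A", ]), rep(1, 3))
  flat <- pwm_from_counts(matrix(5, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(unname(flat$mat), matrix(0.25, 4, 2))
  m2 <- matrix(c(3, 1, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  p1 <- pwm_from_counts(m2, pseudocount = 1)
  expect_equal(unname(p1$mat["A", 1]), 3.25 / 5)
  expect_error(pwm_from_counts(matrix(0, 4, 1), pseudocount = 0), "Zero-total")
})

test_that("site scoring is the summed log likelihood ratio", {
  flat <- pwm_from_counts(matrix(5, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(score_site(flat, "ACG"), 0)
  pwm <- toy_pwm()
  expect_equal(score_site(pwm, "AA"), 2 * log2(3.2), tolerance = 1e-12)
  expect_equal(score_site(pwm, "AA"), 3.3561, tolerance = 1e-4)
  # consensus maximality over all width-2 sites
  sites <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  scores <- vapply(sites, function(s) score_site(pwm, s), numeric(1))
  expect_equal(max(scores), score_site(pwm, pwm_consensus(pwm)))
  expect_equal(pwm_max_score(pwm), max(scores), tolerance = 1e-12)
  expect_error(score_site(pwm, "AAA"), "width")
  # N contributes zero
  expect_equal(score_site(pwm, "AN"), log2(3.2), tolerance = 1e-12)
})

test_that("scoring agrees with a per-position oracle on random PWMs and sites", {
  set.seed(13)
  for (i in 1:50) {
    w <- sample(3:10, 1)
    counts <- matrix(stats::rexp(4 * w) * 20, 4,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    bg <- stats::rexp(4) + 0.2; bg <- bg / sum(bg); names(bg) <- c("A", "C", "G", "T")
    pwm <- pwm_from_counts(counts, pseudocount = 0.8, background = bg)
    site <- random_dna(1, w)
    bases <- strsplit(site, "")[[1]]
    want <- sum(vapply(seq_len(w), function(j) {
      log2(pwm$mat[bases[j], j] / bg[bases[j]])
    }, numeric(1)))
    expect_equal(score_site(pwm, site), want, tolerance = 1e-9)
  }
})

test_that("gene max score is invariant to promoter order and strand", {
  pwm <- toy_pwm(width = 6, pA = 0.9)
  cons <- pwm_consensus(pwm)
  set.seed(17)
  bg1 <- gsub("A", "C", random_dna(1, 100))  # A-free background
  bg2 <- gsub("A", "G", random_dna(1, 100))
  planted <- paste0(substr(bg1, 1, 40), cons, substr(bg1, 47, 100))
  expect_equal(gene_max_score(pwm, c(planted, bg2)), pwm_max_score(pwm))
  expect_equal(gene_max_score(pwm, c(bg2, planted)),
               gene_max_score(pwm, c(planted, bg2)))
  # reverse-strand plant is found with strands = "both" only
  rc_planted <- revcomp(planted)
  expect_equal(gene_max_score(pwm, rc_planted), pwm_max_score(pwm))
  expect_lt(gene_max_score(pwm, rc_planted, strands = "forward"),
            pwm_max_score(pwm))
  expect_error(gene_max_score(pwm, "ACG"), "shorter")
})

test_that("threshold optimization matches an exhaustive re-scan and beats permuted labels", {
  set.seed(23)
  n <- 200
  in_cl <- c(rep(TRUE, 40), rep(FALSE, 160))
  scores <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    score = ifelse(in_cl, 12, stats::runif(n, 0, 4)))
  scores$score[sample(which(!in_cl), 10)] <- stats::runif(10, 5.5, 9)
  thr <- optimize_threshold(scores, in_cl)
  expect_gt(thr$threshold, 5)
  expect_lte(thr$threshold, 12)
  expect_lt(thr$p, 0.05)
  expect_equal(thr$max_score_observed, 12)
  # oracle: exhaustive scan over all distinct scores > 5
  cand <- sort(unique(scores$score[scores$score > 5]))
  ps <- vapply(cand, function(t) {
    a <- sum(scores$score >= t & in_cl); b <- sum(scores$score < t & in_cl)
    c_ <- sum(scores$score >= t & !in_cl); d <- sum(scores$score < t & !in_cl)
    fisher_enum_oracle(a, b, c_, d)
  }, numeric(1))
  expect_equal(thr$p, min(ps), tolerance = 1e-12)
  expect_equal(thr$threshold, cand[which(ps == min(ps))[1]])
  # permuted labels do no better
  set.seed(29)
  perm <- optimize_threshold(scores, sample(in_cl))
  expect_gte(perm$p, thr$p)
  low <- scores; low$score <- pmin(low$score, 4)
  expect_error(optimize_threshold(low, in_cl), "exceeds")
})

test_that("cluster enrichment at threshold recovers the planted cluster", {
  n <- 300
  cl_map <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    cluster = c(rep("A", 40), rep("B", 40), rep(NA, 220)))
  scores <- tibble::tibble(
    gene_id = cl_map$gene_id, motif = "m",
    score = c(rep(10, 40), rep(1, 260)))
  thr <- tibble::tibble(motif = "m", threshold = 6)
  enr <- cluster_enrichment_at_threshold(scores, thr, cl_map)
  expect_equal(enr$cluster[which.min(enr$p)], "A")
  expect_true(all(enr$a + enr$b + enr$c + enr$d == n))
  # nothing above threshold -> p = 1 everywhere
  none <- cluster_enrichment_at_threshold(
    dplyr::mutate(scores, score = 0), thr, cl_map)
  expect_true(all(none$p == 1))
})

test_that("JASPAR-style count matrices round-trip through the reader", {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.1 testmotif",
               "A [ 10  2  0 ]",
               "C [  0  3  1 ]",
               "G [  5  5  9 ]",
               "T [  0  5  5 ]"), path)
  mats <- read_jaspar(path)
  expect_named(mats, "MA0000.1")
  expect_equal(mats[[1]]["A", ], c(10, 2, 0))
  expect_equal(unname(colSums(mats[[1]])), c(15, 15, 15))
  pwm <- pwm_from_counts(mats[[1]], name = "MA0000.1")
  expect_equal(pwm$width, 3)
})
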