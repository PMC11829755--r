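toy_locus <- list(chrom = "c", start = 1000, end = 2000)

aln <- function(read_id, starts, n = length(starts), span = 50,
                chrom = "c") {
  tibble::tibble(read_id = read_id, chrom = chrom, start = starts,
                 end = starts + span, n_align = n)
}

test_that("locus retention policies treat partially outside reads differently", {
  inside <- aln("r1", c(1100, 1200, 1300, 1400))
  mixed <- dplyr::bind_rows(aln("r2", c(1100, 1200, 1300), n = 4),
                            aln("r2", 5000, n = 4))
  outside <- aln("r3", c(5000, 6000))
  all_aln <- dplyr::bind_rows(inside, mixed, outside)
  expect_equal(retain_locus_reads(all_aln, toy_locus), "r1")
  expect_equal(retain_locus_reads(all_aln, toy_locus, policy = "permissive"),
               c("r1", "r2"))
  expect_equal(retain_locus_reads(outside, toy_locus), character(0))
  expect_error(retain_locus_reads(inside[0, ], toy_locus), "Empty")
})

test_that("1/N piles conserve one unit of span per read", {
  one <- aln("r1", 1100, n = 1, span = 100)
  pile <- build_pile(one, toy_locus)
  expect_equal(sum(pile), 100)
  expect_equal(sort(unique(as.numeric(pile))), c(0, 1))

  four <- aln("r1", c(1100, 1250, 1400, 1550), n = 4, span = 100)
  pile4 <- build_pile(four, toy_locus)
  expect_equal(sum(pile4), 100)
  expect_equal(max(pile4), 0.25)

  sim <- simulate_locus_alignments(
    n_reads = 10, locus_interval = toy_locus, read_span = 50, rng_seed = 5)
  p <- build_pile(sim$alignments, sim$locus)
  expect_equal(sum(p), 10 * 50)

  bad <- aln("r1", 5000, n = 1)
  expect_error(build_pile(bad, toy_locus, retained = "r1"), "outside")
})

test_that("retention and piles recover simulator truth exactly", {
  sim <- simulate_locus_alignments(
    n_reads = 40, locus_interval = toy_locus, read_span = 30, rng_seed = 8,
    n_outside = 25)
  kept <- retain_locus_reads(sim$alignments, sim$locus)
  expect_equal(length(kept), sim$truth$n_in_locus)
  expect_true(all(grepl("^read", kept)))
  pile <- build_pile(sim$alignments, sim$locus, kept)
  expect_equal(sum(pile), sim$truth$n_in_locus * sim$truth$read_span)
})

test_that("fragment inference recovers the mature miR427 construction", {
  pr <- simulate_read_pairs(mir427_mature(), read_len = 150)
  fr <- infer_fragments(pr$pairs)
  expect_equal(fr$length, 23L)
  expect_equal(fr$sequence, mir427_mature())
  # fragment of the read length is unrecoverable
  pr2 <- simulate_read_pairs(random_dna(1, 150), read_len = 150)
  fr2 <- infer_fragments(pr2$pairs)
  expect_equal(nrow(fr2), 0)
  expect_equal(attr(fr2, "unrecovered"), "pair00001")
  expect_error(infer_fragments(pr$pairs, adapter = "ACGT"), "5 nt")
})

test_that("mature-sequence counting reports the planted length histogram", {
  q <- mir427_mature()
  frs <- c(substr(q, 1, 22), substr(q, 2, 23),          # 22-mers within query
           q, q,                                        # exact 23-mers
           paste0(q, "A"), paste0(q, "C"),
           paste0("G", q), paste0(q, "T"))              # 24-mers containing it
  pairs <- simulate_read_pairs(frs, read_len = 150)
  got <- count_mature_instances(infer_fragments(pairs$pairs), q)
  expect_equal(got, tibble::tibble(length = c(22L, 23L, 24L),
                                   count = c(2L, 2L, 4L)))
  none <- count_mature_instances(
    tibble::tibble(length = 20L, sequence = strrep("C", 20)), q)
  expect_equal(nrow(none), 0)
  expect_error(count_mature_instances(tibble::tibble(), ""), "non-empty")
})

test_that("sequence files round-trip: FASTA, FASTQ pairs, BED, bedGraph", {
  utrs <- tibble::tibble(gene_id = c("g1", "g2"), isoform = c("g1.1", "g2.1"),
                         seq = random_dna(2, 60))
  fa <- tempfile(fileext = ".fa")
  write_fasta(utrs, fa)
  expect_equal(read_fasta(fa), utrs)

  pairs <- simulate_read_pairs(random_dna(3, 40), read_len = 80)$pairs
  fq <- tempfile()
  write_fastq_pairs(pairs, fq)
  expect_equal(read_fastq_pairs(paste0(fq, "_R1.fastq"),
                                paste0(fq, "_R2.fastq")), pairs)

  sim <- simulate_locus_alignments(5, locus_interval = toy_locus,
                                   read_span = 30, rng_seed = 3)
  bed <- tempfile(fileext = ".bed")
  write_bed_alignments(sim$alignments, bed)
  expect_equal(read_bed_alignments(bed), sim$alignments)

  pile <- build_pile(sim$alignments, sim$locus)
  bg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(pile, bg)
  df <- utils::read.table(bg)
  expect_equal(sum((df$V3 - df$V2) * df$V4), sum(pile))
})
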